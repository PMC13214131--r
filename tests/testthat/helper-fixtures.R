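# Shared fixtures and small independent oracles used across test files.

# Small phantom spec that renders quickly.
tiny_spec <- function(...) phantomSpec(gridShape = c(32L, 32L, 32L), ...)

# A compact segmenter configuration whose full forward/backward runs in well
# under a second (window 1 keeps every stage grid divisible).
tiny_seg_config <- function(...) {
  segConfig(inShape = c(16L, 16L, 16L), numClasses = 3L, embedDim = 4L,
            depths = c(1L, 1L, 1L, 1L), heads = c(1L, 2L, 4L, 8L),
            window = 1L, convFilters = c(4L, 4L, 8L, 8L),
            groupnormGroups = 2L, ...)
}

# A trainable mid-size segmenter config (32-cube, window 2).
small_seg_config <- function(...) {
  segConfig(inShape = c(32L, 32L, 32L), numClasses = 5L, embedDim = 8L,
            depths = c(1L, 1L, 1L, 1L), heads = c(1L, 2L, 4L, 8L),
            window = 2L, convFilters = c(6L, 8L, 12L, 16L),
            groupnormGroups = 4L, ...)
}

tiny_cae_config <- function(...) {
  caeConfig(inShape = c(8L, 8L, 8L), encFilters = c(3L, 4L, 6L),
            latentDim = 8L, ...)
}

# Independent dense multi-head attention oracle: full attention over all
# tokens, computed directly from the projection matrices.
dense_attention_oracle <- function(x, params, heads) {
  C <- ncol(x)
  dh <- C %/% heads
  qkv <- sweep(x %*% params$Wqkv, 2, params$bqkv, "+")
  out <- matrix(0, nrow(x), C)
  for (h in seq_len(heads)) {
    qc <- (h - 1) * dh + seq_len(dh)
    Q <- qkv[, qc, drop = FALSE]
    K <- qkv[, C + qc, drop = FALSE]
    V <- qkv[, 2 * C + qc, drop = FALSE]
    S <- Q %*% t(K) / sqrt(dh)
    A <- exp(S - apply(S, 1, max))
    A <- A / rowSums(A)
    out[, qc] <- A %*% V
  }
  sweep(out %*% params$Wo, 2, params$bo, "+")
}

# Independent O(n^2) HD95 oracle: plain-R surface extraction and all-pairs
# distances, sharing only the stated definition with the implementation.
hd95_oracle <- function(pred, gt, spacing = c(1, 1, 1)) {
  surf <- function(m) {
    d <- dim(m)
    out <- NULL
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (m[i, j, k] == 0) next
      nb <- list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                 c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
      exposed <- FALSE
      for (p in nb) {
        if (any(p < 1) || p[1] > d[1] || p[2] > d[2] || p[3] > d[3]) {
          exposed <- TRUE
        } else if (m[p[1], p[2], p[3]] == 0) exposed <- TRUE
      }
      if (exposed) out <- rbind(out, c(i, j, k) - 1)
    }
    out
  }
  sa <- surf(pred)
  sb <- surf(gt)
  dmat <- outer(seq_len(nrow(sa)), seq_len(nrow(sb)), Vectorize(function(a, b)
    sqrt(sum(((sa[a, ] - sb[b, ]) * spacing)^2))))
  pooled <- c(apply(dmat, 1, min), apply(dmat, 2, min))
  unname(quantile(pooled, 0.95, type = 7))
}

# Same oracle with vectorized distance algebra (still independent of the
# package's C++ nearest-neighbour loop); usable on 16^3 masks at scale.
hd95_oracle_fast <- function(pred, gt, spacing = c(1, 1, 1)) {
  surf_coords <- function(m) {
    d <- dim(m)
    keep <- NULL
    idx <- which(m != 0, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      v <- idx[r, ]
      exposed <- FALSE
      for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1))) {
        p <- v + s
        if (any(p < 1) || p[1] > d[1] || p[2] > d[2] || p[3] > d[3] ||
            m[p[1], p[2], p[3]] == 0) { exposed <- TRUE; break }
      }
      if (exposed) keep <- rbind(keep, v - 1)
    }
    keep
  }
  A <- sweep(surf_coords(pred), 2, spacing, "*")
  B <- sweep(surf_coords(gt), 2, spacing, "*")
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  dm <- sqrt(d2)
  pooled <- c(apply(dm, 1, min), apply(dm, 2, min))
  unname(quantile(pooled, 0.95, type = 7))
}

# Plain-R flood fill from the grid border over zero voxels; voxels not
# reached and not foreground are interior holes.
flood_fill_outside <- function(mask) {
  d <- dim(mask)
  outside <- array(FALSE, d)
  queue <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if ((i == 1 || j == 1 || k == 1 || i == d[1] || j == d[2] || k == d[3]) &&
        mask[i, j, k] == 0) {
      queue <- rbind(queue, c(i, j, k))
      outside[i, j, k] <- TRUE
    }
  }
  while (!is.null(queue) && nrow(queue) > 0) {
    v <- queue[1, , drop = TRUE]
    queue <- queue[-1, , drop = FALSE]
    for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      p <- v + s
      if (any(p < 1) || p[1] > d[1] || p[2] > d[2] || p[3] > d[3]) next
      if (!outside[p[1], p[2], p[3]] && mask[p[1], p[2], p[3]] == 0) {
        outside[p[1], p[2], p[3]] <- TRUE
        queue <- rbind(queue, p)
      }
    }
  }
  outside
}
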