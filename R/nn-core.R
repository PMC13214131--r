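# Native neural-network primitives with hand-written backpropagation.
#
# Feature maps are dense N x C matrices (N = prod(dims) voxels in column-major
# x,y,z order) so that convolution and attention reduce to BLAS matrix
# products over im2col buffers. Every *_f returns list(y, ...cache...) and the
# matching *_b consumes the cache and returns the input gradient plus
# parameter gradients. Correctness is established by finite-difference tests.

vox_matrix <- function(arr) {
  d <- dim(arr)
  if (length(d) == 3L) matrix(as.numeric(arr), ncol = 1L)
  else matrix(as.numeric(arr), nrow = prod(d[1:3]), ncol = d[4])
}

mat_to_array <- function(x, dims) {
  if (ncol(x) == 1L) array(x, dim = dims) else array(x, dim = c(dims, ncol(x)))
}

#' Derive a child seed from a base seed and integer indices
#'
#' Folds the indices into the base seed with a multiplicative-congruential
#' hash, yielding well-separated reproducible streams that stay strictly
#' inside the positive 32-bit integer range.
#'
#' @param seed Base integer seed.
#' @param ... Integer indices identifying the child stream.
#' @return A positive integer seed below 2^31.
#' @export
deriveSeed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + as.double(k) * 16807 + 12345) %% 2147483647
  }
  as.integer(s %% 2147483646) + 1L
}

conv_out_dims <- function(dims, k, s, p) (dims + 2L * p - k) %/% s + 1L

init_conv <- function(k, cin, cout, gain = 2) {
  fan_in <- k^3 * cin
  list(W = matrix(rnorm(fan_in * cout, sd = sqrt(gain / fan_in)),
                  nrow = fan_in, ncol = cout),
       b = numeric(cout))
}

init_convT <- function(k, cin, cout, gain = 2) {
  # weight laid out as the equivalent (out -> in) convolution: (k^3*cout) x cin
  fan_in <- k^3 * cin
  list(W = matrix(rnorm(k^3 * cout * cin, sd = sqrt(gain / fan_in)),
                  nrow = k^3 * cout, ncol = cin),
       b = numeric(cout))
}

init_dense <- function(cin, cout, sd = sqrt(2 / cin)) {
  list(W = matrix(rnorm(cin * cout, sd = sd), nrow = cin, ncol = cout),
       b = numeric(cout))
}

init_norm <- function(C) list(gamma = rep(1, C), beta = numeric(C))

init_attn <- function(C, sd = 0.02) {
  list(Wqkv = matrix(rnorm(C * 3 * C, sd = sd), nrow = C, ncol = 3 * C),
       bqkv = numeric(3 * C),
       Wo = matrix(rnorm(C * C, sd = sd), nrow = C, ncol = C),
       bo = numeric(C))
}

# ---- convolution -----------------------------------------------------------

conv3d_f <- function(x, dims, p, k, s = 1L, pad = (k - 1L) %/% 2L) {
  if (k == 1L && s == 1L) {
    y <- x %*% p$W
    y <- sweep(y, 2L, p$b, "+")
    return(list(y = y, odims = as.integer(dims)))
  }
  cols <- im2col3d(x, as.integer(dims), rep(as.integer(k), 3L),
                   rep(as.integer(s), 3L), rep(as.integer(pad), 3L))
  y <- cols %*% p$W
  y <- sweep(y, 2L, p$b, "+")
  list(y = y, odims = conv_out_dims(dims, k, s, pad))
}

conv3d_b <- function(dy, x, dims, p, k, s = 1L, pad = (k - 1L) %/% 2L) {
  if (k == 1L && s == 1L) {
    return(list(dx = dy %*% t(p$W),
                grads = list(W = crossprod(x, dy), b = colSums(dy))))
  }
  cols <- im2col3d(x, as.integer(dims), rep(as.integer(k), 3L),
                   rep(as.integer(s), 3L), rep(as.integer(pad), 3L))
  dW <- crossprod(cols, dy)
  db <- colSums(dy)
  dcols <- dy %*% t(p$W)
  dx <- col2im3d(dcols, as.integer(dims), rep(as.integer(k), 3L),
                 rep(as.integer(s), 3L), rep(as.integer(pad), 3L))
  list(dx = dx, grads = list(W = dW, b = db))
}

convT3d_f <- function(x, dims, p, k = 2L, s = 2L) {
  odims <- as.integer(s * (dims - 1L) + k)
  ycols <- x %*% t(p$W)
  y <- col2im3d(ycols, odims, rep(as.integer(k), 3L),
                rep(as.integer(s), 3L), c(0L, 0L, 0L))
  y <- sweep(y, 2L, p$b, "+")
  list(y = y, odims = odims)
}

convT3d_b <- function(dy, x, dims, p, k = 2L, s = 2L) {
  odims <- as.integer(s * (dims - 1L) + k)
  dycols <- im2col3d(dy, odims, rep(as.integer(k), 3L),
                     rep(as.integer(s), 3L), c(0L, 0L, 0L))
  dx <- dycols %*% p$W
  dW <- crossprod(dycols, x)
  db <- colSums(dy)
  list(dx = dx, grads = list(W = dW, b = db))
}

# ---- normalization ---------------------------------------------------------

groupnorm_f <- function(x, p, groups, eps = 1e-5) {
  C <- ncol(x)
  cg <- C %/% groups
  xhat <- x
  istd <- numeric(groups)
  mu <- numeric(groups)
  for (g in seq_len(groups)) {
    cols <- ((g - 1L) * cg + 1L):(g * cg)
    xg <- x[, cols, drop = FALSE]
    m <- mean(xg)
    v <- mean((xg - m)^2)
    istd[g] <- 1 / sqrt(v + eps)
    xhat[, cols] <- (xg - m) * istd[g]
    mu[g] <- m
  }
  y <- sweep(sweep(xhat, 2L, p$gamma, "*"), 2L, p$beta, "+")
  list(y = y, xhat = xhat, istd = istd)
}

groupnorm_b <- function(dy, cache, p, groups) {
  C <- ncol(dy)
  cg <- C %/% groups
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, p$gamma, "*")
  dx <- dxhat
  for (g in seq_len(groups)) {
    cols <- ((g - 1L) * cg + 1L):(g * cg)
    dg <- dxhat[, cols, drop = FALSE]
    xg <- xhat[, cols, drop = FALSE]
    m <- length(dg)
    dx[, cols] <- cache$istd[g] *
      (dg - mean(dg) - xg * mean(dg * xg))
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

layernorm_f <- function(x, p, eps = 1e-5) {
  C <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  y <- sweep(sweep(xhat, 2L, p$gamma, "*"), 2L, p$beta, "+")
  list(y = y, xhat = xhat, istd = istd)
}

layernorm_b <- function(dy, cache, p) {
  C <- ncol(dy)
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, p$gamma, "*")
  dx <- cache$istd * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

# ---- pointwise -------------------------------------------------------------

relu_f <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}
relu_b <- function(dy, x) dy * (x > 0)

gelu_f <- function(x) x * stats::pnorm(x)
gelu_b <- function(dy, x) dy * (stats::pnorm(x) + x * stats::dnorm(x))

sigmoid_f <- function(x) 1 / (1 + exp(-x))
sigmoid_b <- function(dy, y) dy * y * (1 - y)

dense_f <- function(x, p) sweep(x %*% p$W, 2L, p$b, "+")
dense_b <- function(dy, x, p) {
  list(dx = dy %*% t(p$W), grads = list(W = crossprod(x, dy), b = colSums(dy)))
}

softmax_rows <- function(z) {
  mx <- z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  e <- exp(z - mx)
  e / rowSums(e)
}

# ---- windowed multi-head self-attention ------------------------------------

# Token bookkeeping for (cyclically shifted) window partition. Returns the
# permutation mapping window-grouped token order to voxel order, plus per-token
# region ids whose disagreement inside a window marks wrapped-around token
# pairs that must not attend to each other. Memoized per geometry.
.window_index_cache <- new.env(parent = emptyenv())

window_index <- function(dims, win, shift) {
  key <- paste(c(dims, win, shift), collapse = ",")
  hit <- .window_index_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- window_index_compute(dims, win, shift)
  .window_index_cache[[key]] <- val
  val
}

window_index_compute <- function(dims, win, shift) {
  if (any(dims %% win != 0))
    stop("feature grid must be padded to window multiples")
  n <- prod(dims)
  idx <- array(seq_len(n), dim = dims)
  region_axis <- function(d, w, s) {
    r <- integer(d)
    if (s > 0) {
      pos <- 0:(d - 1)
      r[pos < d - w] <- 0L
      r[pos >= d - w & pos < d - s] <- 1L
      r[pos >= d - s] <- 2L
    }
    r
  }
  reg <- array(0L, dim = dims)
  if (shift[1] > 0 || shift[2] > 0 || shift[3] > 0) {
    r1 <- region_axis(dims[1], win[1], shift[1])
    r2 <- region_axis(dims[2], win[2], shift[2])
    r3 <- region_axis(dims[3], win[3], shift[3])
    reg <- outer(outer(r1, 3L * r2, "+"), 9L * r3, "+")
  }
  roll <- function(a, s) {
    if (all(s == 0)) return(a)
    d <- dim(a)
    a[(seq_len(d[1]) - 1L + s[1]) %% d[1] + 1L,
      (seq_len(d[2]) - 1L + s[2]) %% d[2] + 1L,
      (seq_len(d[3]) - 1L + s[3]) %% d[3] + 1L, drop = FALSE]
  }
  idx <- roll(idx, shift)
  reg <- roll(reg, shift)
  nw <- dims %/% win
  ord <- integer(n)
  grp <- integer(n)
  t <- prod(win)
  wi <- 0L
  for (wz in seq_len(nw[3])) for (wy in seq_len(nw[2])) for (wx in seq_len(nw[1])) {
    rows <- wi * t + seq_len(t)
    sel_x <- (wx - 1L) * win[1] + seq_len(win[1])
    sel_y <- (wy - 1L) * win[2] + seq_len(win[2])
    sel_z <- (wz - 1L) * win[3] + seq_len(win[3])
    ord[rows] <- as.vector(idx[sel_x, sel_y, sel_z, drop = FALSE])
    grp[rows] <- as.vector(reg[sel_x, sel_y, sel_z, drop = FALSE])
    wi <- wi + 1L
  }
  list(order = ord, group = grp, nwin = prod(nw), t = t)
}

win_attn_f <- function(x, dims, p, win, shift, heads) {
  C <- ncol(x)
  if (C %% heads != 0) stop("heads must divide the channel count")
  dh <- C %/% heads
  wi <- window_index(dims, win, shift)
  xw <- x[wi$order, , drop = FALSE]
  qkv <- sweep(xw %*% p$Wqkv, 2L, p$bqkv, "+")
  t <- wi$t
  scale <- 1 / sqrt(dh)
  A <- vector("list", wi$nwin * heads)
  out <- matrix(0, nrow(xw), C)
  for (w in seq_len(wi$nwin)) {
    rows <- (w - 1L) * t + seq_len(t)
    g <- wi$group[rows]
    mask <- if (any(g != g[1])) outer(g, g, "!=") * -1e9 else NULL
    for (h in seq_len(heads)) {
      qc <- (h - 1L) * dh + seq_len(dh)
      Q <- qkv[rows, qc, drop = FALSE]
      K <- qkv[rows, C + qc, drop = FALSE]
      V <- qkv[rows, 2L * C + qc, drop = FALSE]
      S <- tcrossprod(Q, K) * scale
      if (!is.null(mask)) S <- S + mask
      Aw <- softmax_rows(S)
      A[[(w - 1L) * heads + h]] <- Aw
      out[rows, qc] <- Aw %*% V
    }
  }
  y0 <- sweep(out %*% p$Wo, 2L, p$bo, "+")
  y <- matrix(0, nrow(x), C)
  y[wi$order, ] <- y0
  list(y = y, xw = xw, qkv = qkv, out = out, A = A, wi = wi, heads = heads)
}

win_attn_b <- function(dy, cache, p) {
  C <- ncol(dy)
  heads <- cache$heads
  dh <- C %/% heads
  wi <- cache$wi
  t <- wi$t
  scale <- 1 / sqrt(dh)
  dy0 <- dy[wi$order, , drop = FALSE]
  dWo <- crossprod(cache$out, dy0)
  dbo <- colSums(dy0)
  dout <- dy0 %*% t(p$Wo)
  dqkv <- matrix(0, nrow(dy0), 3L * C)
  qkv <- cache$qkv
  for (w in seq_len(wi$nwin)) {
    rows <- (w - 1L) * t + seq_len(t)
    for (h in seq_len(heads)) {
      qc <- (h - 1L) * dh + seq_len(dh)
      Q <- qkv[rows, qc, drop = FALSE]
      K <- qkv[rows, C + qc, drop = FALSE]
      V <- qkv[rows, 2L * C + qc, drop = FALSE]
      Aw <- cache$A[[(w - 1L) * heads + h]]
      dO <- dout[rows, qc, drop = FALSE]
      dA <- tcrossprod(dO, V)
      dV <- crossprod(Aw, dO)
      dS <- Aw * (dA - rowSums(dA * Aw))
      dqkv[rows, qc] <- (dS %*% K) * scale
      dqkv[rows, C + qc] <- (crossprod(dS, Q)) * scale
      dqkv[rows, 2L * C + qc] <- dV
    }
  }
  dWqkv <- crossprod(cache$xw, dqkv)
  dbqkv <- colSums(dqkv)
  dxw <- dqkv %*% t(p$Wqkv)
  dx <- matrix(0, nrow(dy), C)
  dx[wi$order, ] <- dxw
  list(dx = dx, grads = list(Wqkv = dWqkv, bqkv = dbqkv, Wo = dWo, bo = dbo))
}

#' Windowed multi-head self-attention
#'
#' Multi-head scaled-dot-product attention computed independently inside each
#' (optionally cyclically shifted) non-overlapping window of a 3D feature
#' grid. With a nonzero shift, a wraparound mask prevents token pairs that
#' became adjacent only through the cyclic shift from attending to each other.
#'
#' @param x Feature matrix, `prod(dims)` rows (voxels, column-major x,y,z
#'   order) by `C` channels.
#' @param dims Integer length-3 spatial extent; must be a multiple of `window`.
#' @param params List with `Wqkv` (C x 3C), `bqkv`, `Wo` (C x C), `bo`;
#'   see the internal initializer used by [buildSegmenter()].
#' @param window Integer length-3 (or scalar) window extent.
#' @param shift Integer length-3 (or scalar) cyclic shift; 0 for unshifted.
#' @param heads Number of attention heads; must divide `C`.
#' @return Feature matrix of the same shape as `x`.
#' @export
windowAttention <- function(x, dims, params, window, shift = 0L, heads = 1L) {
  if (length(window) == 1L) window <- rep(window, 3L)
  if (length(shift) == 1L) shift <- rep(shift, 3L)
  win_attn_f(x, as.integer(dims), params, as.integer(window),
             as.integer(shift), as.integer(heads))$y
}

# ---- optimizers and schedules ----------------------------------------------

walk_params <- function(p, g, f) {
  if (is.list(p)) {
    out <- p
    for (nm in names(p)) out[[nm]] <- walk_params(p[[nm]], g[[nm]], f)
    out
  } else f(p, g)
}

zeros_like <- function(p) {
  if (is.list(p)) lapply(p, zeros_like) else p * 0
}

adamw_init <- function(params) list(t = 0L, m = zeros_like(params),
                                    v = zeros_like(params))

# AdamW step (decoupled weight decay); also plain Adam when decay = 0.
adamw_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, decay = 0.01) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * ((m / b1t) / (sqrt(v / b2t) + eps) + decay * p)
    list(p = p, m = m, v = v)
  }
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      pm <- p; mm <- m; vm <- v
      for (nm in names(p)) {
        r <- rec(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        pm[[nm]] <- r$p; mm[[nm]] <- r$m; vm[[nm]] <- r$v
      }
      list(p = pm, m = mm, v = vm)
    } else upd(p, g, m, v)
  }
  r <- rec(params, grads, state$m, state$v)
  list(params = r$p, state = list(t = state$t, m = r$m, v = r$v))
}

scale_grads <- function(g, s) {
  if (is.list(g)) lapply(g, scale_grads, s = s) else g * s
}

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) {
    out <- a
    for (nm in names(a)) out[[nm]] <- add_grads(a[[nm]], b[[nm]])
    out
  } else a + b
}

cosine_lr <- function(base_lr, epoch, total_epochs) {
  base_lr * 0.5 * (1 + cos(pi * (epoch - 1) / max(total_epochs - 1, 1)))
}

step_decay_lr <- function(base_lr, epoch, every = 50L, factor = 0.1) {
  base_lr * factor^((epoch - 1) %/% every)
}
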