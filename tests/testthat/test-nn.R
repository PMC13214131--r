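# Neural-network primitives: finite-difference gradient verification,
# windowed-attention semantics, optimizer schedule arithmetic.

num_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

rel_err <- function(a, b) max(abs(a - b)) / max(max(abs(b)), 1e-8)

test_that("convolution, transposed convolution and normalization gradients match finite differences", {
  ns <- asNamespace("sinusct")
  set.seed(1)
  dims <- c(4L, 5L, 3L); cin <- 2L
  x <- matrix(rnorm(prod(dims) * cin), ncol = cin)
  p <- ns$init_conv(3L, cin, 3L)
  for (s in c(1L, 2L)) {
    fwd <- ns$conv3d_f(x, dims, p, 3L, s)
    bk <- ns$conv3d_b(cos(fwd$y), x, dims, p, 3L, s)
    lx <- function(xv) sum(sin(ns$conv3d_f(matrix(xv, ncol = cin), dims, p, 3L, s)$y))
    expect_lt(rel_err(as.vector(bk$dx), num_grad(lx, as.vector(x))), 1e-6)
    lw <- function(wv) {
      p2 <- p; p2$W <- matrix(wv, nrow = nrow(p$W))
      sum(sin(ns$conv3d_f(x, dims, p2, 3L, s)$y))
    }
    expect_lt(rel_err(as.vector(bk$grads$W), num_grad(lw, as.vector(p$W))), 1e-6)
  }
  xt <- matrix(rnorm(12 * 3), ncol = 3)
  pt <- ns$init_convT(2L, 3L, 4L)
  ft <- ns$convT3d_f(xt, c(3L, 2L, 2L), pt)
  expect_identical(ft$odims, c(6L, 4L, 4L))
  bt <- ns$convT3d_b(cos(ft$y), xt, c(3L, 2L, 2L), pt)
  lt <- function(xv) sum(sin(ns$convT3d_f(matrix(xv, ncol = 3), c(3L, 2L, 2L), pt)$y))
  expect_lt(rel_err(as.vector(bt$dx), num_grad(lt, as.vector(xt))), 1e-6)
  xg <- matrix(rnorm(40), ncol = 4)
  pg <- list(gamma = runif(4, 0.5, 1.5), beta = rnorm(4))
  fg <- ns$groupnorm_f(xg, pg, 2L)
  bg <- ns$groupnorm_b(cos(fg$y), fg, pg, 2L)
  lg <- function(xv) sum(sin(ns$groupnorm_f(matrix(xv, ncol = 4), pg, 2L)$y))
  expect_lt(rel_err(as.vector(bg$dx), num_grad(lg, as.vector(xg))), 1e-5)
  fl <- ns$layernorm_f(xg, pg)
  bl <- ns$layernorm_b(cos(fl$y), fl, pg)
  ll <- function(xv) sum(sin(ns$layernorm_f(matrix(xv, ncol = 4), pg)$y))
  expect_lt(rel_err(as.vector(bl$dx), num_grad(ll, as.vector(xg))), 1e-5)
})

test_that("shifted window attention gradients match finite differences", {
  ns <- asNamespace("sinusct")
  set.seed(2)
  dims <- c(4L, 4L, 4L); C <- 6L
  x <- matrix(rnorm(64 * C), ncol = C)
  p <- ns$init_attn(C, sd = 0.3)
  fwd <- ns$win_attn_f(x, dims, p, c(2L, 2L, 2L), c(1L, 1L, 1L), 2L)
  bk <- ns$win_attn_b(cos(fwd$y), fwd, p)
  lx <- function(xv) sum(sin(ns$win_attn_f(matrix(xv, ncol = C), dims, p,
                                           c(2L, 2L, 2L), c(1L, 1L, 1L), 2L)$y))
  expect_lt(rel_err(as.vector(bk$dx), num_grad(lx, as.vector(x))), 1e-5)
  lw <- function(wv) {
    p2 <- p; p2$Wqkv <- matrix(wv, nrow = C)
    sum(sin(ns$win_attn_f(x, dims, p2, c(2L, 2L, 2L), c(1L, 1L, 1L), 2L)$y))
  }
  expect_lt(rel_err(as.vector(bk$grads$Wqkv), num_grad(lw, as.vector(p$Wqkv))), 1e-5)
})

test_that("window attention covering the grid equals dense attention", {
  ns <- asNamespace("sinusct")
  set.seed(3)
  C <- 6L
  x <- matrix(rnorm(64 * C), ncol = C)
  p <- ns$init_attn(C, sd = 0.3)
  y <- windowAttention(x, c(4, 4, 4), p, window = 4, shift = 0, heads = 3)
  yd <- dense_attention_oracle(x, p, 3L)
  expect_lt(max(abs(y - yd)), 1e-5)
  expect_error(windowAttention(x, c(4, 4, 4), p, window = 4, heads = 5),
               "divide")
  expect_error(windowAttention(x, c(4, 4, 4), p, window = 3),
               "multiple")
})

test_that("unshifted windows are independent (impulse locality)", {
  ns <- asNamespace("sinusct")
  set.seed(4)
  C <- 4L
  p <- ns$init_attn(C, sd = 0.5)
  x0 <- matrix(0, 64, C)
  y0 <- windowAttention(x0, c(4, 4, 4), p, window = 2, shift = 0, heads = 2)
  x1 <- x0
  x1[1, ] <- rnorm(C) * 3            # impulse inside the first window
  y1 <- windowAttention(x1, c(4, 4, 4), p, window = 2, shift = 0, heads = 2)
  wi <- ns$window_index(c(4L, 4L, 4L), c(2L, 2L, 2L), c(0L, 0L, 0L))
  first_win <- wi$order[1:8]
  others <- setdiff(seq_len(64), first_win)
  expect_true(max(abs(y1[others, ] - y0[others, ])) < 1e-12)
  expect_true(max(abs(y1[first_win, ] - y0[first_win, ])) > 0)
})

test_that("cyclic shift bookkeeping inverts exactly under value-passing attention", {
  ns <- asNamespace("sinusct")
  C <- 3L
  # Q=K=0 so attention is uniform; window 1 makes each window a single token,
  # V and the output projection are identities: y must equal x for any shift.
  p <- list(Wqkv = matrix(0, C, 3 * C), bqkv = numeric(3 * C),
            Wo = diag(C), bo = numeric(C))
  p$Wqkv[, 2 * C + 1:C] <- diag(C)
  x <- matrix(rnorm(27 * C), ncol = C)
  y <- windowAttention(x, c(3, 3, 3), p, window = 1, shift = 1, heads = 1)
  expect_equal(y, x, tolerance = 1e-12)
})

test_that("wraparound masking prevents attention across the cyclic seam", {
  ns <- asNamespace("sinusct")
  set.seed(6)
  C <- 4L
  p <- ns$init_attn(C, sd = 0.5)
  # 1D-like geometry: 4 voxels along x, window 2, shift 1 wraps voxel 1 next
  # to voxel 4; masking must keep their outputs independent.
  dims <- c(4L, 1L, 1L)
  # window must divide dims; use window c(2,1,1), shift c(1,0,0)
  x0 <- matrix(0, 4, C)
  y0 <- ns$win_attn_f(x0, dims, p, c(2L, 1L, 1L), c(1L, 0L, 0L), 1L)$y
  x1 <- x0; x1[4, ] <- 5
  y1 <- ns$win_attn_f(x1, dims, p, c(2L, 1L, 1L), c(1L, 0L, 0L), 1L)$y
  # voxel 1 shares a shifted window with voxel 4 but sits across the seam:
  # its output must not react to the voxel-4 impulse
  expect_lt(max(abs(y1[1, ] - y0[1, ])), 1e-9)
})

test_that("learning-rate schedules follow their closed forms", {
  ns <- asNamespace("sinusct")
  expect_equal(ns$step_decay_lr(1e-3, 50), 1e-3)
  expect_equal(ns$step_decay_lr(1e-3, 51), 1e-4)
  expect_equal(ns$step_decay_lr(1e-3, 51) / ns$step_decay_lr(1e-3, 50), 0.1)
  expect_equal(ns$cosine_lr(1, 1, 100), 1)
  expect_equal(ns$cosine_lr(1, 100, 100), 0, tolerance = 1e-12)
  expect_gt(ns$cosine_lr(1, 25, 100), ns$cosine_lr(1, 75, 100))
})

test_that("derived seeds stay in 32-bit range and separate streams", {
  ns <- asNamespace("sinusct")
  s <- vapply(1:200, function(i) ns$deriveSeed(123456789, i), integer(1))
  expect_true(all(s > 0 & s < 2^31))
  expect_identical(length(unique(s)), 200L)
  expect_identical(ns$deriveSeed(7, 1, 2), ns$deriveSeed(7, 1, 2))
  expect_false(ns$deriveSeed(7, 1, 2) == ns$deriveSeed(7, 2, 1))
})
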