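# Low-level operators: convolution adjointness, SoftPool, window
# machinery, finite-difference gradient checks of each layer primitive.

fd_check <- function(f, x, dx_analytic, n = 6, h = 1e-6, tol = 1e-5) {
  set.seed(1)
  for (j in sample(length(x), min(n, length(x)))) {
    x2 <- x; x2[j] <- x2[j] + h
    x3 <- x; x3[j] <- x3[j] - h
    fd <- (f(x2) - f(x3)) / (2 * h)
    expect_equal(dx_analytic[j], fd, tolerance = tol,
                 label = sprintf("analytic grad [%d]", j))
  }
}

test_that("convolution matches a direct dense computation and its adjoint", {
  withr::with_seed(3, {
    x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
    W <- matrix(rnorm(2 * 2 * 2 * 3), 8, 3)
    b <- rnorm(3)
  })
  out <- fthnet:::conv2d_fwd(x, W, b, k = 2L, s = 2L)
  expect_equal(attr(out$y, "H"), 4L)
  # direct computation at one output position (r=2, c=3), channel 1:
  # token index t = (c-1)*H + r in column-major order
  patch <- x[3:4, 5:6, ] # rows 3:4, cols 5:6 for stride-2 position (2,3)
  cols_manual <- as.numeric(patch) # dy fastest, dx, then channel
  expect_equal(out$y[(3 - 1) * 4 + 2, 1], sum(cols_manual * W[, 1]) + b[1])
  # adjoint: <conv(x), u> gradient w.r.t. x equals col2im path
  withr::with_seed(4, u <- matrix(rnorm(16 * 3), 16, 3))
  bw <- fthnet:::conv2d_bwd(u, W, out$cache)
  f <- function(xv) sum(fthnet:::conv2d_fwd(array(xv, dim(x)), W, b, 2L, 2L)$y * u)
  fd_check(f, x, as.numeric(bw$dx))
  # and w.r.t. W
  fW <- function(Wv) sum(fthnet:::conv2d_fwd(x, matrix(Wv, 8, 3), b, 2L, 2L)$y * u)
  fd_check(fW, W, as.numeric(bw$dW))
})

test_that("padded convolution gradients are exact", {
  withr::with_seed(5, {
    x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
    W <- matrix(rnorm(3 * 3 * 2 * 2), 18, 2)
    b <- rnorm(2)
    u <- matrix(rnorm(36 * 2), 36, 2)
  })
  out <- fthnet:::conv2d_fwd(x, W, b, k = 3L, s = 1L, p = 1L)
  expect_equal(dim(out$y), c(36L, 2L))
  bw <- fthnet:::conv2d_bwd(u, W, out$cache)
  f <- function(xv) sum(fthnet:::conv2d_fwd(array(xv, dim(x)), W, b, 3L, 1L, 1L)$y * u)
  fd_check(f, x, as.numeric(bw$dx))
})

test_that("layernorm and gelu gradients are exact", {
  withr::with_seed(6, {
    x <- matrix(rnorm(12 * 5, sd = 2), 12, 5)
    g <- runif(5, 0.5, 1.5); b <- rnorm(5)
    u <- matrix(rnorm(12 * 5), 12, 5)
  })
  ln <- fthnet:::layernorm_fwd(x, g, b)
  lb <- fthnet:::layernorm_bwd(u, ln$cache)
  f <- function(xv) sum(fthnet:::layernorm_fwd(matrix(xv, 12, 5), g, b)$y * u)
  fd_check(f, x, as.numeric(lb$dx), n = 8)
  fg <- function(gv) sum(fthnet:::layernorm_fwd(x, gv, b)$y * u)
  fd_check(fg, g, lb$dg, n = 5)
  ge <- fthnet:::gelu_fwd(x)
  expect_equal(ge$y, x * pnorm(x), tolerance = 1e-12)
  gb <- fthnet:::gelu_bwd(u, ge$cache)
  f2 <- function(xv) sum(fthnet:::gelu_fwd(matrix(xv, 12, 5))$y * u)
  fd_check(f2, x, as.numeric(gb))
})

test_that("softpool is an exponentially weighted average with exact grads", {
  # constant window: identity
  tok <- fthnet:::with_hwb(matrix(3.7, 16, 2), 4L, 4L, 1L)
  sp <- fthnet:::softpool_fwd(tok, 2L)
  expect_equal(as.numeric(sp$y), rep(3.7, 8))
  # one dominant value: softmax concentrates on the max
  f <- array(0, c(2, 2, 1)); f[1, 1, 1] <- 20
  pooled <- softpool(f, 2L)
  expect_equal(as.numeric(pooled), 20, tolerance = 1e-6)
  # bounded by window extremes on random windows
  withr::with_seed(9, {
    x <- fthnet:::with_hwb(matrix(rnorm(100 * 4, sd = 3), 100, 4), 10L, 10L, 1L)
    out <- fthnet:::softpool_fwd(x, 5L)$y
    idx <- fthnet:::window_index(10L, 10L, 5L)
    xs <- x[idx, ]
    for (gp in 1:4) {
      rows <- ((gp - 1) * 25 + 1):(gp * 25)
      expect_true(all(out[gp, ] >= apply(xs[rows, ], 2, min) - 1e-12))
      expect_true(all(out[gp, ] <= apply(xs[rows, ], 2, max) + 1e-12))
    }
    # gradient check
    u <- matrix(rnorm(4 * 4), 4, 4)
    bw <- fthnet:::softpool_bwd(u, fthnet:::softpool_fwd(x, 5L)$cache)
    fsp <- function(xv) {
      xm <- fthnet:::with_hwb(matrix(xv, 100, 4), 10L, 10L, 1L)
      sum(fthnet:::softpool_fwd(xm, 5L)$y * u)
    }
    fd_check(fsp, as.numeric(x), as.numeric(bw), n = 8)
  })
})

test_that("window partition and reverse are exact inverses", {
  withr::with_seed(10, x <- array(rnorm(12 * 12 * 3), c(12, 12, 3)))
  for (w in c(2L, 3L, 4L, 6L, 12L)) {
    wins <- window_partition(x, w)
    expect_length(wins, (12L %/% w)^2)
    expect_identical(window_reverse(wins), x)
  }
  # degenerate single window
  wins <- window_partition(x, 12L)
  expect_length(wins, 1L)
  expect_equal(wins[[1]], x, ignore_attr = TRUE)
  expect_error(window_partition(x, 5L), "divisible")
  # a window's content is the corresponding spatial tile
  wins2 <- window_partition(x, 6L)
  expect_equal(wins2[[1]], x[1:6, 1:6, ], ignore_attr = TRUE)
})

test_that("permutation helpers are consistent inverses", {
  for (spec in list(c(6L, 6L, 2L), c(8L, 4L, 2L))) {
    p <- fthnet:::window_index(spec[1], spec[2], spec[3])
    expect_equal(sort(p), seq_len(spec[1] * spec[2]))
    ip <- fthnet:::inverse_perm(p)
    expect_equal(p[ip], seq_along(p))
  }
  s <- fthnet:::shift_index(6L, 6L, 2L)
  expect_equal(sort(s), 1:36)
  # shifting by H is the identity
  expect_equal(fthnet:::shift_index(6L, 6L, 6L), 1:36)
})

test_that("w_msa agrees with a brute-force attention oracle", {
  # 4-token window (w = 2), explicit-loop oracle
  withr::with_seed(12, {
    C <- 8L; heads <- 2L; n <- 4L
    tok <- matrix(rnorm(n * C), n, C)
    Wqkv <- matrix(rnorm(C * 3 * C, sd = 0.5), C, 3 * C)
    bqkv <- rnorm(3 * C)
    Wproj <- matrix(rnorm(C * C, sd = 0.5), C, C)
    bproj <- rnorm(C)
    rpb <- matrix(rnorm(9 * heads), 9, heads)
  })
  brute <- function(tok, use_rpb) {
    hd <- C / heads
    qkv <- tok %*% Wqkv + matrix(bqkv, n, 3 * C, byrow = TRUE)
    outc <- matrix(0, n, C)
    rp_idx <- fthnet:::relpos_index(2L)
    for (h in seq_len(heads)) {
      cols <- ((h - 1) * hd + 1):(h * hd)
      Q <- qkv[, cols]; K <- qkv[, C + cols]; V <- qkv[, 2 * C + cols]
      S <- matrix(0, n, n)
      for (i in 1:n) for (j in 1:n)
        S[i, j] <- sum(Q[i, ] * K[j, ]) / sqrt(hd) +
          if (use_rpb) rpb[rp_idx[i, j], h] else 0
      A <- matrix(0, n, n)
      for (i in 1:n) A[i, ] <- exp(S[i, ]) / sum(exp(S[i, ]))
      for (i in 1:n) for (d in seq_len(hd))
        outc[i, cols[d]] <- sum(A[i, ] * V[, d])
    }
    outc %*% Wproj + matrix(bproj, n, C, byrow = TRUE)
  }
  got <- w_msa(tok, heads, Wqkv, bqkv, Wproj, bproj, rpb = NULL)
  expect_lt(max(abs(got - brute(tok, FALSE))), 1e-6)
  got_rpb <- w_msa(tok, heads, Wqkv, bqkv, Wproj, bproj, rpb = rpb)
  expect_lt(max(abs(got_rpb - brute(tok, TRUE))), 1e-6)
  # softmax rows sum to 1 implies: uniform tokens (and zero bias) give the
  # same output as a single averaged token
  tok_u <- matrix(rep(tok[1, ], each = n), n, C)
  got_u <- w_msa(tok_u, heads, Wqkv, bqkv, Wproj, bproj)
  expect_equal(got_u[1, ], got_u[4, ], tolerance = 1e-10)
  # single-token window: attention reduces to the projections
  one <- w_msa(tok[1, , drop = FALSE], heads, Wqkv, bqkv, Wproj, bproj)
  qkv1 <- tok[1, , drop = FALSE] %*% Wqkv + bqkv
  expect_equal(as.numeric(one),
               as.numeric(qkv1[, (2 * C + 1):(3 * C)] %*% Wproj + bproj),
               tolerance = 1e-10)
  expect_error(w_msa(tok, 3L, Wqkv, bqkv, Wproj, bproj), "divisible")
})
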