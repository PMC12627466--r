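# Low-level neural-network operators with hand-written backward passes.
#
# Feature maps travel internally as batched "token matrices": a (B*H*W, C)
# matrix with attributes H, W, B; image b occupies rows ((b-1)*H*W + 1) :
# (b*H*W), token index within an image t = (c-1)*H + r (column-major, the
# native R array order, so array <-> token conversion is a free reshape).
# All operators come in _fwd/_bwd pairs; _fwd returns the output plus the
# cache its backward needs. Gradient correctness is pinned by
# finite-difference tests.

tokens_from_array <- function(x) {
  d <- dim(x)
  if (length(d) == 3L)
    return(with_hwb(matrix(as.numeric(x), d[1] * d[2], d[3]), d[1], d[2], 1L))
  B <- d[4]
  # (H, W, C, B) -> rows image-major: move B in front of C
  tok <- matrix(as.numeric(aperm(x, c(1, 2, 4, 3))), d[1] * d[2] * B, d[3])
  with_hwb(tok, d[1], d[2], B)
}

# Returns (H, W, C) for B = 1, else (H, W, C, B).
array_from_tokens <- function(tok, H = attr(tok, "H"), W = attr(tok, "W"),
                              B = attr(tok, "B")) {
  if (is.null(B)) B <- 1L
  C <- ncol(tok)
  if (B == 1L) return(array(as.numeric(tok), c(H, W, C)))
  aperm(array(as.numeric(tok), c(H, W, B, C)), c(1, 2, 4, 3))
}

with_hwb <- function(tok, H, W, B = 1L) {
  attr(tok, "H") <- H; attr(tok, "W") <- W; attr(tok, "B") <- B
  tok
}

copy_hwb <- function(tok, like) {
  with_hwb(tok, attr(like, "H"), attr(like, "W"), attr(like, "B"))
}

batch_size <- function(tok) {
  B <- attr(tok, "B")
  if (is.null(B)) 1L else B
}

# --- im2col convolution -----------------------------------------------------

# im2col / col2im live in src/attention.cpp (im2col_cpp, col2im_cpp);
# patch layout is documented there. R-side conv wrappers below.

# x: (H, W, Cin) or (H, W, Cin, B). One GEMM over the whole batch.
conv2d_fwd <- function(x, W, b, k, s, p = 0L) {
  d <- dim(x)
  B <- if (length(d) == 4L) d[4] else 1L
  cols <- im2col_cpp(as.numeric(x), d[1], d[2], d[3], B,
                     as.integer(k), as.integer(s), as.integer(p))
  y <- cols %*% W
  add_bias_inplace(y, b) # y freshly allocated by %*%
  Ho <- (d[1] + 2 * p - k) %/% s + 1L
  Wo <- (d[2] + 2 * p - k) %/% s + 1L
  list(y = with_hwb(y, Ho, Wo, B),
       cache = list(cols = cols, dimx = d[1:3], B = B, k = k, s = s, p = p))
}

# dx is always (H, W, Cin, B), even for B = 1.
conv2d_bwd <- function(dy, W, cache) {
  dW <- crossprod(cache$cols, dy)
  db <- colSums(dy)
  dcols <- dy %*% t(W)
  dm <- cache$dimx
  dx <- col2im_cpp(dcols, dm[1], dm[2], dm[3], cache$B,
                   as.integer(cache$k), as.integer(cache$s),
                   as.integer(cache$p))
  list(dx = dx, dW = dW, db = db)
}

# --- dense layers -----------------------------------------------------------

linear_fwd <- function(x, W, b = NULL) {
  y <- x %*% W
  if (!is.null(b)) add_bias_inplace(y, b) # y is freshly allocated by %*%
  list(y = y, cache = x)
}

linear_bwd <- function(dy, W, cache, bias = TRUE) {
  list(dx = dy %*% t(W), dW = crossprod(cache, dy),
       db = if (bias) colSums(dy) else NULL)
}

gelu_fwd <- function(x) {
  r <- gelu_fwd_cpp(x)
  list(y = r$y, cache = list(x = x, phi = r$phi))
}

gelu_bwd <- function(dy, cache) {
  gelu_bwd_cpp(dy, cache$x, cache$phi)
}

.LN_EPS <- 1e-5

layernorm_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + .LN_EPS)
  xhat <- xc * inv
  y <- ln_affine_cpp(xhat, g, b)
  list(y = y, cache = list(xhat = xhat, inv = inv, g = g))
}

layernorm_bwd <- function(dy, cache) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- scale_cols_cpp(dy, cache$g)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = dg, db = db)
}

# --- token permutations -----------------------------------------------------

# Row order that groups tokens of an (H, W) grid into non-overlapping
# w x w windows, window-major, tokens within a window column-major.
window_index <- function(H, W, w) {
  if (H %% w || W %% w)
    stop("window_index: spatial sides (", H, ", ", W,
         ") not divisible by window ", w)
  rr <- rep(seq_len(H), W); cc <- rep(seq_len(W), each = H) # token t order
  win <- ((cc - 1) %/% w) * (H %/% w) + (rr - 1) %/% w       # 0-based window
  inside <- ((cc - 1) %% w) * w + (rr - 1) %% w              # 0-based offset
  order(win * w * w + inside)
}

# Cyclic-shift permutation of tokens: new (r, c) reads old (r+s, c+s) mod.
shift_index <- function(H, W, s) {
  rs <- ((seq_len(H) - 1 + s) %% H) + 1
  cs <- ((seq_len(W) - 1 + s) %% W) + 1
  as.vector(outer(rs, (cs - 1) * H, "+"))
}

inverse_perm <- function(p) {
  ip <- integer(length(p)); ip[p] <- seq_along(p)
  ip
}

# Replicate a per-image row permutation across a batch (block offsets).
batch_perm <- function(p, B, N = length(p)) {
  if (B == 1L) return(p)
  as.integer(outer(p, (seq_len(B) - 1L) * N, "+"))
}

# Swin-style attention mask region ids for a cyclically shifted grid, in
# token order. Tokens sharing a window but not a region must not attend.
shift_region_ids <- function(H, W, w, s) {
  seg <- function(n) c(rep(1L, n - w), rep(2L, w - s), rep(3L, s))
  rid <- outer(seg(H), seg(W), function(a, b) a * 10L + b)
  as.vector(rid)
}

# --- relative position bias -------------------------------------------------

# (w^2 x w^2) index into a (2w-1)^2 bias table, Swin convention. Token
# order within a window is column-major (row offset fastest).
relpos_index <- function(w) {
  rs <- rep(seq_len(w), w); cs <- rep(seq_len(w), each = w)
  dr <- outer(rs, rs, "-") + (w - 1)
  dc <- outer(cs, cs, "-") + (w - 1)
  dr * (2L * w - 1L) + dc + 1L
}

# --- SoftPool ---------------------------------------------------------------

# Exponentially-weighted average pooling over non-overlapping k x k
# windows: out = sum(softmax(x) * x) per window and channel. Batch-aware.
softpool_fwd <- function(tok, k) {
  H <- attr(tok, "H"); W <- attr(tok, "W"); B <- batch_size(tok)
  idx <- batch_perm(window_index(H, W, k), B, H * W)
  xg <- tok[idx, , drop = FALSE]          # groups of k^2 contiguous rows
  k2 <- k * k; ng <- nrow(xg) %/% k2; C <- ncol(xg)
  x3 <- array(xg, c(k2, ng, C))
  m <- matrix(x3[1, , ], ng, C)
  if (k2 > 1) for (j in 2:k2) m <- pmax(m, matrix(x3[j, , ], ng, C))
  e3 <- x3 - rep(m, each = k2)
  e3 <- exp(e3)
  den <- colSums(e3, dims = 1)            # (ng, C)
  a3 <- e3 / rep(den, each = k2)
  num <- colSums(a3 * x3, dims = 1)
  out <- with_hwb(matrix(num, ng, C), H %/% k, W %/% k, B)
  list(y = out, cache = list(a3 = a3, x3 = x3, out = num, idx = idx,
                             H = H, W = W, B = B, k = k))
}

softpool_bwd <- function(dy, cache) {
  k2 <- cache$k^2
  d3 <- rep(as.matrix(dy), each = k2)
  o3 <- rep(cache$out, each = k2)
  dxg <- cache$a3 * d3 * (1 + cache$x3 - o3)
  dx <- matrix(dxg, k2 * dim(dxg)[2], dim(dxg)[3])
  dtok <- matrix(0, nrow(dx), ncol(dx))
  dtok[cache$idx, ] <- dx
  with_hwb(dtok, cache$H, cache$W, cache$B)
}

# --- initialisation ---------------------------------------------------------

trunc_normal <- function(n, sd = 0.02, bound = 2) {
  x <- stats::rnorm(n, 0, sd)
  while (any(bad <- abs(x) > bound * sd))
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
  x
}
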