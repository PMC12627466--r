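# User-facing model surface. Features cross this boundary as (H, W, C)
# arrays; internally the network works on token matrices.

#' Create a feature map
#' @param values numeric array (height, width, channels).
#' @param stage backbone stage index (0-3), optional.
#' @return array of class `feature_map` with a `stage` attribute.
#' @export
feature_map <- function(values, stage = NA_integer_) {
  stopifnot(is.array(values), length(dim(values)) == 3L, all(is.finite(values)))
  structure(values, stage = stage, class = c("feature_map", class(values)))
}

#' Non-overlapping patch embedding
#'
#' A 4x4 stride-4 convolution taking a 3-channel image to the shallow
#' feature of width `embed_channels` at a quarter of the resolution;
#' linear in the input pixels plus a bias.
#'
#' @param image numeric array (H, W, 3) with H, W divisible by 32.
#' @param config an [model_config()].
#' @param params parameter list from [init_fthnet()]/training.
#' @return a [feature_map()] of shape (H/4, W/4, C).
#' @export
patch_embed <- function(image, config, params) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) stop("patch_embed: expected (H, W, 3) array")
  if (d[1] %% 32L || d[2] %% 32L)
    stop("patch_embed: sides (", d[1], ", ", d[2], ") must be divisible by 32")
  pe <- conv2d_fwd(image, params[["embed.W"]], params[["embed.b"]], 4L, 4L)
  feature_map(array_from_tokens(pe$y), stage = 0L)
}

#' Partition a feature into non-overlapping windows
#' @param feature (H, W, C) array with sides divisible by `w`.
#' @param w window side length.
#' @return list of (w, w, C) arrays, window-major order; the original shape
#'   is attached as attribute `orig_dim`.
#' @export
window_partition <- function(feature, w) {
  d <- dim(feature)
  tok <- tokens_from_array(feature)
  idx <- window_index(d[1], d[2], w)
  xw <- tok[idx, , drop = FALSE]
  w2 <- w * w; nw <- nrow(xw) %/% w2
  out <- lapply(seq_len(nw), function(k) {
    sub <- xw[((k - 1) * w2 + 1):(k * w2), , drop = FALSE]
    array(as.numeric(sub), c(w, w, d[3])) # tokens are column-major
  })
  attr(out, "orig_dim") <- d
  out
}

#' Reassemble windows into a feature
#' @param windows list produced by [window_partition()].
#' @param shape target (H, W, C), defaults to the recorded original shape.
#' @return (H, W, C) array; `window_reverse(window_partition(x, w)) == x`.
#' @export
window_reverse <- function(windows, shape = attr(windows, "orig_dim")) {
  w <- dim(windows[[1]])[1]
  xw <- do.call(rbind, lapply(windows, function(a)
    matrix(as.numeric(a), w * w, dim(a)[3])))
  idx <- window_index(shape[1], shape[2], w)
  tok <- matrix(0, nrow(xw), ncol(xw))
  tok[idx, ] <- xw
  array_from_tokens(with_hwb(tok, shape[1], shape[2], 1L))
}

#' Window-based multi-head self-attention on one window
#'
#' Standard scaled dot-product attention over the tokens of a single
#' window: per head, `softmax(Q K' / sqrt(d) + B) V`, heads concatenated
#' and passed through the output projection.
#'
#' @param tokens (n, C) matrix of window tokens (n = w^2).
#' @param heads head count; C must be divisible by it.
#' @param Wqkv,bqkv joint query/key/value projection (C x 3C) and bias.
#' @param Wproj,bproj output projection (C x C) and bias.
#' @param rpb optional relative-position-bias table ((2w-1)^2 x heads).
#' @return (n, C) matrix.
#' @export
w_msa <- function(tokens, heads, Wqkv, bqkv, Wproj, bproj, rpb = NULL) {
  tokens <- as.matrix(tokens)
  C <- ncol(tokens)
  if (C %% heads)
    stop("w_msa: channels ", C, " not divisible by heads ", heads)
  n <- nrow(tokens)
  w <- as.integer(round(sqrt(n)))
  geom <- list(w = w, w2 = n, nwB = 1L, masks = array(0, c(n, n, 0)),
               maskid = 0L, no_mask = 0L,
               rp_idx = if (!is.null(rpb)) relpos_index(w))
  attn_fwd(tokens, geom, heads, Wqkv, bqkv, Wproj, bproj, rpb = rpb)$y
}

#' One Basic Transformer Block
#'
#' LayerNorm -> windowed attention (cyclically shifted by w/2 when
#' `shifted`, with the wrap mask) -> residual; LayerNorm -> MLP (linear,
#' GELU, linear) -> residual.
#'
#' @param feature (H, W, C) array (a stage feature).
#' @param config an [model_config()].
#' @param params parameter list.
#' @param stage stage index 1-4; `block` block index within the stage.
#' @param shifted apply the cyclic window shift.
#' @return (H, W, C) [feature_map()].
#' @export
btb_forward <- function(feature, config, params, stage = 1L, block = 1L,
                        shifted = FALSE) {
  tok <- tokens_from_array(feature)
  d <- dim(feature)
  geom <- stage_geometry(d[1], d[2], config$window)
  pfx <- sprintf("bb.s%d.b%d.", stage, block)
  out <- block_fwd(tok, params, pfx, stage_heads(config, stage), geom,
                   shifted = shifted)$y
  feature_map(array_from_tokens(out), stage = stage - 1L)
}

#' Strided-convolution downsampling
#'
#' Stride-2 convolution halving the spatial sides and doubling the
#' channels ((H, W, D) -> (H/2, W/2, 2D)).
#'
#' @param feature (H, W, D) array with even sides.
#' @param W,b convolution weight ((k*k*D) x 2D) and bias.
#' @param kernel kernel side (the calibrated default is 2).
#' @return downsampled array.
#' @export
downsample <- function(feature, W, b, kernel = 2L) {
  d <- dim(feature)
  if (d[1] %% 2L || d[2] %% 2L)
    stop("downsample: spatial sides must be even, got ", d[1], "x", d[2])
  ds <- conv2d_fwd(feature, W, b, as.integer(kernel), 2L)
  array_from_tokens(ds$y)
}

#' Run the transformer backbone
#'
#' @param image (H, W, 3) array, sides divisible by 32 (and stage sides by
#'   the window).
#' @param config an [model_config()].
#' @param params parameter list.
#' @return list of four [feature_map()]s X0..X3, stage i of shape
#'   (H/(4*2^i), W/(4*2^i), 2^i*C).
#' @export
backbone_forward <- function(image, config, params) {
  st <- backbone_fwd(image, params, config)$stages
  lapply(1:4, function(i) feature_map(array_from_tokens(st[[i]]),
                                      stage = i - 1L))
}

#' SoftPool spatial reduction
#'
#' Exponentially weighted average pooling: each non-overlapping k x k
#' window is reduced, per channel, to `sum(softmax(x) * x)` - a convex
#' combination of the window's values, bounded by its extremes.
#'
#' @param feature (H, W, C) array with sides divisible by `kernel`.
#' @param kernel pooling window side (= stride).
#' @return (H/k, W/k, C) array.
#' @export
softpool <- function(feature, kernel) {
  tok <- tokens_from_array(feature)
  array_from_tokens(softpool_fwd(tok, as.integer(kernel))$y)
}

#' Distortion Perception Block
#'
#' 1x1 convolution merging channels to C/8, SoftPool reducing each spatial
#' side by `input_size/32` (12 at the 384 reference resolution), flatten,
#' and a linear map to the per-stage distortion vector of length
#' `semantic_len`.
#'
#' @param feature stage feature (H, W, C) array.
#' @param config an [model_config()].
#' @param params parameter list.
#' @param stage stage index 1-4.
#' @return numeric vector of length `config$semantic_len`.
#' @export
dpb_forward <- function(feature, config, params, stage) {
  d <- dim(feature)
  if (d[3] %% 8L) stop("dpb_forward: channels ", d[3], " not divisible by 8")
  kp <- config$input_size %/% 32L
  if (d[1] %% kp) stop("dpb_forward: side ", d[1], " not divisible by ", kp)
  tok <- tokens_from_array(feature)
  as.numeric(dpb_fwd(tok, params, stage, config)$v)
}

#' Build the semantic vector
#' @param stages list of four stage features ((H, W, C) arrays).
#' @param config,params as elsewhere.
#' @return numeric vector of length L = 4 * semantic_len, stage order.
#' @export
build_semantic_vector <- function(stages, config, params) {
  toks <- lapply(stages, tokens_from_array)
  as.numeric(semantic_fwd(toks, params, config)$v)
}

#' 1x1 channel-halving convolution (hypernetwork merge)
#' @param feature (H, W, D) array with even channel count.
#' @param W,b weight (D x D/2) and bias.
#' @return (H, W, D/2) array.
#' @export
channel_merge <- function(feature, W, b) {
  d <- dim(feature)
  if (d[3] %% 2L) stop("channel_merge: odd channel count ", d[3])
  tok <- tokens_from_array(feature)
  y <- linear_fwd(tok, W, b)$y
  array_from_tokens(with_hwb(y, d[1], d[2], 1L))
}

#' Generate one target-layer weight matrix / bias vector
#'
#' `pgl_weight`: 3x3 convolution (padding 1) with `ceiling(E/A)` output
#' channels (A = spatial area, E = in_dim*out_dim), flattened
#' spatial-fastest in channel-block order, truncated to E elements,
#' reshaped (column-major) to (in_dim x out_dim) and scaled by
#' `1/sqrt(in_dim)` (fan-in scaling, keeping the generated layer's output
#' magnitude comparable to its input). `pgl_bias`: global SoftPool over
#' the spatial grid followed by a linear map to `out_dim`.
#'
#' @param feature hypernet stage feature (H, W, m).
#' @param in_dim,out_dim target layer dimensions.
#' @param Wc,bc 3x3 convolution parameters ((9*m) x K and K).
#' @param Wl,bl bias-branch linear parameters (m x out_dim and out_dim).
#' @return `pgl_weight`: (in_dim x out_dim) matrix; `pgl_bias`: numeric
#'   vector of length out_dim.
#' @export
pgl_weight <- function(feature, in_dim, out_dim, Wc, bc) {
  E <- in_dim * out_dim
  if (E == 0) stop("pgl_weight: empty layer shape")
  tok <- tokens_from_array(feature)
  arr <- array_from_tokens(tok)
  wc <- conv2d_fwd(arr, Wc, bc, 3L, 1L, 1L)
  avail <- length(wc$y)
  if (avail < E)
    stop("pgl_weight: conv emits ", avail, " elements, need ", E)
  matrix(as.numeric(wc$y)[seq_len(E)] / sqrt(in_dim), in_dim, out_dim)
}

#' @rdname pgl_weight
#' @export
pgl_bias <- function(feature, out_dim, Wl, bl) {
  d <- dim(feature)
  tok <- tokens_from_array(feature)
  pooled <- softpool_fwd(tok, d[1])$y
  as.numeric(linear_fwd(pooled, Wl, bl)$y)
}

#' Run the hypernetwork
#'
#' @param x3 deepest backbone feature ((S/32, S/32, 8C) array).
#' @param config,params as elsewhere.
#' @return list of five `list(wp, bp)` matching
#'   [plan_target_shapes()]`(4 * semantic_len)`.
#' @export
hypernet_forward <- function(x3, config, params) {
  layers <- hypernet_fwd(tokens_from_array(x3), params, config)$layers
  lapply(layers, function(x) list(wp = x$wp[[1]], bp = as.numeric(x$bp)))
}

#' Run the target network
#'
#' Five functional linear layers whose parameters are supplied (by the
#' hypernetwork), with GELU between layers 1-4 and a raw scalar output.
#'
#' @param v semantic vector (length L).
#' @param layers list of five `list(wp, bp)`.
#' @param clamp if `TRUE`, clamp the score to [0, 100].
#' @return predicted quality score (numeric scalar).
#' @export
target_forward <- function(v, layers, clamp = FALSE) {
  batched <- lapply(layers, function(x)
    list(wp = list(x$wp), bp = matrix(x$bp, 1, length(x$bp))))
  s <- target_fwd(matrix(v, 1), batched)$score
  if (clamp) s <- min(100, max(0, s))
  s
}

#' Full model forward pass
#'
#' Backbone -> (semantic vector, hypernetwork) -> generated scoring head.
#' Deterministic: repeated calls with the same weights and image give the
#' same score.
#'
#' @param image (H, W, 3) array at `config$input_size`.
#' @param config,params as elsewhere.
#' @param clamp clamp the score to [0, 100].
#' @return numeric scalar score.
#' @export
fthnet_forward <- function(image, config, params, clamp = FALSE) {
  s <- fthnet_fwd(image, params, config)$score
  if (clamp) s <- min(100, max(0, s))
  s
}
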