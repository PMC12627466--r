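# Transformer backbone: patch embedding, four stages of windowed-attention
# blocks with alternating cyclic shifts, strided-convolution downsampling.
# The per-window attention loops run in compiled code (src/attention.cpp);
# everything around them is batched matrix algebra.

# Per-stage geometry (window/shift permutations, attention masks for
# wrapped windows, relative-position index), memoised per (H, W, w, B).
.geom_cache <- new.env(parent = emptyenv())

stage_geometry <- function(H, W, w, B = 1L) {
  key <- paste(H, W, w, B, sep = "x")
  g <- .geom_cache[[key]]
  if (!is.null(g)) return(g)
  s <- w %/% 2L
  win1 <- window_index(H, W, w)
  shf1 <- shift_index(H, W, s)
  # region ids live in shifted coordinates (Swin convention): partitioning
  # them directly yields the mask for the cyclically shifted feature
  rid_win <- shift_region_ids(H, W, w, s)[win1]
  w2 <- w * w; nw <- (H * W) %/% w2
  mask_list <- list(); maskid1 <- integer(nw)
  for (k in seq_len(nw)) {
    ids <- rid_win[((k - 1) * w2 + 1):(k * w2)]
    if (length(unique(ids)) > 1L) {
      mask_list[[length(mask_list) + 1L]] <- -1e9 * outer(ids, ids, "!=")
      maskid1[k] <- length(mask_list)
    }
  }
  masks <- if (length(mask_list))
    array(unlist(mask_list), c(w2, w2, length(mask_list)))
  else array(0, c(w2, w2, 0))
  win <- batch_perm(win1, B, H * W)
  shf <- batch_perm(shf1, B, H * W)
  g <- list(win = win, inv_win = inverse_perm(win),
            shf = shf, inv_shf = inverse_perm(shf),
            masks = masks, maskid = rep.int(maskid1, B),
            no_mask = rep.int(0L, nw * B),
            rp_idx = relpos_index(w), w = w, w2 = w2, nwB = nw * B)
  .geom_cache[[key]] <- g
  g
}

# Expand a relative-position-bias table to per-head (w2, w2, heads) matrices.
rpb_cube <- function(rpb, rp_idx, w2) {
  heads <- ncol(rpb)
  cube <- array(0, c(w2, w2, heads))
  for (h in seq_len(heads)) cube[, , h] <- matrix(rpb[, h][rp_idx], w2, w2)
  cube
}

# Multi-head windowed attention over window-major batched tokens.
attn_fwd <- function(xw, geom, heads, Wqkv, bqkv, Wproj, bproj,
                     rpb = NULL, masked = FALSE, keep = FALSE) {
  C <- ncol(xw)
  hd <- C %/% heads; scale <- 1 / sqrt(hd)
  qkv <- xw %*% Wqkv
  add_bias_inplace(qkv, bqkv)
  use_bias <- !is.null(rpb)
  bias <- if (use_bias) rpb_cube(rpb, geom$rp_idx, geom$w2)
          else array(0, c(geom$w2, geom$w2, 0))
  core <- attn_core_fwd(qkv, geom$w2, heads, bias, use_bias, geom$masks,
                        if (masked) geom$maskid else geom$no_mask,
                        scale, keep)
  y <- core$out %*% Wproj
  add_bias_inplace(y, bproj)
  cache <- if (keep) list(xw = xw, qkv = qkv, oc = core$out, A = core$A,
                          heads = heads, scale = scale, geom = geom)
  list(y = y, cache = cache)
}

attn_bwd <- function(dy, Wqkv, Wproj, rpb, cache) {
  geom <- cache$geom
  dWproj <- crossprod(cache$oc, dy)
  dbproj <- colSums(dy)
  doc <- dy %*% t(Wproj)
  core <- attn_core_bwd(doc, cache$qkv, cache$A, geom$w2, cache$heads,
                        cache$scale, !is.null(rpb))
  drpb <- NULL
  if (!is.null(rpb)) {
    drpb <- matrix(0, nrow(rpb), ncol(rpb))
    iv <- as.vector(geom$rp_idx)
    for (h in seq_len(ncol(rpb))) {
      acc <- rowsum(as.vector(core$dbias[, , h]), iv)
      drpb[as.integer(rownames(acc)), h] <- acc
    }
  }
  dqkv <- core$dqkv
  dxw <- dqkv %*% t(Wqkv)
  dWqkv <- crossprod(cache$xw, dqkv)
  dbqkv <- colSums(dqkv)
  list(dx = dxw, dWqkv = dWqkv, dbqkv = dbqkv,
       dWproj = dWproj, dbproj = dbproj, drpb = drpb)
}

# One Basic Transformer Block on a batched token matrix.
block_fwd <- function(tok, params, pfx, heads, geom, shifted, keep = FALSE) {
  ln1 <- layernorm_fwd(tok, params[[paste0(pfx, "ln1.g")]],
                       params[[paste0(pfx, "ln1.b")]])
  x <- ln1$y
  if (shifted) x <- x[geom$shf, , drop = FALSE]
  xw <- x[geom$win, , drop = FALSE]
  at <- attn_fwd(xw, geom, heads,
                 params[[paste0(pfx, "qkv.W")]], params[[paste0(pfx, "qkv.b")]],
                 params[[paste0(pfx, "proj.W")]], params[[paste0(pfx, "proj.b")]],
                 rpb = params[[paste0(pfx, "rpb")]],
                 masked = shifted, keep = keep)
  y <- at$y[geom$inv_win, , drop = FALSE]
  if (shifted) y <- y[geom$inv_shf, , drop = FALSE]
  f1 <- tok + y
  ln2 <- layernorm_fwd(f1, params[[paste0(pfx, "ln2.g")]],
                       params[[paste0(pfx, "ln2.b")]])
  h1 <- linear_fwd(ln2$y, params[[paste0(pfx, "fc1.W")]],
                   params[[paste0(pfx, "fc1.b")]])
  g1 <- gelu_fwd(h1$y)
  h2 <- linear_fwd(g1$y, params[[paste0(pfx, "fc2.W")]],
                   params[[paste0(pfx, "fc2.b")]])
  out <- copy_hwb(f1 + h2$y, tok)
  cache <- if (keep) list(ln1 = ln1$cache, at = at$cache, ln2 = ln2$cache,
                          h1x = h1$cache, g1x = g1$cache, h2x = h2$cache,
                          geom = geom, shifted = shifted)
  list(y = out, cache = cache)
}

block_bwd <- function(dy, params, pfx, cache, grads) {
  geom <- cache$geom
  # MLP branch
  dh2 <- linear_bwd(dy, params[[paste0(pfx, "fc2.W")]], cache$h2x)
  add_grad(grads, paste0(pfx, "fc2.W"), dh2$dW)
  add_grad(grads, paste0(pfx, "fc2.b"), dh2$db)
  dg1 <- gelu_bwd(dh2$dx, cache$g1x)
  dh1 <- linear_bwd(dg1, params[[paste0(pfx, "fc1.W")]], cache$h1x)
  add_grad(grads, paste0(pfx, "fc1.W"), dh1$dW)
  add_grad(grads, paste0(pfx, "fc1.b"), dh1$db)
  dln2 <- layernorm_bwd(dh1$dx, cache$ln2)
  add_grad(grads, paste0(pfx, "ln2.g"), dln2$dg)
  add_grad(grads, paste0(pfx, "ln2.b"), dln2$db)
  df1 <- dy + dln2$dx
  # attention branch
  dyb <- df1
  if (cache$shifted) dyb <- dyb[geom$shf, , drop = FALSE]
  dyw <- dyb[geom$win, , drop = FALSE]
  ab <- attn_bwd(dyw, params[[paste0(pfx, "qkv.W")]],
                 params[[paste0(pfx, "proj.W")]],
                 params[[paste0(pfx, "rpb")]], cache$at)
  add_grad(grads, paste0(pfx, "qkv.W"), ab$dWqkv)
  add_grad(grads, paste0(pfx, "qkv.b"), ab$dbqkv)
  add_grad(grads, paste0(pfx, "proj.W"), ab$dWproj)
  add_grad(grads, paste0(pfx, "proj.b"), ab$dbproj)
  if (!is.null(ab$drpb)) add_grad(grads, paste0(pfx, "rpb"), ab$drpb)
  dx_attn <- ab$dx[geom$inv_win, , drop = FALSE]
  if (cache$shifted) dx_attn <- dx_attn[geom$inv_shf, , drop = FALSE]
  dln1 <- layernorm_bwd(dx_attn, cache$ln1)
  add_grad(grads, paste0(pfx, "ln1.g"), dln1$dg)
  add_grad(grads, paste0(pfx, "ln1.b"), dln1$db)
  df1 + dln1$dx
}

# Gradient accumulator: an environment of arrays keyed by parameter name.
new_grads <- function() new.env(parent = emptyenv())

add_grad <- function(grads, name, value) {
  cur <- grads[[name]]
  grads[[name]] <- if (is.null(cur)) value else cur + value
  invisible(NULL)
}

grads_as_list <- function(grads, shapes) {
  out <- lapply(names(shapes), function(nm) {
    g <- grads[[nm]]
    if (is.null(g)) {
      d <- shapes[[nm]]
      g <- if (length(d) > 1) matrix(0, d[1], d[2]) else rep(0, d)
    }
    g
  })
  names(out) <- names(shapes)
  out
}

# image: (H, W, 3) array or (H, W, 3, B) batch.
backbone_fwd <- function(image, params, config, keep = FALSE) {
  d <- dim(image)
  if (d[1] %% 32L || d[2] %% 32L)
    stop("backbone: image sides (", d[1], ", ", d[2],
         ") must be divisible by 32")
  pe <- conv2d_fwd(image, params[["embed.W"]], params[["embed.b"]], 4L, 4L)
  tok <- pe$y
  stages <- vector("list", 4)
  caches <- list(pe = if (keep) pe$cache, blocks = list(), ds = list())
  for (i in 1:4) {
    geom <- stage_geometry(attr(tok, "H"), attr(tok, "W"), config$window,
                           batch_size(tok))
    heads <- stage_heads(config, i)
    for (j in seq_len(config$depths[i])) {
      pfx <- sprintf("bb.s%d.b%d.", i, j)
      bf <- block_fwd(tok, params, pfx, heads, geom,
                      shifted = (j %% 2L == 0L), keep = keep)
      tok <- bf$y
      if (keep) caches$blocks[[pfx]] <- bf$cache
    }
    stages[[i]] <- tok
    if (i < 4) {
      arr <- array_from_tokens(tok)
      ds <- conv2d_fwd(arr, params[[sprintf("bb.ds%d.W", i)]],
                       params[[sprintf("bb.ds%d.b", i)]],
                       config$downsample_kernel, 2L)
      tok <- ds$y
      if (keep) caches$ds[[i]] <- ds$cache
    }
  }
  list(stages = stages, cache = if (keep) caches)
}

# dstages: list of four gradients w.r.t. the stage outputs (NULL skipped).
backbone_bwd <- function(dstages, params, config, cache, grads) {
  d <- NULL
  for (i in 4:1) {
    if (i < 4) {
      dsb <- conv2d_bwd(d, params[[sprintf("bb.ds%d.W", i)]], cache$ds[[i]])
      add_grad(grads, sprintf("bb.ds%d.W", i), dsb$dW)
      add_grad(grads, sprintf("bb.ds%d.b", i), dsb$db)
      d <- tokens_from_array(dsb$dx)
    }
    if (!is.null(dstages[[i]]))
      d <- if (is.null(d)) dstages[[i]] else d + dstages[[i]]
    for (j in rev(seq_len(config$depths[i]))) {
      pfx <- sprintf("bb.s%d.b%d.", i, j)
      d <- block_bwd(d, params, pfx, cache$blocks[[pfx]], grads)
    }
  }
  peb <- conv2d_bwd(d, params[["embed.W"]], cache$pe)
  add_grad(grads, "embed.W", peb$dW)
  add_grad(grads, "embed.b", peb$db)
  invisible(peb$dx)
}
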