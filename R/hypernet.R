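# Parameter Hypernetwork: five stages of channel-halving 1x1 convolutions
# and Parameter Generating Layers that emit the weight matrix and bias
# vector of each target-network layer from the deepest backbone feature.
#
# The deepest feature X_3 (8C channels) is first merged to the hypernet's
# internal width m0 by a 1x1 convolution; stage i (i = 1..5) then works at
# width m0 / 2^(i-1). Each PGL generates a weight matrix through a 3x3
# convolution with ceiling(E / A) output channels (A = spatial area,
# E = in_dim * out_dim), flattened (spatial-fastest, channel blocks in
# order) and truncated to the first E elements, and a bias vector through
# global SoftPool followed by a linear layer. Generated parameters are
# activations: they carry gradient back into the hypernetwork but are not
# themselves trainable.

pgl_fwd <- function(ptok, params, i, plan, keep = FALSE) {
  p <- sprintf("hyp.pgl%d.", i)
  H <- attr(ptok, "H"); B <- batch_size(ptok)
  arr <- array_from_tokens(ptok)
  wc <- conv2d_fwd(arr, params[[paste0(p, "wconv.W")]],
                   params[[paste0(p, "wconv.b")]], 3L, 1L, 1L)
  ind <- plan[[i]]$in_dim; outd <- plan[[i]]$out_dim
  E <- ind * outd
  A <- nrow(wc$y) %/% B
  wscale <- 1 / sqrt(ind) # fan-in scaling keeps target activations O(1)
  wp <- lapply(seq_len(B), function(b) {
    flat <- as.numeric(wc$y[((b - 1) * A + 1):(b * A), , drop = FALSE])
    matrix(flat[seq_len(E)] * wscale, ind, outd)
  })
  sp <- softpool_fwd(ptok, H) # global pool: one token per image
  bl <- linear_fwd(sp$y, params[[paste0(p, "blin.W")]],
                   params[[paste0(p, "blin.b")]])
  cache <- if (keep) list(wc = wc$cache, sp = sp$cache, spy = sp$y,
                          ydim = dim(wc$y), E = E, A = A, B = B,
                          wscale = wscale)
  list(wp = wp, bp = bl$y, cache = cache) # bp: (B, out_dim)
}

pgl_bwd <- function(dwp, dbp, params, i, cache, grads) {
  p <- sprintf("hyp.pgl%d.", i)
  bl <- linear_bwd(dbp, params[[paste0(p, "blin.W")]], cache$spy)
  add_grad(grads, paste0(p, "blin.W"), bl$dW)
  add_grad(grads, paste0(p, "blin.b"), bl$db)
  dtok_pool <- softpool_bwd(bl$dx, cache$sp)
  dy <- matrix(0, cache$ydim[1], cache$ydim[2])
  K <- cache$ydim[2]; A <- cache$A
  for (b in seq_len(cache$B)) {
    dflat <- numeric(A * K)
    dflat[seq_len(cache$E)] <- as.numeric(dwp[[b]]) * cache$wscale
    dy[((b - 1) * A + 1):(b * A), ] <- matrix(dflat, A, K)
  }
  cb <- conv2d_bwd(dy, params[[paste0(p, "wconv.W")]], cache$wc)
  add_grad(grads, paste0(p, "wconv.W"), cb$dW)
  add_grad(grads, paste0(p, "wconv.b"), cb$db)
  dtok_conv <- tokens_from_array(cb$dx)
  dtok_pool + dtok_conv
}

hypernet_fwd <- function(x3, params, config, keep = FALSE) {
  plan <- plan_target_shapes(4L * config$semantic_len)
  inc <- linear_fwd(x3, params[["hyp.in.W"]], params[["hyp.in.b"]])
  ptok <- copy_hwb(inc$y, x3)
  layers <- vector("list", 5)
  caches <- list(inc = if (keep) inc$cache, merges = list(), pgls = list())
  for (i in 1:5) {
    if (i > 1) {
      mg <- linear_fwd(ptok, params[[sprintf("hyp.merge%d.W", i - 1L)]],
                       params[[sprintf("hyp.merge%d.b", i - 1L)]])
      if (keep) caches$merges[[i - 1L]] <- mg$cache
      ptok <- copy_hwb(mg$y, ptok)
    }
    pg <- pgl_fwd(ptok, params, i, plan, keep)
    layers[[i]] <- list(wp = pg$wp, bp = pg$bp)
    if (keep) caches$pgls[[i]] <- pg$cache
  }
  list(layers = layers, cache = if (keep) caches)
}

hypernet_bwd <- function(dlayers, params, config, cache, grads) {
  dptok <- NULL
  for (i in 5:1) {
    dtok <- pgl_bwd(dlayers[[i]]$dwp, dlayers[[i]]$dbp, params, i,
                    cache$pgls[[i]], grads)
    dptok <- if (is.null(dptok)) dtok else dptok + dtok
    if (i > 1) {
      mb <- linear_bwd(dptok, params[[sprintf("hyp.merge%d.W", i - 1L)]],
                       cache$merges[[i - 1L]])
      add_grad(grads, sprintf("hyp.merge%d.W", i - 1L), mb$dW)
      add_grad(grads, sprintf("hyp.merge%d.b", i - 1L), mb$db)
      dptok <- mb$dx
    }
  }
  ib <- linear_bwd(dptok, params[["hyp.in.W"]], cache$inc)
  add_grad(grads, "hyp.in.W", ib$dW)
  add_grad(grads, "hyp.in.b", ib$db)
  ib$dx # gradient w.r.t. X_3 tokens
}
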