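# Distortion Perception Network: one block per backbone stage
# (1x1 channel-merge convolution -> SoftPool -> flatten -> linear),
# concatenated into the semantic vector V. Batch-aware throughout: the
# semantic vectors of a batch form the rows of a (B, L) matrix.

# flatten a batched pooled feature (B*ng rows) into one row per image
flatten_pooled <- function(y, B) {
  ng <- nrow(y) %/% B; C <- ncol(y)
  y3 <- array(as.numeric(y), c(ng, B, C))
  matrix(aperm(y3, c(2, 1, 3)), B, ng * C)
}

unflatten_pooled <- function(dflat, B, ng, C) {
  d3 <- array(as.numeric(dflat), c(B, ng, C))
  matrix(aperm(d3, c(2, 1, 3)), ng * B, C)
}

dpb_fwd <- function(tok, params, i, config, keep = FALSE) {
  p <- sprintf("dpb.s%d.", i)
  cm <- linear_fwd(tok, params[[paste0(p, "conv.W")]],
                   params[[paste0(p, "conv.b")]])
  y1 <- copy_hwb(cm$y, tok)
  kp <- config$input_size %/% 32L
  sp <- softpool_fwd(y1, kp)
  B <- batch_size(tok)
  flat <- flatten_pooled(sp$y, B)
  li <- linear_fwd(flat, params[[paste0(p, "lin.W")]],
                   params[[paste0(p, "lin.b")]])
  cache <- if (keep) list(cm = cm$cache, sp = sp$cache, flat = flat,
                          B = B, ng = nrow(sp$y) %/% B, C8 = ncol(sp$y))
  list(v = li$y, cache = cache) # (B, l)
}

dpb_bwd <- function(dv, params, i, cache, grads) {
  p <- sprintf("dpb.s%d.", i)
  lb <- linear_bwd(dv, params[[paste0(p, "lin.W")]], cache$flat)
  add_grad(grads, paste0(p, "lin.W"), lb$dW)
  add_grad(grads, paste0(p, "lin.b"), lb$db)
  dpool <- unflatten_pooled(lb$dx, cache$B, cache$ng, cache$C8)
  dy1 <- softpool_bwd(dpool, cache$sp)
  cb <- linear_bwd(dy1, params[[paste0(p, "conv.W")]], cache$cm)
  add_grad(grads, paste0(p, "conv.W"), cb$dW)
  add_grad(grads, paste0(p, "conv.b"), cb$db)
  cb$dx # gradient w.r.t. the stage tokens
}

semantic_fwd <- function(stages, params, config, keep = FALSE) {
  parts <- lapply(1:4, function(i) dpb_fwd(stages[[i]], params, i, config, keep))
  list(v = do.call(cbind, lapply(parts, `[[`, "v")), # (B, 4l)
       cache = if (keep) lapply(parts, `[[`, "cache"))
}

semantic_bwd <- function(dv, params, config, cache, grads) {
  l <- config$semantic_len
  lapply(1:4, function(i) {
    dpb_bwd(dv[, ((i - 1) * l + 1):(i * l), drop = FALSE],
            params, i, cache[[i]], grads)
  })
}
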