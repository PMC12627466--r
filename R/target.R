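# Target Network (the generated scoring head) and full-model composition.
# The head's five linear layers have per-image parameters, so this is the
# one place the batch is processed image by image (the matrices are tiny).

# Parameter-free per-image standardisation of the semantic vector (zero
# mean, unit variance across its L entries). Decouples the scoring head
# from the scale of the unnormalised backbone features; without it the
# multiplicative hypernetwork path is numerically fragile.
vnorm_fwd <- function(v) {
  mu <- rowMeans(v)
  xc <- v - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + .LN_EPS)
  xhat <- xc * inv
  list(y = xhat, cache = list(xhat = xhat, inv = inv))
}

vnorm_bwd <- function(dy, cache) {
  xhat <- cache$xhat
  m1 <- rowMeans(dy)
  m2 <- rowMeans(dy * xhat)
  cache$inv * (dy - m1 - xhat * m2)
}

# v: (B, L) semantic vectors; layers[[i]]$wp: list of B matrices;
# layers[[i]]$bp: (B, out_dim). GELU between layers 1-4, none on layer 5.
target_fwd <- function(v, layers, keep = FALSE) {
  B <- nrow(v)
  scores <- numeric(B)
  caches <- if (keep) vector("list", B)
  for (b in seq_len(B)) {
    x <- v[b, , drop = FALSE]
    cb <- if (keep) vector("list", 5)
    for (i in 1:5) {
      wp <- layers[[i]]$wp[[b]]
      bp <- layers[[i]]$bp[b, ]
      if (ncol(x) != nrow(wp))
        stop("target_fwd: shape mismatch at layer ", i, ": input ",
             ncol(x), " vs weight ", nrow(wp), "x", ncol(wp))
      li <- linear_fwd(x, wp, bp)
      if (i < 5) {
        g <- gelu_fwd(li$y)
        if (keep) cb[[i]] <- list(x = li$cache, pre = g$cache)
        x <- g$y
      } else {
        if (keep) cb[[i]] <- list(x = li$cache)
        x <- li$y
      }
    }
    scores[b] <- as.numeric(x)
    if (keep) caches[[b]] <- cb
  }
  list(score = scores, cache = if (keep) caches)
}

# dscore: length-B vector. Returns (B, L) gradient w.r.t. v and per-layer
# generated-parameter gradients mirroring the layers structure.
target_bwd <- function(dscore, layers, cache) {
  B <- length(dscore)
  L <- nrow(layers[[1]]$wp[[1]])
  dv <- matrix(0, B, L)
  dlayers <- lapply(1:5, function(i)
    list(dwp = vector("list", B),
         dbp = matrix(0, B, ncol(layers[[i]]$wp[[1]]))))
  for (b in seq_len(B)) {
    dx <- matrix(dscore[b], 1, 1)
    for (i in 5:1) {
      if (i < 5) dx <- gelu_bwd(dx, cache[[b]][[i]]$pre)
      lb <- linear_bwd(dx, layers[[i]]$wp[[b]], cache[[b]][[i]]$x)
      dlayers[[i]]$dwp[[b]] <- lb$dW
      dlayers[[i]]$dbp[b, ] <- lb$db
      dx <- lb$dx
    }
    dv[b, ] <- dx
  }
  list(dv = dv, dlayers = dlayers)
}

# Full forward pass on an image array (H, W, 3) or batch (H, W, 3, B).
fthnet_fwd <- function(image, params, config, keep = FALSE) {
  bb <- backbone_fwd(image, params, config, keep)
  sem <- semantic_fwd(bb$stages, params, config, keep)
  vn <- vnorm_fwd(sem$v)
  B <- nrow(sem$v)
  if (config$hypernet) {
    hyp <- hypernet_fwd(bb$stages[[4]], params, config, keep)
    layers <- hyp$layers
  } else {
    hyp <- NULL
    layers <- lapply(1:5, function(i)
      list(wp = rep(list(params[[sprintf("head%d.W", i)]]), B),
           bp = matrix(params[[sprintf("head%d.b", i)]], B,
                       length(params[[sprintf("head%d.b", i)]]),
                       byrow = TRUE)))
  }
  tg <- target_fwd(vn$y, layers, keep)
  list(score = tg$score, v = sem$v, stages = bb$stages, layers = layers,
       cache = if (keep) list(bb = bb$cache, sem = sem$cache, vn = vn$cache,
                              hyp = if (!is.null(hyp)) hyp$cache,
                              tg = tg$cache))
}

# Backward from per-image score gradients; accumulates into `grads`.
fthnet_bwd <- function(dscore, fwd, params, config, grads) {
  tb <- target_bwd(dscore, fwd$layers, fwd$cache$tg)
  dv <- vnorm_bwd(tb$dv, fwd$cache$vn)
  dstages <- semantic_bwd(dv, params, config, fwd$cache$sem, grads)
  if (config$hypernet) {
    dx3 <- hypernet_bwd(tb$dlayers, params, config, fwd$cache$hyp, grads)
    dstages[[4]] <- dstages[[4]] + dx3
  } else {
    B <- length(dscore)
    for (i in 1:5) {
      dW <- Reduce(`+`, tb$dlayers[[i]]$dwp)
      add_grad(grads, sprintf("head%d.W", i), dW)
      add_grad(grads, sprintf("head%d.b", i), colSums(tb$dlayers[[i]]$dbp))
    }
  }
  backbone_bwd(dstages, params, config, fwd$cache$bb, grads)
  invisible(NULL)
}
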