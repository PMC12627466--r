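# Distortion perception network, hypernetwork and target network
# contracts, plus full-model gradient flow.

test_that("DPB output length is stage-independent and linear in weights", {
  cfg <- micro_config()
  p <- micro_params()
  st <- backbone_forward(random_image(64), cfg, p)
  vs <- lapply(1:4, function(i) dpb_forward(st[[i]], cfg, p, i))
  for (v in vs) expect_length(v, cfg$semantic_len)
  # zero weights give the zero vector
  p0 <- p
  p0[["dpb.s2.conv.W"]] <- p0[["dpb.s2.conv.W"]] * 0
  p0[["dpb.s2.conv.b"]] <- p0[["dpb.s2.conv.b"]] * 0
  p0[["dpb.s2.lin.W"]] <- p0[["dpb.s2.lin.W"]] * 0
  p0[["dpb.s2.lin.b"]] <- p0[["dpb.s2.lin.b"]] * 0
  expect_equal(dpb_forward(st[[2]], cfg, p0, 2), rep(0, cfg$semantic_len))
  # semantic vector: stage-ordered concatenation
  V <- build_semantic_vector(st, cfg, p)
  expect_length(V, 4L * cfg$semantic_len)
  expect_equal(V[1:cfg$semantic_len], vs[[1]])
  expect_equal(V[(3 * cfg$semantic_len + 1):(4 * cfg$semantic_len)], vs[[4]])
  # concatenation is ordered: swapping two per-stage vectors changes V,
  # and feeding stages out of order is a shape error (stage widths differ)
  expect_false(identical(V, c(vs[[2]], vs[[1]], vs[[3]], vs[[4]])))
  expect_error(build_semantic_vector(st[c(2, 1, 3, 4)], cfg, p))
})

test_that("target shape plan halves widths down to a scalar", {
  plan <- plan_target_shapes(384)
  expect_equal(vapply(plan, `[[`, 0L, "in_dim"), c(384L, 192L, 96L, 48L, 24L))
  expect_equal(vapply(plan, `[[`, 0L, "out_dim"), c(192L, 96L, 48L, 24L, 1L))
  plan16 <- plan_target_shapes(16)
  expect_equal(vapply(plan16, `[[`, 0L, "out_dim"), c(8L, 4L, 2L, 1L, 1L))
  expect_error(plan_target_shapes(100), "16")
})

test_that("PGL channel counts follow the ceiling rule", {
  # at 384 input (A = 144) and L = 384 the first generated layer needs
  # E = 384*192 = 73728 elements: K = 512 exactly (no truncation); the
  # last needs 24: K = 1 with truncation 144 -> 24
  cfg <- model_config(depths = c(1, 1, 1, 1), embed_channels = 32,
                      semantic_len = 96L, hyper_width = 160L)
  sh <- fthnet:::fthnet_shapes(cfg)
  expect_equal(sh[["hyp.pgl1.wconv.W"]][2], 512)
  expect_equal(sh[["hyp.pgl5.wconv.W"]][2], 1)
  expect_equal(sh[["hyp.pgl1.blin.W"]], c(160, 192))
  # element conservation: K * A >= E for every layer
  plan <- plan_target_shapes(384)
  for (i in 1:5) {
    E <- plan[[i]]$in_dim * plan[[i]]$out_dim
    K <- sh[[sprintf("hyp.pgl%d.wconv.W", i)]][2]
    expect_gte(K * 144, E)
    expect_lt((K - 1) * 144, E)
  }
})

test_that("hypernetwork emits shape-exact, input-dependent parameters", {
  cfg <- micro_config()
  p <- micro_params()
  st1 <- backbone_forward(random_image(64, seed = 1), cfg, p)
  st2 <- backbone_forward(random_image(64, seed = 2), cfg, p)
  plan <- plan_target_shapes(4L * cfg$semantic_len)
  layers1 <- hypernet_forward(st1[[4]], cfg, p)
  layers2 <- hypernet_forward(st2[[4]], cfg, p)
  for (i in 1:5) {
    expect_equal(dim(layers1[[i]]$wp),
                 c(plan[[i]]$in_dim, plan[[i]]$out_dim))
    expect_length(layers1[[i]]$bp, plan[[i]]$out_dim)
    expect_true(all(is.finite(layers1[[i]]$wp)))
  }
  expect_gt(max(abs(layers1[[1]]$wp - layers2[[1]]$wp)), 0)
  # channel merge halves channels, keeps space
  x3 <- st1[[4]]
  D <- dim(x3)[3]
  withr::with_seed(7, Wm <- matrix(rnorm(D * D / 2), D, D / 2))
  merged <- channel_merge(x3, Wm, rep(0, D / 2))
  expect_equal(dim(merged), c(dim(x3)[1], dim(x3)[2], D / 2))
  expect_error(channel_merge(x3[, , 1:3, drop = FALSE],
                             matrix(0, 3, 1), 0), "odd")
})

test_that("pgl branches behave linearly and respect truncation", {
  withr::with_seed(13, f <- array(rnorm(2 * 2 * 4), c(2, 2, 4)))
  # zero conv -> zero weight matrix; zero linear -> zero bias
  expect_equal(pgl_weight(f, 4, 2, matrix(0, 36, 2), rep(0, 2)),
               matrix(0, 4, 2))
  expect_equal(pgl_bias(f, 3, matrix(0, 4, 3), rep(0, 3)), rep(0, 3))
  # constant feature: global softpool returns the constant
  fc <- array(2.5, c(2, 2, 4))
  expect_equal(pgl_bias(fc, 4, diag(4), rep(0, 4)), rep(2.5, 4))
  # truncation: E < K*A drops the tail deterministically
  withr::with_seed(14, {
    Wc <- matrix(rnorm(36 * 2), 36, 2)
    bc <- rnorm(2)
  })
  w_small <- pgl_weight(f, 2, 1, Wc, bc) # E = 2 of A*K = 8 elements
  w_big <- pgl_weight(f, 2, 2, Wc, bc)   # E = 4
  expect_equal(as.numeric(w_small), as.numeric(w_big)[1:2], tolerance = 1e-12)
})

test_that("target network composes functional linear layers", {
  plan <- plan_target_shapes(16)
  # all-zero parameters give a zero score
  zero_layers <- lapply(plan, function(pl)
    list(wp = matrix(0, pl$in_dim, pl$out_dim), bp = rep(0, pl$out_dim)))
  expect_equal(target_forward(rnorm(16), zero_layers), 0)
  # hand-set params against an explicit matrix-arithmetic oracle
  withr::with_seed(15, {
    layers <- lapply(plan, function(pl)
      list(wp = matrix(rnorm(pl$in_dim * pl$out_dim, sd = 0.3),
                       pl$in_dim, pl$out_dim),
           bp = rnorm(pl$out_dim, sd = 0.1)))
    v <- rnorm(16)
  })
  x <- matrix(v, 1)
  for (i in 1:5) {
    x <- x %*% layers[[i]]$wp + matrix(layers[[i]]$bp, 1)
    if (i < 5) x <- x * pnorm(x)
  }
  expect_equal(target_forward(v, layers), as.numeric(x), tolerance = 1e-9)
  # shape mismatches identify the offending layer
  bad <- layers; bad[[3]]$wp <- matrix(0, 5, 2)
  expect_error(target_forward(v, bad), "layer 3")
  # clamping
  big <- layers; big[[5]]$bp <- 1e4
  expect_equal(target_forward(v, big, clamp = TRUE), 100)
})

test_that("every trainable parameter receives gradient from the loss", {
  cfg <- micro_config()
  p <- micro_params()
  imgs <- array(c(random_image(64, seed = 1), random_image(64, seed = 2)),
                c(64, 64, 3, 2))
  fw <- fthnet:::fthnet_fwd(imgs, p, cfg, keep = TRUE)
  grads <- fthnet:::new_grads()
  # targets inside the quadratic region, asymmetric so that no per-batch
  # gradient component can cancel to exactly zero
  fthnet:::fthnet_bwd(fthnet:::smooth_l1_grad(fw$score + c(0.3, 0.9), fw$score),
                      fw, p, cfg, grads)
  gl <- fthnet:::grads_as_list(grads, fthnet:::fthnet_shapes(cfg))
  norms <- vapply(gl, function(g) sqrt(sum(g^2)), 0)
  expect_true(all(norms > 0),
              info = paste("zero-gradient params:",
                           paste(names(norms)[norms == 0], collapse = ", ")))
})

test_that("static-head ablation trains its own target parameters", {
  cfg <- model_config(depths = c(1, 1, 1, 1), embed_channels = 8,
                      input_size = 64L, semantic_len = 16L,
                      hyper_width = 32L, hypernet = FALSE)
  p <- init_fthnet(cfg, 1)
  expect_true("head1.W" %in% names(p))
  expect_false(any(grepl("^hyp\\.", names(p))))
  img <- random_image(64)
  s <- fthnet_forward(img, cfg, p)
  expect_true(is.finite(s))
})

test_that("model configurations round-trip through YAML", {
  cfg <- fthnet_tiny()
  path <- file.path(tempdir(), "tiny.yaml")
  write_model_config(cfg, path)
  back <- read_model_config(path)
  expect_equal(back, cfg)
  expect_equal(count_parameters(back), count_parameters(cfg))
})
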