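# Training and evaluation pipeline: Adam, warmup + linear-annealing
# schedule, flip/crop augmentation, validation-based checkpoint selection,
# and cross-validation over re-drawn 80/5/15 splits.

#' Training configuration
#'
#' The reference schedule trains for 120000 iterations at batch 16 with
#' Adam, learning rate 0.5e-4, 1000 warmup iterations and linear annealing
#' to zero afterwards, with horizontal/vertical flips and random crops.
#' Desk presets keep the same optimiser and schedule shape at sizes a CPU
#' can run: `"tiny"` (300 iterations, batch 8, lr 1e-3, flips only) and
#' `"small-synthetic"` (2000 iterations, batch 8, lr 3e-4).
#'
#' @param preset `"reference"`, `"tiny"` or `"small-synthetic"`.
#' @param lr,iterations,warmup,batch,val_every,flip,crop,clip,tail_average,seed
#'   overrides of the preset values. `clip` is the global gradient-norm
#'   ceiling (`NULL` disables clipping); `tail_average` is the fraction of
#'   final iterations whose parameters are averaged (Polyak averaging) into
#'   the returned checkpoint when no validation-selected checkpoint exists
#'   - it damps the last-iterate noise of short schedules.
#' @return object of class `fthnet_train_config`.
#' @export
train_config <- function(preset = c("reference", "tiny", "small-synthetic"),
                         lr = NULL, iterations = NULL, warmup = NULL,
                         batch = NULL, val_every = NULL, flip = NULL,
                         crop = NULL, clip = NULL, tail_average = NULL,
                         seed = 1L) {
  preset <- match.arg(preset)
  base <- switch(preset,
    "reference" = list(lr = 0.5e-4, iterations = 120000L, warmup = 1000L,
                   batch = 16L, val_every = 1000L, flip = TRUE, crop = TRUE,
                   clip = 5, tail_average = 0),
    "tiny" = list(lr = 1e-3, iterations = 300L, warmup = 30L,
                  batch = 8L, val_every = 50L, flip = TRUE, crop = FALSE,
                  clip = 5, tail_average = 0.2),
    "small-synthetic" = list(lr = 3e-4, iterations = 2000L, warmup = 100L,
                             batch = 8L, val_every = 200L, flip = TRUE,
                             crop = FALSE, clip = 5, tail_average = 0.2))
  ov <- list(lr = lr, iterations = iterations, warmup = warmup, batch = batch,
             val_every = val_every, flip = flip, crop = crop, clip = clip,
             tail_average = tail_average)
  for (nm in names(ov)) if (!is.null(ov[[nm]])) base[[nm]] <- ov[[nm]]
  base$preset <- preset
  base$seed <- as.integer(seed)
  structure(base, class = "fthnet_train_config")
}

#' Learning rate at an iteration
#'
#' Piecewise linear: `lr * t / warmup` during warmup, then linear decay to
#' zero at the final iteration: `lr * (T - t) / (T - warmup)`.
#'
#' @param t iteration (1-based).
#' @param tc an [train_config()].
#' @return learning rate.
#' @export
lr_at <- function(t, tc) {
  if (t <= tc$warmup) return(tc$lr * t / tc$warmup)
  tc$lr * (tc$iterations - t) / (tc$iterations - tc$warmup)
}

# Scale all gradients down so their global L2 norm is at most `max_norm`
# (stabilises the hypernetwork's multiplicative parameter paths).
clip_global_norm <- function(grads, max_norm) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g * g), 0)))
  if (is.finite(total) && total > max_norm)
    grads <- lapply(grads, function(g) g * (max_norm / total))
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Load an image and resize it to the model resolution
#' @param path PNG/JPEG path.
#' @param size target square side.
#' @return (size, size, 3) array in [0, 1].
#' @export
load_image <- function(path, size) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[1] != size || dim(img)[2] != size)
    img <- EBImage::resize(img, w = size, h = size)
  img <- array(as.numeric(img), dim(img))
  img[img < 0] <- 0; img[img > 1] <- 1
  img
}

# Load all manifest images into a (S, S, 3, n) array.
load_manifest_images <- function(manifest, size) {
  root <- attr(manifest, "root")
  n <- nrow(manifest)
  out <- array(0, c(size, size, 3, n))
  for (i in seq_len(n))
    out[, , , i] <- load_image(file.path(root, manifest$image[i]), size)
  out
}

augment_image <- function(img, flip_h, flip_v) {
  if (flip_h) img <- img[, dim(img)[2]:1, , drop = FALSE]
  if (flip_v) img <- img[dim(img)[1]:1, , , drop = FALSE]
  img
}

#' Predict quality scores with model parameters
#'
#' @param params parameter list (or an `fthnet_checkpoint`).
#' @param config an [model_config()] (ignored if `params` is a checkpoint).
#' @param images (S, S, 3, n) array, list of arrays, or an
#'   [fqs_manifest()] whose images are loaded from disk.
#' @param chunk forward-pass batch size.
#' @return numeric vector of raw predicted scores.
#' @export
predict_scores <- function(params, config = NULL, images, chunk = 16L) {
  if (inherits(params, "fthnet_checkpoint")) {
    config <- params$config
    params <- params$params
  }
  if (inherits(images, "fqs_manifest"))
    images <- load_manifest_images(images, config$input_size)
  if (is.list(images))
    images <- array(unlist(images),
                    c(dim(images[[1]]), length(images)))
  if (length(dim(images)) == 3L) dim(images) <- c(dim(images), 1L)
  n <- dim(images)[4]
  scores <- numeric(n)
  for (s0 in seq.int(1L, n, by = chunk)) {
    s1 <- min(n, s0 + chunk - 1L)
    scores[s0:s1] <- fthnet_fwd(images[, , , s0:s1, drop = FALSE],
                                params, config)$score
  }
  scores
}

#' Train the model
#'
#' Runs the Adam + warmup/linear-annealing schedule on the training subset,
#' logging smooth-L1 loss every iteration and validation SRCC/RMSE every
#' `val_every` iterations; the returned checkpoint holds the parameters
#' with the best validation SRCC (final parameters if no usable validation
#' set). Deterministic for a fixed `train_config$seed`.
#'
#' @param manifest an [fqs_manifest()].
#' @param model_config an [model_config()].
#' @param tc an [train_config()].
#' @param split optional [make_splits()] result; `NULL` trains on all
#'   records (no validation).
#' @param images optional preloaded (S, S, 3, n) array aligned with
#'   `manifest` rows (loaded from disk if missing).
#' @return object of class `fthnet_checkpoint`: list with `params`,
#'   `config`, `train_config`, `history` (data frame), `best_iter`.
#' @export
train <- function(manifest, model_config, tc = train_config("tiny"),
                  split = NULL, images = NULL) {
  ids <- if (is.null(split)) as.character(manifest$image) else split$train_ids
  if (!length(ids)) stop("train: empty training split")
  idx <- match(ids, manifest$image)
  if (is.null(images))
    images <- load_manifest_images(manifest, model_config$input_size)
  y_all <- manifest$mos
  val_idx <- if (!is.null(split) && length(split$val_ids) >= 2L)
    match(split$val_ids, manifest$image)
  params <- init_fthnet(model_config, seed = tc$seed)
  state <- adam_init(params)
  hist <- vector("list", tc$iterations)
  best <- list(srcc = -Inf, params = params, iter = 0L)
  shapes <- fthnet_shapes(model_config)
  ta_frac <- if (is.null(tc$tail_average)) 0 else tc$tail_average
  ta_from <- tc$iterations - floor(ta_frac * tc$iterations) + 1L
  ta_sum <- NULL; ta_n <- 0L
  withr::with_seed(tc$seed + 1L, {
    for (t in seq_len(tc$iterations)) {
      take <- idx[sample.int(length(idx), tc$batch, replace = tc$batch > length(idx))]
      xb <- images[, , , take, drop = FALSE]
      if (tc$flip) {
        fh <- stats::runif(tc$batch) < 0.5
        fv <- stats::runif(tc$batch) < 0.5
        for (b in seq_len(tc$batch))
          if (fh[b] || fv[b])
            xb[, , , b] <- augment_image(xb[, , , b], fh[b], fv[b])
      }
      yb <- y_all[take]
      fw <- fthnet_fwd(xb, params, model_config, keep = TRUE)
      loss <- smooth_l1(yb, fw$score)
      if (!is.finite(loss)) stop("train: non-finite loss at iteration ", t)
      grads <- new_grads()
      fthnet_bwd(smooth_l1_grad(yb, fw$score), fw, params, model_config, grads)
      gl <- grads_as_list(grads, shapes)
      if (!is.null(tc$clip)) gl <- clip_global_norm(gl, tc$clip)
      upd <- adam_step(params, gl, state, lr_at(t, tc))
      params <- upd$params; state <- upd$state
      if (ta_frac > 0 && t >= ta_from) {
        ta_sum <- if (is.null(ta_sum)) params
                  else mapply(`+`, ta_sum, params, SIMPLIFY = FALSE)
        ta_n <- ta_n + 1L
      }
      rec <- list(iter = t, loss = loss, lr = lr_at(t, tc),
                  val_srcc = NA_real_, val_rmse = NA_real_)
      if (!is.null(val_idx) &&
          (t %% tc$val_every == 0L || t == tc$iterations)) {
        vs <- predict_scores(params, model_config,
                             images[, , , val_idx, drop = FALSE])
        rec$val_rmse <- rmse(y_all[val_idx], vs)
        rec$val_srcc <- tryCatch(srcc(y_all[val_idx], vs),
                                 error = function(e) NA_real_)
        if (!is.na(rec$val_srcc) && rec$val_srcc >= best$srcc)
          best <- list(srcc = rec$val_srcc, params = params, iter = t)
      }
      hist[[t]] <- rec
    }
  })
  history <- do.call(rbind, lapply(hist, as.data.frame))
  final <- if (best$iter > 0L) best$params
           else if (ta_n > 0L) lapply(ta_sum, function(x) x / ta_n)
           else params
  structure(list(params = final, final_params = params,
                 config = model_config, train_config = tc,
                 history = history, best_iter = best$iter),
            class = "fthnet_checkpoint")
}

#' @export
print.fthnet_checkpoint <- function(x, ...) {
  cat(sprintf("fthnet checkpoint: %d iterations, final loss %.3f%s\n",
              nrow(x$history), x$history$loss[nrow(x$history)],
              if (x$best_iter > 0)
                sprintf(", best val SRCC %.3f @ iter %d",
                        max(x$history$val_srcc, na.rm = TRUE), x$best_iter)
              else ""))
  invisible(x)
}

#' Evaluate a checkpoint on a manifest
#'
#' @param checkpoint an `fthnet_checkpoint` (or a bare parameter list, with
#'   `config` supplied).
#' @param manifest an [fqs_manifest()]; `ids` optionally restricts to a
#'   subset (e.g. a test split).
#' @param config model configuration when `checkpoint` is a bare list.
#' @param images optional preloaded image array aligned with `manifest`.
#' @return a [metric_report()] with the per-image predictions attached as
#'   attribute `predictions` (data frame: image, mos, score, level).
#' @export
evaluate <- function(checkpoint, manifest, ids = NULL, config = NULL,
                     images = NULL) {
  if (inherits(checkpoint, "fthnet_checkpoint")) {
    config <- checkpoint$config
    params <- checkpoint$params
  } else params <- checkpoint
  if (!is.null(ids)) {
    keep <- match(ids, manifest$image)
    if (!is.null(images)) images <- images[, , , keep, drop = FALSE]
    manifest <- manifest_subset(manifest, ids)
  }
  if (is.null(images))
    images <- load_manifest_images(manifest, config$input_size)
  scores <- predict_scores(params, config, images)
  rep <- metric_report(manifest$mos, scores)
  attr(rep, "predictions") <- data.frame(
    image = manifest$image, mos = manifest$mos, score = scores,
    level = map_quality_level(pmin(100, pmax(0, scores))))
  rep
}

#' Cross-validate with re-drawn splits
#'
#' Repeats split/train/test `rounds` times; round r uses seed
#' `seed + r` for its 80/5/15 split and training RNG.
#'
#' @param manifest an [fqs_manifest()].
#' @param model_config,tc model and training configuration.
#' @param rounds number of rounds (the reference protocol uses 10).
#' @param seed base seed.
#' @return list with `reports` (per round), and `summary` (mean and SD of
#'   SRCC/PLCC/RMSE across rounds).
#' @export
cross_validate <- function(manifest, model_config, tc, rounds = 10L,
                           seed = 1L) {
  if (rounds < 2L) stop("cross_validate: need at least 2 rounds")
  images <- load_manifest_images(manifest, model_config$input_size)
  reports <- vector("list", rounds)
  for (r in seq_len(rounds)) {
    sp <- make_splits(manifest, seed = seed + r)
    tcr <- tc; tcr$seed <- as.integer(seed + r)
    ck <- train(manifest, model_config, tcr, split = sp, images = images)
    reports[[r]] <- evaluate(ck, manifest, ids = sp$test_ids,
                             images = images)
  }
  m <- vapply(reports, function(x) c(x$srcc, x$plcc, x$rmse), numeric(3))
  list(reports = reports,
       summary = data.frame(metric = c("srcc", "plcc", "rmse"),
                            mean = rowMeans(m), sd = apply(m, 1, stats::sd)))
}
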