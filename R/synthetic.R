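# Synthetic fundus phantoms with parameterised clinical degradations.
#
# The generator stands in for expert-scored clinical data: it renders a
# bright circular retina (disc, macula, vessel tree) on a black background,
# applies the clinically common degradations (defocus, motion blur, uneven
# illumination, exposure error, haze, flare artifacts), maps degradation
# severity to a ground-truth quality score through a documented closed form,
# and simulates a six-rater panel around that score.

#' Phantom rendering specification
#'
#' @param size image side in pixels (square), at least 64.
#' @param seed integer seed controlling vessel geometry.
#' @param vessel_count number of major vessels to draw.
#' @param disc_position,macula_position normalised (x, y) in [0,1].
#' @param background_tint RGB gains of the retinal background.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 384L, seed = 1L, vessel_count = 9L,
                         disc_position = c(0.68, 0.45),
                         macula_position = c(0.42, 0.52),
                         background_tint = c(0.92, 0.55, 0.28)) {
  if (size < 64) stop("phantom_spec: size must be at least 64, got ", size)
  structure(list(size = as.integer(size), seed = as.integer(seed),
                 vessel_count = as.integer(vessel_count),
                 disc_position = disc_position,
                 macula_position = macula_position,
                 background_tint = background_tint),
            class = "phantom_spec")
}

# Stamp a disc of given radius into a matrix at (row, col), bounded.
.stamp <- function(mask, r0, c0, rad) {
  n <- nrow(mask)
  rr <- max(1L, floor(r0 - rad)):min(n, ceiling(r0 + rad))
  cc <- max(1L, floor(c0 - rad)):min(n, ceiling(c0 + rad))
  sub <- outer(rr - r0, cc - c0, function(a, b) a * a + b * b) <= rad * rad
  mask[rr, cc] <- mask[rr, cc] | sub
  mask
}

#' Render a fundus phantom
#'
#' Deterministic given the spec's seed. The image is a bright circular
#' field of view on black, with a radially shaded tinted background, one
#' bright optic disc, one dark macula, and `vessel_count` dark curvilinear
#' vessels grown from the disc by a seeded random walk. The logical vessel
#' mask is attached as attribute `vessel_mask` and the field-of-view mask
#' as `fov_mask`.
#'
#' @param spec a [phantom_spec()].
#' @return numeric array (size, size, 3) with values in [0, 1].
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  s <- spec$size
  yy <- matrix(seq_len(s), s, s)              # row index
  xx <- t(yy)                                 # col index
  cx <- (s + 1) / 2
  r_fov <- 0.48 * s
  d2c <- (xx - cx)^2 + (yy - cx)^2
  fov <- d2c <= r_fov^2
  # radial shading: brighter centre, mild falloff to the rim
  shade <- 1 - 0.35 * pmin(1, sqrt(d2c) / r_fov)^2

  disc_x <- spec$disc_position[1] * s; disc_y <- spec$disc_position[2] * s
  mac_x <- spec$macula_position[1] * s; mac_y <- spec$macula_position[2] * s
  disc <- exp(-(((xx - disc_x)^2 + (yy - disc_y)^2)) / (2 * (0.045 * s)^2))
  mac <- exp(-(((xx - mac_x)^2 + (yy - mac_y)^2)) / (2 * (0.075 * s)^2))

  vmask <- withr::with_seed(spec$seed, {
    m <- matrix(FALSE, s, s)
    for (v in seq_len(spec$vessel_count)) {
      ang <- stats::runif(1, 0, 2 * pi)
      px <- disc_x; py <- disc_y
      width <- stats::runif(1, 0.004, 0.009) * s
      n_steps <- round(0.9 * s)
      for (k in seq_len(n_steps)) {
        ang <- ang + stats::rnorm(1, 0, 0.12)
        px <- px + cos(ang); py <- py + sin(ang)
        if ((px - cx)^2 + (py - cx)^2 > (0.96 * r_fov)^2) break
        m <- .stamp(m, py, px, width * (1 - 0.5 * k / n_steps) + 0.6)
      }
    }
    m
  })
  vess <- EBImage::gblur(vmask * 1.0, sigma = max(0.8, s / 400))
  vess <- vess / max(vess, 1e-8)

  img <- array(0, c(s, s, 3))
  for (ch in 1:3) {
    base <- spec$background_tint[ch] * shade
    base <- base + disc * c(0.55, 0.75, 0.85)[ch]     # disc: bright, yellowish
    base <- base - mac * 0.35 * c(0.5, 0.9, 1.0)[ch]  # macula: darker
    base <- base - vess * 0.55 * c(0.55, 0.95, 0.6)[ch] # vessels: dark red
    base[base < 0] <- 0
    base[base > 1] <- 1
    img[, , ch] <- base * fov
  }
  attr(img, "vessel_mask") <- vmask & fov
  attr(img, "fov_mask") <- fov
  img
}

#' Degradation severity profile
#'
#' All severities default to neutral; the neutral profile leaves an image
#' bitwise unchanged. Units: `defocus_sigma` Gaussian sigma in px;
#' `motion_len` blur streak length in px at `motion_angle` radians;
#' `haze_alpha` in [0,1] blends towards flat white; `illum_gradient` in
#' [0,1] darkens one side of the field by that fraction; `exposure_gamma`
#' is a gamma exponent (>1 darkens, <1 over-exposes); `artifact_count`
#' is the number of bright flare spots.
#'
#' @param defocus_sigma,motion_len,motion_angle,haze_alpha,illum_gradient
#'   non-negative severities as described above.
#' @param exposure_gamma positive gamma exponent (1 = neutral).
#' @param artifact_count non-negative integer.
#' @return object of class `degradation_profile`.
#' @export
degradation_profile <- function(defocus_sigma = 0, motion_len = 0,
                                motion_angle = 0, haze_alpha = 0,
                                illum_gradient = 0, exposure_gamma = 1,
                                artifact_count = 0L) {
  p <- list(defocus_sigma = defocus_sigma, motion_len = motion_len,
            motion_angle = motion_angle, haze_alpha = haze_alpha,
            illum_gradient = illum_gradient, exposure_gamma = exposure_gamma,
            artifact_count = as.integer(artifact_count))
  nonneg <- c("defocus_sigma", "motion_len", "haze_alpha", "illum_gradient",
              "artifact_count")
  bad <- nonneg[vapply(p[nonneg], function(v) !is.finite(v) || v < 0, TRUE)]
  if (length(bad))
    stop("degradation_profile: negative severity in: ",
         paste(bad, collapse = ", "))
  if (!is.finite(p$exposure_gamma) || p$exposure_gamma <= 0)
    stop("degradation_profile: exposure_gamma must be positive")
  if (p$haze_alpha > 1) stop("degradation_profile: haze_alpha must be <= 1")
  if (p$illum_gradient > 1) stop("degradation_profile: illum_gradient must be <= 1")
  structure(p, class = "degradation_profile")
}

.blur_channels <- function(img, kern = NULL, sigma = NULL) {
  out <- img
  for (ch in 1:3) {
    out[, , ch] <- if (is.null(kern)) EBImage::gblur(img[, , ch], sigma = sigma)
                   else EBImage::filter2(img[, , ch], kern)
  }
  out
}

# Normalised line kernel for motion blur.
.motion_kernel <- function(len, angle) {
  k <- max(3L, 2L * floor(len / 2) + 1L)
  kern <- matrix(0, k, k)
  c0 <- (k + 1) / 2
  ts <- seq(-len / 2, len / 2, length.out = max(2L, ceiling(2 * len)))
  for (t in ts) {
    r <- round(c0 + t * sin(angle)); c <- round(c0 + t * cos(angle))
    if (r >= 1 && r <= k && c >= 1 && c <= k) kern[r, c] <- kern[r, c] + 1
  }
  kern / sum(kern)
}

#' Apply a degradation profile to an image
#'
#' Operators are applied in a fixed order reflecting acquisition physics
#' (optics before sensor before veiling glare): defocus, motion blur,
#' uneven illumination, exposure, haze, artifacts. A neutral profile
#' returns the input unchanged (bitwise). Output is clamped to [0, 1].
#'
#' @param image numeric array (H, W, 3) in [0, 1].
#' @param profile a [degradation_profile()].
#' @param seed integer seed for the stochastic operators (illumination
#'   direction, artifact placement).
#' @return degraded image, same shape, values in [0, 1].
#' @export
apply_degradations <- function(image, profile, seed = 1L) {
  stopifnot(inherits(profile, "degradation_profile"))
  if (min(image) < -1e-9 || max(image) > 1 + 1e-9)
    stop("apply_degradations: image values must lie in [0, 1]")
  img <- image
  s <- dim(img)[1]
  if (profile$defocus_sigma > 0)
    img <- .blur_channels(img, sigma = profile$defocus_sigma)
  if (profile$motion_len > 0)
    img <- .blur_channels(img, kern = .motion_kernel(profile$motion_len,
                                                     profile$motion_angle))
  # filter ringing can overshoot [0, 1] slightly; clamp before the
  # point-wise operators (gamma on a negative value is undefined)
  if (profile$defocus_sigma > 0 || profile$motion_len > 0) {
    img[img < 0] <- 0
    img[img > 1] <- 1
  }
  rng_needed <- profile$illum_gradient > 0 || profile$artifact_count > 0
  if (rng_needed) {
    img <- withr::with_seed(as.integer(seed) + 77L, {
      x <- img
      if (profile$illum_gradient > 0) {
        ang <- stats::runif(1, 0, 2 * pi)
        yy <- matrix(seq_len(s), s, s); xx <- t(yy)
        proj <- cos(ang) * xx + sin(ang) * yy
        ramp <- (proj - min(proj)) / (max(proj) - min(proj))
        fac <- 1 - profile$illum_gradient * ramp
        for (ch in 1:3) x[, , ch] <- x[, , ch] * fac
      }
      if (profile$exposure_gamma != 1) x <- x^profile$exposure_gamma
      if (profile$haze_alpha > 0)
        x <- (1 - profile$haze_alpha) * x + profile$haze_alpha * 0.9
      if (profile$artifact_count > 0) {
        yy <- matrix(seq_len(s), s, s); xx <- t(yy)
        for (a in seq_len(profile$artifact_count)) {
          ax <- stats::runif(1, 0.2, 0.8) * s; ay <- stats::runif(1, 0.2, 0.8) * s
          rad <- stats::runif(1, 0.03, 0.08) * s
          blob <- exp(-((xx - ax)^2 + (yy - ay)^2) / (2 * rad^2))
          for (ch in 1:3) x[, , ch] <- x[, , ch] + 0.8 * blob
        }
      }
      x
    })
  } else {
    if (profile$exposure_gamma != 1) img <- img^profile$exposure_gamma
    if (profile$haze_alpha > 0)
      img <- (1 - profile$haze_alpha) * img + profile$haze_alpha * 0.9
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

# Per-degradation penalty rates of the severity -> quality closed form.
.SEV_RATES <- c(defocus_sigma = 0.15, motion_len = 0.06, haze_alpha = 1.2,
                illum_gradient = 1.0, exposure = 1.1, artifact_count = 0.2)

#' Map a degradation profile to a ground-truth quality score
#'
#' The closed form is a product of per-degradation exponential penalties,
#' \deqn{q = \max(5,\; 95 \prod_k e^{-c_k s_k}),}
#' with severities `s_k` as in [degradation_profile()] (exposure enters as
#' `|log(exposure_gamma)|`) and rates `c = (0.15, 0.06, 1.2, 1.0, 1.1,
#' 0.2)` for defocus, motion, haze, illumination, exposure and artifacts.
#' The neutral profile scores 95; the score is strictly decreasing in every
#' severity until the floor at 5; a single extreme degradation lands around
#' 20-40 and combinations fall below 20, mirroring how clinical "Reject"
#' images usually combine degradations.
#'
#' @param profile a [degradation_profile()].
#' @return numeric quality score in [5, 95].
#' @export
severity_to_quality <- function(profile) {
  stopifnot(inherits(profile, "degradation_profile"))
  r <- .SEV_RATES
  pen <- exp(-(r[["defocus_sigma"]] * profile$defocus_sigma +
               r[["motion_len"]] * profile$motion_len +
               r[["haze_alpha"]] * profile$haze_alpha +
               r[["illum_gradient"]] * profile$illum_gradient +
               r[["exposure"]] * abs(log(profile$exposure_gamma)) +
               r[["artifact_count"]] * profile$artifact_count))
  max(5, 95 * pen)
}

#' Simulate a six-rater opinion panel
#'
#' Draws three ophthalmologist and three experienced-ophthalmologist
#' integer scores around the true quality. Noise is truncated normal
#' (clamped to [0, 100] and rounded to whole points, as raters score);
#' experienced raters get 0.8x the noise scale. The per-image scale is
#' itself log-normal across images (`sdlog = heterogeneity`), reproducing
#' the wide spread of per-image rater SDs seen in practice: with the
#' defaults the quartiles of the per-image population SD over many images
#' fall near (2.5, 4.3, 6.4) points.
#'
#' @param true_quality numeric in [0, 100].
#' @param seed integer seed.
#' @param scale median rater noise SD in points (default 5.6).
#' @param heterogeneity log-normal sdlog of the per-image scale (0.35).
#' @return a [rater_scores()] object.
#' @export
simulate_raters <- function(true_quality, seed, scale = 5.6,
                            heterogeneity = 0.45) {
  stopifnot(true_quality >= 0, true_quality <= 100)
  withr::with_seed(as.integer(seed), {
    sd_img <- scale * stats::rlnorm(1, 0, heterogeneity)
    o <- true_quality + stats::rnorm(3, 0, sd_img)
    oj <- true_quality + stats::rnorm(3, 0, 0.8 * sd_img)
    rater_scores(round(pmax(0, pmin(100, o))),
                 round(pmax(0, pmin(100, oj))))
  })
}

# Draw a degradation profile whose closed-form quality equals (up to the
# floor) a target score: split the total log-penalty across the six
# severity channels with sparse Dirichlet weights, so most images are
# dominated by one or two degradations. Out-of-focus blur gets the largest
# expected share (it is the most common clinical degradation), making
# defocus the strongest single image-level predictor of MOS.
.profile_for_quality <- function(target_q) {
  total <- -log(target_q / 95)
  g <- stats::rgamma(6, shape = c(2.2, 0.6, 0.6, 0.6, 0.6, 0.6))
  wts <- g / sum(g)
  r <- .SEV_RATES
  degradation_profile(
    defocus_sigma  = wts[1] * total / r[["defocus_sigma"]],
    motion_len     = wts[2] * total / r[["motion_len"]],
    motion_angle   = stats::runif(1, 0, pi),
    haze_alpha     = min(1, wts[3] * total / r[["haze_alpha"]]),
    illum_gradient = min(1, wts[4] * total / r[["illum_gradient"]]),
    exposure_gamma = exp(sample(c(-1, 1), 1) * wts[5] * total / r[["exposure"]]),
    artifact_count = round(wts[6] * total / r[["artifact_count"]])
  )
}

#' Generate a synthetic FQS-style dataset
#'
#' Renders `n` degraded phantoms, writes them as lossless PNG under
#' `out_dir`, and writes `manifest.csv` in the FQS dialect (columns
#' `image, mos, level, o1..o3, oj1..oj3, true_quality`). Target qualities
#' are drawn from a truncated normal centred in the Usable band (mean 72,
#' SD 13.5), so the MOS histogram is unimodal in 60-80 and all three
#' levels are represented; severity profiles are then solved from the
#' closed form of [severity_to_quality()]. Deterministic per seed
#' (byte-identical manifest on regeneration).
#'
#' @param n number of images (>= 1).
#' @param seed integer seed.
#' @param out_dir output directory (created if needed).
#' @param size image side in pixels.
#' @return the written [fqs_manifest()] (invisibly readable back from
#'   `file.path(out_dir, "manifest.csv")`).
#' @export
generate_fqs_dataset <- function(n, seed, out_dir, size = 384L) {
  if (n < 1) stop("generate_fqs_dataset: n must be >= 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("generate_fqs_dataset: cannot create ", out_dir)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    seed_i <- as.integer(seed) + i * 13L
    prof <- withr::with_seed(seed_i, {
      tq <- stats::rnorm(1, 72, 13.5)
      .profile_for_quality(min(95, max(8, tq)))
    })
    img <- render_phantom(phantom_spec(size = size, seed = seed_i))
    img <- apply_degradations(img, prof, seed = seed_i)
    tq <- severity_to_quality(prof)
    raters <- simulate_raters(tq, seed = seed_i + 1L)
    mos <- aggregate_mos(raters)
    id <- sprintf("img_%04d.png", i)
    png::writePNG(img, file.path(out_dir, id))
    rows[[i]] <- data.frame(
      image = id, mos = mos, level = as.character(map_quality_level(mos)),
      o1 = raters$o[1], o2 = raters$o[2], o3 = raters$o[3],
      oj1 = raters$oj[1], oj2 = raters$oj[2], oj3 = raters$oj[3],
      true_quality = round(tq, 4),
      defocus_sigma = round(prof$defocus_sigma, 4), stringsAsFactors = FALSE)
  }
  man <- fqs_manifest(do.call(rbind, rows), root = out_dir)
  write_fqs_manifest(man, file.path(out_dir, "manifest.csv"))
  man
}
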