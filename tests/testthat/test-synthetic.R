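# Phantom rendering, degradation operators, the severity -> quality closed
# form and the rater noise model.

test_that("phantom rendering is deterministic and anatomically plausible", {
  sp <- phantom_spec(size = 96, seed = 3)
  img <- render_phantom(sp)
  expect_identical(img, render_phantom(sp))
  expect_true(all(img >= 0 & img <= 1))
  fov <- attr(img, "fov_mask")
  expect_gt(mean(img[, , 2][fov]), mean(img[, , 2][!fov]))
  expect_error(render_phantom(phantom_spec(size = 32)), "64")
})

test_that("vessel coverage sits in a plausible band across seeds", {
  fr <- vapply(1:8, function(s) {
    img <- render_phantom(phantom_spec(size = 96, seed = s))
    mean(attr(img, "vessel_mask")[attr(img, "fov_mask")])
  }, 0)
  expect_true(all(fr > 0.01 & fr < 0.15))
})

test_that("neutral profile is the identity; operators act as documented", {
  img <- render_phantom(phantom_spec(size = 96, seed = 5))
  dim3 <- array(as.numeric(img), dim(img)) # strip attributes
  expect_identical(apply_degradations(dim3, degradation_profile(), 1), dim3)
  # defocus strictly reduces gradient energy
  energy <- function(x) {
    g <- x[, -1, 2] - x[, -ncol(x[, , 2]), 2]
    sum(g^2)
  }
  blurred <- apply_degradations(dim3, degradation_profile(defocus_sigma = 5), 1)
  expect_lt(energy(blurred), 0.5 * energy(dim3))
  # motion blur also smooths
  mb <- apply_degradations(dim3, degradation_profile(motion_len = 9), 1)
  expect_lt(energy(mb), energy(dim3))
  # gamma > 1 darkens
  dark <- apply_degradations(dim3, degradation_profile(exposure_gamma = 3), 1)
  expect_lt(mean(dark), mean(dim3))
  # haze compresses contrast towards the veil level
  hz <- apply_degradations(dim3, degradation_profile(haze_alpha = 0.7), 1)
  expect_lt(sd(hz), sd(dim3))
  # output always within [0, 1] and finite, even stacked degradations
  prof <- degradation_profile(defocus_sigma = 3, motion_len = 5,
                              haze_alpha = 0.4, illum_gradient = 0.6,
                              exposure_gamma = 0.4, artifact_count = 4)
  out <- apply_degradations(dim3, prof, 9)
  expect_true(all(is.finite(out)))
  expect_true(all(out >= 0 & out <= 1))
  expect_error(degradation_profile(defocus_sigma = -1), "negative")
  expect_error(degradation_profile(exposure_gamma = 0), "positive")
})

test_that("severity_to_quality matches its closed form and is monotone", {
  expect_equal(severity_to_quality(degradation_profile()), 95)
  # independent recomputation of the documented closed form at half severity
  prof <- degradation_profile(defocus_sigma = 4, motion_len = 10,
                              haze_alpha = 0.5, illum_gradient = 0.5,
                              exposure_gamma = exp(0.55), artifact_count = 3)
  by_hand <- 95 * exp(-(0.15 * 4 + 0.06 * 10 + 1.2 * 0.5 + 1.0 * 0.5 +
                        1.1 * 0.55 + 0.2 * 3))
  expect_equal(severity_to_quality(prof), max(5, by_hand))
  # single extreme degradations land in the documented 20-40 band
  singles <- c(severity_to_quality(degradation_profile(defocus_sigma = 8)),
               severity_to_quality(degradation_profile(motion_len = 20)),
               severity_to_quality(degradation_profile(haze_alpha = 1)),
               severity_to_quality(degradation_profile(exposure_gamma = 3)))
  expect_true(all(singles > 18 & singles < 45))
  # randomized pairwise dominance: more severe profile never scores higher
  withr::with_seed(21, for (i in 1:1000) {
    s <- runif(6, 0, c(6, 15, 0.8, 0.8, 1, 5))
    bump <- sample(6, 1)
    s2 <- s; s2[bump] <- s2[bump] + runif(1, 0.05, 1)
    p1 <- degradation_profile(s[1], s[2], 0, s[3], s[4], exp(s[5]), round(s[6]))
    p2 <- degradation_profile(s2[1], s2[2], 0, min(1, s2[3]), min(1, s2[4]),
                              exp(s2[5]), round(s2[6]))
    expect_lte(severity_to_quality(p2), severity_to_quality(p1) + 1e-12)
  })
})

test_that("rater simulation is seeded, integer, and concentrates on truth", {
  rs <- simulate_raters(70, seed = 4)
  expect_identical(rs, simulate_raters(70, seed = 4))
  expect_true(all(c(rs$o, rs$oj) == round(c(rs$o, rs$oj))))
  expect_true(all(c(rs$o, rs$oj) >= 0 & c(rs$o, rs$oj) <= 100))
  # zero noise scale: all six scores equal the true quality
  rs0 <- simulate_raters(70, seed = 4, scale = 0)
  expect_equal(c(rs0$o, rs0$oj), rep(70, 6))
  # aggregated MOS stays within a few noise scales of the truth
  devs <- vapply(1:1000, function(s)
    aggregate_mos(simulate_raters(72, seed = s)) - 72, 0)
  expect_lt(max(abs(devs)), 3 * 5.6 * exp(2 * 0.35))
  expect_lt(abs(mean(devs)), 1)
})

test_that("generated datasets are reproducible and well-formed", {
  man <- micro_dataset()
  expect_s3_class(man, "fqs_manifest")
  expect_equal(anyDuplicated(man$image), 0L)
  expect_true(all(file.exists(file.path(attr(man, "root"), man$image))))
  expect_true(has_rater_scores(man))
  # byte-identical regeneration under the same seed
  d2 <- file.path(tempdir(), "regen")
  generate_fqs_dataset(6, seed = 77, out_dir = d2, size = 64)
  b1 <- readBin(file.path(d2, "manifest.csv"), "raw", 1e6)
  d3 <- file.path(tempdir(), "regen2")
  generate_fqs_dataset(6, seed = 77, out_dir = d3, size = 64)
  b2 <- readBin(file.path(d3, "manifest.csv"), "raw", 1e6)
  expect_identical(b1, b2)
})

test_that("blur severity is negatively rank-correlated with MOS", {
  # the learnable signal: image-level defocus tracks quality down. Checked
  # on simulated profiles (no rendering needed for the correlation).
  withr::with_seed(31, {
    qs <- pmin(95, pmax(8, rnorm(400, 72, 13.5)))
    profs <- lapply(qs, fthnet:::.profile_for_quality)
    mos <- vapply(seq_along(profs), function(i)
      aggregate_mos(simulate_raters(severity_to_quality(profs[[i]]), seed = i)),
      0)
    defoc <- vapply(profs, `[[`, 0, "defocus_sigma")
    expect_lt(srcc(defoc, mos), -0.5)
    total_sev <- -log(vapply(profs, function(p)
      severity_to_quality(p) / 95, 0))
    expect_lt(srcc(total_sev, mos), -0.9)
  })
})
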