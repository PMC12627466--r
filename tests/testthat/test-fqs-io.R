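# Dataset protocol: MOS aggregation, level mapping, rater statistics,
# manifest round-trips and splits.

test_that("aggregate_mos implements the seniority-weighted average", {
  # identical inputs reproduce the common score for any s (convexity)
  for (s in c(0, 33.5, 70, 100))
    expect_equal(aggregate_mos(rater_scores(rep(s, 3), rep(s, 3))), s)
  # hand-computed cases: (1/9)*sum(o) + (2/9)*sum(oj)
  expect_equal(aggregate_mos(rater_scores(c(60, 60, 60), c(90, 90, 90))), 80)
  expect_equal(aggregate_mos(rater_scores(c(70, 75, 80), c(70, 75, 80))), 75)
  # experienced raters carry double weight
  hi_oj <- aggregate_mos(rater_scores(c(50, 50, 50), c(80, 50, 50)))
  hi_o <- aggregate_mos(rater_scores(c(80, 50, 50), c(50, 50, 50)))
  expect_gt(hi_oj, hi_o)
  # result bounded by the score range
  withr::with_seed(5, for (i in 1:50) {
    sc <- runif(6, 0, 100)
    m <- aggregate_mos(rater_scores(sc[1:3], sc[4:6]))
    expect_gte(m, min(sc)); expect_lte(m, max(sc))
  })
})

test_that("aggregate_mos is monotone in every rater score", {
  withr::with_seed(8, for (i in 1:20) {
    o <- runif(3, 10, 90); oj <- runif(3, 10, 90)
    base <- aggregate_mos(rater_scores(o, oj))
    for (j in 1:3) {
      o2 <- o; o2[j] <- o2[j] + 5
      expect_gt(aggregate_mos(rater_scores(o2, oj)), base)
      oj2 <- oj; oj2[j] <- oj2[j] + 5
      expect_gt(aggregate_mos(rater_scores(o, oj2)), base)
    }
  })
})

test_that("rater_scores validates its inputs", {
  expect_error(rater_scores(c(70, 101, 70), c(70, 70, 70)), "o2")
  expect_error(rater_scores(c(70, 70, 70), c(70, 70, -1)), "oj3")
  expect_error(rater_scores(c(70, 70), c(70, 70, 70)), "three")
  expect_error(rater_scores(1:3, 4:6, lambda1 = 0.2, lambda2 = 0.2),
               "convex|weights")
})

test_that("quality levels honour the 80/60 boundaries", {
  expect_equal(as.character(map_quality_level(c(85, 60, 59.9, 80, 100, 0, 79.999))),
               c("Good", "Usable", "Reject", "Good", "Good", "Reject", "Usable"))
  expect_error(map_quality_level(101), "outside")
  expect_error(map_quality_level(-0.5), "outside")
  # exhaustive and mutually exclusive over a fine grid
  grid <- seq(0, 100, by = 0.25)
  lv <- map_quality_level(grid)
  expect_false(anyNA(lv))
  expect_setequal(levels(lv), c("Good", "Usable", "Reject"))
  # composed with aggregation it still covers [0, 100]
  expect_equal(as.character(map_quality_level(
    aggregate_mos(rater_scores(c(80, 80, 80), c(80, 80, 80))))), "Good")
})

test_that("rater SD statistics use population SD and linear interpolation", {
  base <- data.frame(image = c("a.png", "b.png"), mos = c(70, 70),
                     level = c("Usable", "Usable"))
  # identical scores: zero dispersion
  m0 <- fqs_manifest(cbind(base, o1 = 70, o2 = 70, o3 = 70,
                           oj1 = 70, oj2 = 70, oj3 = 70))
  expect_equal(unname(rater_sd_stats(m0)), c(0, 0, 0))
  # two records with population SDs 2 and 6: median 4 by interpolation
  sc1 <- 70 + c(-2, -2, -2, 2, 2, 2)   # population SD 2
  sc2 <- 70 + c(-6, -6, -6, 6, 6, 6)   # population SD 6
  agg <- function(sc) sum(sc * c(1, 1, 1, 2, 2, 2)) / 9
  m1 <- fqs_manifest(data.frame(
    image = c("a.png", "b.png"), mos = c(agg(sc1), agg(sc2)),
    level = c("Usable", "Usable"),
    o1 = c(sc1[1], sc2[1]), o2 = c(sc1[2], sc2[2]), o3 = c(sc1[3], sc2[3]),
    oj1 = c(sc1[4], sc2[4]), oj2 = c(sc1[5], sc2[5]), oj3 = c(sc1[6], sc2[6])))
  expect_equal(unname(rater_sd_stats(m1)), c(3, 4, 5))
  # quartiles agree with the independent quantile implementation
  withr::with_seed(11, {
    n <- 40
    sc <- matrix(runif(6 * n, 20, 90), n)
    df <- data.frame(image = sprintf("i%02d.png", 1:n),
                     mos = (rowSums(sc[, 1:3]) + 2 * rowSums(sc[, 4:6])) / 9,
                     level = "Usable",
                     o1 = sc[, 1], o2 = sc[, 2], o3 = sc[, 3],
                     oj1 = sc[, 4], oj2 = sc[, 5], oj3 = sc[, 6])
    df$level <- as.character(map_quality_level(df$mos))
    mm <- fqs_manifest(df)
    sds <- apply(sc, 1, function(r) sqrt(mean((r - mean(r))^2)))
    expect_equal(unname(rater_sd_stats(mm)),
                 unname(quantile(sds, c(.25, .5, .75), type = 7)))
  })
  # records without raters are rejected by id
  expect_error(rater_sd_stats(fqs_manifest(base)), "lacks|lacking")
})

test_that("manifest CSV round-trips and validates", {
  man <- micro_dataset()
  path <- file.path(tempdir(), "roundtrip.csv")
  write_fqs_manifest(man, path)
  back <- read_fqs_manifest(path, root = attr(man, "root"))
  expect_equal(back$image, man$image)
  expect_equal(back$mos, man$mos, tolerance = 1e-9)
  expect_equal(as.character(back$level), as.character(man$level))
  expect_true(has_rater_scores(back))
  expect_equal(back$true_quality, man$true_quality) # unknown column kept
  # invalid rows are rejected with their position
  df <- data.frame(image = c("x.png", "y.png"), mos = c(50, 101),
                   level = c("Reject", "Good"))
  expect_error(fqs_manifest(df), "2")
  expect_error(fqs_manifest(df[c(1, 1), ]), "duplicate")
  df2 <- data.frame(image = "x.png", mos = 50, level = "Soso")
  expect_error(fqs_manifest(df2), "level")
  # stored mos disagreeing with raters beyond 1e-6 is flagged
  df3 <- data.frame(image = "x.png", mos = 60, level = "Usable",
                    o1 = 70, o2 = 70, o3 = 70, oj1 = 70, oj2 = 70, oj3 = 70)
  expect_error(fqs_manifest(df3), "disagrees")
})

test_that("splits are deterministic exact partitions", {
  man <- micro_dataset()
  n <- nrow(man)
  sp <- make_splits(man, seed = 3)
  expect_equal(length(sp$train_ids), round(0.8 * n))
  expect_equal(length(sp$val_ids), round(0.05 * n))
  expect_setequal(c(sp$train_ids, sp$val_ids, sp$test_ids), man$image)
  expect_identical(make_splits(man, seed = 3), sp)
  # different seeds permute differently but keep sizes
  others <- lapply(4:13, function(s) make_splits(man, seed = s))
  expect_true(any(!vapply(others, function(o)
    identical(o$train_ids, sp$train_ids), TRUE)))
  for (o in others) {
    expect_equal(length(o$train_ids), length(sp$train_ids))
    expect_setequal(c(o$train_ids, o$val_ids, o$test_ids), man$image)
  }
  expect_error(make_splits(man[1:10, ], seed = 1), "20")
})

test_that("a 100-record manifest splits exactly 80/5/15", {
  df <- data.frame(image = sprintf("i%03d.png", 1:100),
                   mos = rep(70, 100), level = "Usable")
  man <- fqs_manifest(df)
  for (s in 1:5) {
    sp <- make_splits(man, seed = s)
    expect_equal(vapply(sp[c("train_ids", "val_ids", "test_ids")], length, 0L),
                 c(train_ids = 80L, val_ids = 5L, test_ids = 15L))
  }
})
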