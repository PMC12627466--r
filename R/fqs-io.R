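# Quality level labels, in decreasing quality order.
.FQS_LEVELS <- c("Good", "Usable", "Reject")

#' Rater score panel for one image
#'
#' Bundles the six opinion scores collected for one fundus photograph:
#' three from ophthalmologists and three from experienced ophthalmologists,
#' together with the aggregation weights. The defaults give an experienced
#' rater double the weight of an ordinary rater, and the six weights form a
#' convex combination (3*lambda1 + 3*lambda2 = 1).
#'
#' @param o numeric(3), ophthalmologist scores, each in [0, 100].
#' @param oj numeric(3), experienced-ophthalmologist scores, each in [0, 100].
#' @param lambda1 weight per ophthalmologist score (default 1/9).
#' @param lambda2 weight per experienced-ophthalmologist score (default 2/9).
#' @return An object of class `rater_scores`.
#' @examples
#' rs <- rater_scores(c(60, 60, 60), c(90, 90, 90))
#' aggregate_mos(rs) # 80
#' @export
rater_scores <- function(o, oj, lambda1 = 1 / 9, lambda2 = 2 / 9) {
  o <- as.numeric(o); oj <- as.numeric(oj)
  if (length(o) != 3L || length(oj) != 3L)
    stop("rater_scores: 'o' and 'oj' must each hold exactly three scores")
  scores <- c(o, oj)
  names(scores) <- c("o1", "o2", "o3", "oj1", "oj2", "oj3")
  bad <- which(!is.finite(scores) | scores < 0 | scores > 100)
  if (length(bad))
    stop("rater_scores: score outside [0, 100] for rater(s): ",
         paste(names(scores)[bad], collapse = ", "))
  if (abs(3 * lambda1 + 3 * lambda2 - 1) > 1e-12)
    stop("rater_scores: weights must satisfy 3*lambda1 + 3*lambda2 = 1")
  structure(list(o = o, oj = oj, lambda1 = lambda1, lambda2 = lambda2),
            class = "rater_scores")
}

#' Aggregate a rater panel into a mean opinion score
#'
#' The MOS is the seniority-weighted average
#' \deqn{MOS = \lambda_1 \sum_{i=1}^{3} O_i + \lambda_2 \sum_{i=1}^{3} Oj_i,}
#' with the default weights \eqn{\lambda_1 = 1/9}, \eqn{\lambda_2 = 2/9} so
#' that an experienced ophthalmologist counts twice as much as an ordinary
#' one. Because the weights are convex, the result always lies between the
#' smallest and the largest of the six scores.
#'
#' @param raters a [rater_scores()] object.
#' @return numeric scalar in [0, 100].
#' @export
aggregate_mos <- function(raters) {
  stopifnot(inherits(raters, "rater_scores"))
  raters$lambda1 * sum(raters$o) + raters$lambda2 * sum(raters$oj)
}

#' Map a continuous quality score to a clinical level
#'
#' Scores are banded into three clinical levels: `Good` for scores in
#' \[80, 100\], `Usable` for \[60, 80) and `Reject` for \[0, 60). The
#' half-open convention extends the integer ranges of the labelling
#' protocol (Good 80-100, Usable 60-79) to the continuous scores produced
#' by weighted averaging, so every real score maps to exactly one level.
#'
#' @param score numeric vector of scores in [0, 100].
#' @return factor with levels `Good`, `Usable`, `Reject`.
#' @examples
#' map_quality_level(c(85, 60, 59.9))
#' @export
map_quality_level <- function(score) {
  score <- as.numeric(score)
  bad <- which(!is.finite(score) | score < 0 | score > 100)
  if (length(bad))
    stop("map_quality_level: score outside [0, 100] at position(s): ",
         paste(bad, collapse = ", "))
  lev <- ifelse(score >= 80, "Good", ifelse(score >= 60, "Usable", "Reject"))
  factor(lev, levels = .FQS_LEVELS)
}

.manifest_rater_cols <- c("o1", "o2", "o3", "oj1", "oj2", "oj3")

#' Construct a dataset manifest
#'
#' A manifest is a data frame with one row per image (columns `image`,
#' `mos`, `level`, optionally the six rater columns `o1..o3`, `oj1..oj3`
#' and any extra columns) plus the image root directory. Stored `mos`
#' takes precedence over recomputation from rater columns; a disagreement
#' larger than `1e-6` is an error.
#'
#' @param records data frame with at least `image`, `mos`, `level`.
#' @param root image directory the `image` paths resolve under.
#' @param check_files if `TRUE`, require every image file to exist.
#' @return object of class `fqs_manifest` (a data frame).
#' @export
fqs_manifest <- function(records, root = ".", check_files = FALSE) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("image", "mos", "level")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("fqs_manifest: missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(records$image)) {
    dup <- unique(records$image[duplicated(records$image)])
    stop("fqs_manifest: duplicate image id(s): ", paste(dup, collapse = ", "))
  }
  records$mos <- as.numeric(records$mos)
  bad <- which(!is.finite(records$mos) | records$mos < 0 | records$mos > 100)
  if (length(bad))
    stop("fqs_manifest: mos outside [0, 100] at row(s): ",
         paste(bad, collapse = ", "))
  if (!all(records$level %in% .FQS_LEVELS)) {
    bad <- which(!(records$level %in% .FQS_LEVELS))
    stop("fqs_manifest: unknown level at row(s): ", paste(bad, collapse = ", "))
  }
  records$level <- factor(as.character(records$level), levels = .FQS_LEVELS)
  if (all(.manifest_rater_cols %in% names(records))) {
    rmat <- as.matrix(records[, .manifest_rater_cols])
    storage.mode(rmat) <- "double"
    recomputed <- (rowSums(rmat[, 1:3, drop = FALSE]) / 9 +
                     2 * rowSums(rmat[, 4:6, drop = FALSE]) / 9)
    off <- which(abs(recomputed - records$mos) > 1e-6)
    if (length(off))
      stop("fqs_manifest: stored mos disagrees with rater aggregate at row(s): ",
           paste(off, collapse = ", "))
  }
  if (check_files) {
    paths <- file.path(root, records$image)
    gone <- which(!file.exists(paths))
    if (length(gone))
      stop("fqs_manifest: missing image file(s): ",
           paste(records$image[gone], collapse = ", "))
  }
  structure(records, root = root, class = c("fqs_manifest", "data.frame"))
}

#' @export
print.fqs_manifest <- function(x, ...) {
  cat(sprintf("FQS manifest: %d images under '%s'\n", nrow(x), attr(x, "root")))
  print(table(x$level))
  invisible(x)
}

#' Does a manifest carry the six raw rater scores?
#' @param manifest an `fqs_manifest`.
#' @return logical scalar.
#' @export
has_rater_scores <- function(manifest) {
  all(.manifest_rater_cols %in% names(manifest))
}

#' Read an FQS manifest CSV
#'
#' The CSV dialect is comma-separated with a mandatory header and `.`
#' decimals; required columns are `image`, `mos`, `level`; the six rater
#' columns and any additional columns are preserved verbatim.
#'
#' @param csv_path path to the manifest CSV.
#' @param root image directory (defaults to the CSV's directory).
#' @param check_files require image files to exist.
#' @return an [fqs_manifest()].
#' @export
read_fqs_manifest <- function(csv_path, root = dirname(csv_path),
                              check_files = FALSE) {
  if (!file.exists(csv_path)) stop("read_fqs_manifest: no such file: ", csv_path)
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!nrow(df)) stop("read_fqs_manifest: empty manifest: ", csv_path)
  suppressWarnings(mos_num <- as.numeric(df$mos))
  bad <- which(is.na(mos_num) & !is.na(df$mos))
  if (length(bad))
    stop("read_fqs_manifest: unparsable mos at row(s): ",
         paste(bad, collapse = ", "))
  df$mos <- mos_num
  fqs_manifest(df, root = root, check_files = check_files)
}

#' Write an FQS manifest CSV
#'
#' Inverse of [read_fqs_manifest()]: `write` then `read` is the identity on
#' all fields. Numeric columns are written at full precision.
#'
#' @param manifest an [fqs_manifest()].
#' @param csv_path output path.
#' @return `csv_path`, invisibly.
#' @export
write_fqs_manifest <- function(manifest, csv_path) {
  stopifnot(inherits(manifest, "fqs_manifest"))
  df <- as.data.frame(manifest)
  df$level <- as.character(df$level)
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  invisible(csv_path)
}

#' Rater-consistency statistics
#'
#' Computes the 25th/50th/75th percentiles of the per-image standard
#' deviation of the six raw rater scores. The population SD (divide by
#' n = 6) is used, since the six scores are the complete rater panel for
#' an image, and percentiles use linear interpolation between order
#' statistics (`stats::quantile` type 7).
#'
#' @param manifest an [fqs_manifest()] whose records all carry rater scores.
#' @return named numeric: `q25`, `q50`, `q75`.
#' @export
rater_sd_stats <- function(manifest) {
  stopifnot(inherits(manifest, "fqs_manifest"))
  if (!has_rater_scores(manifest))
    stop("rater_sd_stats: manifest lacks rater columns for all records")
  rmat <- as.matrix(as.data.frame(manifest)[, .manifest_rater_cols])
  storage.mode(rmat) <- "double"
  gone <- which(!stats::complete.cases(rmat))
  if (length(gone))
    stop("rater_sd_stats: records lacking rater scores: ",
         paste(manifest$image[gone], collapse = ", "))
  mu <- rowMeans(rmat)
  sds <- sqrt(rowMeans((rmat - mu)^2)) # population SD, n = 6
  q <- stats::quantile(sds, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(q25 = q[1], q50 = q[2], q75 = q[3])
}

#' Split a manifest into train/validation/test subsets
#'
#' Randomly partitions the manifest's image ids into train/val/test in the
#' given fractions (default 80/5/15). Subset sizes are `round(f * N)` for
#' train and validation, with the remainder going to test, so the three
#' subsets always partition the ids exactly. Deterministic for a fixed
#' seed; the caller's RNG state is untouched.
#'
#' @param manifest an [fqs_manifest()] (or anything with an `image` column).
#' @param seed integer seed.
#' @param fractions numeric(3) summing to 1 (train, val, test).
#' @return object of class `fqs_split`: list with `train_ids`, `val_ids`,
#'   `test_ids`, `seed`, `fractions`.
#' @export
make_splits <- function(manifest, seed, fractions = c(0.80, 0.05, 0.15)) {
  ids <- as.character(manifest$image)
  n <- length(ids)
  if (n < 20L) stop("make_splits: need at least 20 records, got ", n)
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-9)
    stop("make_splits: fractions must be three numbers summing to 1")
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  n_tr <- round(fractions[1] * n)
  n_va <- round(fractions[2] * n)
  if (n_tr + n_va >= n) stop("make_splits: degenerate fractions for n = ", n)
  structure(list(
    train_ids = ids[perm[seq_len(n_tr)]],
    val_ids   = ids[perm[n_tr + seq_len(n_va)]],
    test_ids  = ids[perm[(n_tr + n_va + 1L):n]],
    seed = as.integer(seed), fractions = fractions
  ), class = "fqs_split")
}

#' Subset a manifest by image ids
#' @param manifest an [fqs_manifest()].
#' @param ids character vector of image ids.
#' @return an [fqs_manifest()] restricted (in `ids` order) to those ids.
#' @export
manifest_subset <- function(manifest, ids) {
  idx <- match(ids, manifest$image)
  if (anyNA(idx))
    stop("manifest_subset: unknown id(s): ",
         paste(ids[is.na(idx)], collapse = ", "))
  fqs_manifest(as.data.frame(manifest)[idx, , drop = FALSE],
               root = attr(manifest, "root"))
}
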