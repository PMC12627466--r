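# Loss and evaluation metrics: smooth L1, RMSE, PLCC, SRCC and the
# three-level confusion matrix. The correlation formulas are written out
# explicitly; tests cross-check them against independent implementations.

#' Smooth L1 loss
#'
#' Mean over elements of the Huber-style penalty
#' \deqn{\ell(d) = 0.5 d^2 \;(|d| < 1), \quad |d| - 0.5 \;(|d| \ge 1),}
#' with \eqn{d = y - y'}. Continuous and differentiable at |d| = 1 (both
#' branches give 0.5).
#'
#' @param y,y_prime numeric vectors (ground truth, prediction).
#' @return mean loss (scalar, >= 0).
#' @examples
#' smooth_l1(0, 0.5)  # 0.125
#' smooth_l1(0, 3)    # 2.5
#' @export
smooth_l1 <- function(y, y_prime) {
  if (length(y) != length(y_prime))
    stop("smooth_l1: length mismatch (", length(y), " vs ", length(y_prime), ")")
  if (!all(is.finite(y)) || !all(is.finite(y_prime)))
    stop("smooth_l1: non-finite input")
  d <- abs(y - y_prime)
  mean(ifelse(d < 1, 0.5 * d^2, d - 0.5))
}

# Gradient of mean smooth L1 w.r.t. y_prime.
smooth_l1_grad <- function(y, y_prime) {
  d <- y - y_prime
  -pmax(-1, pmin(1, d)) / length(y)
}

#' Root mean square error
#' @param y,y_prime equal-length numeric vectors.
#' @return scalar >= 0.
#' @export
rmse <- function(y, y_prime) {
  if (length(y) != length(y_prime))
    stop("rmse: length mismatch (", length(y), " vs ", length(y_prime), ")")
  if (!length(y)) stop("rmse: empty input")
  sqrt(mean((y_prime - y)^2))
}

#' Pearson linear correlation coefficient
#'
#' \deqn{PLCC = \frac{\sum_i (y'_i - \bar y')(y_i - \bar y)}
#'   {\sqrt{\sum_i (y'_i - \bar y')^2 \sum_i (y_i - \bar y)^2}}.}
#' No nonlinear (logistic) remapping is applied before the correlation.
#'
#' @param y,y_prime equal-length numeric vectors, both non-constant.
#' @return scalar in [-1, 1].
#' @export
plcc <- function(y, y_prime) {
  if (length(y) != length(y_prime))
    stop("plcc: length mismatch")
  if (length(y) < 2) stop("plcc: need at least two observations")
  cy <- y - mean(y); cp <- y_prime - mean(y_prime)
  vy <- sum(cy^2); vp <- sum(cp^2)
  if (vy == 0 || vp == 0)
    stop("plcc: correlation undefined for a constant vector")
  sum(cp * cy) / sqrt(vp * vy)
}

#' Spearman rank correlation coefficient
#'
#' Computed on average ranks (ties averaged): the Pearson correlation of
#' the rank vectors, which reduces to \eqn{1 - 6 \sum d_i^2 / (n (n^2-1))}
#' with \eqn{d_i} the rank differences when there are no ties. Invariant
#' to strictly monotone transforms of either argument.
#'
#' @param y,y_prime equal-length numeric vectors, both non-constant.
#' @return scalar in [-1, 1].
#' @export
srcc <- function(y, y_prime) {
  if (length(y) != length(y_prime))
    stop("srcc: length mismatch")
  if (length(y) < 2) stop("srcc: need at least two observations")
  plcc(rank(y, ties.method = "average"), rank(y_prime, ties.method = "average"))
}

#' Three-level confusion matrix
#'
#' Both score vectors are mapped through [map_quality_level()] and
#' cross-tabulated; rows are the true level, columns the predicted level.
#'
#' @param true_scores,pred_scores numeric vectors of scores in [0, 100].
#' @return 3x3 integer matrix with dimnames Good/Usable/Reject.
#' @export
confusion_3level <- function(true_scores, pred_scores) {
  if (length(true_scores) != length(pred_scores))
    stop("confusion_3level: length mismatch")
  tl <- map_quality_level(true_scores)
  pl <- map_quality_level(pred_scores)
  m <- table(true = tl, predicted = pl)
  matrix(as.integer(m), 3, 3, dimnames = list(true = .FQS_LEVELS,
                                              predicted = .FQS_LEVELS))
}

#' Bundle evaluation metrics into a report
#'
#' @param y true MOS values; `y_prime` predictions (same length).
#' @param clamp clamp predictions to [0, 100] before the confusion matrix
#'   (correlations and RMSE always use the raw predictions).
#' @return object of class `metric_report`: list with `srcc`, `plcc`,
#'   `rmse`, `n` and the 3x3 `confusion` matrix.
#' @export
metric_report <- function(y, y_prime, clamp = TRUE) {
  yc <- if (clamp) pmin(100, pmax(0, y_prime)) else y_prime
  structure(list(srcc = srcc(y, y_prime), plcc = plcc(y, y_prime),
                 rmse = rmse(y, y_prime), n = length(y),
                 confusion = confusion_3level(y, yc)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("n = %d  SRCC %.4f  PLCC %.4f  RMSE %.3f\n",
              x$n, x$srcc, x$plcc, x$rmse))
  print(x$confusion)
  invisible(x)
}
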