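#' Pearson correlation between observed and imputed traits
#'
#' Thin wrapper around the sample Pearson correlation with explicit
#' domain checks (equal lengths of at least 3, both vectors non-constant).
#'
#' @param a,b Numeric vectors of equal length.
#' @return The correlation in `[-1, 1]`.
#' @export
trait_cor <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3) {
    stop("need two vectors of equal length >= 3", call. = FALSE)
  }
  if (sd(a) == 0 || sd(b) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  cor(a, b)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Over all case-control pairs, the fraction where the case scores higher,
#' counting ties as one half.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0 = control, 1 = case).
#' @return The AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Sweeps thresholds over the unique scores in descending order; the curve
#' starts at `(0, 0)`, ends at `(1, 1)`, and both coordinates are
#' non-decreasing. Its trapezoidal area equals [auc_score()].
#'
#' @inheritParams auc_score
#' @return A tibble with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & labels == 1), 0L)
  fp <- vapply(thr, function(t) sum(scores >= t & labels == 0), 0L)
  tibble::tibble(threshold = c(Inf, thr),
                 fpr = c(0, fp / n0),
                 tpr = c(0, tp / n1))
}

#' DeLong's paired test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors evaluated on the same samples
#' using the empirical covariance of per-observation placement values.
#' Identical score vectors return `z = 0`, `p = 1` by convention.
#'
#' @param scores_a,scores_b Two score vectors on the same samples.
#' @param labels Binary labels (0/1).
#' @return A one-row tibble with `auc_a`, `auc_b`, `var_diff`, `z`,
#'   `p_value` (two-sided).
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  placements <- function(s) {
    cases <- s[labels == 1]; controls <- s[labels == 0]
    # V10[i]: fraction of controls scored below case i (ties half)
    v10 <- vapply(cases, function(x) mean((x > controls) + 0.5 * (x == controls)), 0)
    v01 <- vapply(controls, function(x) mean((cases > x) + 0.5 * (cases == x)), 0)
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  pa <- placements(scores_a); pb <- placements(scores_b)
  if (identical(as.numeric(scores_a), as.numeric(scores_b))) {
    return(tibble::tibble(auc_a = pa$auc, auc_b = pb$auc, var_diff = 0,
                          z = 0, p_value = 1))
  }
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  d <- pa$auc - pb$auc
  if (var_diff <= 0) {
    if (abs(d) > 1e-12) {
      stop("degenerate variance of the AUC difference with unequal AUCs",
           call. = FALSE)
    }
    return(tibble::tibble(auc_a = pa$auc, auc_b = pb$auc, var_diff = 0,
                          z = 0, p_value = 1))
  }
  z <- d / sqrt(var_diff)
  tibble::tibble(auc_a = pa$auc, auc_b = pb$auc, var_diff = var_diff,
                 z = z, p_value = 2 * pnorm(-abs(z)))
}
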