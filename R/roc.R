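#' Empirical AUC (Mann-Whitney estimator)
#'
#' Fraction of (negative, positive) pairs where the positive score exceeds the
#' negative one, ties counted 1/2. Higher scores are assumed disease-like.
#'
#' @param neg,pos Numeric score vectors for the negative and positive group.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' auc_mw(c(1, 2, 3), c(2, 3, 4))  # 7/9
auc_mw <- function(neg, pos) {
  check_groups(neg, pos)
  n0 <- length(neg); n1 <- length(pos)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (as.numeric(n0) * n1)
}

check_groups <- function(neg, pos) {
  if (!length(neg) || !length(pos)) stop("both score groups must be non-empty")
  if (any(!is.finite(neg)) || any(!is.finite(pos))) stop("scores must be finite")
  invisible(NULL)
}

# Candidate thresholds: midpoints between consecutive distinct pooled values,
# plus -Inf/+Inf sentinels. A subject is called positive iff score > threshold.
youden_scan <- function(neg, pos) {
  u <- sort(unique(c(neg, pos)))
  cand <- if (length(u) > 1L) c(-Inf, u[-length(u)] + diff(u) / 2, Inf) else c(-Inf, Inf)
  sens <- 1 - findInterval(cand, sort(pos)) / length(pos)
  spec <- findInterval(cand, sort(neg)) / length(neg)
  j <- sens + spec - 1
  i <- which.max(j)  # first (= smallest) threshold among ties
  list(cutpoint = cand[i], youden_j = j[i],
       sensitivity = 100 * sens[i], specificity = 100 * spec[i])
}

#' Youden-index optimal cut-point
#'
#' Scans all midpoints between consecutive distinct pooled score values (plus
#' infinite sentinels) and returns the threshold maximizing
#' J = sensitivity + specificity - 1, where a subject is called positive iff
#' its score is strictly greater than the threshold. Among thresholds with
#' equal J the smallest is returned (maximizing sensitivity).
#'
#' @inheritParams auc_mw
#' @param direction Only `"greater"` (higher score = disease) is supported.
#' @return List with `cutpoint`, `youden_j`, `sensitivity` and `specificity`
#'   (the latter two in percent).
#' @export
#' @examples
#' youden_cutpoint(c(1.0, 1.1, 1.2), c(1.5, 1.6))  # cutpoint 1.35, J = 1
youden_cutpoint <- function(neg, pos, direction = "greater") {
  if (!identical(direction, "greater")) stop("only direction = 'greater' is supported")
  check_groups(neg, pos)
  youden_scan(neg, pos)
}

#' Stratified bootstrap CIs for the Youden cut-point
#'
#' Resamples the negative and positive groups independently (with
#' replacement), recomputes the Youden cut-point, sensitivity and specificity
#' on each resample, and returns percentile 95% intervals.
#'
#' @inheritParams auc_mw
#' @param B Number of bootstrap resamples (at least 100).
#' @param seed Integer seed; identical seeds give identical intervals.
#' @return List with the point estimates plus `cut_ci`, `sens_ci`, `spec_ci`
#'   (each `c(low, high)`), `B` and `seed`.
#' @export
bootstrap_cutpoint_ci <- function(neg, pos, B = 2000, seed = 1) {
  check_groups(neg, pos)
  if (B < 100) stop("B must be at least 100")
  if (length(neg) < 10 || length(pos) < 10) {
    stop("bootstrap CIs need at least 10 subjects per group")
  }
  point <- youden_scan(neg, pos)
  set.seed(seed)
  n0 <- length(neg); n1 <- length(pos)
  stat <- matrix(NA_real_, B, 3L)
  for (b in seq_len(B)) {
    r <- youden_scan(neg[sample.int(n0, n0, replace = TRUE)],
                     pos[sample.int(n1, n1, replace = TRUE)])
    stat[b, ] <- c(r$cutpoint, r$sensitivity, r$specificity)
  }
  qs <- apply(stat, 2L, stats::quantile, probs = c(0.025, 0.975), names = FALSE,
              type = 7)
  c(point, list(cut_ci = qs[, 1], sens_ci = qs[, 2], spec_ci = qs[, 3],
                B = B, seed = seed))
}

#' Closed-form binormal AUC and Youden cut-point
#'
#' For scores distributed `N(mu0, sd0^2)` (negatives) and `N(mu1, sd1^2)`
#' (positives, `mu1 >= mu0`): the AUC is `pnorm((mu1 - mu0) / sqrt(sd0^2 +
#' sd1^2))`, and the population Youden-optimal threshold is the crossing point
#' of the two densities (the quadratic-equation root between the means;
#' midpoint `(mu0 + mu1) / 2` in the equal-variance limit).
#'
#' @param mu0,sd0 Negative-group mean and SD (`sd0 > 0`).
#' @param mu1,sd1 Positive-group mean and SD (`sd1 > 0`).
#' @return `binormal_auc()`: AUC in \[0, 1\]; `binormal_youden_cut()`: the
#'   optimal threshold.
#' @export
#' @examples
#' binormal_auc(0, 1, 1, 1)         # pnorm(1 / sqrt(2))
#' binormal_youden_cut(0, 1, 1, 1)  # 0.5
binormal_auc <- function(mu0, sd0, mu1, sd1) {
  if (sd0 <= 0 || sd1 <= 0) stop("sd0 and sd1 must be > 0")
  stats::pnorm((mu1 - mu0) / sqrt(sd0^2 + sd1^2))
}

#' @rdname binormal_auc
#' @export
binormal_youden_cut <- function(mu0, sd0, mu1, sd1) {
  if (sd0 <= 0 || sd1 <= 0) stop("sd0 and sd1 must be > 0")
  if (abs(sd0 - sd1) < 1e-12) return((mu0 + mu1) / 2)
  a <- 1 / sd0^2 - 1 / sd1^2
  b <- -2 * (mu0 / sd0^2 - mu1 / sd1^2)
  cc <- mu0^2 / sd0^2 - mu1^2 / sd1^2 + 2 * log(sd0 / sd1)
  disc <- b^2 - 4 * a * cc
  roots <- (-b + c(-1, 1) * sqrt(max(disc, 0))) / (2 * a)
  lo <- min(mu0, mu1); hi <- max(mu0, mu1)
  inside <- roots[roots >= lo & roots <= hi]
  if (length(inside)) inside[1] else roots[which.min(abs(roots - (mu0 + mu1) / 2))]
}

#' Classify tau positivity against a cut-point
#'
#' A subject is tau-positive iff its composite SUVR is strictly greater than
#' the cut-point (e.g. temporal meta-ROI SUVR > 1.35).
#'
#' @param composite_suvr Numeric vector of composite SUVR values.
#' @param cutpoint Threshold in SUVR units.
#' @return Character vector of `"positive"` / `"negative"`.
#' @export
classify_tau_positive <- function(composite_suvr, cutpoint) {
  if (any(!is.finite(composite_suvr)) || !is.finite(cutpoint)) {
    stop("inputs must be finite")
  }
  ifelse(composite_suvr > cutpoint, "positive", "negative")
}
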