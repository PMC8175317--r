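# Placement values ("structural components") for the DeLong variance
# estimator: v10[i] = fraction of negatives below positive i (ties 1/2),
# v01[j] = fraction of positives above negative j.
delong_components <- function(neg, pos) {
  check_groups(neg, pos)
  n1 <- length(pos); n0 <- length(neg)
  r <- rank(c(pos, neg), ties.method = "average")
  v10 <- (r[seq_len(n1)] - rank(pos, ties.method = "average")) / n0
  v01 <- 1 - (r[n1 + seq_len(n0)] - rank(neg, ties.method = "average")) / n1
  list(auc = mean(v10), v10 = v10, v01 = v01)
}

#' AUC with DeLong confidence interval
#'
#' Variance of the empirical AUC from the placement-value (structural
#' components) estimator: `var(v10)/n1 + var(v01)/n0`. The normal-approximation
#' CI is truncated to \[0, 1\].
#'
#' @inheritParams auc_mw
#' @param conf Confidence level (default 0.95).
#' @return List with `auc`, `se`, `ci` (length 2).
#' @export
delong_ci <- function(neg, pos, conf = 0.95) {
  cmp <- delong_components(neg, pos)
  v <- stats::var(cmp$v10) / length(pos) + stats::var(cmp$v01) / length(neg)
  se <- sqrt(max(v, 0))
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  list(auc = cmp$auc, se = se,
       ci = c(max(0, cmp$auc - zq * se), min(1, cmp$auc + zq * se)))
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two scores measured on the same subjects using the
#' DeLong placement-value covariance estimator and a two-sided normal test.
#'
#' @param scores_a,scores_b Numeric score vectors over the same subjects.
#' @param labels Binary class labels (logical, 0/1, or two-level factor;
#'   `TRUE`/1/second level = positive).
#' @return List with `auc_a`, `auc_b`, `delta` (= `auc_a - auc_b`),
#'   `var_delta`, `z`, `p` (two-sided).
#' @export
#' @examples
#' set.seed(1)
#' y <- rep(c(0, 1), each = 40)
#' s <- rnorm(80) + y
#' delong_paired(s, s + rnorm(80, sd = 0.2), y)
delong_paired <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(labels)) {
    stop("scores_a, scores_b and labels must have equal length")
  }
  pos_idx <- as_binary_labels(labels)
  if (!any(pos_idx) || all(pos_idx)) stop("labels must contain both classes")
  ca <- delong_components(scores_a[!pos_idx], scores_a[pos_idx])
  cb <- delong_components(scores_b[!pos_idx], scores_b[pos_idx])
  n1 <- sum(pos_idx); n0 <- sum(!pos_idx)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  delta <- ca$auc - cb$auc
  if (var_delta < 1e-14) {
    z <- 0; p <- 1
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = ca$auc, auc_b = cb$auc, delta = delta,
       var_delta = max(var_delta, 0), z = z, p = p)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) {
    if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
    return(labels == levels(labels)[2L])
  }
  u <- sort(unique(labels))
  if (length(u) > 2L) stop("labels must be binary")
  labels == u[length(u)]
}
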