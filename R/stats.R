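#' Percent change relative to baseline
#'
#' \eqn{100 (v - v_0) / v_0}, the longitudinal change metric (e.g. V21%,
#' V31%: visit 2 or 3 relative to visit 1). Undefined for a zero baseline;
#' such entries return `NA` with a warning so callers can flag the row.
#' Percent change is scale-free: multiplying a metric by any positive
#' constant (relaxivity, signal scale) leaves it unchanged.
#'
#' @param v_visit Value(s) at the follow-up visit.
#' @param v_baseline Baseline value(s).
#' @return Percent change(s).
#' @examples
#' percent_change(0.44, 0.33)  # +33% to the nearest integer
#' @export
percent_change <- function(v_visit, v_baseline) {
  out <- 100 * (v_visit - v_baseline) / v_baseline
  if (any(v_baseline == 0, na.rm = TRUE)) {
    warning("zero baseline: percent change undefined for some entries",
            call. = FALSE)
    out[v_baseline == 0] <- NA_real_
  }
  out
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Two-sided rank-sum (Mann-Whitney) test: exact enumeration when the
#' combined sample size is at most 12 and there are no ties, otherwise the
#' normal approximation with tie correction and continuity correction.
#' Identical constant groups return p = 1.
#'
#' @param group_a,group_b Numeric vectors, each nonempty.
#' @return Two-sided p-value.
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))  # exact p = 1/3
#' @export
wilcoxon_rank_sum <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  all_vals <- c(group_a, group_b)
  if (length(unique(all_vals)) == 1) return(1)
  ties <- anyDuplicated(all_vals) > 0
  exact <- length(all_vals) <= 12 && !ties
  suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact,
                       correct = !exact)$p.value)
}

#' Paired Student's t-test
#'
#' Two-sided paired t-test on per-subject differences, used e.g. to compare
#' K^trans between analysis approaches (ROI vs voxel, fixed vs measured
#' R1,0, Tofts vs shutter-speed) across the same patients.
#'
#' @param values_a,values_b Paired numeric vectors of equal length >= 2.
#' @return Two-sided p-value.
#' @export
paired_t_test <- function(values_a, values_b) {
  if (length(values_a) != length(values_b) || length(values_a) < 2) {
    stop("paired vectors must have equal length >= 2", call. = FALSE)
  }
  d <- values_a - values_b
  if (stats::sd(d) == 0) {
    stop("zero variance of paired differences: t-test undefined", call. = FALSE)
  }
  stats::t.test(values_a, values_b, paired = TRUE)$p.value
}

# Concordant-pair (rank) AUC with half credit for ties: the probability
# that a positive outranks a negative.
rank_auc <- function(labels, scores) {
  r <- rank(scores)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC analysis of a univariate predictor
#'
#' Fits a univariate logistic regression of the binary label on the score
#' and computes the ROC AUC of the fitted probabilities, alongside the
#' concordant-pair (rank) AUC of the raw score. Because the logistic
#' transform is monotone, the two agree up to score direction; both are
#' computed and the directional AUC of the raw score (higher score =
#' positive class) is reported with a DeLong 95% confidence interval.
#' Negating all scores maps the AUC to 1 − AUC. Tied score pairs receive
#' half credit.
#'
#' @param labels Binary outcome: logical, 0/1, or a two-level factor whose
#'   second level is the positive class.
#' @param scores Numeric predictor, same length.
#' @return A `dce_roc` object: list with `auc`, `auc_logistic`, `ci95`
#'   (DeLong, clipped to [0, 1]), `n_pos`, `n_neg`, and the input data.
#' @examples
#' r <- roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))
#' r$auc  # 0.75
#' @export
roc_auc <- function(labels, scores) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  if (is.character(labels)) labels <- labels == sort(unique(labels))[2]
  labels <- as.logical(labels)
  stopifnot(length(labels) == length(scores))
  ok <- is.finite(scores) & !is.na(labels)
  labels <- labels[ok]; scores <- scores[ok]
  if (length(unique(labels)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  auc <- rank_auc(labels, scores)

  fit <- suppressWarnings(
    stats::glm(labels ~ scores, family = stats::binomial()))
  auc_logit <- rank_auc(labels, stats::fitted(fit))

  ci <- suppressWarnings(suppressMessages(as.numeric(
    pROC::ci.auc(pROC::roc(response = labels, predictor = scores,
                           direction = "<", quiet = TRUE),
                 method = "delong"))))
  ci95 <- pmin(pmax(c(ci[1], ci[3]), 0), 1)
  ci95 <- c(min(ci95[1], auc), max(ci95[2], auc))

  structure(list(auc = auc, auc_logistic = auc_logit, ci95 = ci95,
                 n_pos = sum(labels), n_neg = sum(!labels),
                 labels = labels, scores = scores),
            class = "dce_roc")
}

#' @export
print.dce_roc <- function(x, ...) {
  cat(sprintf("<dce_roc> AUC %.3f (95%% CI %.3f-%.3f), %d pos / %d neg\n",
              x$auc, x$ci95[1], x$ci95[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' Percent-change columns for a cohort metric table
#'
#' Pivots a long cohort table (one row per patient, visit and metric) to
#' one row per patient-metric and appends percent changes of each
#' follow-up visit relative to baseline (columns like `V21_pct`,
#' `V31_pct`). Patients lacking the baseline visit are dropped with a
#' message.
#'
#' @param cohort Long tibble with columns `patient`, `group`, `visit`,
#'   `metric`, `value`.
#' @param baseline Baseline visit id (default `"V1"`).
#' @return Wide tibble `patient`, `group`, `metric`, one value column per
#'   visit, and percent-change columns.
#' @export
cohort_percent_change <- function(cohort, baseline = "V1") {
  wide <- cohort |>
    dplyr::select("patient", "group", "visit", "metric", "value") |>
    tidyr::pivot_wider(names_from = "visit", values_from = "value")
  if (!baseline %in% names(wide)) stop("baseline visit absent", call. = FALSE)
  miss <- is.na(wide[[baseline]])
  if (any(miss)) {
    message(sum(miss), " patient-metric rows lack the baseline visit; dropped")
    wide <- wide[!miss, ]
  }
  for (v in intersect(c("V2", "V3", "V4"), names(wide))) {
    wide[[paste0("V", sub("V", "", v), "1_pct")]] <-
      percent_change(wide[[v]], wide[[baseline]])
  }
  wide
}

#' Group comparison and ROC prediction for one metric
#'
#' Emits one row of a response-prediction table for a chosen metric and
#' percent-change column: per-group median and interquartile bounds of the
#' percent change, the two-sided Wilcoxon rank-sum p-value comparing the
#' groups, and the ROC AUC with DeLong 95% CI from univariate logistic
#' regression. The AUC is reported in the discriminative orientation
#' (>= 0.5). Patients missing the needed visit are dropped and counted in
#' `n_dropped`.
#'
#' @param cohort Long tibble `patient`, `group`, `visit`, `metric`,
#'   `value`; `group` must take the values `"pCR"` and `"non-pCR"`.
#' @param metric Metric name to analyze.
#' @param change Percent-change column, `"V31"` or `"V21"` (or `"V41"`).
#' @param positive Group treated as the positive class (default `"pCR"`).
#' @return One-row tibble: metric, change, group ns, per-group median and
#'   quartiles (rounded percent changes are conventional for reporting;
#'   full precision is retained here), `wilcoxon_p`, `auc`, `auc_lo`,
#'   `auc_hi`, `n_dropped`.
#' @export
predict_response <- function(cohort, metric, change = c("V31", "V21", "V41"),
                             positive = "pCR") {
  change <- match.arg(change)
  col <- paste0(change, "_pct")
  wide <- cohort_percent_change(dplyr::filter(cohort, .data$metric == !!metric))
  if (!col %in% names(wide)) {
    stop(sprintf("visit column for %s not present", change), call. = FALSE)
  }
  n_dropped <- sum(!is.finite(wide[[col]]))
  if (n_dropped > 0) {
    message(n_dropped, " patient(s) missing the ", change,
            " visit for ", metric, "; dropped")
  }
  wide <- wide[is.finite(wide[[col]]), ]
  x <- wide[[col]]
  grp <- wide$group
  pos <- grp == positive
  if (!any(pos) || all(pos)) stop("both groups must be present", call. = FALSE)

  q <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  qp <- q(x[pos]); qn <- q(x[!pos])
  roc <- roc_auc(pos, x)
  if (roc$auc < 0.5) roc <- roc_auc(pos, -x)

  tibble::tibble(
    metric = metric, change = change,
    n_pos = sum(pos), n_neg = sum(!pos), n_dropped = n_dropped,
    median_pos = qp[2], q25_pos = qp[1], q75_pos = qp[3],
    median_neg = qn[2], q25_neg = qn[1], q75_neg = qn[3],
    wilcoxon_p = wilcoxon_rank_sum(x[pos], x[!pos]),
    auc = roc$auc, auc_lo = roc$ci95[1], auc_hi = roc$ci95[2]
  )
}
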