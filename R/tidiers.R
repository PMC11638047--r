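#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a single-curve pharmacokinetic fit
#'
#' One row per estimated parameter with its value, in broom style.
#'
#' @param x A `pk_fit` from [fit_tm()] or [fit_ssm()].
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`.
#' @exportS3Method generics::tidy
tidy.pk_fit <- function(x, ...) {
  terms <- c("ktrans", "ve", "kep", if (x$model == "ssm") "kio")
  tibble::tibble(term = terms,
                 estimate = as.numeric(x[1, terms]))
}

#' One-row fit diagnostics for a pharmacokinetic fit
#'
#' @param x A `pk_fit`.
#' @param ... Unused.
#' @return Tibble with `model`, `rss`, `converged`, `at_bound`, `bat`.
#' @exportS3Method generics::glance
glance.pk_fit <- function(x, ...) {
  tibble::tibble(model = x$model, rss = x$rss, converged = x$converged,
                 at_bound = x$at_bound, bat = x$bat)
}

#' Tidy an ROC result
#'
#' @param x A `dce_roc` from [roc_auc()].
#' @param ... Unused.
#' @return One-row tibble: `auc`, `auc_logistic`, `ci_low`, `ci_high`,
#'   `n_pos`, `n_neg`.
#' @exportS3Method generics::tidy
tidy.dce_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, auc_logistic = x$auc_logistic,
                 ci_low = x$ci95[1], ci_high = x$ci95[2],
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @rdname tidy.dce_roc
#' @exportS3Method generics::glance
glance.dce_roc <- function(x, ...) tidy.dce_roc(x)

#' Plot observed and fitted DCE time courses
#'
#' @param object A `pk_fit` with its attached curve.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pk_fit <- function(object, ...) {
  curve <- attr(object, "curve")
  if (is.null(curve)) stop("fit carries no curve data", call. = FALSE)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), color = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "signal",
                  title = sprintf("%s fit: Ktrans %.3g /min, ve %.2g%s",
                                  toupper(object$model), object$ktrans,
                                  object$ve,
                                  if (is.na(object$kio)) "" else
                                    sprintf(", kio %.3g /s", object$kio))) +
    ggplot2::theme_minimal()
}

#' Plot an ROC curve
#'
#' Empirical ROC curve of the score with the AUC in the title.
#'
#' @param object A `dce_roc`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.dce_roc <- function(object, ...) {
  th <- sort(unique(object$scores), decreasing = TRUE)
  pts <- purrr::map_dfr(c(Inf, th, -Inf), function(t) {
    tibble::tibble(fpr = mean(object$scores[!object$labels] >= t),
                   tpr = mean(object$scores[object$labels] >= t))
  })
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC: AUC %.2f (95%% CI %.2f-%.2f)",
                                  object$auc, object$ci95[1], object$ci95[2])) +
    ggplot2::theme_minimal()
}

#' Plot the arterial input function
#'
#' @param object An `aif_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.aif_curve <- function(object, ...) {
  d <- tibble::tibble(time = object$times, cp = object$cp)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$cp)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = expression(C[p] ~ "(mM)"),
                  title = "Arterial input function") +
    ggplot2::theme_minimal()
}

#' Histogram of a voxel parameter with its interquartile band
#'
#' The response-monitoring view of intratumor heterogeneity: a histogram
#' of voxel values with the interquartile range shaded (its width is the
#' iqr metric reported per tumor and visit).
#'
#' @param values Numeric voxel values (e.g. SSM K^trans).
#' @param metric Axis label.
#' @param bins Histogram bins.
#' @return A ggplot.
#' @export
plot_metric_histogram <- function(values, metric = "Ktrans (1/min)",
                                  bins = 40) {
  values <- values[is.finite(values)]
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  ggplot2::ggplot(tibble::tibble(value = values),
                  ggplot2::aes(x = .data$value)) +
    ggplot2::annotate("rect", xmin = q[1], xmax = q[2],
                      ymin = -Inf, ymax = Inf, fill = "grey80") +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            color = "white") +
    ggplot2::labs(x = metric, y = "voxels",
                  title = sprintf("iqr = %.3g", diff(q))) +
    ggplot2::theme_minimal()
}
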