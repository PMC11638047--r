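#' @importFrom rlang .data
NULL

# Forward DCE signal for a parameter set. model "tm" uses the FXL linear R1,
# "ssm" the FXR exchange eigenvalue. s0 is pre-calibrated, not fitted.
forward_dce <- function(par, model, r10, s0, aif, protocol, times) {
  ct <- kety_concentration(par[["ktrans"]], par[["ve"]], aif, times = times)
  r1_t <- if (model == "tm") {
    fxl_r1(ct, r10, protocol$relaxivity_r1)
  } else {
    # pre-contrast compartmental rates assumed equal: r1i = r1o0 = R1,0
    fxr_r1(ct, par[["ve"]], par[["kio"]], r1i = r10, r1o0 = r10,
           relaxivity = protocol$relaxivity_r1)
  }
  spgr_signal(s0, r1_t, protocol$fa_dce, protocol$tr_dce)
}

pk_bounds <- function(model) {
  if (model == "tm") {
    list(lower = c(ktrans = 0, ve = 1e-3),
         upper = c(ktrans = 5, ve = 1))
  } else {
    list(lower = c(ktrans = 0, ve = 1e-3, kio = 1e-3),
         upper = c(ktrans = 5, ve = 1, kio = 1000))
  }
}

# Fixed multi-start list. The first SSM start sits at the FXL-limit kio
# boundary: exchange-insensitive curves leave it there (the flat direction
# has no gradient), reproducing the boundary-pileup behaviour of fits on
# low-extravasation voxels, while informative curves pull it away.
pk_starts <- function(model) {
  if (model == "tm") {
    list(c(ktrans = 0.1, ve = 0.3),
         c(ktrans = 0.5, ve = 0.6))
  } else {
    list(c(ktrans = 0.2, ve = 0.4, kio = 1000),
         c(ktrans = 0.1, ve = 0.3, kio = 3),
         c(ktrans = 0.5, ve = 0.6, kio = 0.3))
  }
}

fit_pk_curve <- function(signal, times, model, r10, aif, protocol, bat = 0) {
  stopifnot(length(signal) == length(times))
  base_idx <- which(times < injection_time(protocol))
  if (length(base_idx) < 2) {
    stop("need at least 2 pre-injection frames", call. = FALSE)
  }
  baseline <- mean(signal[base_idx])
  unit <- spgr_signal(1, r10, protocol$fa_dce, protocol$tr_dce)
  s0 <- baseline / unit
  aif_use <- if (bat != 0) shift_aif(aif, bat) else aif

  b <- pk_bounds(model)
  resid_fn <- function(par) {
    names(par) <- names(b$lower)
    signal - forward_dce(par, model, r10, s0, aif_use, protocol, times)
  }

  best <- NULL
  for (start in pk_starts(model)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = b$lower, upper = b$upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss * (1 - 1e-9)) {
      best <- list(fit = fit, rss = rss)
    }
  }

  if (is.null(best)) {
    par <- stats::setNames(rep(NA_real_, length(b$lower)), names(b$lower))
    return(new_pk_fit(model, par, s0, bat, NA_real_, FALSE, FALSE,
                      times, signal, rep(NA_real_, length(signal))))
  }

  par <- stats::setNames(as.numeric(best$fit$par), names(b$lower))
  converged <- best$fit$info %in% 1:4
  tol <- 1e-4
  at_bound <- any(par - b$lower < tol * pmax(abs(b$lower), 1) |
                  b$upper - par < tol * abs(b$upper))
  fitted <- forward_dce(par, model, r10, s0, aif_use, protocol, times)
  new_pk_fit(model, par, s0, bat, best$rss, converged, at_bound,
             times, signal, fitted)
}

new_pk_fit <- function(model, par, s0, bat, rss, converged, at_bound,
                       times, observed, fitted) {
  out <- tibble::tibble(
    model = model,
    ktrans = par[["ktrans"]],
    ve = par[["ve"]],
    kep = par[["ktrans"]] / par[["ve"]],
    kio = if ("kio" %in% names(par)) par[["kio"]] else NA_real_,
    s0 = s0, bat = bat, rss = rss,
    converged = converged, at_bound = at_bound
  )
  attr(out, "curve") <- tibble::tibble(time = times, observed = observed,
                                       fitted = fitted)
  class(out) <- c("pk_fit", class(out))
  out
}

#' Fit the Tofts model to one DCE time course
#'
#' Nonlinear least squares over \eqn{(K^{trans}, v_e)} of the composed
#' forward model (Kety kinetics, FXL linear R1, SPGR readout). The
#' equilibrium scale is calibrated from the pre-injection frames and `r10`
#' rather than fitted, and \eqn{k_{ep} = K^{trans}/v_e} is derived from the
#' estimates. Bounds: \eqn{K^{trans} \in [0, 5]} min^-1,
#' \eqn{v_e \in (10^{-3}, 1]}.
#'
#' @param signal Numeric vector of frame signals for one voxel (or an
#'   ROI-averaged curve).
#' @param protocol An [acq_protocol()].
#' @param r10 Pre-contrast R1 (s^-1): the fixed literature value (0.60 at
#'   3T for breast tumor) or a voxel's measured value.
#' @param aif An [aif_curve()] aligned to the injection time.
#' @param bat Additional bolus arrival delay (s) applied to the AIF, e.g.
#'   from [estimate_bat()].
#' @param times Frame times (s); defaults to `frame_times(protocol)`.
#' @return A one-row `pk_fit` tibble: `model`, `ktrans` (min^-1), `ve`,
#'   `kep` (min^-1), `kio` (NA for the Tofts model), `s0`, `bat`, `rss`,
#'   `converged`, `at_bound`. The observed and fitted curves are attached
#'   as the `"curve"` attribute (see [autoplot.pk_fit()]).
#' @seealso [fit_ssm()], [fit_dce()]
#' @export
fit_tm <- function(signal, protocol, r10, aif, bat = 0,
                   times = frame_times(protocol)) {
  fit_pk_curve(signal, times, "tm", r10, aif, protocol, bat)
}

#' Fit the shutter-speed model to one DCE time course
#'
#' As [fit_tm()], but the forward model uses the FXR two-site water-exchange
#' R1 ([fxr_r1()]) and additionally fits the cellular water efflux rate
#' constant \eqn{k_{io} \in (10^{-3}, 1000]} s^-1. The wide upper bound
#' keeps genuinely exchange-informative fits away from a premature boundary
#' stop; exchange-insensitive voxels (negligible extravasation) typically
#' return `kio` at a boundary with `at_bound = TRUE`, and should be
#' screened with [filter_kio()]. A fixed three-point multi-start guards
#' against local minima; results are deterministic.
#'
#' @inheritParams fit_tm
#' @return A one-row `pk_fit` tibble (see [fit_tm()]) with `kio` populated.
#' @export
fit_ssm <- function(signal, protocol, r10, aif, bat = 0,
                    times = frame_times(protocol)) {
  fit_pk_curve(signal, times, "ssm", r10, aif, protocol, bat)
}

#' Average a DCE series over an ROI
#'
#' Concatenated multi-slice tumor ROIs are reduced to a single
#' frame-by-frame arithmetic mean time course for ROI-based fitting.
#'
#' @param dce Long tibble with columns `voxel`, `frame`, `time`, `signal`
#'   (as produced by [simulate_dce_series()]).
#' @param voxels Optional subset of voxel ids to average (e.g. the
#'   enhancing mask); default all.
#' @return Tibble with one row per frame: `frame`, `time`, `signal`.
#' @export
roi_average_curve <- function(dce, voxels = NULL) {
  if (!is.null(voxels)) dce <- dplyr::filter(dce, .data$voxel %in% voxels)
  if (nrow(dce) == 0) stop("empty ROI: no voxels to average", call. = FALSE)
  dce |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(time = .data$time[1], signal = mean(.data$signal),
                     .groups = "drop") |>
    dplyr::arrange(.data$frame)
}

#' Estimate per-voxel bolus arrival time
#'
#' Model-based AIF alignment: for each candidate time shift the linearized
#' Tofts system
#' \deqn{C_t(t_i) = K^{trans}\int_0^{t_i} C_p - k_{ep}\int_0^{t_i} C_t}
#' is solved by linear least squares on concentration-converted data (SPGR
#' inversion with the supplied fixed `r10`), and the shift minimizing the
#' residual is returned. The search runs in two phases: a brute-force
#' coarse grid from -2 to +6 frame intervals in quarter-frame steps, then a
#' derivative-free refinement confined to one coarse step around the best
#' grid point.
#'
#' @param signal Frame signals of an enhancing voxel.
#' @param protocol An [acq_protocol()].
#' @param aif Nominal (unshifted) [aif_curve()].
#' @param r10 Fixed pre-contrast R1 (s^-1) for concentration conversion.
#' @param times Frame times (s).
#' @param threshold Minimum fractional peak enhancement below which the
#'   curve is considered non-enhancing and BAT undefined.
#' @return The estimated additional AIF delay in seconds (0 means the
#'   nominal alignment is best).
#' @export
estimate_bat <- function(signal, protocol, aif, r10 = 0.6,
                         times = frame_times(protocol), threshold = 0.3) {
  base_idx <- which(times < injection_time(protocol))
  baseline <- mean(signal[base_idx])
  enh <- (max(signal[-base_idx]) - baseline) / baseline
  if (!is.finite(enh) || enh < threshold) {
    stop("BAT undefined: curve does not enhance above threshold", call. = FALSE)
  }
  ct <- signal_to_concentration(signal, protocol, r10)
  int_ct <- cumtrapz(times, ct)
  # integral of Cp on the fine AIF grid: frame-rate sampling would miss the
  # bolus peak entirely
  int_cp_grid <- cumtrapz(aif$times, aif$cp)

  score <- function(delta) {
    int_cp <- stats::approx(aif$times, int_cp_grid, xout = times - delta,
                            yleft = 0, rule = 2)$y
    x <- cbind(int_cp, -int_ct)
    fit <- stats::lm.fit(x, ct)
    sum(fit$residuals^2)
  }

  step <- protocol$frame_interval / 4
  grid <- seq(-2 * protocol$frame_interval, 6 * protocol$frame_interval,
              by = step)
  rss <- vapply(grid, score, numeric(1))
  best <- grid[which.min(rss)]
  opt <- stats::optimize(score, interval = c(best - step, best + step),
                         tol = 1e-3)
  if (opt$objective <= min(rss)) opt$minimum else best
}

cumtrapz <- function(t, y) {
  n <- length(t)
  c(0, cumsum(diff(t) * (y[-n] + y[-1]) / 2))
}

#' Fit pharmacokinetic models across a DCE series
#'
#' Data-frame-first driver over the per-curve fitters: voxel mode fits each
#' voxel's time course, ROI mode first averages the (enhancing) voxels into
#' a single curve. `r10` may be the fixed literature value (scalar) or a
#' measured per-voxel map from [fit_vfa_r1()] (ROI mode then uses the median
#' of the valid voxel values).
#'
#' @param dce Long tibble `voxel`, `frame`, `time`, `signal`.
#' @param protocol An [acq_protocol()].
#' @param aif An [aif_curve()] aligned to the injection time.
#' @param model `"tm"` or `"ssm"`.
#' @param r10 Scalar fixed R1,0 (s^-1) or a tibble with columns `voxel`,
#'   `r1` (and optionally `valid`) as returned by [fit_vfa_r1()].
#' @param mode `"voxel"` or `"roi"`.
#' @param voxels Optional voxel subset (e.g. enhancing mask from
#'   [mask_unenhanced()]).
#' @param align_bat If `TRUE`, estimate and apply a per-curve bolus arrival
#'   shift with [estimate_bat()] before fitting (curves for which BAT is
#'   undefined fall back to the nominal alignment).
#' @return A `pk_map` tibble with one row per fitted curve (`voxel` is `NA`
#'   for ROI mode) and the `pk_fit` columns.
#' @export
fit_dce <- function(dce, protocol, aif, model = c("tm", "ssm"),
                    r10 = 0.6, mode = c("voxel", "roi"),
                    voxels = NULL, align_bat = FALSE) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  fitter <- if (model == "tm") fit_tm else fit_ssm

  r10_for <- function(v) {
    if (is.numeric(r10) && length(r10) == 1) return(r10)
    idx <- match(v, r10$voxel)
    r10$r1[idx]
  }

  one <- function(sig, tt, r10v, vox) {
    bat <- 0
    if (align_bat) {
      bat <- tryCatch(estimate_bat(sig, protocol, aif, r10 = r10v, times = tt),
                      error = function(e) 0)
    }
    fit <- fitter(sig, protocol, r10 = r10v, aif = aif, bat = bat, times = tt)
    attr(fit, "curve") <- NULL
    dplyr::bind_cols(tibble::tibble(voxel = vox), fit)
  }

  if (mode == "roi") {
    curve <- roi_average_curve(dce, voxels = voxels)
    r10v <- if (is.numeric(r10) && length(r10) == 1) {
      r10
    } else {
      stats::median(r10$r1[if ("valid" %in% names(r10)) r10$valid else TRUE],
                    na.rm = TRUE)
    }
    out <- one(curve$signal, curve$time, r10v, NA_integer_)
  } else {
    if (!is.null(voxels)) dce <- dplyr::filter(dce, .data$voxel %in% voxels)
    out <- dce |>
      dplyr::arrange(.data$voxel, .data$frame) |>
      dplyr::group_by(.data$voxel) |>
      dplyr::group_map(~ one(.x$signal, .x$time, r10_for(.y$voxel), .y$voxel)) |>
      dplyr::bind_rows()
  }
  class(out) <- c("pk_map", class(out))
  out
}
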