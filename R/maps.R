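#' Mask out unenhanced voxels
#'
#' Quality-control masking: a voxel is retained only if its peak
#' post-injection signal exceeds its pre-injection baseline by at least
#' `threshold` as a fraction of baseline. Unenhanced voxels carry no
#' kinetic information and would otherwise contaminate SER maps and
#' k_io fitting.
#'
#' @param dce Long tibble `voxel`, `frame`, `time`, `signal`.
#' @param protocol An [acq_protocol()] (defines the pre-injection frames).
#' @param threshold Minimum fractional peak enhancement (default 0.3).
#' @return Tibble `voxel`, `enhancement` (fractional), `enhancing`
#'   (logical).
#' @export
mask_unenhanced <- function(dce, protocol, threshold = 0.3) {
  if (threshold < 0) stop("threshold must be non-negative", call. = FALSE)
  t_inj <- injection_time(protocol)
  dce |>
    dplyr::group_by(.data$voxel) |>
    dplyr::summarise(
      enhancement = (max(.data$signal[.data$time >= t_inj]) -
                       mean(.data$signal[.data$time < t_inj])) /
        mean(.data$signal[.data$time < t_inj]),
      .groups = "drop") |>
    dplyr::mutate(enhancing = .data$enhancement >= threshold)
}

#' Map post-injection target times to SER frames
#'
#' On the default 15 s grid with injection at frame 3 the conventional SER
#' frames are baseline 2, early 9, delayed 26. For other frame grids this
#' helper picks the last pre-injection frame as baseline and the frames
#' nearest the requested early/delayed post-injection offsets.
#'
#' @param protocol An [acq_protocol()].
#' @param early,late Target times after injection (s) for the early and
#'   delayed phases.
#' @return Named integer vector `baseline`, `early`, `late` (frame
#'   indices, 1-based).
#' @export
ser_frames <- function(protocol, early = 110, late = 380) {
  tt <- frame_times(protocol)
  t0 <- injection_time(protocol)
  c(baseline = protocol$injection_frame - 1L,
    early = which.min(abs(tt - (t0 + early)))[1],
    late = which.min(abs(tt - (t0 + late)))[1])
}

#' Signal enhancement ratio (SER) map
#'
#' Semi-quantitative early-to-delayed enhancement ratio
#' \deqn{SER = (S_{early} - S_{base}) / (S_{late} - S_{base}),}
#' conventionally frames 2 (pre-contrast baseline), 9 (early phase) and 26
#' (delayed phase) on a 15 s grid. SER > 1 indicates wash-out, SER < 1
#' persistent enhancement. Computed only on enhancing voxels; voxels whose
#' late-minus-baseline denominator is numerically zero are flagged
#' invalid.
#'
#' @param dce Long tibble `voxel`, `frame`, `time`, `signal`.
#' @param enhancing Optional mask tibble from [mask_unenhanced()] (columns
#'   `voxel`, `enhancing`); voxels absent or not enhancing get `valid =
#'   FALSE`.
#' @param frames Named frame indices `baseline`, `early`, `late`.
#' @return Tibble `voxel`, `ser`, `valid`.
#' @export
compute_ser <- function(dce, enhancing = NULL,
                        frames = c(baseline = 2L, early = 9L, late = 26L)) {
  need <- frames[c("baseline", "early", "late")]
  if (any(is.na(need))) stop("frames must name baseline, early, late", call. = FALSE)
  if (any(!need %in% dce$frame)) stop("requested SER frames not present", call. = FALSE)
  wide <- dce |>
    dplyr::filter(.data$frame %in% need) |>
    dplyr::select("voxel", "frame", "signal") |>
    tidyr::pivot_wider(names_from = "frame", values_from = "signal")
  sb <- wide[[as.character(need[["baseline"]])]]
  se <- wide[[as.character(need[["early"]])]]
  sl <- wide[[as.character(need[["late"]])]]
  denom <- sl - sb
  guard <- .Machine$double.eps^0.5 * pmax(abs(sl) + abs(sb), 1)
  ok <- abs(denom) > guard
  ser <- ifelse(ok, (se - sb) / denom, NA_real_)
  out <- tibble::tibble(voxel = wide$voxel, ser = ser, valid = ok)
  if (!is.null(enhancing)) {
    keep <- enhancing$voxel[enhancing$enhancing]
    out$valid <- out$valid & out$voxel %in% keep
    out$ser[!out$valid] <- NA_real_
  }
  out
}

#' Filter fitted k_io values to the physiologically meaningful range
#'
#' Retains voxels whose fitted cellular water efflux rate lies strictly
#' inside (`lo`, `hi`). Values at or below 0.1 s^-1 imply mean
#' intracellular water lifetimes of 10 s or more — implausibly long for
#' breast tissue cell sizes — while values at or above 20 s^-1 put the
#' exchange system so close to the fast-exchange limit that a standard-dose
#' DCE acquisition cannot determine them; both typically arise from
#' exchange-insensitive (low extravasation) time courses whose fits pile up
#' at boundaries. The retained fraction is itself a reported tumor metric.
#' The operation is idempotent: filtering retained values changes nothing.
#'
#' @param kio Numeric vector of fitted k_io values (s^-1); NAs count as
#'   not retained.
#' @param lo,hi Open-interval filter bounds (s^-1); defaults 0.1 and 20.
#' @return List with `retained` (logical, same length) and `fraction`
#'   (retained / total, in [0, 1]).
#' @export
filter_kio <- function(kio, lo = 0.1, hi = 20) {
  if (lo >= hi) stop("lo must be less than hi", call. = FALSE)
  retained <- !is.na(kio) & kio > lo & kio < hi
  list(retained = retained,
       fraction = if (length(kio)) mean(retained) else NA_real_)
}

#' Time-summed EES contrast-agent concentration map
#'
#' \eqn{\Sigma[CA_o] = \sum_k [CA_o](t_k)\,\Delta t} with
#' \eqn{[CA_o] = C_t / v_e}: a simple surrogate for total contrast-agent
#' extravasation and hence for the water-exchange sensitivity of a voxel's
#' time course. Cold spots mark voxels whose fitted k_io is unreliable and
#' tend to coincide with the k_io-filtered-out regions. The default
#' weights each frame by the frame interval (units mM s, grid
#' independent); `mode = "plain"` returns the literal frame sum (mM).
#'
#' @param ct_t Concentration time courses: a numeric matrix (voxels x
#'   frames) or a single voxel's vector (mM).
#' @param ve EES volume fraction per voxel (scalar or vector), positive.
#' @param frame_interval Frame spacing (s).
#' @param mode `"dt"` (default) or `"plain"`.
#' @return Numeric vector, one value per voxel.
#' @export
sum_cao_map <- function(ct_t, ve, frame_interval, mode = c("dt", "plain")) {
  mode <- match.arg(mode)
  if (any(ve <= 0)) stop("ve must be positive on evaluated voxels", call. = FALSE)
  if (is.matrix(ct_t)) {
    s <- rowSums(ct_t) / ve
  } else {
    s <- sum(ct_t) / ve
  }
  if (mode == "dt") s * frame_interval else s
}

#' Histogram summary of a voxel metric per lesion
#'
#' Per-lesion mean, median and interquartile width
#' (iqr = 75th − 25th percentile of the voxel values; quantiles by linear
#' interpolation of order statistics at position 1 + p(n−1)) over the
#' valid voxels of each lesion. Non-finite values are dropped; a lesion
#' with no valid voxel is an error.
#'
#' @param values Numeric voxel values of one metric.
#' @param lesion Lesion id per voxel (default: a single lesion).
#' @param metric Name recorded in the output.
#' @return A `tumor_summary` tibble: `lesion`, `metric`, `n_voxels`,
#'   `mean`, `median`, `iqr`.
#' @seealso [patient_value()] for the multi-lesion patient-level value.
#' @export
summarize_metric <- function(values, lesion = NULL, metric = "metric") {
  if (is.null(lesion)) lesion <- rep(1L, length(values))
  stopifnot(length(lesion) == length(values))
  d <- tibble::tibble(lesion = lesion, value = values) |>
    dplyr::filter(is.finite(.data$value))
  missing_lesions <- setdiff(unique(lesion), unique(d$lesion))
  if (length(missing_lesions) || nrow(d) == 0) {
    stop("lesion with no valid voxel values", call. = FALSE)
  }
  out <- d |>
    dplyr::group_by(.data$lesion) |>
    dplyr::summarise(
      metric = metric,
      n_voxels = dplyr::n(),
      mean = mean(.data$value),
      median = stats::median(.data$value),
      iqr = diff(stats::quantile(.data$value, c(0.25, 0.75),
                                 names = FALSE, type = 7)),
      .groups = "drop")
  class(out) <- c("tumor_summary", class(out))
  out
}

#' Patient-level value from a multi-lesion summary
#'
#' When multiple tumors are present, the patient value of each statistic is
#' the unweighted mean of the per-lesion values.
#'
#' @param summary A `tumor_summary` tibble.
#' @param stat One of `"mean"`, `"median"`, `"iqr"`.
#' @return Scalar patient-level value.
#' @export
patient_value <- function(summary, stat = c("mean", "median", "iqr")) {
  stat <- match.arg(stat)
  mean(summary[[stat]])
}
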