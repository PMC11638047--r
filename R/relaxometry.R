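#' Correct per-angle intensity scaling of a VFA series
#'
#' Some platforms apply different image-intensity scaling factors to the
#' volumes acquired at different flip angles; fitting the SPGR equation
#' across angles then requires dividing each angle's signals by its factor
#' first. Unit factors leave the data unchanged.
#'
#' @param vfa Tibble with columns `voxel`, `angle` (nominal degrees) and
#'   `signal`, one row per voxel-angle.
#' @param scale_factors Per-angle factors: either a numeric vector named by
#'   angle, or unnamed in the order of `sort(unique(vfa$angle))`. If `NULL`,
#'   a `scale` column in `vfa` is used.
#' @return The VFA tibble with corrected `signal` (and any `scale` column
#'   dropped).
#' @export
apply_scale_correction <- function(vfa, scale_factors = NULL) {
  if (is.null(scale_factors)) {
    if (!"scale" %in% names(vfa)) {
      stop("no scale_factors supplied and no scale column present", call. = FALSE)
    }
    sc <- vfa$scale
  } else {
    angles <- sort(unique(vfa$angle))
    if (is.null(names(scale_factors))) {
      if (length(scale_factors) != length(angles)) {
        stop("scale_factors length must match number of flip angles", call. = FALSE)
      }
      names(scale_factors) <- as.character(angles)
    }
    sc <- scale_factors[as.character(vfa$angle)]
  }
  if (any(!is.finite(sc) | sc <= 0)) {
    stop("scale factors must be positive and finite", call. = FALSE)
  }
  vfa$signal <- vfa$signal / as.numeric(sc)
  vfa$scale <- NULL
  vfa
}

# Linearized SPGR (DESPOT) estimate for one voxel: regress S/sin(a) on
# S/tan(a); slope = E = exp(-TR R1), intercept = S0 (1 - E).
despot_init <- function(signal, alpha_deg, tr) {
  a <- alpha_deg * pi / 180
  y <- signal / sin(a)
  x <- signal / tan(a)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx <= 0) return(c(r1 = NA_real_, s0 = NA_real_))
  slope <- sum((x - mx) * (y - my)) / sxx
  e <- min(max(slope, 1e-8), 1 - 1e-8)
  r1 <- -log(e) / tr
  s0 <- (my - slope * mx) / (1 - e)
  c(r1 = r1, s0 = s0)
}

#' Fit a B1-corrected R1 map from variable flip angle data
#'
#' Voxel-by-voxel nonlinear least squares of the SPGR equation
#' ([spgr_signal()]) over \eqn{(R_1, S_0)}, with the nominal flip angle
#' replaced by `ratio x nominal` from the B1 map. The standard SPGR
#' linearization (S/sin a vs S/tan a) seeds the nonlinear refinement.
#' Applied to pre-contrast data this yields the native R1,0 map. Voxels
#' that fail (all-zero signal, degenerate linearization, non-convergence,
#' or R1 at the (0, 20] s^-1 bound) are flagged `valid = FALSE`, never
#' dropped silently.
#'
#' @param vfa Tibble `voxel`, `angle`, `signal` (scale-corrected; see
#'   [apply_scale_correction()]).
#' @param protocol An [acq_protocol()]; supplies `tr_vfa`.
#' @param b1 B1 ratio map: scalar, or tibble with columns `voxel`, `ratio`
#'   (actual/nominal flip angle; 1 means perfect calibration). Missing
#'   voxels default to 1.
#' @param refine If `FALSE`, return the linearized estimate without
#'   nonlinear refinement (used for diagnostics).
#' @return An `r1_map` tibble: `voxel`, `r1` (s^-1), `s0`, `residual`
#'   (RMS), `valid`.
#' @export
fit_vfa_r1 <- function(vfa, protocol, b1 = 1, refine = TRUE) {
  tr <- protocol$tr_vfa
  ratio_for <- function(v) {
    if (is.numeric(b1) && length(b1) == 1) return(rep(b1, length(v)))
    r <- b1$ratio[match(v, b1$voxel)]
    r[is.na(r)] <- 1
    r
  }
  if (any(ratio_for(unique(vfa$voxel)) <= 0)) {
    stop("B1 ratio must be positive", call. = FALSE)
  }

  fit_one <- function(d, key) {
    sig <- d$signal
    alpha <- d$angle * ratio_for(rep(key$voxel, nrow(d)))
    bad <- function() tibble::tibble(voxel = key$voxel, r1 = NA_real_,
                                     s0 = NA_real_, residual = NA_real_,
                                     valid = FALSE)
    if (length(unique(alpha)) < 2 || all(sig == 0) || any(!is.finite(sig))) {
      return(bad())
    }
    init <- despot_init(sig, alpha, tr)
    if (!is.finite(init["r1"]) || !is.finite(init["s0"])) return(bad())
    start <- c(r1 = min(max(init[["r1"]], 1e-3), 20),
               s0 = max(init[["s0"]], 1e-6))
    if (!refine) {
      fitted <- spgr_signal(start[["s0"]], start[["r1"]], alpha, tr)
      return(tibble::tibble(voxel = key$voxel, r1 = start[["r1"]],
                            s0 = start[["s0"]],
                            residual = sqrt(mean((sig - fitted)^2)),
                            valid = start[["r1"]] > 0 && start[["r1"]] < 20))
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = start, lower = c(r1 = 1e-9, s0 = 0),
        upper = c(r1 = 20, s0 = Inf),
        fn = function(p) sig - spgr_signal(p[["s0"]], p[["r1"]], alpha, tr),
        control = minpack.lm::nls.lm.control(maxiter = 200,
                                             ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) return(bad())
    r1 <- fit$par[["r1"]]; s0 <- fit$par[["s0"]]
    valid <- fit$info %in% 1:4 && r1 > 1e-6 && r1 < 20 - 1e-6 &&
      is.finite(r1) && is.finite(s0)
    tibble::tibble(voxel = key$voxel, r1 = r1, s0 = s0,
                   residual = sqrt(mean(fit$fvec^2)), valid = valid)
  }

  out <- vfa |>
    dplyr::arrange(.data$voxel, .data$angle) |>
    dplyr::group_by(.data$voxel) |>
    dplyr::group_map(fit_one) |>
    dplyr::bind_rows()
  class(out) <- c("r1_map", class(out))
  out
}

#' Quality-control check of a measured R1,0 map
#'
#' Flags a tumor R1,0 map as unusable when its median valid-voxel value
#' falls outside a plausibility range for breast tissue at 3T. Platform
#' miscalibrations that inflate VFA R1 estimates by ~100% or more are
#' caught here; affected patients should then be analyzed with the fixed
#' literature R1,0 only.
#'
#' @param r1_map An `r1_map` tibble from [fit_vfa_r1()].
#' @param range Acceptable range (s^-1) for the median R1,0.
#' @return List with `ok` (logical), `median_r1`, `n_valid`.
#' @export
qc_r1_map <- function(r1_map, range = c(0.2, 1.2)) {
  vals <- r1_map$r1[r1_map$valid]
  med <- if (length(vals)) stats::median(vals) else NA_real_
  list(ok = isTRUE(is.finite(med) && med >= range[1] && med <= range[2]),
       median_r1 = med, n_valid = length(vals))
}
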