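#' Spoiled gradient-echo (SPGR) steady-state signal
#'
#' Evaluates the SPGR signal equation
#' \deqn{S(\alpha) = S_0 \, (1 - E) \sin\alpha \, / \, (1 - E\cos\alpha),
#'       \quad E = e^{-TR \cdot R_1},}
#' the forward model shared by VFA R1 mapping (where \eqn{\alpha} is the
#' B1-corrected flip angle and \eqn{R_1, S_0} are the fit parameters) and
#' by the dynamic readout (where \eqn{R_1(t)} varies with contrast-agent
#' concentration).
#'
#' Arguments recycle in the usual way, so `r1` may be a vector (a time
#' course or a map) against a scalar angle, or vice versa.
#'
#' @param s0 Equilibrium signal scale (arbitrary units).
#' @param r1 Longitudinal relaxation rate (s^-1); `r1 = 0` gives zero signal.
#' @param alpha Flip angle in degrees, strictly between 0 and 90.
#' @param tr Repetition time (s).
#' @return Signal in the units of `s0`.
#' @examples
#' spgr_signal(1000, r1 = 0.6, alpha = 9, tr = 0.0056)
#' @export
spgr_signal <- function(s0, r1, alpha, tr) {
  if (any(tr <= 0)) stop("tr must be positive", call. = FALSE)
  if (any(alpha <= 0 | alpha >= 90)) {
    stop("alpha must lie strictly between 0 and 90 degrees", call. = FALSE)
  }
  a <- alpha * pi / 180
  e <- exp(-tr * r1)
  s0 * (1 - e) * sin(a) / (1 - cos(a) * e)
}

# Invert the SPGR equation for E = exp(-TR R1) given S/S0 at angle alpha.
# Returns R1 (s^-1); values are clipped into (0, Inf) guard range by caller.
spgr_invert_r1 <- function(signal, s0, alpha, tr) {
  a <- alpha * pi / 180
  e <- (s0 * sin(a) - signal) / (s0 * sin(a) - signal * cos(a))
  e <- pmin(pmax(e, 1e-12), 1 - 1e-12)
  -log(e) / tr
}

#' Map a time-resolved R1 to a dynamic SPGR signal
#'
#' Applies [spgr_signal()] framewise at the DCE flip angle and TR. When a
#' `baseline` level and the pre-contrast `r10` are supplied instead of `s0`,
#' the equilibrium scale is calibrated so that the modeled pre-injection
#' signal equals `baseline` exactly.
#'
#' @param r1_t Numeric vector, R1 per frame (s^-1).
#' @param protocol An [acq_protocol()].
#' @param s0 Equilibrium signal scale. Exactly one of `s0` and `baseline`
#'   must be given.
#' @param baseline Measured pre-injection signal level used to calibrate
#'   `s0` through `r10`.
#' @param r10 Pre-contrast R1 (s^-1); required with `baseline`.
#' @return Signal per frame.
#' @export
signal_from_r1 <- function(r1_t, protocol, s0 = NULL, baseline = NULL, r10 = NULL) {
  if (is.null(s0) == is.null(baseline)) {
    stop("supply exactly one of s0 or baseline", call. = FALSE)
  }
  if (!is.null(baseline)) {
    if (is.null(r10)) stop("r10 is required when calibrating from baseline", call. = FALSE)
    unit <- spgr_signal(1, r10, protocol$fa_dce, protocol$tr_dce)
    s0 <- baseline / unit
  }
  spgr_signal(s0, r1_t, protocol$fa_dce, protocol$tr_dce)
}

#' Convert a measured DCE signal to contrast-agent concentration
#'
#' Inverts the SPGR equation frame by frame under the fast-exchange-limit
#' (linear) relation \eqn{R_1(t) = R_{1,0} + r_1 C_t(t)}. The equilibrium
#' scale is calibrated from the pre-injection frames and the supplied
#' `r10`, mirroring a fixed-R1,0-first workflow.
#'
#' @param signal Numeric vector of frame signals.
#' @param protocol An [acq_protocol()].
#' @param r10 Pre-contrast R1 (s^-1).
#' @return Tissue concentration per frame (mM); pre-injection frames are
#'   near zero up to noise.
#' @export
signal_to_concentration <- function(signal, protocol, r10) {
  base_idx <- seq_len(protocol$injection_frame - 1L)
  baseline <- mean(signal[base_idx])
  if (!is.finite(baseline) || baseline <= 0) {
    stop("non-positive baseline signal; cannot convert to concentration", call. = FALSE)
  }
  unit <- spgr_signal(1, r10, protocol$fa_dce, protocol$tr_dce)
  s0 <- baseline / unit
  r1_t <- spgr_invert_r1(signal, s0, protocol$fa_dce, protocol$tr_dce)
  (r1_t - r10) / protocol$relaxivity_r1
}
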