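# Deterministic seed derivation for nested simulation stages. Keeps all
# derived seeds inside 32-bit signed range.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  mix <- (as.numeric(seed) + sum(as.numeric(idx) * c(1000003, 7919, 104729,
                                                     293, 17)[seq_along(idx)]))
  as.integer(mix %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Default longitudinal group-effect table
#'
#' Median percent changes (relative to the pre-treatment visit V1) and
#' their patient-to-patient dispersion for each ground-truth parameter,
#' per response group and visit. The V2/V3 K^trans entries and the V2 v_e
#' entries follow published cohort medians for pCR vs non-pCR breast
#' tumors under NAC (pCR: large K^trans drops, e.g. -71% at V2 and -91% at
#' V3; non-pCR: small/heterogeneous changes), with dispersion set to half
#' the printed interquartile widths. Entries not available from published
#' tables (v_e at V3/V4, all k_io effects, V4) are stated modeling
#' assumptions that preserve the qualitative structure: k_io and K^trans
#' decline more in responders, v_e rises modestly in responders.
#'
#' @return Tibble with columns `group`, `visit`, `metric`, `effect`
#'   (median percent change), `sd` (between-patient SD of the percent
#'   change).
#' @export
default_effect_table <- function() {
  tibble::tribble(
    ~group,     ~visit, ~metric,  ~effect, ~sd,
    "pCR",      "V2",   "ktrans", -71,     6.5,
    "pCR",      "V2",   "ve",       8,     2.5,
    "pCR",      "V2",   "kio",    -20,    10,
    "pCR",      "V3",   "ktrans", -91,     4.5,
    "pCR",      "V3",   "ve",      10,     5,
    "pCR",      "V3",   "kio",    -40,    20,
    "pCR",      "V4",   "ktrans", -95,     3,
    "pCR",      "V4",   "ve",      12,     6,
    "pCR",      "V4",   "kio",    -60,    20,
    "non-pCR",  "V2",   "ktrans",   1,    55,
    "non-pCR",  "V2",   "ve",       0,     5.5,
    "non-pCR",  "V2",   "kio",     -5,    10,
    "non-pCR",  "V3",   "ktrans", -27,    25,
    "non-pCR",  "V3",   "ve",       0,     8,
    "non-pCR",  "V3",   "kio",    -10,    15,
    "non-pCR",  "V4",   "ktrans", -50,    20,
    "non-pCR",  "V4",   "ve",       0,     8,
    "non-pCR",  "V4",   "kio",    -20,    15
  )
}

#' Design of a synthetic DCE-MRI cohort
#'
#' Describes a digital-reference-object patient cohort: group sizes, visit
#' schedule, baseline parameter medians, intratumor heterogeneity,
#' longitudinal group effects, noise level and master seed. Defaults match
#' a 15-patient NAC cohort (6 pCR, 9 non-pCR) imaged at V1-V3.
#'
#' @param n_pcr,n_nonpcr Patients per response group.
#' @param visits Subset of `c("V1","V2","V3","V4")`.
#' @param medians Named baseline (V1) medians: `ktrans` (min^-1), `ve`,
#'   `kio` (s^-1), `r10` (s^-1). Defaults 0.25 / 0.4 / 2 / 0.6 are typical
#'   malignant breast tumor values at 3T.
#' @param effect_table See [default_effect_table()]; percent changes must
#'   exceed -100.
#' @param heterogeneity Coefficient of variation of the lognormal voxel
#'   distribution within a tumor (default 0.5, giving non-degenerate
#'   histogram widths).
#' @param voxel_jitter CV of the voxel-level multiplicative jitter applied
#'   on top of the patient-level visit effect.
#' @param voxels_per_tumor Approximate ROI size in voxels (ellipsoidal
#'   multi-slice ROI).
#' @param noise_sigma Rician noise SD relative to the baseline signal
#'   (0.02 = SNR 50).
#' @param baseline_signal Pre-injection signal level (arbitrary units).
#' @param miscalibrated_patients Patient indices simulated on a platform
#'   whose B1 map misreports the applied field (see
#'   [simulate_vfa_and_b1()]).
#' @param seed Master seed; a fixed seed makes the whole cohort
#'   byte-reproducible.
#' @return A `cohort_design` object.
#' @export
cohort_design <- function(n_pcr = 6, n_nonpcr = 9,
                          visits = c("V1", "V2", "V3"),
                          medians = c(ktrans = 0.25, ve = 0.4,
                                      kio = 2, r10 = 0.6),
                          effect_table = default_effect_table(),
                          heterogeneity = 0.5,
                          voxel_jitter = 0.1,
                          voxels_per_tumor = 500,
                          noise_sigma = 0.02,
                          baseline_signal = 1000,
                          miscalibrated_patients = integer(0),
                          seed = 42L) {
  stopifnot(n_pcr >= 0, n_nonpcr >= 0, n_pcr + n_nonpcr >= 1)
  if (!all(visits %in% c("V1", "V2", "V3", "V4"))) {
    stop("visits must be a subset of V1-V4", call. = FALSE)
  }
  need <- c("ktrans", "ve", "kio", "r10")
  if (!all(need %in% names(medians))) {
    stop("medians must name ktrans, ve, kio, r10", call. = FALSE)
  }
  if (any(medians[need] <= 0) || medians[["ve"]] > 1) {
    stop("medians must be positive (ve in (0,1])", call. = FALSE)
  }
  if (any(effect_table$effect <= -100)) {
    stop("effect_table percent changes must exceed -100", call. = FALSE)
  }
  if (noise_sigma < 0) stop("noise_sigma must be non-negative", call. = FALSE)
  structure(list(
    n_pcr = as.integer(n_pcr), n_nonpcr = as.integer(n_nonpcr),
    visits = visits, medians = medians, effect_table = effect_table,
    heterogeneity = heterogeneity, voxel_jitter = voxel_jitter,
    voxels_per_tumor = as.integer(voxels_per_tumor),
    noise_sigma = noise_sigma, baseline_signal = baseline_signal,
    miscalibrated_patients = as.integer(miscalibrated_patients),
    seed = as.integer(seed)
  ), class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf("<cohort_design> %d pCR + %d non-pCR, visits %s, ~%d voxels/tumor, seed %d\n",
              x$n_pcr, x$n_nonpcr, paste(x$visits, collapse = "/"),
              x$voxels_per_tumor, x$seed))
  invisible(x)
}

patient_group <- function(design, patient_index) {
  if (patient_index < 1 || patient_index > design$n_pcr + design$n_nonpcr) {
    stop("patient_index outside the cohort", call. = FALSE)
  }
  if (patient_index <= design$n_pcr) "pCR" else "non-pCR"
}

# Ellipsoidal multi-slice ROI: integer voxel coordinates inside an
# ellipsoid sized to hold approximately n voxels (axis ratios 1.2:1:0.7,
# the short axis mimicking thicker slices).
ellipsoid_roi <- function(n) {
  ratios <- c(1.2, 1, 0.7)
  r <- (3 * n / (4 * pi * prod(ratios)))^(1 / 3)
  semi <- pmax(ratios * r, 1)
  ext <- ceiling(semi)
  g <- expand.grid(i = -ext[1]:ext[1], j = -ext[2]:ext[2], k = -ext[3]:ext[3])
  keep <- (g$i / semi[1])^2 + (g$j / semi[2])^2 + (g$k / semi[3])^2 <= 1
  g <- g[keep, , drop = FALSE]
  off <- ext + 2L  # 1-based voxel indices with a 1-voxel margin
  tibble::tibble(i = g$i + off[1], j = g$j + off[2], k = g$k + off[3])
}

#' Generate ground-truth parameter maps for one patient visit
#'
#' Baseline (V1) voxel values of K^trans, v_e, k_io and R1,0 are drawn from
#' lognormal distributions around the design medians with the design's
#' coefficient of variation, on an ellipsoidal multi-slice ROI. Later
#' visits rescale the same patient's V1 voxel values by
#' `1 + effect/100`, where the patient-level effect is drawn around the
#' group's effect-table median with the tabulated SD (truncated above
#' -99%), times voxel-level lognormal jitter. R1,0 is longitudinally
#' stable. Everything is deterministic given the design seed: V1 maps
#' regenerate identically whichever visit is requested.
#'
#' @param design A [cohort_design()].
#' @param patient_index 1-based patient index; patients `1:n_pcr` are the
#'   pCR group.
#' @param visit One of the design's visits.
#' @return A `truth_maps` tibble: `voxel`, `i`, `j`, `k`, `ktrans`, `ve`,
#'   `kio`, `r10`, `lesion`, with attributes `group`, `patient`, `visit`,
#'   `dim` (bounding grid).
#' @export
generate_truth_maps <- function(design, patient_index, visit) {
  if (!visit %in% design$visits) {
    stop(sprintf("unknown visit '%s' for this design", visit), call. = FALSE)
  }
  group <- patient_group(design, patient_index)
  cv <- design$heterogeneity
  sdlog <- sqrt(log(1 + cv^2))

  roi <- ellipsoid_roi(design$voxels_per_tumor)
  n <- nrow(roi)

  v1 <- with_seed(derive_seed(design$seed, patient_index, 0), {
    list(
      ktrans = stats::rlnorm(n, log(design$medians[["ktrans"]]), sdlog),
      ve = pmin(stats::rlnorm(n, log(design$medians[["ve"]]), sdlog), 0.99),
      kio = stats::rlnorm(n, log(design$medians[["kio"]]), sdlog),
      r10 = stats::rlnorm(n, log(design$medians[["r10"]]), sdlog)
    )
  })

  vals <- v1
  if (visit != "V1") {
    vnum <- match(visit, c("V1", "V2", "V3", "V4"))
    jit_sdlog <- sqrt(log(1 + design$voxel_jitter^2))
    vals <- with_seed(derive_seed(design$seed, patient_index, vnum), {
      out <- v1
      for (metric in c("ktrans", "ve", "kio")) {
        row <- design$effect_table[design$effect_table$group == group &
                                     design$effect_table$visit == visit &
                                     design$effect_table$metric == metric, ]
        eff <- if (nrow(row) == 0) 0 else {
          max(stats::rnorm(1, row$effect[1], row$sd[1]), -99)
        }
        jitter <- stats::rlnorm(n, 0, jit_sdlog)
        out[[metric]] <- v1[[metric]] * (1 + eff / 100) * jitter
      }
      out
    })
    vals$ve <- pmin(vals$ve, 0.99)
  }

  out <- tibble::tibble(
    voxel = seq_len(n), i = roi$i, j = roi$j, k = roi$k,
    ktrans = vals$ktrans, ve = vals$ve, kio = vals$kio, r10 = vals$r10,
    lesion = 1L
  )
  attr(out, "group") <- group
  attr(out, "patient") <- as.integer(patient_index)
  attr(out, "visit") <- visit
  attr(out, "grid_dim") <- c(max(roi$i) + 1L, max(roi$j) + 1L, max(roi$k) + 1L)
  class(out) <- c("truth_maps", class(out))
  out
}

#' Add Rician noise to magnitude signals
#'
#' Magnitude-MRI noise: each noiseless signal A is replaced by
#' \eqn{\sqrt{(A + x)^2 + y^2}} with independent Gaussian x, y of SD
#' `sigma`. At SNR of about 3 and above this is within ~1% of the
#' Gaussian approximation in mean signal.
#'
#' @param signal Noiseless magnitudes.
#' @param sigma Noise SD (same units as `signal`).
#' @return Noisy magnitudes.
#' @export
add_rician_noise <- function(signal, sigma) {
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  if (sigma == 0) return(signal)
  n <- length(signal)
  sqrt((signal + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}

#' Simulate a dynamic contrast-enhanced series from ground truth
#'
#' Forward composition of the quantitative models: per voxel, the tissue
#' concentration follows the Kety convolution of the population AIF with
#' the voxel's (K^trans, v_e); R1(t) follows the FXR water-exchange
#' expression with the voxel's k_io (so the generated data are
#' exchange-sensitized, and Tofts-model fits are biased low by
#' construction); the SPGR readout converts R1(t) to signal, calibrated so
#' pre-injection frames sit exactly at the design baseline level; Rician
#' noise corrupts the magnitudes. Injection occurs at the start of the
#' protocol's injection frame, so earlier frames carry baseline signal
#' only.
#'
#' @param truth A `truth_maps` tibble from [generate_truth_maps()].
#' @param protocol An [acq_protocol()].
#' @param aif Optional [aif_curve()]; default is [population_aif()] on a
#'   1 s grid with bolus arrival at the injection time.
#' @param noise_sigma Noise SD relative to the baseline signal; `NULL`
#'   uses 0 (noiseless).
#' @param noise `"rician"`, `"gaussian"` (analytic tests) or `"none"`.
#' @param baseline_signal Pre-injection signal level.
#' @param seed Seed for the noise draw.
#' @return Long tibble `voxel`, `frame`, `time`, `signal` with the input
#'   attributes carried over and the `aif` attached.
#' @export
simulate_dce_series <- function(truth, protocol, aif = NULL,
                                noise_sigma = 0.02,
                                noise = c("rician", "gaussian", "none"),
                                baseline_signal = 1000, seed = 1L) {
  noise <- match.arg(noise)
  if (is.null(noise_sigma)) noise_sigma <- 0
  if (noise_sigma < 0) stop("noise_sigma must be non-negative", call. = FALSE)
  tt <- frame_times(protocol)
  if (is.null(aif)) {
    grid <- seq(0, max(tt), by = 1)
    aif <- population_aif(grid, bat_shift = injection_time(protocol))
  }
  if (max(aif$times) < max(tt)) {
    stop("AIF support must cover the DCE frame times", call. = FALSE)
  }

  n <- nrow(truth)
  sig <- matrix(0, nrow = n, ncol = length(tt))
  unit1 <- spgr_signal(1, truth$r10, protocol$fa_dce, protocol$tr_dce)
  s0 <- baseline_signal / unit1
  for (v in seq_len(n)) {
    ct <- kety_concentration(truth$ktrans[v], truth$ve[v], aif, times = tt)
    r1_t <- fxr_r1(ct, truth$ve[v], truth$kio[v],
                   r1i = truth$r10[v], r1o0 = truth$r10[v],
                   relaxivity = protocol$relaxivity_r1)
    sig[v, ] <- spgr_signal(s0[v], r1_t, protocol$fa_dce, protocol$tr_dce)
  }

  if (noise != "none" && noise_sigma > 0) {
    sigma <- noise_sigma * baseline_signal
    sig <- with_seed(seed, {
      if (noise == "rician") {
        matrix(add_rician_noise(as.numeric(sig), sigma), nrow = n)
      } else {
        sig + matrix(stats::rnorm(length(sig), 0, sigma), nrow = n)
      }
    })
  }

  out <- tibble::tibble(
    voxel = rep(truth$voxel, each = length(tt)),
    frame = rep(seq_along(tt), times = n),
    time = rep(tt, times = n),
    signal = as.numeric(t(sig))
  )
  for (a in c("group", "patient", "visit", "grid_dim")) {
    attr(out, a) <- attr(truth, a)
  }
  attr(out, "aif") <- aif
  attr(out, "baseline_signal") <- baseline_signal
  class(out) <- c("dce_series", class(out))
  out
}

#' Simulate a variable-flip-angle series and its B1 ratio map
#'
#' Generates SPGR signals at the protocol's VFA angles from the truth R1,0
#' map, with the *actual* flip angle equal to `b1_field` times nominal.
#' In `bias_mode = "none"` the emitted B1 ratio map reports the applied
#' field truthfully, so B1-corrected fitting recovers R1,0 exactly. In
#' `bias_mode = "miscalibrated"` the map reports 1.0 regardless of the
#' field actually applied — reproducing a platform failure in which VFA
#' R1,0 comes out biased (in the small-angle regime the uncorrected fit
#' returns roughly `R1 / b1_field^2`, so an applied field below 1 yields
#' overestimation) and downstream fitting with the measured map is
#' compromised.
#'
#' @param truth A `truth_maps` tibble.
#' @param protocol An [acq_protocol()].
#' @param b1_field Applied transmit-field scaling: scalar or per-voxel
#'   numeric vector (must be positive).
#' @param bias_mode `"none"` or `"miscalibrated"`.
#' @param scale_factors Optional per-angle intensity scale factors applied
#'   to the emitted signals (vendor scaling emulation); recorded in a
#'   `scale` column.
#' @param noise_sd Gaussian noise SD in signal units (0 for noiseless).
#' @param s0_scale Equilibrium signal scale. For consistency with a DCE
#'   scan sharing the receiver gain, use `baseline_signal` divided by the
#'   unit SPGR signal at the DCE settings (as [simulate_patient()] does),
#'   which puts the VFA signals near the DCE baseline level.
#' @param seed Seed for the noise draw.
#' @return List with `vfa` (tibble `voxel`, `angle`, `signal`[, `scale`])
#'   and `b1` (tibble `voxel`, `ratio`).
#' @export
simulate_vfa_and_b1 <- function(truth, protocol, b1_field = 1,
                                bias_mode = c("none", "miscalibrated"),
                                scale_factors = NULL,
                                noise_sd = 0, s0_scale = 1000, seed = 1L) {
  bias_mode <- match.arg(bias_mode)
  if (any(b1_field <= 0)) stop("b1_field must be positive", call. = FALSE)
  if (any(b1_field * protocol$vfa_angles <= 0) ||
      any(b1_field * max(protocol$vfa_angles) >= 90)) {
    stop("applied flip angles must stay in (0, 90) degrees", call. = FALSE)
  }
  n <- nrow(truth)
  field <- rep(b1_field, length.out = n)
  vfa <- tidyr::expand_grid(voxel = truth$voxel, angle = protocol$vfa_angles)
  idx <- match(vfa$voxel, truth$voxel)
  vfa$signal <- spgr_signal(s0_scale, truth$r10[idx],
                            vfa$angle * field[idx], protocol$tr_vfa)
  if (noise_sd > 0) {
    vfa$signal <- with_seed(seed, {
      vfa$signal + stats::rnorm(nrow(vfa), 0, noise_sd)
    })
  }
  if (!is.null(scale_factors)) {
    angles <- sort(unique(vfa$angle))
    if (is.null(names(scale_factors))) names(scale_factors) <- as.character(angles)
    vfa$scale <- as.numeric(scale_factors[as.character(vfa$angle)])
    vfa$signal <- vfa$signal * vfa$scale
  }
  ratio <- if (bias_mode == "miscalibrated") rep(1, n) else field
  list(vfa = vfa, b1 = tibble::tibble(voxel = truth$voxel, ratio = ratio))
}

#' Simulate one complete patient visit
#'
#' Bundles ground truth, DCE series, VFA series and B1 map for one patient
#' at one visit, with all randomness derived from the design seed.
#' Patients listed in the design's `miscalibrated_patients` are simulated
#' with an applied B1 field of 0.6 whose ratio map misreports 1.0,
#' emulating a vendor platform whose VFA R1,0 is overestimated by >= 100%.
#'
#' @param design A [cohort_design()].
#' @param patient_index Patient index.
#' @param visit Visit id.
#' @param protocol An [acq_protocol()].
#' @return A `dro_patient` list: `truth`, `dce`, `vfa`, `b1`, `manifest`.
#' @export
simulate_patient <- function(design, patient_index, visit,
                             protocol = acq_protocol()) {
  truth <- generate_truth_maps(design, patient_index, visit)
  vnum <- match(visit, c("V1", "V2", "V3", "V4"))
  dce <- simulate_dce_series(
    truth, protocol, noise_sigma = design$noise_sigma,
    baseline_signal = design$baseline_signal,
    seed = derive_seed(design$seed, patient_index, vnum, 1))
  miscal <- patient_index %in% design$miscalibrated_patients
  s0_scale <- design$baseline_signal /
    spgr_signal(1, design$medians[["r10"]], protocol$fa_dce, protocol$tr_dce)
  vb <- simulate_vfa_and_b1(
    truth, protocol,
    b1_field = if (miscal) 0.6 else 1,
    bias_mode = if (miscal) "miscalibrated" else "none",
    noise_sd = design$noise_sigma * design$baseline_signal,
    s0_scale = s0_scale,
    seed = derive_seed(design$seed, patient_index, vnum, 2))
  manifest <- list(
    patient = as.integer(patient_index),
    group = patient_group(design, patient_index),
    visit = visit, seed = design$seed,
    miscalibrated_b1 = miscal,
    protocol = unclass(protocol)
  )
  structure(list(truth = truth, dce = dce, vfa = vb$vfa, b1 = vb$b1,
                 manifest = manifest), class = "dro_patient")
}
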