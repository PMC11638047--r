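---
title: "Models and methods in dcequant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in dcequant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcequant)
```

dcequant implements quantitative pharmacokinetic (PK) analysis of dynamic
contrast-enhanced (DCE) MRI for longitudinal therapy-response monitoring.
This vignette explains the models, the assumptions behind them, the
parameters that matter and their defaults, what the synthetic cohort
generator does and does not emulate, and the numerical and design choices
made where more than one reasonable option existed.

## The forward model chain

A DCE experiment observes a voxel's SPGR signal over time while a
gadolinium contrast agent (CA) passes through the tissue. dcequant
composes four stages, each exposed as its own function so every link can
be validated independently:

1. **Arterial input.** `population_aif()` provides the plasma
   concentration $C_p(t)$ as the standard parametric population form: two
   Gaussian bolus passes plus a sigmoid-damped exponential washout.
   A per-patient measured AIF is out of scope; the population curve is
   the common choice when dynamic imaging does not capture a reliable
   artery, and any AIF sampled as (times, concentrations) can be
   substituted through `aif_curve()`. Because the reference population
   AIF's samples are not published, the parametric stand-in is a declared
   substitute; its absolute scale cancels in longitudinal percent
   changes, which are the response metrics.

2. **Tissue kinetics.** `kety_concentration()` evaluates the Kety/Tofts
   convolution $C_t(t) = K^{trans}\int_0^t C_p(\tau)
   e^{-k_{ep}(t-\tau)}d\tau$ with $k_{ep} = K^{trans}/v_e$. The AIF is
   treated as piecewise linear and each segment integrated in closed
   form, so there is no quadrature error beyond the AIF sampling itself;
   on uniform grids the segment recursion runs through compiled code
   (`stats::filter`). The boxcar-input closed form
   $v_e(1-e^{-k_{ep}t})$ is reproduced to machine precision (see
   `tests/testthat/test-kety.R`).

3. **Relaxation.** Two water-exchange regimes are implemented.
   The fast-exchange limit (FXL) underlying the Tofts model (TM) takes
   $R_1(t) = R_{1,0} + r_1 C_t(t)$. The fast-exchange-regime (FXR)
   expression of the shutter-speed model (SSM) instead uses the smaller
   eigenvalue of the two-site (intracellular/extracellular) exchange
   matrix, which depends on the cellular water efflux rate constant
   $k_{io}$ and slows apparent enhancement when exchange is finite.
   Water population fractions are taken as $p_o = v_e$, $p_i = 1 - v_e$
   (water-density corrections omitted — a deliberate simplification, and
   the reason $k_{oi} = k_{io}(1-v_e)/v_e$), and both compartments share
   the pre-contrast rate: $R_{1i} = R_{1o,0} = R_{1,0}$. That equality is
   required for a single fixed $R_{1,0}$ to define the pre-contrast state
   at all; it is also why the FXR curve degenerates exactly to $R_{1,0}$
   without CA.

4. **Readout.** `spgr_signal()` is the spoiled gradient-echo steady
   state. The equilibrium scale $S_0$ is never fitted in dynamic
   analysis: it is calibrated so the modeled pre-injection frames equal
   the measured baseline mean exactly, which removes one degree of
   freedom and makes all fits invariant to receiver gain.

## Fitting

`fit_tm()` fits $(K^{trans}, v_e)$ and `fit_ssm()` additionally
$k_{io}$, by bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`, `ftol = ptol = 1e-12`, 200 iterations) on the
composed forward model. Bounds are $K^{trans} \in [0, 5]$ min⁻¹,
$v_e \in (10^{-3}, 1]$, $k_{io} \in (10^{-3}, 1000]$ s⁻¹. The wide
$k_{io}$ ceiling is intentional: it keeps informative fits away from a
premature boundary stop, while exchange-insensitive voxels (low CA
extravasation) park $k_{io}$ at a boundary, which is exactly the
behaviour the downstream filter looks for.

SSM fitting uses a fixed three-point multi-start
$(0.2, 0.4, 1000)$, $(0.1, 0.3, 3)$, $(0.5, 0.6, 0.3)$ to mitigate the
known $K^{trans}$–$k_{io}$ ridge; the start list is fixed so results are
deterministic, ties resolve to the first start, and the first start sits
at the FXL-limit boundary so that curves carrying no exchange
information deterministically surface as `at_bound = TRUE`. `kep` is
always derived as `ktrans/ve`, never fitted separately, so the identity
holds exactly in every result row.

**ROI vs voxel.** `fit_dce(mode = "roi")` concatenates the multi-slice
tumor ROI and fits its frame-wise mean curve once (high SNR, one fit);
`mode = "voxel"` fits every voxel (heterogeneity preserved). On
homogeneous tumors the two agree exactly, which is tested. On the
default heterogeneous cohort the TM voxel-mean $K^{trans}$ exceeds the
ROI estimate by ~30% — averaging curves dilutes high-transfer voxels —
while for the SSM the two modes agree to within about 1% with
seed-dependent sign: the extra $k_{io}$ freedom lets the averaged-curve
fit track the mean enhancement without lowering $K^{trans}$. The strict
voxel > ROI ordering is therefore asserted only for the TM; treating
the SSM ordering as an open empirical question on real data is the
honest position for this generator.

**Fixed vs measured R1,0.** The pre-contrast rate enters both the
baseline calibration and the concentration conversion. `fit_dce` accepts
either the fixed literature value $fR_{1,0} = 0.60$ s⁻¹ (breast tumor at
3T) or a measured per-voxel map from `fit_vfa_r1()`. Absolute PK values
shift with this choice, but visit percent changes are scale-free, which
is why a fixed value is viable for longitudinal prediction.

**Bolus arrival time.** `estimate_bat()` scores candidate AIF delays by
the residual of the linearized Tofts system
$C_t(t_i) = K^{trans}\int_0^{t_i}C_p - k_{ep}\int_0^{t_i}C_t$ solved by
linear least squares on concentration-converted data (SPGR inversion at
the fixed $R_{1,0}$ — matching a fixed-R1,0-first workflow). The search
is a coarse grid from −2 to +6 frame intervals in quarter-frame steps
(covering physiologic transit delays at 12–16 s frame rates) followed by
a derivative-free refinement confined to one coarse step; the two-phase
scheme avoids the local minima of the one-parameter problem. The
$\int C_p$ term is evaluated on the fine AIF grid and interpolated —
sampling $C_p$ at the frame rate would alias the bolus peak.

## VFA relaxometry and B1

`fit_vfa_r1()` maps native $R_{1,0}$ from variable-flip-angle SPGR
volumes (default angles 3°/9°/15°, chosen to bracket the Ernst angle of
a ~0.6 s⁻¹ tissue). Each voxel's nominal angles are first multiplied by
the B1 ratio map (actual/prescribed flip angle; 1.0 = perfect
calibration), then $(R_1, S_0)$ are fitted with the standard SPGR
linearization ($S/\sin\alpha$ on $S/\tan\alpha$) seeding a bounded
nonlinear refinement ($R_1 \in (0, 20]$ s⁻¹). Per-angle vendor intensity
scale factors are divided out first (`apply_scale_correction()`).
Failures are flagged `valid = FALSE`, never dropped silently.

If the true transmit field deviates from what the B1 map reports, the
fitted $R_1$ is biased by approximately the inverse square of the field
factor (exact values verified against a brute-force grid search in the
tests): a platform applying only 60% of the nominal angle while its map
claims calibration overestimates $R_{1,0}$ by ~180%. `qc_r1_map()`
catches such maps by a plausibility band on the tumor-median
($[0.2, 1.2]$ s⁻¹ by default — generous around literature breast values
so genuine biology is not flagged), and `run_pipeline()` then excludes
those patients from measured-R1,0 conditions only, keeping them under
fixed R1,0. This reproduces, at pipeline level, the practical rationale
for preferring fixed R1,0 in multi-platform studies.

## Derived maps and summaries

* `mask_unenhanced()` retains voxels whose peak post-injection signal
  exceeds baseline by ≥30% of baseline. The threshold is a declared
  default (no published value exists); it is configurable and all
  dependent quantities are reported with it.
* `compute_ser()` uses frames 2/9/26 on the default 32 × 15 s grid; on
  other grids `ser_frames()` maps ~110 s and ~380 s post-injection to
  the nearest frames. SER > 1 marks wash-out, SER < 1 persistent
  enhancement, and the ratio is invariant to global signal scaling.
* `filter_kio()` keeps $k_{io}$ strictly inside (0.1, 20) s⁻¹. Below
  0.1 s⁻¹ the implied mean intracellular water lifetime (≥10 s) is
  incompatible with epithelial cell sizes; at 20 s⁻¹ and above the
  system is effectively in the FXL, where a standard-dose DCE
  acquisition carries no $k_{io}$ information. Endpoints are excluded
  because boundary values are exactly the implausible ones. The retained
  fraction is itself a per-tumor metric.
* `sum_cao_map()` integrates the EES concentration $C_t/v_e$ over the
  acquisition ($\Delta t$-weighted by default for grid independence; a
  plain frame-sum mode exists). Cold spots predict where $k_{io}$ is
  unreliable, and the tests assert that coincidence on a constructed
  low-perfusion fixture — as a strong stochastic association, not a
  voxel-by-voxel identity.
* `summarize_metric()` reports per-lesion mean, median and interquartile
  width with quantiles by linear interpolation of order statistics at
  position $1 + p(n-1)$ (R type 7; fixed because no convention is
  universal), and multi-lesion patients average lesions without
  weighting.

## Response statistics

Percent changes ($100(v - v_1)/v_1$) per visit feed the group analysis:
two-sided Wilcoxon rank-sum (exact by enumeration up to a combined
n of 12 without ties, tie- and continuity-corrected normal approximation
otherwise), paired t-tests between analysis approaches, and univariate
logistic ROC. The AUC is computed twice on purpose — as the
concordant-pair rank statistic (ties get half credit) and as the ROC of
logistic-fitted probabilities — and their monotone-transform equality is
asserted on every tested input. Confidence intervals use DeLong's
method; `predict_response()` reports the discriminative orientation
(AUC ≥ 0.5), drops patients missing the needed visit and counts them.
Because percent change is scale-free, neither relaxivity (default
4.0 mM⁻¹s⁻¹, a 3T gadoteridol literature value — not stated by
acquisition protocols) nor signal scale affects these statistics.

## The synthetic cohort generator

`cohort_design()` + `simulate_patient()` produce a DRO cohort whose
defaults are the study conditions the analysis assumes: 6 + 9 patients
(responders/non-responders), visits V1–V3 (V4 supported), ellipsoidal
multi-slice ROIs of ~500 voxels, voxel values lognormal around medians
$K^{trans} = 0.25$ min⁻¹, $v_e = 0.4$, $k_{io} = 2$ s⁻¹,
$R_{1,0} = 0.6$ s⁻¹ with a 0.5 coefficient of variation (so iqr metrics
are non-degenerate), Rician noise at SNR 50, and injection at the start
of frame 3 of a 32 × 15 s dynamic series. Baseline medians are stated
assumptions — typical malignant breast values — because source
distributions for V1 are not published.

Longitudinal change applies a per-patient effect drawn around the
group-visit median of `default_effect_table()` (SD = half the published
interquartile widths where available), times small voxel-level lognormal
jitter; $R_{1,0}$ is longitudinally stable. The V2/V3 $K^{trans}$ and V2
$v_e$ entries follow published cohort medians; $v_e$ at V3/V4, all
$k_{io}$ effects and all V4 effects are modeling assumptions that
preserve the qualitative structure (responders: large $K^{trans}$ and
$k_{io}$ declines, modest $v_e$ rise). DCE data are generated through
the FXR model, so the cohort is exchange-sensitized by construction and
TM fits of it underestimate $K^{trans}$ — the SSM > TM ordering in the
tests is a consequence of the generating physics, not an assertion about
all tissues.

What the generator does **not** emulate: breast anatomy and fat signal,
k-space undersampling/view-sharing reconstruction, motion, registration
error, spatially structured (rather than i.i.d.) parameter fields, and
measured per-patient AIFs. Passing tests therefore validate the
numerics and the statistical machinery under the stated model — they do
not certify accuracy on scanner data subject to those effects.

## Numerical choices and test problem sizes

* AIF grid: 1 s spacing; halving it changes post-injection
  concentrations by <0.5% (tested).
* FXL-limit validation of the FXR eigenvalue runs at $k_{io} = 10^4$ s⁻¹
  over $v_e \in [0.1, 0.9]$ and tissue concentrations up to 0.3 mM —
  the physiologic range; the residual deviation of the exact eigenvalue
  from the population-weighted limit grows as
  $p_i p_o (r_1 C_t/v_e)^2 v_e / k_{io}$ and necessarily exceeds the
  10⁻⁴ check beyond it.
* Cohort-level regression tests run at reduced scale chosen as a
  compromise between sampling noise and iteration speed: the
  qualitative-ordering run uses 15 patients × ~60 voxels at V1, and the
  discrimination property (V31% median-$K^{trans}$ AUC > 0.9 in ≥95 of
  100 replicates, 8 + 8 patients) is evaluated on generator ground-truth
  summaries, with a single fitted small cohort (40 voxels/tumor, V1+V3,
  voxel SSM) confirming that the fitted pipeline reaches the same
  discrimination. Voxel-wise nonlinear fitting inside all 100 replicates
  would add nothing statistically: the fits are unbiased at the
  cohort's SNR (tested separately) and the discrimination is a property
  of the generator's group structure plus the ROC machinery.
* Determinism: every stochastic stage takes or derives a seed
  (`derive_seed` folds patient/visit/stage indices into the master seed
  below 2³¹); reruns of `run_pipeline()` with the same config are
  byte-identical, which is asserted on the written CSVs.

## Known limitations

* The FXR implementation is the monoexponential minor-eigenvalue form;
  a full two-pool signal model (both eigencomponents, TR-dependent
  apparent rate) would differ at very slow exchange.
* The population AIF is a stand-in; absolute $K^{trans}$ values carry
  its scale. Comparisons across software should use percent changes.
* `k_{io}` is only interpretable where extravasation is substantial;
  the filter fraction must accompany any $k_{io}$ summary.
* B1 maps are assumed voxel-aligned with the VFA data (nearest-neighbor
  lookup); image registration is out of scope because synthetic data are
  generated aligned.
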