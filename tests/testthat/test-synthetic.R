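test_that("visit effects scale baseline voxel values directly", {
  # single fixed effect, no dispersion, no voxel jitter: V3 = 0.5 x V1
  eff <- tibble::tibble(group = "pCR", visit = "V3", metric = "ktrans",
                        effect = -50, sd = 0)
  des <- cohort_design(n_pcr = 1, n_nonpcr = 0, visits = c("V1", "V3"),
                       effect_table = eff, voxel_jitter = 0,
                       voxels_per_tumor = 40, seed = 7)
  v1 <- generate_truth_maps(des, 1, "V1")
  v3 <- generate_truth_maps(des, 1, "V3")
  expect_equal(v3$ktrans, 0.5 * v1$ktrans, tolerance = 1e-12)
  expect_equal(v3$r10, v1$r10)  # native R1 longitudinally stable
  expect_equal(v3$ve, v1$ve)    # no ve entry in this table: unchanged
})

test_that("truth maps are deterministic and respect their invariants", {
  des <- cohort_design(voxels_per_tumor = 60, seed = 123)
  a <- generate_truth_maps(des, 3, "V2")
  b <- generate_truth_maps(des, 3, "V2")
  expect_identical(a, b)
  expect_true(all(a$ve > 0 & a$ve <= 1))
  expect_true(all(a$ktrans >= 0))
  expect_true(all(a$kio > 0))
  expect_true(all(a$r10 > 0))
  expect_error(generate_truth_maps(des, 3, "V9"), "unknown visit")
  expect_error(generate_truth_maps(des, 99, "V1"), "patient_index")
})

test_that("generated voxel medians match the design medians", {
  des <- cohort_design(n_pcr = 1, n_nonpcr = 0, voxels_per_tumor = 10000,
                       seed = 21)
  tr <- generate_truth_maps(des, 1, "V1")
  expect_lt(abs(median(tr$ktrans) - 0.25) / 0.25, 0.05)
  expect_lt(abs(median(tr$ve) - 0.4) / 0.4, 0.05)
  expect_lt(abs(median(tr$kio) - 2) / 2, 0.05)
  expect_lt(abs(median(tr$r10) - 0.6) / 0.6, 0.05)
})

test_that("no extravasation means flat baseline time courses", {
  des <- cohort_design(n_pcr = 1, n_nonpcr = 0, voxels_per_tumor = 20,
                       medians = c(ktrans = 1e-12, ve = 0.4, kio = 2,
                                   r10 = 0.6), seed = 3)
  tr <- generate_truth_maps(des, 1, "V1")
  tr$ktrans <- 0
  d <- simulate_dce_series(tr, default_protocol(), noise_sigma = 0,
                           noise = "none")
  spread <- tapply(d$signal, d$voxel, function(s) diff(range(s)))
  expect_true(all(spread < 1e-9))
})

test_that("noiseless simulated curves are closed by the SSM fit", {
  p <- default_protocol(); aif <- default_aif(p)
  des <- cohort_design(n_pcr = 1, n_nonpcr = 0, voxels_per_tumor = 12,
                       seed = 17)
  tr <- generate_truth_maps(des, 1, "V1")
  d <- simulate_dce_series(tr, p, noise_sigma = 0, noise = "none")
  fits <- fit_dce(d, p, aif, model = "ssm",
                  r10 = tibble::tibble(voxel = tr$voxel, r1 = tr$r10),
                  mode = "voxel")
  expect_lt(max(abs(fits$ktrans - tr$ktrans) / tr$ktrans), 1e-2)
  expect_lt(max(abs(fits$ve - tr$ve) / tr$ve), 1e-2)
  expect_lt(max(abs(fits$kio - tr$kio) / tr$kio), 1e-2)
})

test_that("simulation is reproducible under a fixed seed", {
  p <- default_protocol()
  des <- cohort_design(voxels_per_tumor = 20, seed = 5)
  tr <- generate_truth_maps(des, 2, "V1")
  d1 <- simulate_dce_series(tr, p, noise_sigma = 0.05, seed = 77)
  d2 <- simulate_dce_series(tr, p, noise_sigma = 0.05, seed = 77)
  expect_identical(d1, d2)
  d3 <- simulate_dce_series(tr, p, noise_sigma = 0.05, seed = 78)
  expect_false(identical(d1$signal, d3$signal))
  expect_error(simulate_dce_series(tr, p, noise_sigma = -1), "non-negative")
  # pre-injection frames carry baseline signal only (noiseless)
  d0 <- simulate_dce_series(tr, p, noise_sigma = 0, noise = "none")
  pre <- d0$signal[d0$time < injection_time(p)]
  expect_equal(unique(round(pre, 6)), 1000)
})

test_that("Rician mean stays within 1% of the noiseless signal at SNR 50", {
  set.seed(31)
  a <- 1000; sigma <- 20  # SNR 50
  draws <- add_rician_noise(rep(a, 2e5), sigma)
  expect_lt(abs(mean(draws) - a) / a, 0.01)
  expect_error(add_rician_noise(1, -1), "non-negative")
})

test_that("VFA simulation honors the B1 field and bias mode", {
  p <- default_protocol()
  des <- cohort_design(voxels_per_tumor = 15, seed = 9)
  tr <- generate_truth_maps(des, 1, "V1")
  # identity field, no noise: signals equal the SPGR equation at nominal FAs
  vb <- simulate_vfa_and_b1(tr, p, b1_field = 1)
  idx <- match(vb$vfa$voxel, tr$voxel)
  expect_equal(vb$vfa$signal,
               spgr_signal(1000, tr$r10[idx], vb$vfa$angle, p$tr_vfa),
               tolerance = 1e-12)
  expect_equal(vb$b1$ratio, rep(1, nrow(tr)))
  # consistent 1.2 field: corrected fit recovers the truth exactly
  vb2 <- simulate_vfa_and_b1(tr, p, b1_field = 1.2)
  fit <- fit_vfa_r1(vb2$vfa, p, b1 = vb2$b1)
  expect_equal(fit$r1, tr$r10, tolerance = 1e-6)
  # miscalibrated mode reports a unit map despite the applied field
  vb3 <- simulate_vfa_and_b1(tr, p, b1_field = 1.2, bias_mode = "miscalibrated")
  expect_equal(vb3$b1$ratio, rep(1, nrow(tr)))
  expect_equal(vb3$vfa$signal, vb2$vfa$signal)
  expect_error(simulate_vfa_and_b1(tr, p, b1_field = -1), "positive")
})

test_that("a full simulated patient is reproducible end to end", {
  des <- cohort_design(n_pcr = 1, n_nonpcr = 1, voxels_per_tumor = 15,
                       seed = 101)
  a <- simulate_patient(des, 1, "V1")
  b <- simulate_patient(des, 1, "V1")
  expect_identical(a$dce$signal, b$dce$signal)
  expect_identical(a$vfa$signal, b$vfa$signal)
  expect_equal(a$manifest$group, "pCR")
  expect_equal(simulate_patient(des, 2, "V1")$manifest$group, "non-pCR")
})
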