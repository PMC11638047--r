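test_that("noiseless Tofts round trip recovers the generating parameters", {
  p <- default_protocol(); aif <- default_aif(p)
  sig <- tm_curve(0.25, 0.4, protocol = p, aif = aif)
  fit <- fit_tm(sig, p, 0.6, aif)
  expect_lt(abs(fit$ktrans - 0.25) / 0.25, 1e-3)
  expect_lt(abs(fit$ve - 0.4) / 0.4, 1e-3)
  expect_equal(fit$kep, fit$ktrans / fit$ve)
  expect_true(fit$converged)
})

test_that("a flat curve yields an essentially zero transfer constant", {
  p <- default_protocol(); aif <- default_aif(p)
  fit <- fit_tm(rep(1000, p$n_frames), p, 0.6, aif)
  expect_lt(fit$ktrans, 1e-4)
})

test_that("noiseless shutter-speed round trip recovers all three parameters", {
  p <- default_protocol(); aif <- default_aif(p)
  sig <- ssm_curve(0.25, 0.4, 2, protocol = p, aif = aif)
  fit <- fit_ssm(sig, p, 0.6, aif)
  expect_lt(abs(fit$ktrans - 0.25) / 0.25, 1e-2)
  expect_lt(abs(fit$ve - 0.4) / 0.4, 1e-2)
  expect_lt(abs(fit$kio - 2) / 2, 1e-2)
  expect_equal(fit$kep, fit$ktrans / fit$ve)
})

test_that("the Tofts fit of an exchange-sensitized curve underestimates Ktrans", {
  p <- default_protocol(); aif <- default_aif(p)
  sig <- ssm_curve(0.25, 0.4, 2, protocol = p, aif = aif)
  tm <- fit_tm(sig, p, 0.6, aif)
  ssm <- fit_ssm(sig, p, 0.6, aif)
  expect_lt(tm$ktrans, ssm$ktrans)
})

test_that("exchange-insensitive curves park kio at a fitting boundary", {
  p <- default_protocol(); aif <- default_aif(p)
  sig <- ssm_curve(1e-4, 0.4, 2, protocol = p, aif = aif)
  noisy <- with(list(), {
    set.seed(99)
    sqrt((sig + rnorm(length(sig), 0, 20))^2 + rnorm(length(sig), 0, 20)^2)
  })
  fit <- fit_ssm(noisy, p, 0.6, aif)
  expect_true(fit$at_bound)
  expect_true(fit$kio > 999 || fit$kio < 2e-3)
})

test_that("ROI averaging is the framewise arithmetic mean", {
  p <- default_protocol()
  tt <- frame_times(p)
  c1 <- tm_curve(0.2, 0.4, protocol = p)
  dce <- tibble::tibble(
    voxel = rep(1:2, each = length(tt)),
    frame = rep(seq_along(tt), 2),
    time = rep(tt, 2),
    signal = c(c1, 3 * c1))
  avg <- roi_average_curve(dce)
  expect_equal(avg$signal, 2 * c1)
  one <- roi_average_curve(dce, voxels = 1L)
  expect_equal(one$signal, c1)
  expect_error(roi_average_curve(dce, voxels = 99L), "empty")
})

test_that("ROI fit of a homogeneous tumor equals the voxel fit", {
  p <- default_protocol(); aif <- default_aif(p)
  tt <- frame_times(p)
  sig <- ssm_curve(0.3, 0.5, 3, protocol = p, aif = aif)
  dce <- tibble::tibble(
    voxel = rep(1:4, each = length(tt)),
    frame = rep(seq_along(tt), 4),
    time = rep(tt, 4),
    signal = rep(sig, 4))
  roi <- fit_dce(dce, p, aif, model = "ssm", r10 = 0.6, mode = "roi")
  vox <- fit_dce(dce, p, aif, model = "ssm", r10 = 0.6, mode = "voxel")
  expect_equal(roi$ktrans, vox$ktrans[1], tolerance = 1e-8)
  expect_equal(roi$kio, vox$kio[1], tolerance = 1e-6)
})

test_that("every emitted fit satisfies kep = ktrans / ve exactly", {
  p <- default_protocol(); aif <- default_aif(p)
  set.seed(4)
  for (i in 1:5) {
    kt <- runif(1, 0.05, 0.6); ve <- runif(1, 0.1, 0.8)
    sig <- tm_curve(kt, ve, protocol = p, aif = aif)
    sig <- sqrt((sig + rnorm(length(sig), 0, 10))^2 +
                  rnorm(length(sig), 0, 10)^2)
    fit <- fit_tm(sig, p, 0.6, aif)
    expect_lt(abs(fit$kep * fit$ve - fit$ktrans), 1e-9)
  }
})

test_that("bolus arrival time is recovered from shifted curves", {
  p <- default_protocol(); aif <- default_aif(p)
  tt <- frame_times(p)
  sig0 <- tm_curve(0.25, 0.4, protocol = p, aif = aif)
  expect_lt(abs(estimate_bat(sig0, p, aif, 0.6)), 0.5)

  aif_late <- shift_aif(aif, 7.5)
  ct <- kety_concentration(0.25, 0.4, aif_late, times = tt)
  sig7 <- signal_from_r1(fxl_r1(ct, 0.6, p$relaxivity_r1), p,
                         baseline = 1000, r10 = 0.6)
  expect_lt(abs(estimate_bat(sig7, p, aif, 0.6) - 7.5), 1)
})

test_that("the returned shift beats every coarse-grid candidate", {
  p <- default_protocol(); aif <- default_aif(p)
  tt <- frame_times(p)
  aif_late <- shift_aif(aif, 5)
  ct <- kety_concentration(0.3, 0.5, aif_late, times = tt)
  sig <- signal_from_r1(fxl_r1(ct, 0.6, p$relaxivity_r1), p,
                        baseline = 1000, r10 = 0.6)
  bat_hat <- estimate_bat(sig, p, aif, 0.6)

  # independent reconstruction of the linearized-model residual
  score <- function(delta) {
    ctm <- signal_to_concentration(sig, p, 0.6)
    int_cp <- approx(aif$times, pracma::cumtrapz(aif$times, aif$cp),
                     xout = tt - delta, yleft = 0, rule = 2)$y
    int_ct <- pracma::cumtrapz(tt, ctm)
    x <- cbind(int_cp, -as.numeric(int_ct))
    sum(lm.fit(x, ctm)$residuals^2)
  }
  coarse <- seq(-2 * p$frame_interval, 6 * p$frame_interval,
                by = p$frame_interval / 4)
  expect_lte(score(bat_hat), min(vapply(coarse, score, numeric(1))) + 1e-12)
})

test_that("non-enhancing curves have undefined bolus arrival", {
  p <- default_protocol(); aif <- default_aif(p)
  expect_error(estimate_bat(rep(1000, p$n_frames), p, aif, 0.6),
               "BAT undefined")
})

test_that("tidy and glance expose fit parameters and diagnostics", {
  p <- default_protocol(); aif <- default_aif(p)
  fit <- fit_ssm(ssm_curve(0.25, 0.4, 2, protocol = p, aif = aif), p, 0.6, aif)
  td <- generics::tidy(fit)
  expect_setequal(td$term, c("ktrans", "ve", "kep", "kio"))
  gl <- generics::glance(fit)
  expect_true(gl$converged)
  plt <- ggplot2::autoplot(fit)
  expect_s3_class(plt, "ggplot")
})
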