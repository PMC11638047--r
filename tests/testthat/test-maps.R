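make_dce <- function(curves, protocol = default_protocol()) {
  tt <- frame_times(protocol)
  tibble::tibble(
    voxel = rep(seq_along(curves), each = length(tt)),
    frame = rep(seq_along(tt), length(curves)),
    time = rep(tt, length(curves)),
    signal = unlist(curves))
}

test_that("unenhanced voxels are masked by fractional peak enhancement", {
  p <- default_protocol()
  flat <- rep(100, p$n_frames)
  up <- c(100, 100, seq(100, 200, length.out = p$n_frames - 2))
  weak <- c(100, 100, seq(100, 110, length.out = p$n_frames - 2))
  m <- mask_unenhanced(make_dce(list(flat, up, weak), p), p, threshold = 0.3)
  expect_equal(m$enhancing, c(FALSE, TRUE, FALSE))
  expect_error(mask_unenhanced(make_dce(list(flat), p), p, threshold = -1),
               "non-negative")
})

test_that("a constructed half-enhancing ROI retains exactly half its voxels", {
  p <- default_protocol()
  flat <- rep(100, p$n_frames)
  up <- c(100, 100, rep(160, p$n_frames - 2))
  curves <- c(rep(list(up), 10), rep(list(flat), 10))
  m <- mask_unenhanced(make_dce(curves, p), p, threshold = 0.3)
  expect_equal(sum(m$enhancing), 10)
})

test_that("SER follows its defining arithmetic and sign analysis", {
  p <- default_protocol()
  mk <- function(s2, s9, s26) {
    s <- rep(s2, p$n_frames); s[9] <- s9; s[26] <- s26
    s[3:8] <- (s2 + s9) / 2; s[10:25] <- (s9 + s26) / 2
    s
  }
  dce <- make_dce(list(mk(100, 300, 250),  # wash-out
                       mk(100, 300, 300),  # plateau
                       mk(100, 200, 320)), # persistent
                  p)
  ser <- compute_ser(dce)
  expect_equal(ser$ser[1], 200 / 150)
  expect_equal(ser$ser[2], 1)
  expect_lt(ser$ser[3], 1)
  expect_gt(ser$ser[1], 1)
})

test_that("SER is invariant to global multiplicative scaling", {
  p <- default_protocol()
  base <- c(100, 100, seq(105, 300, length.out = p$n_frames - 2))
  dce1 <- make_dce(list(base), p)
  dce2 <- make_dce(list(base * 37.5), p)
  expect_equal(compute_ser(dce1)$ser, compute_ser(dce2)$ser, tolerance = 1e-12)
})

test_that("degenerate SER denominators and non-enhancing voxels are invalid", {
  p <- default_protocol()
  flat <- rep(100, p$n_frames)
  ser <- compute_ser(make_dce(list(flat), p))
  expect_false(ser$valid[1])
  up <- c(100, 100, seq(100, 250, length.out = p$n_frames - 2))
  dce <- make_dce(list(up, flat), p)
  mask <- mask_unenhanced(dce, p)
  ser2 <- compute_ser(dce, enhancing = mask)
  expect_true(ser2$valid[1])
  expect_false(ser2$valid[2])
})

test_that("SER frames track the early and delayed post-injection times", {
  p <- default_protocol()
  expect_equal(unname(ser_frames(p, early = 90, late = 345)),
               c(2L, 9L, 26L))
})

test_that("kio filtering keeps the open physiologic interval", {
  f <- filter_kio(c(0.05, 5, 10, 30))
  expect_equal(f$retained, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(f$fraction, 0.5)
  expect_true(filter_kio(5)$retained)
  expect_false(filter_kio(0.05)$retained)
  # strict endpoints
  expect_false(filter_kio(0.1)$retained)
  expect_false(filter_kio(20)$retained)
  expect_error(filter_kio(1, lo = 5, hi = 2), "less than")
})

test_that("kio filtering is idempotent and bounded", {
  set.seed(8)
  k <- 10^runif(200, -2, 3)
  f1 <- filter_kio(k)
  f2 <- filter_kio(k[f1$retained])
  expect_true(all(f2$retained))
  expect_equal(f2$fraction, 1)
  expect_gte(f1$fraction, 0)
  expect_lte(f1$fraction, 1)
})

test_that("EES concentration summation scales as expected", {
  ct <- matrix(c(0, 0.2, 0.5, 0.3,
                 0, 0, 0, 0), nrow = 2, byrow = TRUE)
  s <- sum_cao_map(ct, ve = c(0.4, 0.4), frame_interval = 15)
  expect_equal(s[2], 0)
  expect_equal(s[1], sum(ct[1, ]) / 0.4 * 15)
  # halving ve doubles the summed EES concentration
  s_half <- sum_cao_map(ct, ve = c(0.2, 0.2), frame_interval = 15)
  expect_equal(s_half[1], 2 * s[1])
  # plain mode drops the frame-interval weighting
  expect_equal(sum_cao_map(ct, c(0.4, 0.4), 15, mode = "plain")[1],
               sum(ct[1, ]) / 0.4)
})

test_that("low extravasation voxels are both cold in Sigma[CAo] and filtered", {
  p <- default_protocol(); aif <- default_aif(p)
  tt <- frame_times(p)
  # two populations: perfused and nearly unperfused
  kt <- c(rep(0.3, 10), rep(1e-3, 10))
  ct <- t(vapply(kt, function(k) kety_concentration(k, 0.4, aif, times = tt),
                 numeric(length(tt))))
  sig <- sum_cao_map(ct, ve = rep(0.4, 20), frame_interval = p$frame_interval)
  curves <- lapply(seq_len(20), function(v) {
    r1t <- fxr_r1(ct[v, ], 0.4, 2, 0.6, 0.6, p$relaxivity_r1)
    s <- signal_from_r1(r1t, p, baseline = 1000, r10 = 0.6)
    set.seed(500 + v)
    sqrt((s + rnorm(length(s), 0, 20))^2 + rnorm(length(s), 0, 20)^2)
  })
  fits <- fit_dce(make_dce(curves, p), p, aif, model = "ssm",
                  r10 = 0.6, mode = "voxel")
  filt <- filter_kio(fits$kio)
  cold <- sig < median(sig)
  # filtered-out kio voxels coincide with the cold spots of the
  # EES-concentration map (a stochastic coincidence, not an identity)
  expect_lt(mean(filt$retained[cold]), 0.2)
  expect_gt(mean(filt$retained[!cold]), 0.7)
})

test_that("histogram summaries follow the stated quantile convention", {
  s <- summarize_metric(c(1, 2, 3, 4, 5))
  expect_equal(s$mean, 3)
  expect_equal(s$median, 3)
  expect_equal(s$iqr, 2)
  expect_equal(s$n_voxels, 5)
})

test_that("iqr is translation invariant and positively homogeneous", {
  set.seed(13)
  x <- rlnorm(200, 0, 0.5)
  s0 <- summarize_metric(x)
  expect_equal(summarize_metric(x + 10)$iqr, s0$iqr, tolerance = 1e-12)
  expect_equal(summarize_metric(3 * x)$iqr, 3 * s0$iqr, tolerance = 1e-12)
  # order independence
  expect_equal(summarize_metric(sample(x))$iqr, s0$iqr)
})

test_that("multi-lesion patients average their lesions without weighting", {
  vals <- c(rep(0.2, 10), rep(0.4, 30))
  lesions <- rep(c(1, 2), c(10, 30))
  s <- summarize_metric(vals, lesions)
  expect_equal(nrow(s), 2)
  expect_equal(patient_value(s, "mean"), 0.3)
  expect_error(summarize_metric(c(NA, NA), c(1, 1)), "no valid")
})
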