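test_that("percent change behaves as a scale-free relative difference", {
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(0.44, 0.33), 100 * 0.11 / 0.33)
  # positive rescaling of the metric cancels
  v <- c(0.2, 0.5); b <- c(0.4, 0.25)
  expect_equal(percent_change(7.3 * v, 7.3 * b), percent_change(v, b))
  expect_warning(out <- percent_change(1, 0), "zero baseline")
  expect_true(is.na(out))
})

test_that("exact Wilcoxon matches full enumeration for small groups", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4)), 1 / 3, tolerance = 1e-12)
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4)),
               wilcoxon_enumeration_p(c(1, 2), c(3, 4)), tolerance = 1e-12)
  set.seed(20)
  for (i in 1:8) {
    n_a <- sample(2:6, 1); n_b <- sample(2:6, 1)
    a <- rnorm(n_a); b <- rnorm(n_b, 0.5)
    expect_equal(wilcoxon_rank_sum(a, b), wilcoxon_enumeration_p(a, b),
                 tolerance = 1e-10)
  }
})

test_that("degenerate and approximate Wilcoxon cases are handled", {
  expect_equal(wilcoxon_rank_sum(c(2, 2, 2), c(2, 2)), 1)
  set.seed(6)
  a <- rnorm(6); b <- rnorm(6, 1)
  p_exact <- wilcoxon_rank_sum(a, b)
  p_approx <- suppressWarnings(
    stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
  expect_lt(abs(p_exact - p_approx), 0.02)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "nonempty")
})

test_that("paired t-test matches the closed-form statistic", {
  # differences {1,2,3}: t = 2 sqrt(3), df = 2
  a <- c(2, 4, 6); b <- c(1, 2, 3)
  p_closed <- 2 * stats::pt(-2 * sqrt(3), df = 2)
  expect_equal(paired_t_test(a, b), p_closed, tolerance = 1e-12)
  # reduction identity: paired test equals one-sample test of differences
  set.seed(2)
  x <- rnorm(10); y <- x + 0.4 + rnorm(10, 0, 0.2)
  expect_equal(paired_t_test(x, y), stats::t.test(x - y)$p.value,
               tolerance = 1e-12)
  # sign-flip symmetry
  expect_equal(paired_t_test(x, y), paired_t_test(y, x))
  expect_error(paired_t_test(c(1, 2), c(2, 3)), "variance")
  expect_error(paired_t_test(1, c(1, 2)), "equal length")
})

test_that("rank AUC matches brute-force pair counting", {
  labels <- c(0, 0, 1, 1); scores <- c(0.1, 0.4, 0.35, 0.8)
  r <- roc_auc(labels, scores)
  expect_equal(r$auc, 0.75)
  expect_equal(r$auc, pair_count_auc(labels, scores))
  set.seed(40)
  for (i in 1:10) {
    lab <- rep(c(TRUE, FALSE), c(5, 7))
    sc <- sample(round(rnorm(12), 1))  # rounded: creates occasional ties
    expect_equal(roc_auc(lab, sc)$auc, pair_count_auc(lab, sc))
  }
})

test_that("AUC symmetry, separation, and error cases hold", {
  lab <- rep(c(TRUE, FALSE), c(4, 5))
  sep <- c(rnorm(4, 10), rnorm(5, 0))
  expect_equal(roc_auc(lab, sep)$auc, 1)
  set.seed(41)
  sc <- rnorm(9)
  expect_equal(roc_auc(lab, -sc)$auc, 1 - roc_auc(lab, sc)$auc)
  expect_error(roc_auc(rep(TRUE, 4), rnorm(4)), "both classes")
})

test_that("logistic-ROC equals the rank AUC up to score direction", {
  set.seed(42)
  for (i in 1:20) {
    lab <- rep(c(TRUE, FALSE), c(6, 9))
    sc <- rnorm(15, mean = ifelse(lab, runif(1, -1, 1), 0))
    r <- roc_auc(lab, sc)
    expect_true(abs(r$auc_logistic - r$auc) < 1e-10 ||
                  abs(r$auc_logistic - (1 - r$auc)) < 1e-10)
  }
})

test_that("DeLong interval brackets the AUC and matches pROC", {
  set.seed(43)
  lab <- rep(c(TRUE, FALSE), c(8, 8))
  sc <- rnorm(16, mean = ifelse(lab, 1, 0))
  r <- roc_auc(lab, sc)
  expect_lte(r$ci95[1], r$auc)
  expect_gte(r$ci95[2], r$auc)
  # independent cross-check of the point estimate
  expect_equal(r$auc,
               as.numeric(pROC::auc(pROC::roc(lab, sc, direction = "<",
                                              quiet = TRUE))))
  td <- generics::tidy(r)
  expect_equal(td$auc, r$auc)
  expect_s3_class(ggplot2::autoplot(r), "ggplot")
})

test_that("cohort percent-change pivoting flags missing baselines", {
  cohort <- tibble::tibble(
    patient = c(1, 1, 2, 2, 3),
    group = c("pCR", "pCR", "non-pCR", "non-pCR", "non-pCR"),
    visit = c("V1", "V3", "V1", "V3", "V3"),
    metric = "ktrans_mean",
    value = c(0.4, 0.1, 0.5, 0.45, 0.3))
  expect_message(wide <- cohort_percent_change(cohort), "lack the baseline")
  expect_equal(nrow(wide), 2)
  expect_equal(wide$V31_pct, c(-75, -10))
})

test_that("response prediction separates disjoint groups and keeps books", {
  set.seed(44)
  cohort <- tidyr::expand_grid(patient = 1:15, visit = c("V1", "V3")) |>
    dplyr::mutate(
      group = ifelse(patient <= 6, "pCR", "non-pCR"),
      metric = "ktrans_mean",
      value = ifelse(visit == "V1", 0.4 + runif(30, 0, 0.05),
                     ifelse(patient <= 6, 0.04, 0.36) + runif(30, 0, 0.02)))
  row <- predict_response(cohort, "ktrans_mean", change = "V31")
  expect_equal(row$auc, 1)
  expect_lt(row$wilcoxon_p, 0.05)
  expect_equal(row$n_pos + row$n_neg, 15)
  # drop one patient's V3: n decremented by exactly one
  cohort2 <- cohort[!(cohort$patient == 15 & cohort$visit == "V3"), ]
  row2 <- suppressMessages(predict_response(cohort2, "ktrans_mean",
                                            change = "V31"))
  expect_equal(row2$n_dropped, 1)
  expect_equal(row2$n_pos + row2$n_neg, 14)
})

test_that("permuted labels give chance-level AUC on average", {
  set.seed(45)
  scores <- rnorm(15)
  labels <- rep(c(TRUE, FALSE), c(6, 9))
  aucs <- replicate(200, roc_auc(sample(labels), scores)$auc)
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})
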