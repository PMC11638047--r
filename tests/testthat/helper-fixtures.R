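# Shared fixtures: default protocol/AIF and independent oracles used across
# test files. Oracles are deliberately written from scratch (enumeration,
# direct arithmetic) rather than reusing package internals.

default_protocol <- function(...) acq_protocol(...)

default_aif <- function(protocol = default_protocol()) {
  population_aif(seq(0, max(frame_times(protocol)), by = 1),
                 bat_shift = injection_time(protocol))
}

# Noiseless forward curves through the package's composed models.
tm_curve <- function(ktrans, ve, r10 = 0.6, protocol = default_protocol(),
                     aif = default_aif(protocol), baseline = 1000) {
  tt <- frame_times(protocol)
  ct <- kety_concentration(ktrans, ve, aif, times = tt)
  signal_from_r1(fxl_r1(ct, r10, protocol$relaxivity_r1), protocol,
                 baseline = baseline, r10 = r10)
}

ssm_curve <- function(ktrans, ve, kio, r10 = 0.6,
                      protocol = default_protocol(),
                      aif = default_aif(protocol), baseline = 1000) {
  tt <- frame_times(protocol)
  ct <- kety_concentration(ktrans, ve, aif, times = tt)
  r1t <- fxr_r1(ct, ve, kio, r1i = r10, r1o0 = r10,
                relaxivity = protocol$relaxivity_r1)
  signal_from_r1(r1t, protocol, baseline = baseline, r10 = r10)
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# choose(n_a + n_b, n_a) rank assignments (no ties assumed).
wilcoxon_enumeration_p <- function(a, b) {
  n_a <- length(a)
  all_ranks <- rank(c(a, b))
  w_obs <- sum(all_ranks[seq_len(n_a)])
  combos <- utils::combn(n_a + length(b), n_a)
  ranks <- seq_len(n_a + length(b))
  w_all <- apply(combos, 2, function(idx) sum(ranks[idx]))
  mu <- n_a * (n_a + length(b) + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# Brute-force concordant-pair AUC (half credit for ties).
pair_count_auc <- function(labels, scores) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}
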