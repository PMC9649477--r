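# Independent brute-force oracles, deliberately naive: these recompute the
# quantities the package implements by direct enumeration on raw inputs.

# Mann-Whitney pair-counting AUC: concordant + half-tied over all pos x neg pairs
oracle_auc <- function(scores, labels, positive, direction = "greater") {
  s <- if (direction == "greater") scores else -scores
  pos <- s[labels == positive]
  neg <- s[labels != positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# exhaustive Youden search over every midpoint threshold (+/-Inf ends),
# tie-break: maximal J, then maximal specificity
oracle_youden <- function(scores, labels, positive, direction = "greater") {
  s <- if (direction == "greater") scores else -scores
  is_pos <- labels == positive
  u <- sort(unique(s))
  cand <- c(-Inf, (u[-1] + u[-length(u)]) / 2, Inf)
  best <- list(j = -Inf, spec = -Inf, thr = NA_real_)
  for (t in cand) {
    sens <- mean(s[is_pos] > t)
    spec <- mean(s[!is_pos] <= t)
    j <- sens + spec - 1
    if (j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec + 1e-12)) {
      best <- list(j = j, spec = spec, thr = t)
    }
  }
  list(cutoff = if (direction == "greater") best$thr else -best$thr,
       youden_j = best$j)
}

# peak-to-peak by direct arithmetic on the raw sample vector
oracle_ptp <- function(samples, sampling_rate, t0_ms, t1_ms) {
  i0 <- ceiling(t0_ms * sampling_rate / 1000) + 1
  i1 <- floor(t1_ms * sampling_rate / 1000) + 1
  max(samples[i0:i1]) - min(samples[i0:i1])
}

# a noise-free unconditioned sweep with programmed peak-to-peak amplitude
synth_sweep_for_test <- function(A, cfg) {
  cfg$amplitude_uv <- A
  r <- stats::setNames(rep(100, length(ISI_BATTERY)), ISI_BATTERY)
  targ <- list(MAS = r2_recovery_curve("MAS", as.list(r)),
               LAS = r2_recovery_curve("LAS", as.list(r)))
  batt <- generate_blink_traces(targ, cfg)$MAS
  Filter(function(tr) length(tr$stimulus_onsets) == 1, batt)[[1]]
}

# a noise-free two-sided battery programmed at the given percent ratios
make_clean_battery <- function(ratios_mas, ratios_las = ratios_mas,
                               isis = ISI_BATTERY, ...) {
  cfg <- cohort_config(noise_sd_uv = 0, n_trials = 1L, n_uncond_trials = 1L,
                       ...)
  targ <- list(
    MAS = r2_recovery_curve("MAS", as.list(stats::setNames(ratios_mas, isis))),
    LAS = r2_recovery_curve("LAS", as.list(stats::setNames(ratios_las, isis))))
  generate_blink_traces(targ, cfg, isis = isis)
}
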