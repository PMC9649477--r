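## Synthetic cohort generation: two diagnostic groups (PD, CBS) with the
## published demographic, blink-reflex-asymmetry and MRI-asymmetry
## distributions, in summary mode (metric draws only) or trace mode
## (full paired-stimulation EMG batteries synthesised per patient).

#' Mean of a normal distribution truncated to an interval
#'
#' Closed-form mean of \eqn{N(\mu, \sigma^2)} truncated to
#' `[lower, upper]`.  Used as the analytic oracle for the truncated-normal
#' draws of the cohort generator.
#'
#' @param mean,sd Parameters of the untruncated normal.
#' @param lower,upper Truncation bounds.
#' @return The truncated mean.
#' @export
truncnorm_mean <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(min(max(mean, lower), upper))
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

#' Draw from a truncated normal distribution
#'
#' Inverse-CDF sampler for \eqn{N(\mu, \sigma^2)} truncated to
#' `[lower, upper]`.  With `sd = 0` the (clamped) mean is returned, making
#' degenerate configurations exactly reproducible.
#'
#' @param n Number of draws.
#' @inheritParams truncnorm_mean
#' @return Numeric vector of `n` draws in `[lower, upper]`.
#' @export
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) stop("rtruncnorm(): sd must be >= 0", call. = FALSE)
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  pa <- stats::pnorm(lower, mean, sd)
  pb <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pa + stats::runif(n) * (pb - pa), mean, sd)
}

mom <- function(mean, sd) c(mean = mean, sd = sd)

#' Configuration of the synthetic cohort generator
#'
#' Default values are the published group summaries of the study cohort
#' (drug-naive PD, n = 14; early CBS, n = 10): demographics, asymmetry
#' index of the R2 blink-reflex recovery cycle at ISIs 100/150/200 ms,
#' total grey-matter volume and the MRI asymmetry index.  Asymmetry
#' indices are drawn from normals truncated to \[0, 1\]; ages, durations,
#' scores and volumes from normals truncated to be non-negative.  The
#' recovery-profile parameters shape the per-side recovery-cycle targets
#' used in trace mode and are package conventions, not published values.
#'
#' @param n_pd,n_cbs Per-group sample sizes.
#' @param pd,cbs Named lists of `c(mean, sd)` pairs for the per-group
#'   quantities; see the defaults for the full field list (`age`,
#'   `duration`, `updrs_me`, `hy`, `ai_100`, `ai_150`, `ai_200`,
#'   `total_gm`, `ai_mri`) plus scalar proportions `male_prop` and
#'   `right_mas_prop`.
#' @param profile_base Recovery-ratio (%) baseline at each battery ISI — a
#'   monotone saturating curve from strong short-ISI suppression to full
#'   recovery at 750 ms.
#' @param profile_midlevel Mean of the two stimulation sides' recovery
#'   ratios (%) at the short ISIs (100/150/200 ms) used to convert a drawn
#'   asymmetry target into a (higher, lower) side pair.
#' @param amplitude_uv Unconditioned R2 peak-to-peak amplitude (microvolt)
#'   programmed into synthetic sweeps.
#' @param noise_sd_uv Additive Gaussian noise SD (microvolt) of synthetic
#'   sweeps.
#' @param sampling_rate_hz Sampling rate of synthetic sweeps.
#' @param n_trials,n_uncond_trials Conditioned sweeps per ISI and
#'   unconditioned sweeps per side.
#' @param ai_tolerance Declared round-trip tolerance: at the default noise
#'   level, re-extracting a patient's asymmetry index from synthesised
#'   traces reproduces the drawn target within this absolute margin.  Two
#'   error sources are covered by propagation through the index formula:
#'   the ratio-level round-trip error (about 5 percentage points) and, at
#'   extreme asymmetry, the noise floor of peak-to-peak measurement — a
#'   near-zero suppressed response cannot be extracted below the expected
#'   span of window noise (about 3.5 points here), which shrinks an index
#'   near 1 by roughly `2 * 3.5 / (2 * midlevel)` ~ 0.1.  The bias is a
#'   property of raw peak-to-peak extraction, deliberately not corrected.
#' @param seed Integer seed; every draw of the generator flows from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(
    n_pd = 14L, n_cbs = 10L,
    pd = list(age = mom(64.6, 7.5), duration = mom(1.7, 1.3),
              updrs_me = mom(24.8, 11.8), hy = mom(1.9, 0.3),
              ai_100 = mom(0.86, 0.36), ai_150 = mom(0.81, 0.37),
              ai_200 = mom(0.42, 0.36),
              total_gm = mom(402387, 28257), ai_mri = mom(0.006, 0.005),
              male_prop = 0.50, right_mas_prop = 0.50),
    cbs = list(age = mom(71.1, 5.9), duration = mom(2.9, 1.4),
               updrs_me = mom(37.6, 15.2), hy = mom(2.1, 0.5),
               ai_100 = mom(0.10, 0.32), ai_150 = mom(0.10, 0.32),
               ai_200 = mom(0.04, 0.10),
               total_gm = mom(346242, 24986), ai_mri = mom(0.02, 0.02),
               male_prop = 0.40, right_mas_prop = 0.70),
    profile_base = c(`100` = 5, `150` = 12, `200` = 30, `300` = 55,
                     `400` = 75, `500` = 90, `750` = 100),
    profile_midlevel = c(`100` = 30, `150` = 30, `200` = 35),
    amplitude_uv = 200, noise_sd_uv = 2, sampling_rate_hz = 5000,
    n_trials = 5L, n_uncond_trials = 2L, ai_tolerance = 0.2, seed = 1L) {
  cfg <- list(n_pd = as.integer(n_pd), n_cbs = as.integer(n_cbs),
              pd = pd, cbs = cbs,
              profile_base = profile_base,
              profile_midlevel = profile_midlevel,
              amplitude_uv = amplitude_uv, noise_sd_uv = noise_sd_uv,
              sampling_rate_hz = sampling_rate_hz,
              n_trials = as.integer(n_trials),
              n_uncond_trials = as.integer(n_uncond_trials),
              ai_tolerance = ai_tolerance,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_pd < 1L || cfg$n_cbs < 1L)
    stop("cohort_config(): sample sizes must be >= 1", call. = FALSE)
  for (g in c("pd", "cbs")) {
    grp <- cfg[[g]]
    for (nm in c("age", "duration", "updrs_me", "hy", "ai_100", "ai_150",
                 "ai_200", "total_gm", "ai_mri")) {
      v <- grp[[nm]]
      if (is.null(v) || length(v) != 2L || any(!is.finite(v)) || v[2] < 0)
        stop(sprintf("cohort_config(): %s$%s must be finite c(mean, sd) with sd >= 0",
                     g, nm), call. = FALSE)
    }
    for (nm in c("male_prop", "right_mas_prop")) {
      p <- grp[[nm]]
      if (!is.finite(p) || p < 0 || p > 1)
        stop(sprintf("cohort_config(): %s$%s must be a proportion in [0, 1]",
                     g, nm), call. = FALSE)
    }
  }
  if (any(!is.finite(cfg$profile_base)) || any(cfg$profile_base < 0) ||
      any(!is.finite(cfg$profile_midlevel)) || any(cfg$profile_midlevel <= 0))
    stop("cohort_config(): recovery-profile parameters must be finite and non-negative",
         call. = FALSE)
  if (cfg$noise_sd_uv < 0 || cfg$amplitude_uv <= 0 || cfg$sampling_rate_hz <= 0)
    stop("cohort_config(): trace parameters out of range", call. = FALSE)
  invisible(cfg)
}

round_half_step <- function(x, lo = 1, hi = 5) pmin(pmax(round(x * 2) / 2, lo), hi)

draw_group <- function(grp, n, group_label, id_prefix) {
  ai_100 <- rtruncnorm(n, grp$ai_100[1], grp$ai_100[2], 0, 1)
  ai_150 <- rtruncnorm(n, grp$ai_150[1], grp$ai_150[2], 0, 1)
  ai_200 <- rtruncnorm(n, grp$ai_200[1], grp$ai_200[2], 0, 1)
  ai_mri <- rtruncnorm(n, grp$ai_mri[1], grp$ai_mri[2], 0, 1)
  total_gm <- rtruncnorm(n, grp$total_gm[1], grp$total_gm[2], 0, Inf)
  mas_side <- ifelse(stats::runif(n) < grp$right_mas_prop, "right", "left")
  # hemisphere volumes consistent with the drawn asymmetry index: the
  # hemisphere contralateral to the clinical MAS is the atrophic one
  mas_hemi <- total_gm * (1 - ai_mri) / 2
  las_hemi <- total_gm * (1 + ai_mri) / 2
  mas_hemisphere <- ifelse(mas_side == "right", "left", "right")
  left_volume <- ifelse(mas_hemisphere == "left", mas_hemi, las_hemi)
  right_volume <- ifelse(mas_hemisphere == "left", las_hemi, mas_hemi)
  patients <- data.frame(
    patient_id = sprintf("%s%02d", id_prefix, seq_len(n)),
    group = group_label,
    sex = ifelse(stats::runif(n) < grp$male_prop, "M", "F"),
    age = rtruncnorm(n, grp$age[1], grp$age[2], 0, Inf),
    disease_duration = rtruncnorm(n, grp$duration[1], grp$duration[2], 0, Inf),
    updrs_me = rtruncnorm(n, grp$updrs_me[1], grp$updrs_me[2], 0, 108),
    hy_stage = round_half_step(stats::rnorm(n, grp$hy[1], grp$hy[2])),
    mas_side = mas_side,
    stringsAsFactors = FALSE)
  metrics <- data.frame(
    patient_id = patients$patient_id,
    group = group_label,
    mas_side = mas_side,
    ai_r2brrc_100 = ai_100, ai_r2brrc_150 = ai_150, ai_r2brrc_200 = ai_200,
    ai_mri = ai_mri,
    total_gm_volume = total_gm,
    left_volume = left_volume, right_volume = right_volume,
    stringsAsFactors = FALSE)
  list(patients = patients, metrics = metrics)
}

#' Generate a synthetic two-group cohort
#'
#' Draws a cohort of PD and CBS patients whose demographics, blink-reflex
#' asymmetry indices and MRI metrics follow the distributions of
#' [cohort_config()].  In `"summary"` mode the per-patient metric values
#' are drawn directly.  In `"trace"` mode, each patient additionally
#' receives a full paired-stimulation EMG battery for both stimulation
#' sides, synthesised so that the blink-reflex extraction stack recovers
#' the patient's drawn asymmetry targets (exactly so when
#' `noise_sd_uv = 0`).
#'
#' @param config A [cohort_config].
#' @param mode `"summary"` or `"trace"`.
#' @return An object of class `cohort_dataset`: list with `patients`
#'   (demographics data frame), `metrics` (per-patient asymmetry indices
#'   and hemispheric volumes), `target_curves` and `traces` (trace mode
#'   only), and the `config`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            mode = c("summary", "trace")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  pd <- draw_group(config$pd, config$n_pd, "PD", "PD")
  cbs <- draw_group(config$cbs, config$n_cbs, "CBS", "CBS")
  patients <- rbind(pd$patients, cbs$patients)
  metrics <- rbind(pd$metrics, cbs$metrics)
  rownames(patients) <- rownames(metrics) <- NULL
  out <- structure(list(patients = patients, metrics = metrics,
                        target_curves = NULL, traces = NULL,
                        mode = mode, config = config),
                   class = "cohort_dataset")
  if (mode == "trace") {
    out$target_curves <- lapply(seq_len(nrow(metrics)), function(i)
      target_recovery_curves(metrics[i, ], config))
    names(out$target_curves) <- metrics$patient_id
    out$traces <- lapply(out$target_curves, generate_blink_traces,
                         config = config)
  }
  out
}

#' @export
print.cohort_dataset <- function(x, ...) {
  tab <- table(x$patients$group)
  cat(sprintf("<cohort_dataset> %d patients (%s), %s mode%s\n",
              nrow(x$patients),
              paste(sprintf("%s n=%d", names(tab), tab), collapse = ", "),
              x$mode,
              if (is.null(x$traces)) "" else ", EMG traces attached"))
  invisible(x)
}

#' Per-side recovery-cycle targets consistent with a patient's asymmetry
#'
#' Converts a patient's drawn asymmetry-index targets at the short ISIs
#' into a (MAS-stimulation, LAS-stimulation) pair of recovery-ratio
#' targets: the two sides are placed at
#' `midlevel * (1 +/- ai)` so their asymmetry index is exactly the target.
#' For PD the elevated side is LAS stimulation (the published short-ISI
#' pattern); for CBS, whose asymmetry is small, the elevated side is the
#' patient's `mas_side`-independent coin flip drawn from the generator
#' stream.  Long ISIs (300-750 ms) follow the symmetric baseline profile.
#'
#' @param metric_row One row of a cohort's `metrics` data frame.
#' @param config The [cohort_config].
#' @return Named list with [r2_recovery_curve] targets `MAS` and `LAS`.
#' @export
target_recovery_curves <- function(metric_row, config) {
  base <- config$profile_base
  mid <- config$profile_midlevel
  short <- names(mid)
  ai <- c(`100` = metric_row$ai_r2brrc_100,
          `150` = metric_row$ai_r2brrc_150,
          `200` = metric_row$ai_r2brrc_200)[short]
  hi <- mid * (1 + ai)
  lo <- mid * (1 - ai)
  las_elevated <- if (metric_row$group == "PD") TRUE else stats::runif(1) < 0.5
  las <- mas <- base
  if (las_elevated) {
    las[short] <- hi; mas[short] <- lo
  } else {
    las[short] <- lo; mas[short] <- hi
  }
  list(MAS = r2_recovery_curve("MAS", as.list(mas)),
       LAS = r2_recovery_curve("LAS", as.list(las)))
}

#' Extract the per-patient asymmetry-index table from a cohort
#'
#' Returns the analysis table (one row per patient: group, MAS side,
#' blink-reflex asymmetry index at ISIs 100/150/200 ms, MRI asymmetry
#' index).  With `from_traces = TRUE` the blink-reflex indices are
#' recomputed by running the full extraction stack
#' ([build_recovery_cycle()] then [r2brrc_ai()]) on the cohort's EMG
#' batteries, and the MRI index by [mri_ai()] on the hemispheric volumes —
#' the round trip the trace generator is designed to close.
#'
#' @param cohort A [generate_cohort()] / [fixture_cohort()] result.
#' @param from_traces Recompute indices from raw traces (trace-mode
#'   cohorts only) instead of reading the drawn targets.
#' @param window [response_window] used for re-extraction.
#' @return Data frame with columns `patient_id`, `group`, `mas_side`,
#'   `ai_r2brrc_100`, `ai_r2brrc_150`, `ai_r2brrc_200`, `ai_mri`.
#' @export
ai_table <- function(cohort, from_traces = FALSE, window = response_window()) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  m <- cohort$metrics
  if (!from_traces)
    return(m[, c("patient_id", "group", "mas_side",
                 "ai_r2brrc_100", "ai_r2brrc_150", "ai_r2brrc_200", "ai_mri")])
  if (is.null(cohort$traces))
    stop("ai_table(): cohort has no traces; generate with mode = \"trace\"",
         call. = FALSE)
  rows <- lapply(seq_len(nrow(m)), function(i) {
    id <- m$patient_id[i]
    batt <- cohort$traces[[id]]
    cv_mas <- build_recovery_cycle(batt$MAS, window = window)
    cv_las <- build_recovery_cycle(batt$LAS, window = window)
    hm <- hemisphere_metrics(m$left_volume[i], m$right_volume[i])
    data.frame(patient_id = id, group = m$group[i], mas_side = m$mas_side[i],
               ai_r2brrc_100 = r2brrc_ai(cv_mas, cv_las, 100),
               ai_r2brrc_150 = r2brrc_ai(cv_mas, cv_las, 150),
               ai_r2brrc_200 = r2brrc_ai(cv_mas, cv_las, 200),
               ai_mri = mri_ai(hm, m$mas_side[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
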