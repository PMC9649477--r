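## Synthetic paired-stimulation EMG sweeps.  The waveform model is a
## package convention chosen so the extraction stack closes the loop
## exactly in the noise-free case: stimulus artifact at the onset, a small
## R1 complex early, and an R2 complex as a damped sinusoid compactly
## supported on the R2 window, rescaled so its sampled peak-to-peak
## amplitude equals the programmed value before noise is added.

# damped-sine R2 complex added in place; support [onset+start, onset+end] ms
add_r2_complex <- function(samples, sampling_rate, onset_ms, ptp_uv,
                           start_ms = 27, end_ms = 87,
                           freq_hz = 60, tau_ms = 22) {
  if (ptp_uv <= 0) return(samples)
  n <- length(samples)
  t_ms <- (seq_len(n) - 1L) * 1000 / sampling_rate
  rel <- t_ms - onset_ms - start_ms
  idx <- which(rel >= 0 & t_ms <= onset_ms + end_ms)
  if (length(idx) < 2L)
    stop("add_r2_complex(): R2 window holds fewer than two samples", call. = FALSE)
  w <- sin(2 * pi * freq_hz * rel[idx] / 1000) * exp(-rel[idx] / tau_ms)
  span <- max(w) - min(w)
  samples[idx] <- samples[idx] + w * (ptp_uv / span)
  samples
}

add_stim_artifact <- function(samples, sampling_rate, onset_ms, amp_uv = 300) {
  n <- length(samples)
  t_ms <- (seq_len(n) - 1L) * 1000 / sampling_rate
  idx <- which(t_ms >= onset_ms & t_ms <= onset_ms + 1.5)
  samples[idx] <- samples[idx] + amp_uv * exp(-(t_ms[idx] - onset_ms) / 0.4)
  samples
}

# small ipsilateral R1 complex, support [onset+8, onset+16] ms
add_r1_complex <- function(samples, sampling_rate, onset_ms, amp_uv = 60) {
  add_r2_complex(samples, sampling_rate, onset_ms, amp_uv,
                 start_ms = 8, end_ms = 16, freq_hz = 180, tau_ms = 5)
}

synth_sweep <- function(stim_side, onsets_ms, duration_ms, target_r2_uv,
                        config) {
  fs <- config$sampling_rate_hz
  n <- floor(duration_ms * fs / 1000) + 1L
  s <- numeric(n)
  for (k in seq_along(onsets_ms)) {
    s <- add_stim_artifact(s, fs, onsets_ms[k])
    s <- add_r1_complex(s, fs, onsets_ms[k])
    s <- add_r2_complex(s, fs, onsets_ms[k], target_r2_uv[k])
  }
  if (config$noise_sd_uv > 0)
    s <- s + stats::rnorm(n, 0, config$noise_sd_uv)
  emg_trace(s, fs, onsets_ms, stim_side = stim_side,
            record_side = "ipsilateral")
}

#' Synthesise a paired-stimulation EMG battery for one patient
#'
#' Builds, for each stimulation side, the unconditioned single-stimulus
#' sweeps and the conditioned paired-stimulation sweeps over the full ISI
#' battery, with the conditioned R2 complex programmed at
#' `target ratio x unconditioned amplitude` before noise.  Running
#' [build_recovery_cycle()] on the output recovers the programmed ratios
#' (exactly when `noise_sd_uv = 0`).
#'
#' @param target_curves Named list with [r2_recovery_curve] targets `MAS`
#'   and `LAS`, e.g. from [target_recovery_curves()].
#' @param config A [cohort_config] supplying amplitude, noise, sampling
#'   rate and trial counts.
#' @param isis ISI battery (ms) that must be covered by both targets.
#' @return Named list (`MAS`, `LAS`) of sweep batteries, each a list of
#'   [emg_trace] objects.
#' @export
generate_blink_traces <- function(target_curves, config = cohort_config(),
                                  isis = ISI_BATTERY) {
  stopifnot(is.list(target_curves),
            all(c("MAS", "LAS") %in% names(target_curves)))
  pre_ms <- 10  # baseline before the (first) stimulus
  post_ms <- 100  # must cover the R2 window after the last stimulus
  out <- list()
  for (side in c("MAS", "LAS")) {
    curve <- target_curves[[side]]
    stopifnot(inherits(curve, "r2_recovery_curve"))
    have <- as.numeric(names(curve$ratios))
    miss <- setdiff(isis, have)
    if (length(miss) > 0L)
      stop(sprintf("generate_blink_traces(): %s target curve missing ISI(s) %s ms",
                   side, paste(miss, collapse = ", ")), call. = FALSE)
    battery <- list()
    for (k in seq_len(config$n_uncond_trials))
      battery[[length(battery) + 1L]] <-
        synth_sweep(side, pre_ms, pre_ms + post_ms, config$amplitude_uv, config)
    for (isi in isis) {
      ratio <- curve$ratios[[as.character(isi)]]
      if (ratio < 0)
        stop("generate_blink_traces(): target ratios must be >= 0", call. = FALSE)
      cond_uv <- config$amplitude_uv * ratio / 100
      for (k in seq_len(config$n_trials))
        battery[[length(battery) + 1L]] <-
          synth_sweep(side, c(pre_ms, pre_ms + isi), pre_ms + isi + post_ms,
                      c(config$amplitude_uv, cond_uv), config)
    }
    out[[side]] <- battery
  }
  out
}

#' Write / read one EMG battery as plain-text trace files
#'
#' The interchange layout is one directory per patient with one
#' sub-directory per stimulation side; each sweep is a CSV with columns
#' `time_ms`, `amplitude_uv` (file `uncond_<k>.csv` or `isi<ISI>_<k>.csv`)
#' and a JSON sidecar of the same stem carrying `sampling_rate_hz` and
#' `stimulus_onsets_ms`.
#'
#' @param battery Named list (`MAS`, `LAS`) of [emg_trace] lists.
#' @param dir Patient directory to write into (created if needed).
#' @return `write_trace_battery()` the directory (invisibly);
#'   `read_trace_battery()` the battery list.
#' @export
write_trace_battery <- function(battery, dir) {
  for (side in names(battery)) {
    sd_dir <- file.path(dir, side)
    dir.create(sd_dir, recursive = TRUE, showWarnings = FALSE)
    counters <- new.env(parent = emptyenv())
    for (tr in battery[[side]]) {
      stem <- if (length(tr$stimulus_onsets) == 1L) "uncond" else
        sprintf("isi%d", as.integer(round(diff(tr$stimulus_onsets))))
      k <- (if (is.null(counters[[stem]])) 0L else counters[[stem]]) + 1L
      counters[[stem]] <- k
      base <- file.path(sd_dir, sprintf("%s_%d", stem, k))
      t_ms <- (seq_along(tr$samples) - 1L) * 1000 / tr$sampling_rate
      utils::write.csv(data.frame(time_ms = t_ms, amplitude_uv = tr$samples),
                       paste0(base, ".csv"), row.names = FALSE)
      jsonlite::write_json(list(sampling_rate_hz = tr$sampling_rate,
                                stimulus_onsets_ms = tr$stimulus_onsets,
                                stim_side = tr$stim_side,
                                record_side = tr$record_side),
                           paste0(base, ".json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(dir)
}

#' @rdname write_trace_battery
#' @export
read_trace_battery <- function(dir) {
  sides <- intersect(c("MAS", "LAS"), list.dirs(dir, recursive = FALSE,
                                                full.names = FALSE))
  if (length(sides) == 0L)
    stop(sprintf("read_trace_battery(): no MAS/LAS sub-directories under %s", dir),
         call. = FALSE)
  out <- list()
  for (side in sides) {
    files <- sort(list.files(file.path(dir, side), pattern = "\\.csv$",
                             full.names = TRUE))
    out[[side]] <- lapply(files, function(f) {
      meta <- jsonlite::read_json(sub("\\.csv$", ".json", f),
                                  simplifyVector = TRUE)
      dat <- utils::read.csv(f)
      emg_trace(dat$amplitude_uv, meta$sampling_rate_hz,
                meta$stimulus_onsets_ms,
                stim_side = meta$stim_side, record_side = meta$record_side)
    })
  }
  out
}
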