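#' One EMG sweep from orbicularis oculi recording
#'
#' A single recorded sweep of surface EMG following supraorbital nerve
#' stimulation.  Unconditioned sweeps carry one stimulus onset; conditioned
#' (paired-stimulation) sweeps carry two, the conditioning and the test
#' stimulus, whose separation is the interstimulus interval (ISI).
#'
#' @param samples Numeric vector of amplitudes (microvolt), sampled at
#'   `sampling_rate`; time 0 is the first sample.
#' @param sampling_rate Sampling rate in Hz.
#' @param stimulus_onsets Stimulus times in ms, strictly increasing, within
#'   the sweep; length 1 (unconditioned) or 2 (conditioned).
#' @param stim_side Stimulated body side relative to the clinical
#'   lateralisation: `"MAS"` or `"LAS"`.
#' @param record_side Recorded muscle relative to the stimulated side:
#'   `"ipsilateral"` or `"contralateral"`.
#' @return An object of class `emg_trace`.
#' @export
emg_trace <- function(samples, sampling_rate, stimulus_onsets,
                      stim_side = c("MAS", "LAS"),
                      record_side = c("ipsilateral", "contralateral")) {
  stim_side <- match.arg(stim_side)
  record_side <- match.arg(record_side)
  if (!is.numeric(samples) || !all(is.finite(samples)))
    stop("emg_trace(): samples must be finite numeric", call. = FALSE)
  if (!is.finite(sampling_rate) || sampling_rate <= 0)
    stop("emg_trace(): sampling_rate must be positive", call. = FALSE)
  dur_ms <- 1000 * (length(samples) - 1L) / sampling_rate
  if (length(stimulus_onsets) < 1L || any(diff(stimulus_onsets) <= 0) ||
      any(stimulus_onsets < 0) || any(stimulus_onsets > dur_ms))
    stop("emg_trace(): stimulus onsets must be strictly increasing and within the sweep",
         call. = FALSE)
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate,
                 stimulus_onsets = as.numeric(stimulus_onsets),
                 stim_side = stim_side, record_side = record_side),
            class = "emg_trace")
}

#' @export
print.emg_trace <- function(x, ...) {
  cat(sprintf("<emg_trace> %d samples @ %g Hz, %s-stimulation, %s recording, onsets %s ms\n",
              length(x$samples), x$sampling_rate, x$stim_side, x$record_side,
              paste(x$stimulus_onsets, collapse = ", ")))
  invisible(x)
}

#' Latency window relative to a stimulus onset
#'
#' Bounds (ms after a stimulus) within which a response component is
#' measured.  No canonical R2 window is universal; the package default
#' (27--87 ms) follows conventional blink-reflex practice and is
#' configurable everywhere it is used.
#'
#' @param start_ms,end_ms Window bounds in ms, `0 <= start_ms < end_ms`.
#' @return An object of class `response_window`.
#' @export
response_window <- function(start_ms = 27, end_ms = 87) {
  if (!is.finite(start_ms) || !is.finite(end_ms) ||
      start_ms < 0 || start_ms >= end_ms)
    stop("response_window(): need 0 <= start_ms < end_ms", call. = FALSE)
  structure(list(start_ms = start_ms, end_ms = end_ms),
            class = "response_window")
}

#' R2 peak-to-peak amplitude within a response window
#'
#' Measures `max - min` of the raw sweep inside the window anchored at the
#' indexed stimulus onset.  No rectification or filtering is applied: the
#' recording-chain filters are treated as properties of the input data.
#'
#' @param trace An [emg_trace].
#' @param stimulus_index Which stimulus onset anchors the window (1-based);
#'   2 selects the test stimulus of a conditioned sweep.
#' @param window A [response_window]; default the package R2 window.
#' @return Peak-to-peak amplitude in microvolt (non-negative).
#' @export
r2_peak_to_peak <- function(trace, stimulus_index = length(trace$stimulus_onsets),
                            window = response_window()) {
  stopifnot(inherits(trace, "emg_trace"), inherits(window, "response_window"))
  if (stimulus_index < 1L || stimulus_index > length(trace$stimulus_onsets))
    stop("r2_peak_to_peak(): stimulus_index out of range", call. = FALSE)
  onset <- trace$stimulus_onsets[stimulus_index]
  t0 <- onset + window$start_ms
  t1 <- onset + window$end_ms
  i0 <- ceiling(t0 * trace$sampling_rate / 1000) + 1L
  i1 <- floor(t1 * trace$sampling_rate / 1000) + 1L
  if (i0 < 1L || i1 > length(trace$samples))
    stop(sprintf("r2_peak_to_peak(): window %g-%g ms after onset %g ms lies outside the sweep",
                 window$start_ms, window$end_ms, onset), call. = FALSE)
  if (i1 < i0)
    stop("r2_peak_to_peak(): window contains no samples at this sampling rate",
         call. = FALSE)
  seg <- trace$samples[i0:i1]
  max(seg) - min(seg)
}

#' Recovery ratio of conditioned to unconditioned R2 amplitude
#'
#' The percentage ratio between the R2 peak-to-peak amplitude of the
#' conditioned (test-stimulus) response and that of the unconditioned
#' response.  Values above 100 are possible (facilitation).
#'
#' @param conditioned_amp,unconditioned_amp Peak-to-peak amplitudes
#'   (microvolt); `unconditioned_amp` must be positive.
#' @return Recovery ratio in percent.
#' @export
recovery_ratio <- function(conditioned_amp, unconditioned_amp) {
  if (!is.finite(conditioned_amp) || conditioned_amp < 0)
    stop("recovery_ratio(): conditioned amplitude must be finite and >= 0",
         call. = FALSE)
  if (!is.finite(unconditioned_amp) || unconditioned_amp <= 0)
    stop("recovery_ratio(): unconditioned R2 amplitude must be positive (degenerate baseline response)",
         call. = FALSE)
  100 * conditioned_amp / unconditioned_amp
}

#' The standard paired-stimulation ISI battery (ms)
#' @export
ISI_BATTERY <- c(100L, 150L, 200L, 300L, 400L, 500L, 750L)

#' R2 recovery-cycle curve for one side of stimulation
#'
#' @param stim_side `"MAS"` or `"LAS"`.
#' @param ratios Named numeric vector or list, ISI (ms) -> recovery ratio (%).
#' @param unconditioned_amplitude Mean unconditioned R2 peak-to-peak
#'   amplitude (microvolt) the ratios were computed against.
#' @param window_overlap ISIs (ms) at which the test-stimulus window may
#'   overlap late conditioning-response activity; metadata only.
#' @return An object of class `r2_recovery_curve`.
#' @export
r2_recovery_curve <- function(stim_side, ratios, unconditioned_amplitude = NA_real_,
                              window_overlap = integer()) {
  stim_side <- match.arg(stim_side, c("MAS", "LAS"))
  ratios <- as.list(ratios)
  if (is.null(names(ratios)) || any(!nzchar(names(ratios))))
    stop("r2_recovery_curve(): ratios must be named by ISI (ms)", call. = FALSE)
  vals <- unlist(ratios)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("r2_recovery_curve(): ratios must be finite and >= 0", call. = FALSE)
  ratios <- ratios[order(as.numeric(names(ratios)))]
  structure(list(stim_side = stim_side, ratios = ratios,
                 unconditioned_amplitude = unconditioned_amplitude,
                 window_overlap = window_overlap),
            class = "r2_recovery_curve")
}

#' @export
print.r2_recovery_curve <- function(x, ...) {
  cat(sprintf("<r2_recovery_curve> %s stimulation\n", x$stim_side))
  print(round(unlist(x$ratios), 1))
  invisible(x)
}

#' Build the R2 recovery cycle from a paired-stimulation sweep battery
#'
#' Groups the battery's sweeps of one stimulation side into unconditioned
#' (single-onset) sweeps and conditioned sweeps per ISI, extracts R2
#' peak-to-peak amplitudes, and forms one recovery ratio per ISI.  With the
#' default `trials_policy = "mean_amplitude"`, amplitudes are averaged across
#' trials *before* the ratio is taken (the ratio of mean amplitudes), which
#' is stable when individual conditioned responses are near zero;
#' `"mean_ratio"` instead averages per-trial ratios.
#'
#' @param battery List of [emg_trace] sweeps, all with the same `stim_side`.
#' @param window [response_window] for the R2 complex (applied to the last
#'   onset of every sweep).
#' @param isis ISIs (ms) the battery must cover; default [ISI_BATTERY].
#' @param trials_policy `"mean_amplitude"` (default) or `"mean_ratio"`.
#' @param isi_tol Tolerance (ms) when matching a sweep's onset separation to
#'   a battery ISI.
#' @return An [r2_recovery_curve] complete over `isis`.
#' @export
build_recovery_cycle <- function(battery, window = response_window(),
                                 isis = ISI_BATTERY,
                                 trials_policy = c("mean_amplitude", "mean_ratio"),
                                 isi_tol = 0.5) {
  trials_policy <- match.arg(trials_policy)
  stopifnot(length(battery) > 0L)
  ok <- vapply(battery, inherits, logical(1), what = "emg_trace")
  if (!all(ok)) stop("build_recovery_cycle(): battery must contain emg_trace objects",
                     call. = FALSE)
  sides <- unique(vapply(battery, `[[`, character(1), "stim_side"))
  if (length(sides) != 1L)
    stop("build_recovery_cycle(): battery mixes stimulation sides; build one curve per side",
         call. = FALSE)
  n_onsets <- vapply(battery, function(tr) length(tr$stimulus_onsets), integer(1))
  uncond <- battery[n_onsets == 1L]
  cond <- battery[n_onsets == 2L]
  if (length(uncond) == 0L)
    stop("build_recovery_cycle(): no unconditioned (single-stimulus) sweep in battery",
         call. = FALSE)
  sweep_isi <- vapply(cond, function(tr) diff(tr$stimulus_onsets), numeric(1))

  uncond_amps <- vapply(uncond, r2_peak_to_peak, numeric(1),
                        stimulus_index = 1L, window = window)
  uncond_mean <- mean(uncond_amps)
  if (uncond_mean <= 0)
    stop("build_recovery_cycle(): unconditioned R2 amplitude is zero (degenerate baseline response)",
         call. = FALSE)

  ratios <- setNames(numeric(length(isis)), as.character(isis))
  missing <- character(0)
  for (isi in isis) {
    sel <- cond[abs(sweep_isi - isi) <= isi_tol]
    if (length(sel) == 0L) { missing <- c(missing, as.character(isi)); next }
    amps <- vapply(sel, r2_peak_to_peak, numeric(1),
                   stimulus_index = 2L, window = window)
    ratios[[as.character(isi)]] <- switch(trials_policy,
      mean_amplitude = recovery_ratio(mean(amps), uncond_mean),
      mean_ratio = mean(vapply(amps, recovery_ratio, numeric(1),
                               unconditioned_amp = uncond_mean)))
  }
  if (length(missing) > 0L)
    stop(sprintf("build_recovery_cycle(): battery incomplete, missing ISI(s) %s ms",
                 paste(missing, collapse = ", ")), call. = FALSE)
  # late conditioning-response activity can outlast the nominal R2 window;
  # flag short ISIs whose test window opens before ~150 ms post-conditioning
  overlap <- isis[isis + window$start_ms < 150]
  r2_recovery_curve(sides, ratios, unconditioned_amplitude = uncond_mean,
                    window_overlap = as.integer(overlap))
}
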