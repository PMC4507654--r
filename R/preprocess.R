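## Zero-phase IIR filtering with odd (endpoint-mirrored) reflective padding.
## The pad length is expressed in time constants of the filter's slowest
## corner frequency; transients from the forward and backward passes decay
## inside the pad and the padded ends are discarded.
zero_phase_filter <- function(flt, x, fs, corner_hz, pad_tc = 10) {
  n <- length(x)
  pad <- ceiling(pad_tc * fs / (2 * pi * corner_hz))
  if (n < pad + 2L)
    stop("signal shorter than the filter warm-up (", pad, " samples)")
  # filter relative to the first sample so start-up transients scale with
  # the signal's excursion, not its absolute level; the offset is restored
  # through the filter's DC gain (squared for the two passes)
  x0 <- x[1]
  x <- x - x0
  g0 <- sum(flt$b) / sum(flt$a)
  xp <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- as.numeric(signal::filter(flt, xp))
  y <- rev(as.numeric(signal::filter(flt, rev(y))))
  y[(pad + 1L):(pad + n)] + g0^2 * x0
}

#' Detrend a cuff-pressure signal into the pulsatile oscillometric waveform
#'
#' Applies a first-order Butterworth band-pass (default 0.5-5 Hz) forward and
#' backward, giving a zero-phase, effectively second-order response that
#' suppresses the DC level and the slow deflation ramp while passing the
#' heart-beat-locked oscillations. Edge transients are handled by odd
#' reflective padding (`pad_tc` time constants of the low corner).
#'
#' @param cp cuff-pressure series, mmHg.
#' @param fs sampling rate, Hz (> 10).
#' @param band band edges, Hz.
#' @param pad_tc reflective pad length in time constants of `band[1]`.
#' @return the oscillometric waveform (OMW), same length as `cp`, mmHg.
#' @export
detrend_oscillometric <- function(cp, fs, band = c(0.5, 5), pad_tc = 10) {
  stopifnot(fs > 10, band[1] > 0, band[2] > band[1], band[2] < fs / 2)
  flt <- signal::butter(1, band / (fs / 2), type = "pass")
  zero_phase_filter(flt, cp, fs, band[1], pad_tc)
}

#' Low-pass estimate of the cuff-deflation baseline
#'
#' Zero-phase second-order Butterworth low-pass (default cutoff 0.3 Hz)
#' isolating the deflation trend from the cardiac oscillations. Used for the
#' pressure axis of the envelope (`cp_at_peak`) and for the sudden
#' pressure-rise artifact rule.
#'
#' @inheritParams detrend_oscillometric
#' @param cutoff low-pass cutoff, Hz.
#' @param order Butterworth order per pass.
#' @return baseline series, same length as `cp`, mmHg.
#' @export
lowpass_cuff_baseline <- function(cp, fs, cutoff = 0.3, order = 2,
                                  pad_tc = 10) {
  stopifnot(fs > 10, cutoff > 0, cutoff < fs / 2)
  flt <- signal::butter(order, cutoff / (fs / 2), type = "low")
  zero_phase_filter(flt, cp, fs, cutoff, pad_tc)
}

#' Segment the oscillometric waveform into per-beat pulses
#'
#' One pulse per consecutive R-peak pair: the pulse span is the half-open
#' sample interval between the two R-peaks, the peak/bottom are the extrema
#' of the OMW within the span, and the two peak-to-trough heights are taken
#' against the troughs preceding and following the peak inside the span.
#' The cuff pressure at the peak is read from the low-passed baseline, not
#' from the raw signal, so the envelope's pressure axis is free of
#' oscillation.
#'
#' @param omw oscillometric waveform from [detrend_oscillometric()].
#' @param rec the source `cuff_recording` (supplies `fs` and `r_peaks`).
#' @param baseline optional precomputed [lowpass_cuff_baseline()] of
#'   `rec$cp`; computed on demand when `NULL`.
#' @return a data frame of class `bp_pulses`, one row per pulse, with columns
#'   `start`, `end` (half-open span, samples), `peak_idx`, `t_peak` (s),
#'   `peak_value`, `bottom_value`, `pk2bt_prev`, `pk2bt_next`, `cp_at_peak`
#'   (mmHg), `outlier` (logical) and `reason`.
#' @export
segment_pulses <- function(omw, rec, baseline = NULL) {
  stopifnot(inherits(rec, "cuff_recording"), length(omw) == length(rec$cp))
  rp <- rec$r_peaks
  if (length(rp) < 2L) stop("at least 2 R-peaks are required")
  if (is.null(baseline)) baseline <- lowpass_cuff_baseline(rec$cp, rec$fs)
  m <- length(rp) - 1L
  out <- data.frame(start = rp[-length(rp)], end = rp[-1L],
                    peak_idx = NA_integer_, t_peak = NA_real_,
                    peak_value = NA_real_, bottom_value = NA_real_,
                    pk2bt_prev = NA_real_, pk2bt_next = NA_real_,
                    cp_at_peak = NA_real_,
                    outlier = FALSE, reason = NA_character_)
  for (k in seq_len(m)) {
    seg <- out$start[k]:(out$end[k] - 1L)
    pk <- seg[which.max(omw[seg])]
    out$peak_idx[k] <- pk
    out$t_peak[k] <- (pk - 1) / rec$fs
    out$peak_value[k] <- omw[pk]
    out$bottom_value[k] <- min(omw[seg])
    out$pk2bt_prev[k] <- omw[pk] - min(omw[seg[1L]:pk])
    out$pk2bt_next[k] <- omw[pk] - min(omw[pk:seg[length(seg)]])
    out$cp_at_peak[k] <- baseline[pk]
  }
  class(out) <- c("bp_pulses", "data.frame")
  out
}
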