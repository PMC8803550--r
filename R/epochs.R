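#' Epoch a recording around trigger events
#'
#' Extracts fixed-length trials around each event onset. Events whose window
#' would exit the record are dropped and logged.
#'
#' @param rec an `opm_recording`.
#' @param events an `opm_events` table.
#' @param t_pre seconds before onset (positive number).
#' @param t_post seconds after onset.
#' @return an object of class `opm_epochs`: `data` (trials x channels x
#'   times array, tesla), `times` (seconds relative to onset, includes 0),
#'   `channels`, `codes`, `onset_sample` per retained trial, `fs`,
#'   `dropped` log, and the recording's rank deficit.
#' @export
epoch_by_trigger <- function(rec, events, t_pre, t_post) {
  validate_recording(rec)
  if (nrow(events) == 0) stop("no events to epoch")
  n_pre <- round(t_pre * rec$fs)
  n_post <- round(t_post * rec$fs)
  n <- ncol(rec$data)
  ok <- events$onset_sample - n_pre >= 1 &
    events$onset_sample + n_post <= n
  dropped <- events[!ok, , drop = FALSE]
  kept <- events[ok, , drop = FALSE]
  if (nrow(kept) == 0) stop("every event window exits the record")
  times <- (-n_pre:n_post) / rec$fs
  n_t <- length(times)
  idx <- channel_idx(rec)
  dat <- array(0, c(nrow(kept), length(idx), n_t))
  for (k in seq_len(nrow(kept))) {
    span <- (kept$onset_sample[k] - n_pre):(kept$onset_sample[k] + n_post)
    dat[k, , ] <- rec$data[idx, span]
  }
  structure(list(data = dat, times = times,
                 channels = rec$channels[idx, , drop = FALSE],
                 codes = kept$code, onset_sample = kept$onset_sample,
                 fs = rec$fs, t0 = rec$t0,
                 rank_deficit = rec$rank_deficit %||% 0L,
                 dropped = dropped, rejected = integer(0)),
            class = "opm_epochs")
}

#' @export
print.opm_epochs <- function(x, ...) {
  cat("<opm_epochs> ", dim(x$data)[1], " trials x ", dim(x$data)[2],
      " channels x ", dim(x$data)[3], " samples (",
      sprintf("%.3f", min(x$times)), " to ", sprintf("%.3f", max(x$times)),
      " s)\n", sep = "")
  if (length(x$rejected) > 0)
    cat("  rejected trials: ", length(x$rejected), "\n", sep = "")
  invisible(x)
}

#' Reject trials overlapping artifact segments
#'
#' Removes every trial whose full span (onset - t_pre to onset + t_post, in
#' recording time) intersects any marked artifact segment.
#'
#' @param epochs an `opm_epochs`.
#' @param segments data.frame with `start_s`, `end_s` in recording time
#'   (e.g. from [detect_artifact_segments()]).
#' @return the `opm_epochs` with offending trials removed and the rejection
#'   log updated.
#' @export
reject_artifact_trials <- function(epochs, segments) {
  stopifnot(inherits(epochs, "opm_epochs"))
  if (is.null(segments) || nrow(segments) == 0) return(epochs)
  t_lo <- epochs$t0 + (epochs$onset_sample - 1) / epochs$fs +
    min(epochs$times)
  t_hi <- epochs$t0 + (epochs$onset_sample - 1) / epochs$fs +
    max(epochs$times)
  bad <- vapply(seq_along(t_lo), function(k)
    any(t_lo[k] < segments$end_s & t_hi[k] > segments$start_s),
    logical(1))
  if (!any(bad)) return(epochs)
  out <- epochs
  out$data <- epochs$data[!bad, , , drop = FALSE]
  out$codes <- epochs$codes[!bad]
  out$onset_sample <- epochs$onset_sample[!bad]
  out$rejected <- c(epochs$rejected, which(bad))
  out
}

#' Evoked response t-statistics
#'
#' Baseline-corrects every trial (subtracting the per-trial, per-channel
#' mean over the baseline window) and computes, at every channel and time
#' point, the one-sample t statistic across trials against zero, together
#' with the trial-mean waveform.
#'
#' @param epochs an `opm_epochs` with at least 3 trials.
#' @param baseline `c(t_lo, t_hi)` baseline window in seconds relative to
#'   onset (default the 0.1 s before onset).
#' @return list of class `opm_evoked`: `t` and `mean` (channels x times
#'   matrices), `times`, `channel_names`, `n_trials`. Zero-variance points
#'   yield `Inf`/`NaN` and are flagged in `degenerate`.
#' @export
evoked_tstats <- function(epochs, baseline = c(-0.1, 0)) {
  stopifnot(inherits(epochs, "opm_epochs"))
  n_tr <- dim(epochs$data)[1]
  if (n_tr < 3) stop("evoked t-statistics need at least 3 trials")
  bidx <- which(epochs$times >= baseline[1] & epochs$times <= baseline[2])
  if (length(bidx) == 0) stop("baseline window contains no samples")
  dat <- epochs$data
  bl <- apply(dat[, , bidx, drop = FALSE], c(1, 2), mean)
  dat <- sweep(dat, c(1, 2), bl)
  m <- apply(dat, c(2, 3), mean)
  s <- apply(dat, c(2, 3), stats::sd)
  t_mat <- m / (s / sqrt(n_tr))
  structure(list(t = t_mat, mean = m, times = epochs$times,
                 channel_names = epochs$channels$name, n_trials = n_tr,
                 degenerate = !is.finite(t_mat)),
            class = "opm_evoked")
}

#' @export
print.opm_evoked <- function(x, ...) {
  pk <- which(abs(x$t) == max(abs(x$t), na.rm = TRUE), arr.ind = TRUE)[1, ]
  cat("<opm_evoked> ", nrow(x$t), " channels x ", ncol(x$t),
      " times, ", x$n_trials, " trials\n", sep = "")
  cat("  peak |t| = ", sprintf("%.1f", max(abs(x$t), na.rm = TRUE)),
      " at ", sprintf("%.0f", x$times[pk[2]] * 1000), " ms (",
      x$channel_names[pk[1]], ")\n", sep = "")
  invisible(x)
}

#' Sensor-level SNR gain between two evoked analyses
#'
#' `20 * log10` of the ratio of the maximum absolute t value over channels
#' and the analysis window, after versus before processing. Quantifies the
#' effective SNR increase of a pipeline at the evoked-response peak.
#'
#' @param t_before `opm_evoked` from the unprocessed data.
#' @param t_after `opm_evoked` from the processed data, same channels/times.
#' @param window `c(t_lo, t_hi)` analysis window in seconds.
#' @return gain in dB (scalar).
#' @export
snr_gain_db <- function(t_before, t_after, window) {
  if (!isTRUE(all.equal(t_before$times, t_after$times)))
    stop("snr_gain_db needs matching time axes")
  idx <- which(t_before$times >= window[1] & t_before$times <= window[2])
  if (length(idx) == 0) stop("empty analysis window")
  a <- max(abs(t_after$t[, idx]), na.rm = TRUE)
  b <- max(abs(t_before$t[, idx]), na.rm = TRUE)
  if (b == 0) stop("zero denominator in SNR gain")
  20 * log10(a / b)
}

#' Hanning-taper time-frequency analysis
#'
#' Sliding-window single-Hann-taper spectral power per trial, averaged
#' across trials, so the result pools phase-locked (evoked) and
#' non-phase-locked (induced) activity. The first and last `trim_s` of each
#' trial are discarded to avoid edge artifacts.
#'
#' @param epochs an `opm_epochs`.
#' @param freqs analysis frequencies in Hz (default 1 to 41 in steps of 2).
#' @param window_s taper window length in seconds (default 0.5).
#' @param step_s sliding step (default 0.05).
#' @param trim_s edge trim per trial (default 0.5).
#' @return object of class `opm_tfr`: `power` (channels x freqs x times,
#'   T^2/Hz), `freqs`, `times`, `channel_names`, `taper = "hanning"`.
#' @export
tfr_hanning <- function(epochs, freqs = seq(1, 41, by = 2), window_s = 0.5,
                        step_s = 0.05, trim_s = 0.5) {
  stopifnot(inherits(epochs, "opm_epochs"))
  fs <- epochs$fs
  if (any(freqs >= fs / 2)) stop("analysis frequencies above Nyquist")
  n_t <- dim(epochs$data)[3]
  L <- round(window_s * fs)
  t_lo <- min(epochs$times) + trim_s
  t_hi <- max(epochs$times) - trim_s
  if (t_hi - t_lo < window_s)
    stop("trial too short for the window after trimming")
  centres <- seq(t_lo + window_s / 2, t_hi - window_s / 2, by = step_s)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / L)
  u <- sum(w^2)
  tt <- (seq_len(L) - 1) / fs
  # complex Hann-tapered kernels, one column per frequency
  kern <- sapply(freqs, function(f) w * exp(-2i * pi * f * tt))
  n_ch <- dim(epochs$data)[2]
  n_tr <- dim(epochs$data)[1]
  pow <- array(0, c(n_ch, length(freqs), length(centres)))
  for (tr in seq_len(n_tr)) {
    x <- matrix(epochs$data[tr, , ], n_ch, n_t)
    for (j in seq_along(centres)) {
      s0 <- round((centres[j] - window_s / 2 - min(epochs$times)) * fs) + 1
      seg <- x[, s0:(s0 + L - 1), drop = FALSE]
      X <- seg %*% kern                       # n_ch x n_freq, complex
      pow[, , j] <- pow[, , j] + 2 * Mod(X)^2 / (fs * u)
    }
  }
  pow <- pow / n_tr
  structure(list(power = pow, freqs = freqs, times = centres,
                 channel_names = epochs$channels$name, taper = "hanning",
                 scale = "power"),
            class = "opm_tfr")
}

#' @export
print.opm_tfr <- function(x, ...) {
  cat("<opm_tfr> ", dim(x$power)[1], " channels x ", length(x$freqs),
      " freqs x ", length(x$times), " times (", x$scale, ")\n", sep = "")
  invisible(x)
}

#' Baseline-correct a TFR to decibels
#'
#' Per channel and frequency: `10 * log10(P(t) / mean P over baseline)`.
#'
#' @param tfr an `opm_tfr` on the power scale.
#' @param baseline `c(t_lo, t_hi)` baseline window in seconds.
#' @return an `opm_tfr` with `power` in dB relative to baseline.
#' @export
baseline_db <- function(tfr, baseline) {
  stopifnot(inherits(tfr, "opm_tfr"))
  if (!identical(tfr$scale, "power"))
    stop("baseline_db expects a power-scale TFR")
  bidx <- which(tfr$times >= baseline[1] & tfr$times <= baseline[2])
  if (length(bidx) == 0) stop("baseline window outside the TFR times")
  base <- apply(tfr$power[, , bidx, drop = FALSE], c(1, 2), mean)
  if (any(base <= 0)) stop("zero baseline power")
  out <- tfr
  out$power <- 10 * log10(sweep(tfr$power, c(1, 2), base, "/"))
  out$scale <- "dB"
  out
}
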