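# zero-phase Butterworth on a single vector with odd reflective padding;
# pad length scales with the impulse-response time constant of the lowest
# cutoff so the forward-backward passes settle before the data start.
# Band-pass is realised as a high-pass/low-pass cascade: single-cutoff
# transfer functions stay numerically stable at low normalised cutoffs
# where a direct band-pass polynomial of the same order does not.
zerophase_filter_vec <- function(x, fs, kind, cutoff, order) {
  nyq <- fs / 2
  if (any(cutoff <= 0) || any(cutoff >= nyq))
    stop("cutoff must lie strictly inside (0, Nyquist)")
  if (order < 1) stop("filter order must be >= 1")
  if (kind == "bandpass") {
    if (length(cutoff) != 2 || cutoff[1] >= cutoff[2])
      stop("bandpass needs cutoff = c(lo, hi) with lo < hi")
    y <- zerophase_filter_vec(x, fs, "highpass", cutoff[1], order)
    return(zerophase_filter_vec(y, fs, "lowpass", cutoff[2], order))
  }
  type <- switch(kind, highpass = "high", lowpass = "low",
                 stop("unknown filter kind: ", kind))
  flt <- signal::butter(order, cutoff / nyq, type = type)
  n <- length(x)
  pad <- min(n - 1, ceiling(3 * fs / min(cutoff)))
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::filter(flt, xp)
  y <- rev(as.numeric(signal::filter(flt, rev(as.numeric(y)))))
  y[(pad + 1):(pad + n)]
}

#' Zero-phase Butterworth filtering of a recording
#'
#' Applies a Butterworth filter forward and backward (zero phase shift) to
#' every magnetometer channel, with odd reflective padding at least three
#' impulse-response time constants long so edges settle. Trigger channels
#' pass through untouched. Filters must be applied to continuous data;
#' epoched data are refused (filter them before epoching to avoid edge
#' artifacts inside every trial).
#'
#' @param rec an `opm_recording`.
#' @param kind `"highpass"`, `"lowpass"`, or `"bandpass"`.
#' @param cutoff cutoff frequency in Hz (two values for bandpass).
#' @param order filter order (per pass; the bidirectional application
#'   doubles the effective roll-off).
#' @return the filtered `opm_recording`.
#' @export
butter_zerophase <- function(rec, kind = c("highpass", "lowpass", "bandpass"),
                             cutoff, order = 5) {
  if (inherits(rec, "opm_epochs"))
    stop("temporal filters must be applied to continuous data, not epochs")
  validate_recording(rec)
  kind <- match.arg(kind)
  if (kind == "bandpass" && length(cutoff) != 2)
    stop("bandpass needs two cutoff frequencies")
  out <- rec
  for (i in channel_idx(rec))
    out$data[i, ] <- zerophase_filter_vec(rec$data[i, ], rec$fs, kind,
                                          cutoff, order)
  append_history(out, "butter_zerophase",
                 list(kind = kind, cutoff = cutoff, order = order))
}

#' Spectral interpolation of narrow-band interference
#'
#' An alternative to notch filtering suited to interference whose amplitude
#' drifts over time: in the full-record DFT, every bin within `halfwidth` of
#' a target frequency has its amplitude replaced by the mean amplitude over
#' the two flanking bands, keeping its phase; the data are then inverse
#' transformed. Conjugate symmetry is enforced so the output is real.
#'
#' @param rec an `opm_recording` (continuous data).
#' @param targets interference frequencies in Hz.
#' @param halfwidth half width of the replaced band in Hz (default 0.5, i.e.
#'   a 1 Hz bandwidth around each target).
#' @param neighbour_width width of each flanking band in Hz (default 1, i.e.
#'   +/- 1 Hz either side).
#' @return the interpolated `opm_recording`.
#' @export
spectral_interpolate <- function(rec, targets, halfwidth = 0.5,
                                 neighbour_width = 1.0) {
  if (inherits(rec, "opm_epochs"))
    stop("spectral interpolation needs continuous data, not epochs")
  validate_recording(rec)
  nyq <- rec$fs / 2
  targets <- sort(as.numeric(targets))
  if (any(targets - halfwidth - neighbour_width <= 0) ||
      any(targets + halfwidth + neighbour_width >= nyq))
    stop("targets and neighbour bands must lie inside (0, Nyquist)")
  # a target's notch band must not collide with another target's notch or
  # flanking bands
  if (length(targets) > 1) {
    for (i in seq_along(targets)) for (j in seq_along(targets)) {
      if (i == j) next
      span_i <- c(targets[i] - halfwidth - neighbour_width,
                  targets[i] + halfwidth + neighbour_width)
      notch_j <- c(targets[j] - halfwidth, targets[j] + halfwidth)
      if (notch_j[1] < span_i[2] && notch_j[2] > span_i[1])
        stop("target/neighbour band collision between ", targets[i],
             " Hz and ", targets[j], " Hz")
    }
  }
  n0 <- ncol(rec$data)
  # pad (odd reflection) to a 2-3-5-smooth length: the mixed-radix FFT
  # degrades badly when the record length has a large prime factor
  n <- stats::nextn(n0, c(2, 3, 5))
  pad <- n - n0
  freqs <- (seq_len(n) - 1) * rec$fs / n
  half <- freqs <= nyq  # positive-frequency half (plus DC)
  out <- rec
  for (i in channel_idx(rec)) {
    x <- rec$data[i, ]
    if (pad > 0)
      x <- c(x, 2 * x[n0] - x[n0 - seq_len(pad)])
    X <- stats::fft(x)
    amp <- Mod(X)
    for (f0 in targets) {
      inside <- half & abs(freqs - f0) <= halfwidth
      flank <- half & ((freqs >= f0 - halfwidth - neighbour_width &
                          freqs < f0 - halfwidth) |
                         (freqs > f0 + halfwidth &
                            freqs <= f0 + halfwidth + neighbour_width))
      if (!any(inside) || !any(flank)) next
      repl <- mean(amp[flank])
      k <- which(inside)
      phase <- X[k] / ifelse(amp[k] > 0, amp[k], 1)
      phase[amp[k] == 0] <- 1
      X[k] <- repl * phase
      # mirror bins (conjugate symmetry); bin 1 is DC, bin m maps to n-m+2
      mk <- k[k > 1]
      X[n - mk + 2] <- Conj(X[mk])
    }
    y <- stats::fft(X, inverse = TRUE) / n
    if (max(abs(Im(y))) > 1e-10 * max(abs(Re(y)), 1e-300))
      warning("spectral_interpolate: imaginary residue above tolerance")
    out$data[i, ] <- Re(y)[seq_len(n0)]
  }
  append_history(out, "spectral_interpolate",
                 list(targets = targets, halfwidth = halfwidth,
                      neighbour_width = neighbour_width))
}

#' Windowed polynomial detrending
#'
#' Fits a low-order polynomial to each channel in overlapping windows and
#' subtracts it, blending windows with a raised-cosine cross-fade. An
#' offline alternative to high-pass filtering; the robust option iteratively
#' reweights with Tukey's biweight so glitches and railing segments do not
#' drag the fit.
#'
#' @param rec an `opm_recording`.
#' @param poly_order polynomial order (0 = windowed mean removal).
#' @param window_s window length in seconds.
#' @param overlap window overlap fraction (default 0.5).
#' @param robust use iteratively reweighted (Tukey biweight) fitting.
#' @return the detrended `opm_recording`.
#' @export
detrend_windowed <- function(rec, poly_order = 1, window_s, overlap = 0.5,
                             robust = FALSE) {
  validate_recording(rec)
  stopifnot(poly_order >= 0, overlap >= 0, overlap < 1)
  n <- ncol(rec$data)
  L <- round(window_s * rec$fs)
  if (L > n) stop("window longer than the record")
  if (L <= poly_order + 1) stop("window too short for the polynomial order")
  starts <- window_starts(n, L, overlap)
  w_taper <- raised_cosine_weights(L)
  mag <- channel_idx(rec)
  fitted <- matrix(0, length(mag), n)
  wsum <- numeric(n)
  for (s in starts) {
    idx <- s:(s + L - 1)
    tt <- seq(-1, 1, length.out = L)
    X <- if (poly_order >= 1) {
      P <- stats::poly(tt, degree = poly_order, raw = FALSE)
      cbind(1, P[, 1:poly_order, drop = FALSE])
    } else matrix(1, L, 1)
    Y <- t(rec$data[mag, idx, drop = FALSE])
    beta <- qr.solve(X, Y)
    if (robust) {
      for (it in 1:3) {
        res <- Y - X %*% beta
        sc <- apply(res, 2, function(r) stats::mad(r) + 1e-300)
        for (ci in seq_along(mag)) {
          u <- res[, ci] / (4.685 * sc[ci])
          w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
          Xw <- X * sqrt(w)
          beta[, ci] <- qr.solve(Xw, Y[, ci] * sqrt(w))
        }
      }
    }
    fit <- t(X %*% beta)
    fitted[, idx] <- fitted[, idx] + fit * rep(w_taper, each = length(mag))
    wsum[idx] <- wsum[idx] + w_taper
  }
  fitted <- fitted / rep(pmax(wsum, 1e-12), each = length(mag))
  out <- rec
  out$data[mag, ] <- rec$data[mag, , drop = FALSE] - fitted
  append_history(out, "detrend_windowed",
                 list(poly_order = poly_order, window_s = window_s,
                      overlap = overlap, robust = robust))
}

window_starts <- function(n, L, overlap) {
  step <- max(1, round(L * (1 - overlap)))
  starts <- seq(1, max(1, n - L + 1), by = step)
  if (starts[length(starts)] + L - 1 < n)
    starts <- c(starts, n - L + 1)
  starts
}

raised_cosine_weights <- function(L) {
  if (L == 1) return(1)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / (L - 1))
  w + 1e-6  # small floor so single-window edges keep support
}

#' Welch amplitude spectral density
#'
#' Per-channel one-sided Welch estimate: Hann-tapered segments of
#' `window_s` seconds with 50% overlap, periodograms averaged, returned as
#' amplitude spectral density (the square root of the PSD) in fT/sqrt(Hz).
#'
#' @param rec an `opm_recording` at least one window long.
#' @param window_s segment length in seconds (default 10).
#' @param channels optional channel-name subset (default: scalp channels —
#'   reference sensors are off-head and would distort array summaries).
#' @return an object of class `opm_psd`: list with `freqs` (Hz), `asd`
#'   (channels x freqs matrix, fT/sqrt(Hz)), `window_s`, `channel_names`.
#' @export
welch_asd <- function(rec, window_s = 10, channels = NULL) {
  validate_recording(rec)
  n <- ncol(rec$data)
  L <- round(window_s * rec$fs)
  if (L > n) stop("record shorter than one Welch window")
  idx <- if (is.null(channels)) channel_idx(rec, "scalp") else {
    m <- match(channels, rec$channels$name)
    if (anyNA(m)) stop("unknown channel names in welch_asd")
    m
  }
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / L)  # periodic Hann
  u <- sum(w^2)
  starts <- seq(1, n - L + 1, by = max(1, floor(L / 2)))
  n_freq <- floor(L / 2) + 1
  freqs <- (seq_len(n_freq) - 1) * rec$fs / L
  psd <- matrix(0, length(idx), n_freq)
  for (s in starts) {
    seg <- rec$data[idx, s:(s + L - 1), drop = FALSE]
    seg <- seg - rowMeans(seg)
    segw <- seg * rep(w, each = length(idx))
    X <- t(stats::mvfft(t(segw)))[, seq_len(n_freq), drop = FALSE]
    p <- (Mod(X)^2) / (rec$fs * u)
    p[, 2:(n_freq - 1)] <- 2 * p[, 2:(n_freq - 1)]  # one-sided
    psd <- psd + p
  }
  psd <- psd / length(starts)
  structure(list(freqs = freqs, asd = sqrt(psd) * 1e15,
                 window_s = window_s,
                 channel_names = rec$channels$name[idx]),
            class = "opm_psd")
}

#' @export
print.opm_psd <- function(x, ...) {
  cat("<opm_psd> ", nrow(x$asd), " channels x ", length(x$freqs),
      " frequencies (0-", sprintf("%.1f", max(x$freqs)), " Hz, ",
      x$window_s, " s windows)\n", sep = "")
  invisible(x)
}

#' Channel-mean amplitude spectral density
#' @param psd an `opm_psd`.
#' @return numeric vector over frequencies: the RMS-across-channels ASD
#'   (square root of the channel-mean PSD), fT/sqrt(Hz).
#' @export
mean_asd <- function(psd) sqrt(colMeans(psd$asd^2))

#' Interference-suppression gain in dB
#'
#' The shielding-factor metric: `20 * log10(ASD_before / ASD_after)`,
#' elementwise over channels and frequencies. Positive values mean the
#' processing step reduced spectral amplitude at that channel and frequency.
#'
#' @param psd_before `opm_psd` before the step.
#' @param psd_after `opm_psd` after the step, same channels and frequency
#'   grid.
#' @return matrix (channels x freqs) of gains in dB; bins where the
#'   denominator is zero come back `Inf` with a warning.
#' @export
gain_db <- function(psd_before, psd_after) {
  if (!isTRUE(all.equal(psd_before$freqs, psd_after$freqs)) ||
      !identical(psd_before$channel_names, psd_after$channel_names))
    stop("gain_db needs matching frequency axes and channel sets")
  g <- 20 * log10(psd_before$asd / psd_after$asd)
  if (any(is.infinite(g)))
    warning("gain_db: zero-denominator bins flagged as Inf")
  dimnames(g) <- list(psd_before$channel_names, NULL)
  g
}

#' Maximum field change per chunk
#'
#' Splits the record into non-overlapping chunks and reports, per chunk, the
#' maximum over scalp channels of the within-chunk peak-to-peak field, in
#' picotesla. A scalar summary of low-frequency interference used to compare
#' pipeline stages.
#'
#' @param rec an `opm_recording`.
#' @param chunk_s chunk length in seconds (default 1).
#' @return data.frame with `t_start` (s) and `max_change_pt` (pT) per chunk.
#' @export
max_field_change <- function(rec, chunk_s = 1) {
  validate_recording(rec)
  L <- round(chunk_s * rec$fs)
  n <- ncol(rec$data)
  if (L > n) stop("record shorter than one chunk")
  n_chunk <- floor(n / L)
  scalp <- channel_idx(rec, "scalp")
  out <- numeric(n_chunk)
  for (k in seq_len(n_chunk)) {
    idx <- ((k - 1) * L + 1):(k * L)
    seg <- rec$data[scalp, idx, drop = FALSE]
    out[k] <- max(apply(seg, 1, function(v) max(v) - min(v)))
  }
  data.frame(t_start = rec$t0 + (seq_len(n_chunk) - 1) * chunk_s,
             max_change_pt = out * 1e12)
}
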