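#' Windowed multiple linear regression of nuisance regressors
#'
#' Fits each scalp channel onto an intercept plus the supplied regressors by
#' ordinary least squares in overlapping windows, subtracts the fitted
#' values, and blends overlapping windows with a raised-cosine cross-fade so
#' the output is continuous. Short windows side-step slow non-stationarities
#' in the coupling between the regressors and the field. Reference and
#' trigger channels are left untouched.
#'
#' @param rec an `opm_recording`.
#' @param regressors matrix (n_regressors x n_samples), same sample count as
#'   the recording.
#' @param window_s window length in seconds; if longer than the record, a
#'   single full-span window is used.
#' @param overlap window overlap fraction (default 0.5).
#' @param regressor_names optional names for reporting.
#' @return list with `recording` (cleaned) and `report` (an
#'   `opm_regression_report`: window spans, per-window coefficient array,
#'   per-window per-channel variance explained, dropped-column log).
#' @export
windowed_regress <- function(rec, regressors, window_s, overlap = 0.5,
                             regressor_names = NULL) {
  validate_recording(rec)
  regressors <- as.matrix(regressors)
  if (ncol(regressors) != ncol(rec$data))
    stop("regressors and data differ in sample count")
  if (!all(is.finite(regressors)))
    stop("regressors contain non-finite values")
  n_reg <- nrow(regressors)
  if (all(abs(regressors) < 1e-300))
    stop("regressor matrix is identically zero (rank-deficient design)")
  n <- ncol(rec$data)
  L <- min(n, round(window_s * rec$fs))
  if (L <= n_reg + 2)
    stop("window too short for ", n_reg, " regressors")
  if (is.null(regressor_names))
    regressor_names <- paste0("reg", seq_len(n_reg))
  starts <- window_starts(n, L, overlap)
  w_taper <- raised_cosine_weights(L)
  # reference level for the subtracted contribution: the global regressor
  # mean, identical for every window, so overlapping windows never disagree
  # by a constant and the cross-fade stays offset-free
  g_mean <- rowMeans(regressors)
  scalp <- channel_idx(rec, "scalp")
  n_ch <- length(scalp)
  fitted <- matrix(0, n_ch, n)
  wsum <- numeric(n)
  coefs <- array(NA_real_, c(length(starts), n_reg + 1, n_ch),
                 dimnames = list(NULL, c("(intercept)", regressor_names),
                                 rec$channels$name[scalp]))
  varexp <- matrix(NA_real_, length(starts), n_ch)
  dropped <- vector("list", length(starts))
  for (wi in seq_along(starts)) {
    idx <- starts[wi]:(starts[wi] + L - 1)
    R <- t(regressors[, idx, drop = FALSE])
    R <- sweep(R, 2, colMeans(R))  # demean per window; intercept separate
    # standardise columns so rank detection is scale-free (field data are
    # O(1e-10) tesla against an O(1) intercept)
    sc_r <- apply(R, 2, stats::sd)
    zero_var <- sc_r <= 0
    sc_r[zero_var] <- 1
    R <- sweep(R, 2, sc_r, "/")
    X <- cbind(1, R)
    qrX <- qr(X)
    keep <- seq_len(ncol(X))
    if (any(zero_var) || qrX$rank < ncol(X)) {
      keep_qr <- sort(qrX$pivot[seq_len(qrX$rank)])
      keep <- setdiff(keep_qr, which(zero_var) + 1L)
      dropped[[wi]] <- colnames(coefs)[setdiff(seq_len(ncol(X)), keep)]
      X <- X[, keep, drop = FALSE]
      qrX <- qr(X)
    }
    Y <- t(rec$data[scalp, idx, drop = FALSE])
    beta <- qr.coef(qrX, Y)
    fit <- X %*% beta
    beta_raw <- beta / c(1, sc_r)[keep]  # undo standardisation
    coefs[wi, keep, ] <- beta_raw
    ss_tot <- colSums(sweep(Y, 2, colMeans(Y))^2)
    ss_res <- colSums((Y - fit)^2)
    varexp[wi, ] <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot, 0)
    # subtract the regressor contribution only: the intercept is part of
    # the design (so coefficients are unbiased) but channel means are kept.
    # The subtraction references the global regressor mean, not the window
    # mean the fit was demeaned against — see g_mean above.
    reg_cols <- keep != 1
    keep_reg <- keep[reg_cols] - 1L
    Rsub <- sweep(t(regressors[keep_reg, idx, drop = FALSE]), 2,
                  g_mean[keep_reg])
    fit_sub <- Rsub %*% beta_raw[reg_cols, , drop = FALSE]
    fitted[, idx] <- fitted[, idx] +
      t(fit_sub) * rep(w_taper, each = n_ch)
    wsum[idx] <- wsum[idx] + w_taper
  }
  fitted <- fitted / rep(pmax(wsum, 1e-12), each = n_ch)
  out <- rec
  out$data[scalp, ] <- rec$data[scalp, , drop = FALSE] - fitted
  out <- append_history(out, "windowed_regress",
                        list(n_regressors = n_reg, window_s = window_s,
                             overlap = overlap))
  report <- structure(
    list(windows = cbind(start = starts, end = starts + L - 1),
         coefficients = coefs, variance_explained = varexp,
         dropped = dropped, channel_names = rec$channels$name[scalp]),
    class = "opm_regression_report")
  list(recording = out, report = report)
}

#' @export
print.opm_regression_report <- function(x, ...) {
  cat("<opm_regression_report> ", nrow(x$windows), " windows x ",
      dim(x$coefficients)[2] - 1, " regressors x ",
      length(x$channel_names), " channels\n", sep = "")
  cat("  mean variance explained: ",
      sprintf("%.3f", mean(x$variance_explained, na.rm = TRUE)), "\n",
      sep = "")
  invisible(x)
}

#' Regress motion-capture pose from a recording
#'
#' Windowed multiple linear regression of the six rigid-body pose parameters
#' (three translations, three rotations) from every scalp channel. Removes
#' artifacts generated by the sensors moving through remnant field gradients.
#' The motion trace must already be conditioned (low-pass filtered, typically
#' at 2 Hz via [condition_motion()]) and aligned/upsampled to the recording's
#' time base via [sync_and_upsample_motion()].
#'
#' @param rec an `opm_recording`.
#' @param motion an `opm_motion` with exactly one pose sample per recording
#'   sample.
#' @param window_s regression window in seconds (default 10).
#' @param overlap window overlap fraction (default 0.5).
#' @return list with `recording` and `report`, as [windowed_regress()].
#' @export
regress_motion <- function(rec, motion, window_s = 10, overlap = 0.5) {
  stopifnot(inherits(motion, "opm_motion"))
  if (length(motion$time) != ncol(rec$data))
    stop("motion trace length (", length(motion$time),
         ") does not match recording samples (", ncol(rec$data), ")")
  if (max(abs(motion_pose(motion))) == 0) {
    # a perfectly still participant: nothing to regress
    out <- append_history(rec, "regress_motion",
                          list(window_s = window_s, note = "zero motion"))
    return(list(recording = out, report = NULL))
  }
  res <- windowed_regress(rec, t(motion_pose(motion)), window_s, overlap,
                          regressor_names = c("tx", "ty", "tz",
                                              "rx", "ry", "rz"))
  res$recording$history[[length(res$recording$history)]]$step <-
    "regress_motion"
  res
}

#' Synthetic gradiometry: reference-channel regression
#'
#' Uses static off-head reference OPMs to subtract environmental
#' interference from the scalp channels, emulating a hardware gradiometer.
#' Each reference channel is split into frequency bands (default: below and
#' above 20 Hz, separating slow environmental/vibration noise from
#' line-frequency interference) so the regression can adopt a different
#' coupling per band; the regression runs in long overlapping windows to
#' ride out non-stationary coupling.
#'
#' The split uses complementary zero-phase Butterworth low/high-pass pairs
#' at each `split_freqs` edge: their bidirectional responses sum exactly to
#' one, so the band regressors together carry the reference signal
#' unchanged. Outer band limits (e.g. 2 and 80 Hz) are not re-imposed here:
#' the temporal filters of the pipeline run over reference channels too, so
#' the references arrive already limited to the same band as the scalp
#' data — re-filtering only the references would misalign their passband
#' shape against the data and bias the fit.
#'
#' @param rec an `opm_recording` containing the reference channels.
#' @param reference_names names of the reference channels to use; defaults
#'   to every channel of kind `"reference"`.
#' @param split_freqs internal band edges in Hz (default 20, giving two
#'   bands per reference; `numeric(0)` regresses the unsplit references).
#' @param window_s regression window in seconds (default 100).
#' @param overlap window overlap fraction (default 0.5).
#' @param filter_order Butterworth order for the split filters (default 6).
#' @return list with `recording` and `report`, as [windowed_regress()].
#' @export
synthetic_gradiometry <- function(rec, reference_names = NULL,
                                  split_freqs = 20,
                                  window_s = 100, overlap = 0.5,
                                  filter_order = 6) {
  validate_recording(rec)
  if (is.null(reference_names))
    reference_names <- rec$channels$name[rec$channels$kind == "reference"]
  ri <- match(reference_names, rec$channels$name)
  if (anyNA(ri))
    stop("unknown reference channels: ",
         paste(reference_names[is.na(ri)], collapse = ", "))
  if (length(ri) < 1) stop("at least one reference channel is required")
  split_freqs <- sort(split_freqs)
  if (any(split_freqs <= 0 | split_freqs >= rec$fs / 2))
    stop("split_freqs must lie inside (0, Nyquist)")
  regs <- list()
  nms <- character(0)
  for (k in seq_along(ri)) {
    pieces <- list(rec$data[ri[k], ])
    for (f0 in split_freqs) {
      last <- pieces[[length(pieces)]]
      pieces[[length(pieces)]] <-
        zerophase_filter_vec(last, rec$fs, "lowpass", f0, filter_order)
      pieces[[length(pieces) + 1]] <-
        zerophase_filter_vec(last, rec$fs, "highpass", f0, filter_order)
    }
    edges <- c(0, split_freqs, rec$fs / 2)
    for (b in seq_along(pieces)) {
      regs[[length(regs) + 1]] <- pieces[[b]]
      nms <- c(nms, sprintf("%s[%g-%g]", reference_names[k], edges[b],
                            edges[b + 1]))
    }
  }
  res <- windowed_regress(rec, do.call(rbind, regs), window_s, overlap,
                          regressor_names = nms)
  res$recording$history[[length(res$recording$history)]]$step <-
    "synthetic_gradiometry"
  res
}
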