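#' Spatial projector constructor
#'
#' A symmetric idempotent channels-by-channels matrix encoding a spatial
#' filter (applied as `P %*% data`). Construction validates symmetry,
#' idempotence and the stated rank deficit.
#'
#' @param matrix projector matrix (n x n).
#' @param model_order dimension of the removed subspace.
#' @param channel_names channels the projector applies to, in order.
#' @return an object of class `opm_projector`.
#' @export
new_projector <- function(matrix, model_order, channel_names) {
  stopifnot(nrow(matrix) == ncol(matrix),
            nrow(matrix) == length(channel_names))
  if (max(abs(matrix - t(matrix))) > 1e-10)
    stop("projector is not symmetric")
  if (max(abs(matrix %*% matrix - matrix)) > 1e-8)
    stop("projector is not idempotent")
  r <- sum(eigen(matrix, symmetric = TRUE, only.values = TRUE)$values > 0.5)
  if (r != nrow(matrix) - model_order)
    stop("projector rank ", r, " does not match n - model_order")
  structure(list(matrix = matrix, model_order = model_order,
                 channel_names = channel_names),
            class = "opm_projector")
}

#' @export
print.opm_projector <- function(x, ...) {
  cat("<opm_projector> ", length(x$channel_names), " channels, removes a ",
      x$model_order, "-dimensional subspace\n", sep = "")
  invisible(x)
}

#' Homogeneous field correction projector
#'
#' Models the interference as a spatially constant (homogeneous) magnetic
#' field: a first-order spherical-harmonic model of the field over the
#' array. The model basis is the row-wise concatenation of the sensors'
#' sensitive-axis unit normals, N (n x 3); the projector removes the span of
#' N by regression: `P = I - N (N'N)^-1 N'`. Any field that is the same
#' 3-vector at every sensor is annihilated exactly, whatever its time
#' course.
#'
#' @param channels channel table of the channels to correct (>= 4
#'   magnetometers whose orientation matrix has rank 3; a coplanar
#'   all-radial array is degenerate and refused).
#' @return an `opm_projector` with `model_order = 3`.
#' @export
hfc_projector <- function(channels) {
  mag <- channels$kind %in% c("scalp", "reference")
  channels <- channels[mag, , drop = FALSE]
  if (nrow(channels) < 4)
    stop("HFC needs at least 4 magnetometer channels")
  N <- orientation_matrix(channels)
  sv <- svd(N)$d
  if (sv[3] < 1e-9 * sv[1])
    stop("orientation matrix is rank deficient (rank < 3): ",
         "the array cannot distinguish the three homogeneous components")
  P <- diag(nrow(N)) - N %*% solve(crossprod(N), t(N))
  new_projector(P, model_order = 3L, channel_names = channels$name)
}

#' Apply a spatial projector to a recording
#'
#' Left-multiplies the data rows of the projector's channels by its matrix.
#' The recording's tracked rank deficit is increased by the projector's
#' model order so downstream covariance operations can regularise
#' appropriately.
#'
#' @param rec an `opm_recording`.
#' @param proj an `opm_projector` whose channels are all present in `rec`.
#' @param step history step name.
#' @return the projected `opm_recording`.
#' @export
apply_projector <- function(rec, proj, step = "apply_projector") {
  validate_recording(rec)
  idx <- match(proj$channel_names, rec$channels$name)
  if (anyNA(idx))
    stop("projector channels missing from recording: ",
         paste(proj$channel_names[is.na(idx)], collapse = ", "))
  out <- rec
  out$data[idx, ] <- proj$matrix %*% rec$data[idx, , drop = FALSE]
  out$rank_deficit <- (rec$rank_deficit %||% 0L) + proj$model_order
  append_history(out, step,
                 list(model_order = proj$model_order,
                      rank_reduction = proj$model_order))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Homogeneous field correction
#'
#' Builds the HFC projector for the scoped channels and applies it
#' sample-by-sample. The default scope corrects the scalp array only (the
#' usual case when references have already been consumed by synthetic
#' gradiometry); `"scalp_and_reference"` builds one model over all
#' magnetometers.
#'
#' @param rec an `opm_recording`.
#' @param scope `"scalp_only"` (default) or `"scalp_and_reference"`.
#' @return the corrected `opm_recording` (rank reduced by 3 on the scoped
#'   channels).
#' @export
apply_hfc <- function(rec, scope = c("scalp_only", "scalp_and_reference")) {
  scope <- match.arg(scope)
  kinds <- if (scope == "scalp_only") "scalp" else c("scalp", "reference")
  ch <- rec$channels[rec$channels$kind %in% kinds, , drop = FALSE]
  proj <- hfc_projector(ch)
  apply_projector(rec, proj, step = "apply_hfc")
}

#' Signal space projection from a noise recording
#'
#' Learns the dominant spatial patterns of interference from a noise
#' recording (for example an empty-room measurement) by PCA of its channel
#' covariance, and returns the projector onto the orthogonal complement of
#' the top `n_components` principal axes.
#'
#' @param noise_rec an `opm_recording` of noise, same channel set as the
#'   data the projector will be applied to.
#' @param n_components number of principal noise directions to remove
#'   (0 gives the identity projector).
#' @return an `opm_projector`.
#' @export
ssp_from_noise <- function(noise_rec, n_components) {
  validate_recording(noise_rec)
  idx <- channel_idx(noise_rec)
  n_ch <- length(idx)
  if (n_components >= n_ch)
    stop("n_components must be below the channel count")
  X <- noise_rec$data[idx, , drop = FALSE]
  X <- X - rowMeans(X)
  C <- tcrossprod(X) / ncol(X)
  P <- diag(n_ch)
  if (n_components > 0) {
    U <- eigen(C, symmetric = TRUE)$vectors[, seq_len(n_components),
                                            drop = FALSE]
    P <- P - tcrossprod(U)
  }
  new_projector(P, model_order = as.integer(n_components),
                channel_names = noise_rec$channels$name[idx])
}

#' Detect bad channels
#'
#' Automated stand-in for visual channel screening. Flags channels whose
#' broadband ASD median exceeds `asd_factor` times the array median (large
#' idiosyncratic fluctuations) or whose longest constant-value run exceeds
#' `rail_s` seconds (railing: a sensor stuck at the edge of its dynamic
#' range).
#'
#' @param rec an `opm_recording` at least 10 s long.
#' @param asd_factor multiple of the array-median ASD above which a channel
#'   is flagged (default 5).
#' @param rail_s constant-run duration in seconds that flags railing
#'   (default 0.5).
#' @param psd_window_s Welch window for the ASD screen (default 5).
#' @return character vector of flagged channel names (possibly empty).
#' @export
detect_bad_channels <- function(rec, asd_factor = 5, rail_s = 0.5,
                                psd_window_s = 5) {
  validate_recording(rec)
  if (n_seconds(rec) < 10)
    stop("detect_bad_channels needs at least 10 s of data")
  idx <- channel_idx(rec)
  psd <- welch_asd(rec, window_s = min(psd_window_s, n_seconds(rec) / 2),
                   channels = rec$channels$name[idx])
  band <- psd$freqs > 0
  ch_med <- apply(psd$asd[, band, drop = FALSE], 1, stats::median)
  flagged <- ch_med > asd_factor * stats::median(ch_med)
  rail_n <- round(rail_s * rec$fs)
  for (k in seq_along(idx)) {
    if (flagged[k]) next
    r <- rle(diff(rec$data[idx[k], ]) == 0)
    if (any(r$lengths[r$values] + 1 > rail_n)) flagged[k] <- TRUE
  }
  rec$channels$name[idx][flagged]
}

#' Detect transient artifact segments
#'
#' Automated stand-in for manual artifact marking: flags spans where the
#' within-window peak-to-peak field exceeds `jump_threshold` on at least
#' `min_channel_fraction` of scalp channels simultaneously (transient,
#' array-wide field jumps). Adjacent marks are merged and each span padded.
#'
#' @param rec an `opm_recording`.
#' @param jump_threshold peak-to-peak threshold in tesla (default 5e-12,
#'   i.e. 5 pT).
#' @param jump_window window length in seconds (default 0.1); windows slide
#'   by half their length.
#' @param min_channel_fraction fraction of scalp channels that must exceed
#'   the threshold (default 0.5).
#' @param pad_s padding added to both ends of each span (default 0.1 s).
#' @return data.frame with columns `start_s`, `end_s` (recording time);
#'   zero rows when the record is clean.
#' @export
detect_artifact_segments <- function(rec, jump_threshold = 5e-12,
                                     jump_window = 0.1,
                                     min_channel_fraction = 0.5,
                                     pad_s = 0.1) {
  validate_recording(rec)
  scalp <- channel_idx(rec, "scalp")
  n <- ncol(rec$data)
  L <- max(2, round(jump_window * rec$fs))
  step <- max(1, floor(L / 2))
  starts <- seq(1, max(1, n - L + 1), by = step)
  hit <- logical(length(starts))
  for (k in seq_along(starts)) {
    idx <- starts[k]:(starts[k] + L - 1)
    seg <- rec$data[scalp, idx, drop = FALSE]
    ptp <- apply(seg, 1, function(v) max(v) - min(v))
    hit[k] <- mean(ptp > jump_threshold) >= min_channel_fraction
  }
  if (!any(hit)) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  t_lo <- rec$t0 + (starts[hit] - 1) / rec$fs - pad_s
  t_hi <- rec$t0 + (starts[hit] + L - 2) / rec$fs + pad_s
  # merge overlapping/adjacent spans
  o <- order(t_lo)
  t_lo <- t_lo[o]; t_hi <- t_hi[o]
  ms <- t_lo[1]; me <- t_hi[1]
  out_lo <- numeric(0); out_hi <- numeric(0)
  for (k in seq_along(t_lo)[-1]) {
    if (t_lo[k] <= me) me <- max(me, t_hi[k])
    else { out_lo <- c(out_lo, ms); out_hi <- c(out_hi, me)
           ms <- t_lo[k]; me <- t_hi[k] }
  }
  out_lo <- c(out_lo, ms); out_hi <- c(out_hi, me)
  data.frame(start_s = out_lo, end_s = out_hi)
}
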