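#' Sensor covariance from epoched data
#'
#' Per-trial sample covariance over a post-stimulus window, averaged across
#' trials (each trial demeaned over the window). The rank is estimated from
#' the eigenvalue spectrum and capped by any known projector deficit carried
#' by the epochs.
#'
#' @param epochs an `opm_epochs` (scalp channels are used).
#' @param window `c(t_lo, t_hi)` covariance window in seconds relative to
#'   onset.
#' @param method `"trial_mean"` (average of per-trial covariances, default)
#'   or `"concatenated"` (one covariance of the concatenated window data).
#' @return list with `cov` (n_scalp x n_scalp, tesla^2), `rank`,
#'   `n_samples`, `channel_names`, `window`.
#' @export
epoch_covariance <- function(epochs, window,
                             method = c("trial_mean", "concatenated")) {
  stopifnot(inherits(epochs, "opm_epochs"))
  method <- match.arg(method)
  n_tr <- dim(epochs$data)[1]
  if (n_tr < 2) stop("covariance needs at least 2 trials")
  idx_t <- which(epochs$times >= window[1] & epochs$times <= window[2])
  if (length(idx_t) == 0) stop("empty covariance window")
  scalp <- which(epochs$channels$kind == "scalp")
  n_ch <- length(scalp)
  if (method == "trial_mean") {
    C <- matrix(0, n_ch, n_ch)
    for (tr in seq_len(n_tr)) {
      x <- matrix(epochs$data[tr, scalp, idx_t], n_ch)
      x <- x - rowMeans(x)
      C <- C + tcrossprod(x) / length(idx_t)
    }
    C <- C / n_tr
  } else {
    X <- matrix(aperm(epochs$data[, scalp, idx_t, drop = FALSE],
                      c(2, 3, 1)), n_ch)
    X <- X - rowMeans(X)
    C <- tcrossprod(X) / ncol(X)
  }
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  rank_ev <- sum(ev > 1e-10 * max(ev, 0))
  rank <- min(rank_ev, n_ch - (epochs$rank_deficit %||% 0L))
  list(cov = C, rank = rank, n_samples = length(idx_t) * n_tr,
       channel_names = epochs$channels$name[scalp], window = window)
}

#' LCMV beamformer weights
#'
#' Linearly constrained minimum variance spatial filter with unit gain at
#' every lead-field column (so a multi-source lead field yields a
#' multi-source constraint, nulling the cross-talk between simultaneously
#' modelled correlated sources). The covariance is diagonally loaded:
#' `C_r = C + lambda * (trace(C)/n) * I`, i.e. `lambda` is a fraction of the
#' mean sensor variance (the usual "lambda = 0.1%" convention is
#' `lambda_fraction = 0.001`). Diagonal loading also handles the rank
#' deficit left by spatial projectors.
#'
#' @param leadfield matrix (n_channels x 3k) for k sources, full column
#'   rank.
#' @param cov sensor covariance (n_channels x n_channels) or the list
#'   returned by [epoch_covariance()].
#' @param lambda_fraction regularisation as a fraction of the mean
#'   eigenvalue (default 0.001).
#' @param source_positions optional list of source positions for reporting.
#' @return object of class `opm_beamformer`: `weights` (3k x n_channels),
#'   `leadfield`, `lambda_fraction`, `n_sources`, `channel_names`.
#' @export
lcmv_weights <- function(leadfield, cov, lambda_fraction = 0.001,
                         source_positions = NULL) {
  ch_names <- NULL
  if (is.list(cov) && !is.null(cov$cov)) {
    ch_names <- cov$channel_names
    cov <- cov$cov
  }
  L <- as.matrix(leadfield)
  if (lambda_fraction < 0) stop("lambda_fraction must be non-negative")
  n <- nrow(L)
  stopifnot(nrow(cov) == n, ncol(cov) == n)
  if (max(abs(cov - t(cov))) > 1e-8 * max(abs(cov)))
    stop("covariance must be symmetric")
  if (qr(L)$rank < ncol(L)) stop("lead field is rank deficient")
  Cr <- cov + lambda_fraction * (sum(diag(cov)) / n) * diag(n)
  CiL <- solve(Cr, L)
  M <- crossprod(L, CiL)
  Mi <- tryCatch(solve(M), error = function(e)
    stop("singular constraint matrix L' C^-1 L: sources too close or ",
         "covariance degenerate"))
  W <- Mi %*% t(CiL)
  n_ori <- attr(leadfield, "n_ori") %||% 3L
  structure(list(weights = W, leadfield = L,
                 lambda_fraction = lambda_fraction,
                 n_ori = n_ori,
                 n_sources = ncol(L) / n_ori,
                 source_positions = source_positions,
                 channel_names = ch_names),
            class = "opm_beamformer")
}

#' @export
print.opm_beamformer <- function(x, ...) {
  cat("<opm_beamformer> ", x$n_sources, " source(s), ",
      ncol(x$weights), " channels, lambda = ",
      format(x$lambda_fraction), "\n", sep = "")
  err <- max(abs(x$weights %*% x$leadfield - diag(ncol(x$leadfield))))
  cat("  unit-gain constraint residual: ", format(err, digits = 3), "\n",
      sep = "")
  invisible(x)
}

#' Extract a virtual channel from beamformer weights
#'
#' Applies the spatial filter to sensor data and collapses the three dipole
#' orientations of one source to a single time course: either along the
#' dominant SVD component of the trial-averaged 3-by-time matrix
#' (`"svd"`, default) or along the fixed orientation maximising evoked
#' power in `window` (`"max_evoked"`). The sign is fixed so the peak inside
#' `window` is positive.
#'
#' @param bf an `opm_beamformer`.
#' @param x an `opm_recording` or `opm_epochs` with matching scalp channels.
#' @param source_index which source of the model to extract (default 1).
#' @param orientation `"svd"` or `"max_evoked"`.
#' @param window `c(t_lo, t_hi)` analysis window in seconds for orientation
#'   and sign fixing (epochs only; defaults to the full epoch).
#' @return for a recording: numeric time series. For epochs: list with
#'   `trials` (n_trials x n_times), `mean`, `times`, `orientation` (unit
#'   vector in the source's moment basis).
#' @export
virtual_channel <- function(bf, x, source_index = 1,
                            orientation = c("svd", "max_evoked"),
                            window = NULL) {
  orientation <- match.arg(orientation)
  k <- bf$n_ori %||% 3L
  rows <- (k * (source_index - 1) + 1):(k * source_index)
  if (inherits(x, "opm_recording")) {
    scalp <- channel_idx(x, "scalp")
    check_bf_channels(bf, x$channels$name[scalp])
    Y <- bf$weights[rows, , drop = FALSE] %*% x$data[scalp, , drop = FALSE]
    u <- svd(Y)$u[, 1]
    v <- as.numeric(crossprod(u, Y))
    if (max(v) < -min(v)) { v <- -v; u <- -u }
    return(v)
  }
  stopifnot(inherits(x, "opm_epochs"))
  scalp <- which(x$channels$kind == "scalp")
  check_bf_channels(bf, x$channels$name[scalp])
  n_tr <- dim(x$data)[1]
  n_t <- dim(x$data)[3]
  if (is.null(window)) window <- range(x$times)
  widx <- which(x$times >= window[1] & x$times <= window[2])
  tri <- array(0, c(n_tr, k, n_t))
  for (tr in seq_len(n_tr))
    tri[tr, , ] <- bf$weights[rows, , drop = FALSE] %*%
      matrix(x$data[tr, scalp, ], length(scalp), n_t)
  avg <- apply(tri, c(2, 3), mean)
  if (orientation == "svd") {
    u <- svd(avg[, widx, drop = FALSE])$u[, 1]
  } else {
    pw <- tcrossprod(avg[, widx, drop = FALSE])
    u <- eigen(pw, symmetric = TRUE)$vectors[, 1]
  }
  m <- as.numeric(crossprod(u, avg))
  if (max(m[widx]) < max(-m[widx])) { u <- -u; m <- -m }
  trials <- matrix(0, n_tr, n_t)
  for (tr in seq_len(n_tr))
    trials[tr, ] <- crossprod(u, matrix(tri[tr, , ], k, n_t))
  list(trials = trials, mean = m, times = x$times, orientation = u)
}

check_bf_channels <- function(bf, names) {
  if (ncol(bf$weights) != length(names))
    stop("beamformer channel count (", ncol(bf$weights),
         ") does not match data (", length(names), ")")
  if (!is.null(bf$channel_names) && !identical(bf$channel_names, names))
    stop("beamformer channel set does not match the data")
  invisible(TRUE)
}
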