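# Whitened symmetric fastICA with the cubic (kurtosis) nonlinearity.
# X: (n_signals x n_samples), already centred. Returns the unmixing matrix
# relative to X (n_comp x n_signals), the mixing matrix (n_signals x n_comp)
# and the source estimates.
fastica_core <- function(X, n_comp, seed, max_iter = 200, tol = 1e-4) {
  n_sig <- nrow(X)
  n_s <- ncol(X)
  C <- tcrossprod(X) / n_s
  eg <- eigen(C, symmetric = TRUE)
  keep <- seq_len(n_comp)
  d <- eg$values[keep]
  if (any(d <= 0)) stop("covariance not positive on the retained subspace")
  K <- diag(1 / sqrt(d)) %*% t(eg$vectors[, keep, drop = FALSE])  # whitening
  Z <- K %*% X
  set.seed(seed)
  W <- matrix(stats::rnorm(n_comp^2), n_comp)
  W <- sym_decorrelate(W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- WZ^3
    W_new <- tcrossprod(G, Z) / n_s - 3 * W  # E[g'(u)] = 3 E[u^2] = 3 (white)
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(1 - abs(rowSums(W_new * W))))
    W <- W_new
    if (delta < tol) { converged <- TRUE; break }
  }
  unmixing <- W %*% K                                   # n_comp x n_sig
  mixing <- eg$vectors[, keep, drop = FALSE] %*% diag(sqrt(d)) %*% t(W)
  list(unmixing = unmixing, mixing = mixing, sources = unmixing %*% X,
       converged = converged, iterations = it)
}

sym_decorrelate <- function(W) {
  s <- svd(W)
  s$u %*% t(s$v)
}

#' ICA-based artifact removal
#'
#' Decomposes the scalp channels into independent components with a whitened
#' symmetric fastICA (cubic nonlinearity, i.e. directions of maximal
#' kurtosis), flags artifact components, zeroes them, and remixes. The
#' decomposition is reproducible from the seed. Data should be continuous
#' and high-pass filtered (1-2 Hz) beforehand; low-frequency drift degrades
#' the decomposition.
#'
#' @param rec an `opm_recording`.
#' @param n_components number of components to return (default 50; capped at
#'   the available rank).
#' @param seed RNG seed for the random initial unmixing matrix.
#' @param flag_components explicit integer indices of components to remove
#'   (overrides the automatic rules, mirroring manual selection).
#' @param flag_rules list of automatic flagging rules: `low_freq`
#'   (flag components whose power fraction below `lf_cut` Hz exceeds
#'   `lf_frac` and that lack an alpha peak) and `templates` (matrix of
#'   reference time courses, e.g. pseudo-ECG/EOG; components with
#'   `|cor| > template_corr` are flagged).
#' @param max_iter,tol fastICA iteration cap and convergence tolerance.
#'   When components beyond the few non-Gaussian artifact directions span
#'   an essentially Gaussian subspace, the symmetric update has a genuine
#'   rotation indeterminacy there and the global criterion may never reach
#'   `tol`; the decomposition is then returned with a warning (the
#'   informative directions stabilise early), matching how the standard
#'   fastICA implementations behave at their iteration cap.
#' @return list with `recording` (artifact components removed) and `report`
#'   (class `opm_ica_report`: mixing/unmixing matrices, component sources,
#'   per-component low-frequency power fraction, flags and reasons,
#'   convergence info).
#' @export
ica_denoise <- function(rec, n_components = 50, seed = 454,
                        flag_components = NULL,
                        flag_rules = list(low_freq = TRUE, lf_cut = 5,
                                          lf_frac = 0.6, templates = NULL,
                                          template_corr = 0.5),
                        max_iter = 200, tol = 1e-4) {
  validate_recording(rec)
  scalp <- channel_idx(rec, "scalp")
  deficit <- rec$rank_deficit %||% 0L
  max_comp <- length(scalp) - deficit
  if (n_components > length(scalp))
    stop("more components than channels")
  n_comp <- min(n_components, max_comp)
  X <- rec$data[scalp, , drop = FALSE]
  mu <- rowMeans(X)
  X <- X - mu
  fit <- fastica_core(X, n_comp, seed, max_iter, tol)
  if (!fit$converged)
    warning("fastICA hit the iteration cap (", max_iter,
            "); returning the current decomposition")
  S <- fit$sources
  # per-component spectral summary
  fs <- rec$fs
  lf_frac <- apply(S, 1, function(s) {
    p <- Mod(stats::fft(s))^2
    nf <- floor(length(s) / 2)
    fr <- (seq_len(nf) - 1) * fs / length(s)
    p <- p[seq_len(nf)]
    sum(p[fr < (flag_rules$lf_cut %||% 5) & fr > 0]) / sum(p[fr > 0])
  })
  alpha_peak <- apply(S, 1, function(s) {
    p <- Mod(stats::fft(s))^2
    nf <- floor(length(s) / 2)
    fr <- (seq_len(nf) - 1) * fs / length(s)
    a <- mean(p[fr >= 8 & fr <= 12])
    b <- stats::median(p[fr >= 5 & fr <= 15])
    is.finite(a) && is.finite(b) && b > 0 && a > 2 * b
  })
  flags <- logical(n_comp)
  reasons <- rep("", n_comp)
  if (!is.null(flag_components)) {
    flags[flag_components] <- TRUE
    reasons[flag_components] <- "manual"
  } else {
    if (isTRUE(flag_rules$low_freq)) {
      hit <- lf_frac > (flag_rules$lf_frac %||% 0.6) & !alpha_peak
      flags[hit] <- TRUE
      reasons[hit] <- "low-frequency dominance"
    }
    if (!is.null(flag_rules$templates)) {
      tm <- as.matrix(flag_rules$templates)
      for (k in seq_len(n_comp)) {
        cc <- max(abs(stats::cor(S[k, ], tm)))
        if (cc > (flag_rules$template_corr %||% 0.5)) {
          flags[k] <- TRUE
          reasons[k] <- paste0(reasons[k],
                               if (nzchar(reasons[k])) "; " else "",
                               "template correlation")
        }
      }
    }
  }
  out <- rec
  if (any(flags)) {
    removed <- fit$mixing[, flags, drop = FALSE] %*%
      S[flags, , drop = FALSE]
    out$data[scalp, ] <- X - removed + mu
    if (all(flags))
      warning("all components flagged: output reduced to channel means")
  }
  out <- append_history(out, "ica_denoise",
                        list(n_components = n_comp, seed = seed,
                             flagged = which(flags)))
  report <- structure(
    list(mixing = fit$mixing, unmixing = fit$unmixing, sources = S,
         low_freq_fraction = lf_frac, alpha_peak = alpha_peak,
         flags = flags, reasons = reasons,
         converged = fit$converged, iterations = fit$iterations,
         channel_names = rec$channels$name[scalp]),
    class = "opm_ica_report")
  list(recording = out, report = report)
}

#' @export
print.opm_ica_report <- function(x, ...) {
  cat("<opm_ica_report> ", nrow(x$sources), " components (",
      x$iterations, " iterations), ", sum(x$flags), " flagged\n", sep = "")
  if (any(x$flags))
    cat("  flagged: ", paste(which(x$flags), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}
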