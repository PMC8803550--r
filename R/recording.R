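#' Construct an OPM recording
#'
#' A recording holds a channel table, a channels-by-samples data matrix in
#' tesla, the sampling rate, a start time, and a history of processing steps.
#' All interference-suppression operations in this package consume and return
#' objects of this class.
#'
#' @param channels data.frame with columns `name`, `kind` (one of `"scalp"`,
#'   `"reference"`, `"trigger"`), `axis` (`"RAD"`, `"TAN"`, `"TAN2"`, `"X"`,
#'   `"Y"`, `"Z"`, or `NA` for triggers), `pos_x`, `pos_y`, `pos_z` (metres,
#'   head frame), `ori_x`, `ori_y`, `ori_z` (unit sensitive-axis vector;
#'   `NA` for triggers).
#' @param data numeric matrix, `nrow(channels)` rows by `n_samples` columns,
#'   magnetometer rows in tesla.
#' @param fs sampling rate in Hz.
#' @param t0 start time in seconds (default 0).
#' @param history list of prior processing-step descriptors.
#' @return An object of class `opm_recording`.
#' @export
new_recording <- function(channels, data, fs, t0 = 0, history = list()) {
  rec <- structure(
    list(channels = channels, data = data, fs = fs, t0 = t0,
         history = history),
    class = "opm_recording")
  validate_recording(rec)
  rec
}

#' Validate an OPM recording
#'
#' Checks the structural invariants: row count matches channel count, positive
#' sampling rate, finite samples, unique channel names, and unit-norm
#' orientations for magnetometer channels.
#'
#' @param rec an `opm_recording`.
#' @return `rec`, invisibly. Errors describe the violated invariant.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "opm_recording"))
  ch <- rec$channels
  required <- c("name", "kind", "axis", "pos_x", "pos_y", "pos_z",
                "ori_x", "ori_y", "ori_z")
  missing_cols <- setdiff(required, names(ch))
  if (length(missing_cols) > 0)
    stop("channel table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!is.matrix(rec$data) || nrow(rec$data) != nrow(ch))
    stop("data row count (", nrow(rec$data),
         ") does not match channel count (", nrow(ch), ")")
  if (!is.numeric(rec$fs) || length(rec$fs) != 1 || rec$fs <= 0)
    stop("fs must be a single positive number")
  if (anyDuplicated(ch$name))
    stop("channel names are not unique: ",
         paste(unique(ch$name[duplicated(ch$name)]), collapse = ", "))
  bad_kind <- setdiff(unique(ch$kind), c("scalp", "reference", "trigger"))
  if (length(bad_kind) > 0)
    stop("unknown channel kind: ", paste(bad_kind, collapse = ", "))
  if (!all(is.finite(rec$data)))
    stop("data contains non-finite samples")
  mag <- ch$kind %in% c("scalp", "reference")
  if (any(mag)) {
    nrm <- sqrt(ch$ori_x[mag]^2 + ch$ori_y[mag]^2 + ch$ori_z[mag]^2)
    if (any(!is.finite(nrm)) || any(abs(nrm - 1) > 1e-9))
      stop("magnetometer orientations must be unit vectors (norm 1 +/- 1e-9)")
  }
  invisible(rec)
}

#' @export
print.opm_recording <- function(x, ...) {
  kinds <- table(factor(x$channels$kind,
                        levels = c("scalp", "reference", "trigger")))
  cat("<opm_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (", sprintf("%.1f", n_seconds(x)), " s)\n",
      sep = "")
  cat("  scalp: ", kinds[["scalp"]], "  reference: ", kinds[["reference"]],
      "  trigger: ", kinds[["trigger"]], "\n", sep = "")
  if (length(x$history) > 0)
    cat("  history: ",
        paste(vapply(x$history, `[[`, "", "step"), collapse = " -> "),
        "\n", sep = "")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `opm_recording`.
#' @return duration in seconds (`n_samples / fs`).
#' @export
n_seconds <- function(rec) ncol(rec$data) / rec$fs

#' Sample time axis of a recording
#' @param rec an `opm_recording`.
#' @return numeric vector of sample times in seconds, starting at `t0`.
#' @export
rec_times <- function(rec) rec$t0 + (seq_len(ncol(rec$data)) - 1) / rec$fs

#' Append a history entry to a recording
#' @param rec an `opm_recording`.
#' @param step character step name.
#' @param params named list of step parameters.
#' @return the recording with one more history entry.
#' @keywords internal
append_history <- function(rec, step, params = list()) {
  rec$history <- c(rec$history, list(list(step = step, params = params)))
  rec
}

#' Indices of channels of a given kind
#' @param rec an `opm_recording`.
#' @param kind character vector of kinds to match.
#' @return integer indices into the channel table.
#' @export
channel_idx <- function(rec, kind = c("scalp", "reference")) {
  which(rec$channels$kind %in% kind)
}

#' Orientation matrix of selected channels
#' @param channels a channel table (data.frame).
#' @return matrix (n x 3) of sensitive-axis unit vectors.
#' @export
orientation_matrix <- function(channels) {
  as.matrix(channels[, c("ori_x", "ori_y", "ori_z")])
}

#' Position matrix of selected channels
#' @param channels a channel table (data.frame).
#' @return matrix (n x 3) of sensor positions in metres.
#' @export
position_matrix <- function(channels) {
  as.matrix(channels[, c("pos_x", "pos_y", "pos_z")])
}

unit_scale_to_tesla <- function(unit) {
  switch(unit,
         "T" = 1, "mT" = 1e-3, "uT" = 1e-6, "nT" = 1e-9,
         "pT" = 1e-12, "fT" = 1e-15,
         stop("unknown unit in sidecar: ", unit))
}

#' Write a recording container to disk
#'
#' The on-disk container is three files sharing a stem:
#' `<stem>_channels.tsv` (the channel table), `<stem>_meta.json` (sampling
#' rate, unit, dimensions, byte order, history), and `<stem>_data.bin`
#' (row-major channels-by-samples float64, little endian). The format is
#' bit-exact and language agnostic.
#'
#' @param rec an `opm_recording`.
#' @param stem path stem (files get `_channels.tsv`, `_meta.json`,
#'   `_data.bin` appended).
#' @return `stem`, invisibly.
#' @export
write_recording <- function(rec, stem) {
  validate_recording(rec)
  if (ncol(rec$data) == 0)
    stop("refusing to write an empty (0-sample) recording")
  dir <- dirname(stem)
  if (!dir.exists(dir))
    stop("unwritable path: directory does not exist: ", dir)
  utils::write.table(rec$channels, paste0(stem, "_channels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(fs_hz = rec$fs, unit = "T", t0 = rec$t0,
               n_channels = nrow(rec$data), n_samples = ncol(rec$data),
               byte_order = "little", dtype = "float64",
               history = rec$history)
  jsonlite::write_json(meta, paste0(stem, "_meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(paste0(stem, "_data.bin"), "wb")
  on.exit(close(con))
  # row-major: channel rows contiguous
  writeBin(as.double(t(rec$data)), con, size = 8, endian = "little")
  invisible(stem)
}

#' Read a recording container from disk
#'
#' Inverse of [write_recording()]. Values are converted to tesla using the
#' sidecar's `unit` field; the history is restored and a load entry appended.
#'
#' @param stem path stem written by [write_recording()].
#' @return an `opm_recording`.
#' @export
read_recording <- function(stem) {
  meta_path <- paste0(stem, "_meta.json")
  chan_path <- paste0(stem, "_channels.tsv")
  data_path <- paste0(stem, "_data.bin")
  for (p in c(meta_path, chan_path, data_path))
    if (!file.exists(p)) stop("missing container file: ", p)
  meta <- jsonlite::read_json(meta_path, simplifyVector = FALSE)
  for (f in c("fs_hz", "unit", "n_channels", "n_samples"))
    if (is.null(meta[[f]])) stop("missing sidecar field: ", f)
  channels <- utils::read.delim(chan_path, stringsAsFactors = FALSE)
  n_ch <- as.integer(meta$n_channels)
  n_s <- as.integer(meta$n_samples)
  if (nrow(channels) != n_ch)
    stop("channel-count mismatch: sidecar declares ", n_ch,
         " channels, table has ", nrow(channels))
  con <- file(data_path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = n_ch * n_s, size = 8, endian = "little")
  if (length(v) != n_ch * n_s)
    stop("data block has ", length(v), " values, expected ", n_ch * n_s)
  if (!all(is.finite(v)))
    stop("non-finite samples in data block")
  dat <- matrix(v, nrow = n_ch, byrow = TRUE) * unit_scale_to_tesla(meta$unit)
  history <- if (is.null(meta$history)) list() else meta$history
  t0 <- if (is.null(meta$t0)) 0 else meta$t0
  rec <- new_recording(channels, dat, fs = meta$fs_hz, t0 = t0,
                       history = history)
  append_history(rec, "read_recording", list(path = stem))
}

#' Select channels of a recording
#'
#' Filters channel rows and the corresponding data rows consistently. The
#' selector may be a character vector of names to keep, a logical/integer
#' index, or a predicate function taking the channel table and returning a
#' logical vector.
#'
#' @param rec an `opm_recording`.
#' @param keep channel selector (names, indices, logical mask, or predicate).
#' @param drop if `TRUE`, invert the selection (drop the named channels).
#' @return the filtered `opm_recording`, with history appended.
#' @export
select_channels <- function(rec, keep, drop = FALSE) {
  validate_recording(rec)
  ch <- rec$channels
  if (is.function(keep)) {
    mask <- keep(ch)
    if (!is.logical(mask) || length(mask) != nrow(ch))
      stop("predicate must return a logical vector over channels")
  } else if (is.character(keep)) {
    unknown <- setdiff(keep, ch$name)
    if (length(unknown) > 0)
      stop("unknown channel names: ", paste(unknown, collapse = ", "))
    mask <- ch$name %in% keep
  } else if (is.logical(keep)) {
    stopifnot(length(keep) == nrow(ch))
    mask <- keep
  } else {
    mask <- rep(FALSE, nrow(ch))
    mask[keep] <- TRUE
  }
  if (drop) mask <- !mask
  if (!any(mask)) stop("channel selection keeps 0 channels")
  out <- rec
  out$channels <- ch[mask, , drop = FALSE]
  rownames(out$channels) <- NULL
  out$data <- rec$data[mask, , drop = FALSE]
  append_history(out, "select_channels",
                 list(kept = sum(mask), dropped = sum(!mask)))
}

#' Resample a recording to a lower rate
#'
#' Magnetometer channels are resampled in the frequency domain: the record
#' is reflect-padded to a length commensurate with the (rationalised) rate
#' ratio, Fourier transformed, truncated at the new Nyquist frequency
#' (ideal anti-alias), and inverse transformed onto the new grid. Amplitude
#' of band-limited content is preserved essentially exactly. Trigger
#' channels are reconstructed by re-indexing their pulse onsets at the new
#' rate (nearest sample) rather than low-pass filtered, so event timing is
#' preserved and pulses are not smeared.
#'
#' @param rec an `opm_recording`.
#' @param fs_new new sampling rate in Hz, must be below `rec$fs`.
#' @return the resampled `opm_recording`.
#' @export
resample_recording <- function(rec, fs_new) {
  validate_recording(rec)
  if (fs_new <= 0) stop("fs_new must be positive")
  if (fs_new >= rec$fs) stop("fs_new must be below the current rate")
  ratio <- fs_new / rec$fs
  pq <- rational_approx(ratio, max_den = 1024)
  n <- ncol(rec$data)
  n_new <- floor(n * ratio)
  # pad (odd reflection) to a multiple of q so the new grid lands exactly
  # on multiples of 1/fs_new, with at least ~1 s of padding for the edges
  q <- pq[2]
  pad_min <- min(n - 1, round(rec$fs))
  N <- as.integer(ceiling((n + pad_min) / q) * q)
  pad <- N - n
  N_new <- as.integer(N * pq[1] / q)
  keep <- floor(N_new / 2)  # bins below the new Nyquist
  out_data <- matrix(0, nrow(rec$data), n_new)
  mag <- rec$channels$kind %in% c("scalp", "reference")
  for (i in which(mag)) {
    x <- rec$data[i, ]
    xp <- c(x, 2 * x[n] - x[n - seq_len(pad)])
    X <- stats::fft(xp)
    Y <- complex(real = numeric(N_new), imaginary = numeric(N_new))
    Y[1:(keep + 1)] <- X[1:(keep + 1)]
    if (keep > 0)
      Y[N_new - seq_len(keep) + 1] <- X[N - seq_len(keep) + 1]
    y <- Re(stats::fft(Y, inverse = TRUE)) / N
    out_data[i, ] <- y[seq_len(n_new)]
  }
  for (i in which(!mag)) {
    x <- rec$data[i, ]
    y <- numeric(n_new)
    on <- pulse_onsets(x)
    if (length(on) > 0) {
      lens <- pulse_lengths(x, on)
      amps <- x[on]
      new_on <- pmin(pmax(round((on - 1) * ratio) + 1, 1), n_new)
      new_len <- pmax(1, round(lens * ratio))
      for (k in seq_along(new_on)) {
        span <- new_on[k]:min(n_new, new_on[k] + new_len[k] - 1)
        y[span] <- amps[k]
      }
    }
    out_data[i, ] <- y
  }
  out <- rec
  out$data <- out_data
  out$fs <- fs_new
  append_history(out, "resample", list(fs_new = fs_new))
}

rational_approx <- function(x, max_den = 1024) {
  # continued-fraction rational approximation
  best <- c(round(x), 1)
  if (abs(x - best[1]) < 1e-12) return(best)
  a <- x
  h <- c(1, floor(a)); k <- c(0, 1)
  while (k[length(k)] <= max_den) {
    frac <- a - floor(a)
    if (frac < 1e-12) break
    a <- 1 / frac
    h <- c(h, floor(a) * h[length(h)] + h[length(h) - 1])
    k <- c(k, floor(a) * k[length(k)] + k[length(k) - 1])
  }
  ok <- which(k >= 1 & k <= max_den)
  i <- ok[length(ok)]
  c(h[i], k[i])
}

# first samples of threshold crossings (half max) in a trigger trace
pulse_onsets <- function(x, threshold = NULL) {
  if (all(x == x[1])) return(integer(0))
  if (is.null(threshold)) threshold <- max(x) / 2
  above <- x >= threshold
  which(above & !c(FALSE, above[-length(above)]))
}

pulse_lengths <- function(x, onsets, threshold = NULL) {
  if (is.null(threshold)) threshold <- max(x) / 2
  above <- x >= threshold
  vapply(onsets, function(on) {
    end <- on
    while (end <= length(x) && above[end]) end <- end + 1
    as.integer(end - on)
  }, integer(1))
}

#' Event table constructor
#'
#' @param onset_sample integer vector of strictly increasing onset samples.
#' @param code character event codes (recycled).
#' @return data.frame of class `opm_events` with columns `onset_sample`, `code`.
#' @export
new_events <- function(onset_sample, code = "stim") {
  if (is.unsorted(onset_sample, strictly = TRUE))
    stop("event onsets must be strictly increasing")
  structure(data.frame(onset_sample = as.integer(onset_sample),
                       code = rep_len(as.character(code),
                                      length(onset_sample)),
                       stringsAsFactors = FALSE),
            class = c("opm_events", "data.frame"))
}

#' Extract events from a trigger channel
#'
#' Onsets are the first samples at which the trigger trace crosses half its
#' maximum amplitude.
#'
#' @param rec an `opm_recording`.
#' @param trigger_channel trigger channel name.
#' @param code event code to assign.
#' @return an `opm_events` table.
#' @export
events_from_trigger <- function(rec, trigger_channel, code = "stim") {
  i <- match(trigger_channel, rec$channels$name)
  if (is.na(i)) stop("no such channel: ", trigger_channel)
  on <- pulse_onsets(rec$data[i, ])
  if (length(on) == 0) stop("no pulses found on ", trigger_channel)
  new_events(on, code)
}

#' Write an event table as TSV
#' @param events an `opm_events` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an event table from TSV
#' @param path path to a TSV with columns `onset_sample`, `code`.
#' @return an `opm_events` table.
#' @export
read_events <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  new_events(d$onset_sample, d$code)
}
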