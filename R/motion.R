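#' Construct a 6-DOF motion trace
#'
#' A motion trace holds the solved rigid-body pose of the sensor array over
#' time: three translations (right-left, down-up, back-forward) in metres and
#' three Euler rotations (pitch, yaw, roll) in degrees.
#'
#' @param time numeric vector of sample times in seconds, strictly increasing.
#' @param translation matrix (n x 3), metres, columns `tx`, `ty`, `tz`.
#' @param rotation matrix (n x 3), degrees, columns `rx`, `ry`, `rz`.
#' @param axis_order Euler axis convention, default intrinsic `"ZYX"`
#'   (yaw-pitch-roll).
#' @return an object of class `opm_motion`.
#' @export
new_motion <- function(time, translation, rotation, axis_order = "ZYX") {
  translation <- as.matrix(translation)
  rotation <- as.matrix(rotation)
  stopifnot(length(time) == nrow(translation),
            length(time) == nrow(rotation),
            ncol(translation) == 3, ncol(rotation) == 3)
  if (any(!is.finite(time)) || any(!is.finite(translation)) ||
      any(!is.finite(rotation)))
    stop("motion trace contains non-finite values")
  if (is.unsorted(time, strictly = TRUE))
    stop("motion time must be strictly increasing")
  colnames(translation) <- c("tx", "ty", "tz")
  colnames(rotation) <- c("rx", "ry", "rz")
  structure(list(time = as.numeric(time), translation = translation,
                 rotation = rotation, axis_order = axis_order),
            class = "opm_motion")
}

#' @export
print.opm_motion <- function(x, ...) {
  cat("<opm_motion> ", length(x$time), " samples, ",
      sprintf("%.2f", diff(range(x$time))), " s, Euler ", x$axis_order,
      "\n", sep = "")
  rng <- apply(x$translation, 2, function(v) diff(range(v)))
  cat("  translation range (m): ",
      paste(sprintf("%.3f", rng), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Pose matrix of a motion trace
#' @param m an `opm_motion`.
#' @return matrix (n x 6) with columns tx, ty, tz, rx, ry, rz.
#' @export
motion_pose <- function(m) cbind(m$translation, m$rotation)

#' Read a 6-DOF motion CSV
#'
#' Expects a header row and columns `time_s, tx, ty, tz, rx, ry, rz`
#' (translations in metres, rotations in degrees). Gaps (empty cells / NA)
#' are linearly interpolated; leading or trailing gaps are filled with the
#' nearest observed value.
#'
#' @param path CSV path.
#' @param axis_order Euler convention recorded in the trace metadata.
#' @return an `opm_motion`.
#' @export
read_motion_csv <- function(path, axis_order = "ZYX") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("time_s", "tx", "ty", "tz", "rx", "ry", "rz")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols) > 0)
    stop("motion CSV lacks columns: ", paste(missing_cols, collapse = ", "))
  t <- as.numeric(d$time_s)
  valid_t <- which(is.finite(t))
  if (length(valid_t) < 2) stop("motion CSV has fewer than 2 valid rows")
  d <- d[valid_t, , drop = FALSE]
  t <- t[valid_t]
  if (is.unsorted(t, strictly = TRUE))
    stop("motion CSV time is not strictly increasing")
  pose <- sapply(required[-1], function(cn) {
    v <- as.numeric(d[[cn]])
    ok <- is.finite(v)
    if (sum(ok) < 2) stop("motion CSV column ", cn, " has <2 valid values")
    if (!all(ok))
      v <- stats::approx(t[ok], v[ok], xout = t, rule = 2)$y
    v
  })
  new_motion(t, pose[, 1:3, drop = FALSE], pose[, 4:6, drop = FALSE],
             axis_order = axis_order)
}

#' Write a motion trace as CSV
#' @param m an `opm_motion`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_motion_csv <- function(m, path) {
  d <- data.frame(time_s = m$time, m$translation, m$rotation)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Synchronise and upsample a motion trace onto a recording's time base
#'
#' The motion clock is aligned so that motion time zero lands on the first
#' half-maximum threshold crossing of the named trigger channel. Pose is then
#' linearly interpolated at every recording sample; outside the observed span
#' it is linearly extrapolated from the end slopes for up to `clamp_after`
#' seconds and clamped to the first/last observed pose beyond that.
#'
#' @param m an `opm_motion`.
#' @param rec an `opm_recording` containing the sync trigger channel.
#' @param trigger_channel name of the sync trigger channel.
#' @param clamp_after seconds of linear extrapolation allowed beyond the
#'   motion span before clamping (default 0.5).
#' @return an `opm_motion` with one pose sample per recording sample.
#' @export
sync_and_upsample_motion <- function(m, rec, trigger_channel,
                                     clamp_after = 0.5) {
  i <- match(trigger_channel, rec$channels$name)
  if (is.na(i)) stop("no such channel: ", trigger_channel)
  on <- pulse_onsets(rec$data[i, ])
  if (length(on) == 0) stop("no sync pulse found on ", trigger_channel)
  if (length(on) > 1)
    warning("multiple pulses on ", trigger_channel, "; using the first")
  t_pulse <- rec$t0 + (on[1] - 1) / rec$fs
  t_rec <- rec_times(rec)
  # recording times expressed on the motion clock
  tq <- t_rec - t_pulse + m$time[1]
  pose <- motion_pose(m)
  n <- length(m$time)
  out <- matrix(0, length(tq), 6)
  lo <- m$time[1]; hi <- m$time[n]
  slope_lo <- (pose[2, ] - pose[1, ]) / (m$time[2] - m$time[1])
  slope_hi <- (pose[n, ] - pose[n - 1, ]) / (m$time[n] - m$time[n - 1])
  for (j in 1:6) {
    v <- stats::approx(m$time, pose[, j], xout = pmin(pmax(tq, lo), hi))$y
    below <- tq < lo
    above <- tq > hi
    v[below] <- pose[1, j] + slope_lo[j] * pmax(tq[below] - lo, -clamp_after)
    v[above] <- pose[n, j] + slope_hi[j] * pmin(tq[above] - hi, clamp_after)
    out[, j] <- v
  }
  new_motion(tq, out[, 1:3, drop = FALSE], out[, 4:6, drop = FALSE],
             axis_order = m$axis_order)
}

#' Low-pass condition a motion trace for regression
#'
#' Applies a zero-phase Butterworth low-pass to each pose column, the
#' conditioning applied to motion-capture traces before they are used as
#' nuisance regressors.
#'
#' @param m an `opm_motion` on a uniform time grid.
#' @param cutoff low-pass cutoff in Hz (default 2).
#' @param order filter order (default 4).
#' @return the filtered `opm_motion`.
#' @export
condition_motion <- function(m, cutoff = 2, order = 4) {
  dt <- diff(m$time)
  if (diff(range(dt)) > 1e-6 * mean(dt))
    stop("condition_motion needs a uniformly sampled trace")
  fs <- 1 / mean(dt)
  pose <- motion_pose(m)
  filt <- apply(pose, 2, function(v)
    zerophase_filter_vec(v, fs, "lowpass", cutoff, order))
  new_motion(m$time, filt[, 1:3, drop = FALSE], filt[, 4:6, drop = FALSE],
             axis_order = m$axis_order)
}

#' Rotation matrices from Euler angles
#'
#' Intrinsic ZYX (yaw-pitch-roll) rotation matrices for each row of an
#' angle matrix in degrees.
#'
#' @param rotation matrix (n x 3) of Euler angles in degrees (rx = pitch,
#'   ry = yaw... columns are applied as R = Rz(rz) Ry(ry) Rx(rx)).
#' @return array (3 x 3 x n) of rotation matrices.
#' @export
euler_to_rotmat <- function(rotation) {
  rotation <- as.matrix(rotation)
  n <- nrow(rotation)
  a <- rotation * pi / 180
  out <- array(0, c(3, 3, n))
  cx <- cos(a[, 1]); sx <- sin(a[, 1])
  cy <- cos(a[, 2]); sy <- sin(a[, 2])
  cz <- cos(a[, 3]); sz <- sin(a[, 3])
  # R = Rz %*% Ry %*% Rx, vectorised entries
  out[1, 1, ] <- cz * cy
  out[1, 2, ] <- cz * sy * sx - sz * cx
  out[1, 3, ] <- cz * sy * cx + sz * sx
  out[2, 1, ] <- sz * cy
  out[2, 2, ] <- sz * sy * sx + cz * cx
  out[2, 3, ] <- sz * sy * cx - cz * sx
  out[3, 1, ] <- -sy
  out[3, 2, ] <- cy * sx
  out[3, 3, ] <- cy * cx
  out
}
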