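#' Interference specification for the session simulator
#'
#' Describes the interference mix of a synthetic OPM session: a homogeneous
#' (spatially constant 3-vector) low-frequency remnant-field drift, a static
#' remnant-field gradient that moving sensors sweep through, narrow-band
#' line interferers with slow amplitude drift, and white sensor noise.
#'
#' @param homogeneous_peak peak magnitude of the homogeneous field drift in
#'   tesla (default 5e-10, i.e. 500 pT — dominant at very low frequencies).
#' @param homogeneous_band frequency band of the drift in Hz (default
#'   0.02-5 Hz).
#' @param homogeneous_exponent spectral slope of the drift: component
#'   amplitudes scale as `1/f^exponent` (default 1).
#' @param static_field static remnant field magnitude in tesla (default
#'   2e-9, i.e. 2 nT — a typical residual after degaussing a shielded
#'   room). Sensors sweeping their sensitive axes through this field as the
#'   head rotates produce the dominant movement artifact.
#' @param gradient_scale magnitude of the static traceless symmetric
#'   remnant-field gradient in T/m (default 1e-9, i.e. 1 nT/m).
#' @param lines data.frame with columns `freq` (Hz), `amplitude` (tesla,
#'   peak channel amplitude), `drift` (fractional slow amplitude
#'   modulation), `ref_visible` (logical: do the reference sensors couple
#'   to this interferer).
#' @param sensor_noise_asd white sensor-noise amplitude spectral density in
#'   fT/sqrt(Hz) (default 15, the second-generation OPM floor).
#' @return an object of class `opm_interference_spec`.
#' @export
interference_spec <- function(homogeneous_peak = 5e-10,
                              homogeneous_band = c(0.02, 5),
                              homogeneous_exponent = 1,
                              static_field = 2e-9,
                              gradient_scale = 1e-9,
                              lines = default_lines("aef"),
                              sensor_noise_asd = 15) {
  stopifnot(homogeneous_peak >= 0, static_field >= 0, gradient_scale >= 0,
            sensor_noise_asd >= 0)
  if (!is.null(lines) && nrow(lines) > 0)
    stopifnot(all(lines$amplitude >= 0), all(lines$freq > 0))
  structure(list(homogeneous_peak = homogeneous_peak,
                 homogeneous_band = homogeneous_band,
                 homogeneous_exponent = homogeneous_exponent,
                 static_field = static_field,
                 gradient_scale = gradient_scale, lines = lines,
                 sensor_noise_asd = sensor_noise_asd),
            class = "opm_interference_spec")
}

#' Default narrow-band interferer tables
#'
#' The line sets seen in the two experiments: mains harmonics (50/100 Hz),
#' an LED driver at 120 Hz, and unexplained narrow-band sources at 21, 41.5,
#' 83 and 106 Hz. The 21 and 41.5 Hz interferers in the tapping set do not
#' couple to the reference sensors.
#'
#' @param which `"aef"` or `"tapping"`.
#' @return a `lines` data.frame for [interference_spec()].
#' @export
default_lines <- function(which = c("aef", "tapping")) {
  which <- match.arg(which)
  if (which == "aef")
    data.frame(freq = c(21, 50, 100, 106, 120),
               amplitude = c(3e-13, 2e-12, 5e-13, 3e-13, 1e-12),
               drift = 0.2,
               ref_visible = TRUE)
  else
    data.frame(freq = c(21, 41.5, 50, 83, 100),
               amplitude = c(4e-13, 3e-13, 2e-12, 3e-13, 5e-13),
               drift = 0.2,
               ref_visible = c(FALSE, FALSE, TRUE, TRUE, TRUE))
}

#' Simulate a smooth 6-DOF motion trajectory
#'
#' A band-limited (< 2 Hz) random rigid-body path: zero pose until
#' `still_until`, then smooth random translations and rotations, rescaled so
#' the max-min range of every translation axis equals `translation_range`
#' (and every rotation axis `rotation_range`).
#'
#' @param duration trace duration in seconds.
#' @param fs motion sampling rate in Hz (default 120, a typical
#'   motion-capture rate).
#' @param still_until seconds of stillness at the start (default 0).
#' @param translation_range per-axis translation range in metres.
#' @param rotation_range per-axis rotation range in degrees.
#' @param seed RNG seed.
#' @return an `opm_motion`.
#' @export
simulate_motion_trajectory <- function(duration, fs = 120, still_until = 0,
                                       translation_range = 1.0,
                                       rotation_range = 10, seed = 1) {
  stopifnot(duration > 0, still_until >= 0, still_until <= duration)
  if (translation_range < 0) stop("translation_range must be non-negative")
  set.seed(seed)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  pose <- matrix(0, n, 6)
  moving <- t >= still_until
  if (any(moving) && still_until < duration) {
    # smooth random path: sum of low-frequency sinusoids below 0.5 Hz
    # (natural sway and deliberate head movements are slow)
    K <- 24
    for (j in 1:6) {
      fr <- stats::runif(K, 0.02, 0.5)
      ph <- stats::runif(K, 0, 2 * pi)
      am <- 1 / (fr + 0.05)
      v <- colSums(am * sin(2 * pi * outer(fr, t) + ph))
      # anchor to zero at movement onset, fade in over 2 s
      v <- v - stats::approx(t, v, xout = still_until, rule = 2)$y
      ramp <- pmin(pmax((t - still_until) / 2, 0), 1)
      ramp <- (1 - cos(pi * ramp)) / 2
      v <- v * ramp
      rng <- max(v) - min(v)
      target <- if (j <= 3) translation_range else rotation_range
      pose[, j] <- if (rng > 0) v * (target / rng) else v
    }
  }
  new_motion(t, pose[, 1:3, drop = FALSE], pose[, 4:6, drop = FALSE])
}

# interpolate a motion trace onto an arbitrary time grid (linear, clamped)
pose_at <- function(m, t_query) {
  pose <- motion_pose(m)
  sapply(1:6, function(j)
    stats::approx(m$time, pose[, j], xout = t_query, rule = 2)$y)
}

#' Simulate interference components for an array
#'
#' Generates the per-component interference matrices of
#' [interference_spec()] for a given channel set and motion path:
#' \describe{
#'   \item{homogeneous}{every magnetometer sees the same field 3-vector
#'     `B0(t)` through its own orientation (exactly rank 3 across
#'     channels);}
#'   \item{gradient_motion}{each scalp sensor is carried through the static
#'     gradient field by the rigid-body motion (references stay put);}
#'   \item{lines}{amplitude-drifting sinusoids with a fixed random spatial
#'     coupling vector per line;}
#'   \item{sensor_noise}{independent white noise per channel at the stated
#'     ASD.}
#' }
#'
#' @param channels channel table (scalp + reference magnetometers; trigger
#'   rows get zeros).
#' @param spec an `opm_interference_spec`.
#' @param motion an `opm_motion` covering the duration (for the
#'   gradient-motion term).
#' @param duration seconds to simulate.
#' @param fs sampling rate in Hz.
#' @param seed RNG seed.
#' @return list of matrices (`n_channels x n_samples`, tesla):
#'   `homogeneous`, `gradient_motion`, `lines`, `sensor_noise`; plus `b0`
#'   (3 x n field drift) and `gradient_tensor` (3 x 3).
#' @export
simulate_interference <- function(channels, spec, motion, duration, fs,
                                  seed = 1) {
  stopifnot(inherits(spec, "opm_interference_spec"))
  if (!is.null(motion) && max(motion$time) < duration - 0.1)
    stop("motion trace shorter than the requested duration")
  set.seed(seed)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  n_ch <- nrow(channels)
  mag <- channels$kind %in% c("scalp", "reference")
  scalp <- which(channels$kind == "scalp")
  ori <- matrix(0, n_ch, 3)
  ori[mag, ] <- orientation_matrix(channels[mag, , drop = FALSE])
  pos <- matrix(0, n_ch, 3)
  pos[mag, ] <- position_matrix(channels[mag, , drop = FALSE])

  # (a) homogeneous drift: 1/f^a-weighted sinusoids in the stated band
  b0 <- matrix(0, 3, n)
  if (spec$homogeneous_peak > 0) {
    K <- 60
    for (j in 1:3) {
      fr <- exp(stats::runif(K, log(spec$homogeneous_band[1]),
                             log(spec$homogeneous_band[2])))
      ph <- stats::runif(K, 0, 2 * pi)
      am <- 1 / fr^spec$homogeneous_exponent
      b0[j, ] <- colSums(am * sin(2 * pi * outer(fr, t) + ph))
    }
    b0 <- b0 * (spec$homogeneous_peak / max(sqrt(colSums(b0^2))))
  }
  homog <- ori %*% b0

  # (b) gradient-motion: scalp sensors ride the rigid body through the
  # static field B_c + G r (references stay put, so they see none of it)
  grad_mot <- matrix(0, n_ch, n)
  G <- matrix(0, 3, 3)
  Bc <- c(0, 0, 0)
  if ((spec$gradient_scale > 0 || spec$static_field > 0) &&
      !is.null(motion)) {
    A <- matrix(stats::rnorm(9), 3)
    G <- (A + t(A)) / 2
    G <- G - diag(3) * sum(diag(G)) / 3
    if (norm(G, "F") > 0)
      G <- G * (spec$gradient_scale / norm(G, "F"))
    Bc <- stats::rnorm(3)
    Bc <- Bc / sqrt(sum(Bc^2)) * spec$static_field
    pose <- pose_at(motion, t)
    R <- euler_to_rotmat(pose[, 4:6, drop = FALSE])
    r11 <- R[1, 1, ]; r12 <- R[1, 2, ]; r13 <- R[1, 3, ]
    r21 <- R[2, 1, ]; r22 <- R[2, 2, ]; r23 <- R[2, 3, ]
    r31 <- R[3, 1, ]; r32 <- R[3, 2, ]; r33 <- R[3, 3, ]
    for (i in scalp) {
      p <- pos[i, ]; o <- ori[i, ]
      px <- r11 * p[1] + r12 * p[2] + r13 * p[3] + pose[, 1]
      py <- r21 * p[1] + r22 * p[2] + r23 * p[3] + pose[, 2]
      pz <- r31 * p[1] + r32 * p[2] + r33 * p[3] + pose[, 3]
      ox <- r11 * o[1] + r12 * o[2] + r13 * o[3]
      oy <- r21 * o[1] + r22 * o[2] + r23 * o[3]
      oz <- r31 * o[1] + r32 * o[2] + r33 * o[3]
      bx <- Bc[1] + G[1, 1] * px + G[1, 2] * py + G[1, 3] * pz
      by <- Bc[2] + G[2, 1] * px + G[2, 2] * py + G[2, 3] * pz
      bz <- Bc[3] + G[3, 1] * px + G[3, 2] * py + G[3, 3] * pz
      v <- ox * bx + oy * by + oz * bz
      grad_mot[i, ] <- v - v[1]
    }
  }

  # (c) narrow-band lines with slow amplitude drift and fixed coupling
  lines_mat <- matrix(0, n_ch, n)
  if (!is.null(spec$lines) && nrow(spec$lines) > 0) {
    for (k in seq_len(nrow(spec$lines))) {
      ln <- spec$lines[k, ]
      cpl <- stats::rnorm(n_ch)
      cpl[!mag] <- 0
      if (!isTRUE(ln$ref_visible)) cpl[channels$kind == "reference"] <- 0
      cpl <- cpl / max(abs(cpl))
      ph <- stats::runif(1, 0, 2 * pi)
      drift_ph <- stats::runif(1, 0, 2 * pi)
      s <- (1 + ln$drift * sin(2 * pi * 0.03 * t + drift_ph)) *
        sin(2 * pi * ln$freq * t + ph)
      lines_mat <- lines_mat + (ln$amplitude * cpl) %o% s
    }
  }

  # (d) white sensor noise
  noise <- matrix(0, n_ch, n)
  if (spec$sensor_noise_asd > 0) {
    sigma <- spec$sensor_noise_asd * 1e-15 * sqrt(fs / 2)
    noise[mag, ] <- stats::rnorm(sum(mag) * n, sd = sigma)
  }

  list(homogeneous = homog, gradient_motion = grad_mot, lines = lines_mat,
       sensor_noise = noise, b0 = b0, gradient_tensor = G,
       static_field = Bc)
}

# biphasic evoked waveform: difference of two Gaussians, shifted so its
# maximum sits exactly at `peak_t`, unit peak amplitude
evoked_waveform <- function(t, peak_t = 0.1) {
  g <- function(x) exp(-(x - 0.100)^2 / (2 * 0.018^2)) -
    0.55 * exp(-(x - 0.200)^2 / (2 * 0.035^2))
  xf <- seq(0, 0.4, by = 1e-5)
  shift <- xf[which.max(g(xf))] - peak_t
  w <- g(t + shift)
  w / max(g(xf))
}

# physiological artifact matrices; returns list(physiological, blink_times,
# cardiac_times, blink_durations)
physiological_components <- function(channels, duration, fs, blink_rate,
                                     heart_rate, seed,
                                     blink_amplitude = 2e-12,
                                     cardiac_amplitude = 1e-12) {
  set.seed(seed)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  n_ch <- nrow(channels)
  mag <- channels$kind %in% c("scalp", "reference")
  pos <- matrix(0, n_ch, 3)
  pos[mag, ] <- position_matrix(channels[mag, , drop = FALSE])
  scalp <- channels$kind == "scalp"
  blink_tc <- numeric(n); cardiac_tc <- numeric(n)
  blink_cpl <- numeric(n_ch); cardiac_cpl <- numeric(n_ch)
  blink_times <- numeric(0); blink_durations <- numeric(0)
  cardiac_times <- numeric(0)
  if (blink_rate > 0) {
    eye <- c(0, 0.10, -0.01)  # anterior (+y), low z
    d2 <- rowSums(sweep(pos, 2, eye)^2)
    blink_cpl <- exp(-d2 / (2 * 0.05^2))
    blink_cpl[!scalp] <- 0
    blink_cpl <- blink_cpl / max(blink_cpl) * blink_amplitude
    tt <- stats::rexp(ceiling(blink_rate / 60 * duration * 3),
                      rate = blink_rate / 60)
    tt <- cumsum(tt)
    tt <- tt[tt < duration - 0.6]
    for (b in tt) {
      d <- stats::runif(1, 0.2, 0.5)
      idx <- which(t >= b & t < b + d)
      tau <- (t[idx] - b) / d
      blink_tc[idx] <- blink_tc[idx] + sin(2 * pi * tau) * sin(pi * tau)^2
      blink_durations <- c(blink_durations, d)
    }
    blink_times <- tt
  }
  if (heart_rate > 0) {
    side <- c(-0.12, -0.02, -0.05)  # left lateral, inferior
    d2 <- rowSums(sweep(pos, 2, side)^2)
    cardiac_cpl <- exp(-d2 / (2 * 0.08^2))
    cardiac_cpl[!scalp] <- 0
    cardiac_cpl <- cardiac_cpl / max(cardiac_cpl) * cardiac_amplitude
    period <- 60 / heart_rate
    beats <- numeric(0)
    b <- stats::runif(1, 0, period)
    while (b < duration - 0.1) {
      beats <- c(beats, b)
      b <- b + period * (1 + stats::runif(1, -0.03, 0.03))
    }
    sg <- 0.012
    for (b in beats) {
      idx <- which(abs(t - b) <= 4 * sg)
      tau <- t[idx] - b
      cardiac_tc[idx] <- cardiac_tc[idx] +
        (1 - (tau / sg)^2) * exp(-tau^2 / (2 * sg^2))
    }
    cardiac_times <- beats
  }
  out <- blink_cpl %o% blink_tc + cardiac_cpl %o% cardiac_tc
  list(physiological = out, blink_tc = blink_tc, blink_coupling = blink_cpl,
       cardiac_tc = cardiac_tc, cardiac_coupling = cardiac_cpl,
       blink_times = blink_times, blink_durations = blink_durations,
       cardiac_times = cardiac_times)
}

#' Inject physiological artifacts into a recording
#'
#' Adds eye-blink transients (sporadic biphasic deflections of 0.2-0.5 s,
#' coupled most strongly to low, anterior sensors) and a quasi-periodic
#' QRS-like cardiac wavelet train (period jittered by +/- 3%, coupled
#' laterally) to the scalp channels.
#'
#' @param rec an `opm_recording`.
#' @param blink_rate blinks per minute (0 disables).
#' @param heart_rate beats per minute (0 disables).
#' @param seed RNG seed.
#' @param blink_amplitude peak blink field in tesla (default 2 pT).
#' @param cardiac_amplitude peak QRS field in tesla (default 1 pT).
#' @return list with `recording` (artifacts added) and `components`
#'   (the added `physiological` matrix plus blink/beat times).
#' @export
inject_physiological_artifacts <- function(rec, blink_rate = 0,
                                           heart_rate = 0, seed = 1,
                                           blink_amplitude = 2e-12,
                                           cardiac_amplitude = 1e-12) {
  validate_recording(rec)
  stopifnot(blink_rate >= 0, heart_rate >= 0)
  comp <- physiological_components(rec$channels, n_seconds(rec), rec$fs,
                                   blink_rate, heart_rate, seed,
                                   blink_amplitude, cardiac_amplitude)
  out <- rec
  out$data <- rec$data + comp$physiological
  out <- append_history(out, "inject_physiological_artifacts",
                        list(blink_rate = blink_rate,
                             heart_rate = heart_rate, seed = seed))
  list(recording = out, components = comp)
}

#' Configuration for a synthetic auditory-evoked-field session
#'
#' Emulates a mobile experiment: a standing, continuously moving
#' participant, bilateral auditory sources driven by a biphasic response
#' peaking 100 ms after each tone, tones at a fixed 0.5 s inter-stimulus
#' interval starting after an initial still period, and the full
#' interference mix (remnant-field drift, gradient motion artifacts, lines,
#' sensor noise).
#'
#' @param n_trials number of tones (default 570, the full session; tests
#'   and examples use far fewer).
#' @param n_sensors,axes array layout (default 43 dual-axis sensors, 86
#'   channels).
#' @param fs sampling rate in Hz (default 1000).
#' @param isi inter-stimulus interval in seconds (default 0.5).
#' @param still_until seconds before movement and stimulation start
#'   (default 6; the full-scale session used a longer lead-in).
#' @param amplitude_target peak noiseless evoked sensor field in tesla
#'   (default 2.2e-13, i.e. 220 fT).
#' @param translation_range,rotation_range movement ranges (default 1 m and
#'   10 degrees — large natural movements).
#' @param interference an `opm_interference_spec`.
#' @param blink_rate,heart_rate physiological artifact rates (default 0).
#' @param duration session length in seconds; `NULL` (default) fits the
#'   stimulus train plus a 1 s tail.
#' @return config list for [simulate_evoked_session()].
#' @export
aef_config <- function(n_trials = 570, n_sensors = 43, axes = "dual",
                       fs = 1000, isi = 0.5, still_until = 6,
                       amplitude_target = 2.2e-13,
                       translation_range = 1.0, rotation_range = 10,
                       interference = interference_spec(),
                       blink_rate = 0, heart_rate = 0, duration = NULL) {
  if (n_trials < 1) stop("n_trials must be at least 1")
  if (amplitude_target <= 0) stop("amplitude_target must be positive")
  if (is.null(duration)) duration <- still_until + n_trials * isi + 1
  list(kind = "aef", n_trials = n_trials, n_sensors = n_sensors,
       axes = axes, fs = fs, isi = isi, still_until = still_until,
       amplitude_target = amplitude_target,
       translation_range = translation_range,
       rotation_range = rotation_range, interference = interference,
       blink_rate = blink_rate, heart_rate = heart_rate,
       duration = duration)
}

#' Simulate an auditory-evoked-field session
#'
#' Builds the array, motion path, bilateral correlated dipole sources,
#' interference and trigger channels of an [aef_config()] session, and
#' returns the assembled recording together with exact per-component ground
#' truth (every magnetometer row of the data equals the sum of the truth
#' components).
#'
#' @param config an [aef_config()] list.
#' @param seed RNG seed; the whole session is reproducible from it.
#' @return list with `recording` (`opm_recording`), `truth` (class
#'   `opm_truth`: `components` matrices `brain`, `homogeneous`,
#'   `gradient_motion`, `lines`, `physiological`, `sensor_noise`; `sources`
#'   with positions/moments/time courses; `events`; `motion` at 120 Hz;
#'   `sphere`), and `events`.
#' @export
simulate_evoked_session <- function(config = aef_config(n_trials = 40),
                                    seed = 1) {
  stopifnot(identical(config$kind, "aef"))
  fs <- config$fs
  duration <- config$duration
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  geom <- build_array_geometry(config$n_sensors, config$axes)
  refs <- build_reference_channels()
  channels <- rbind(geom, refs, trigger_channel_row("NI-TRIG"),
                    trigger_channel_row("FluxZ-A"))
  n_ch <- nrow(channels)
  sphere <- sphere_model()

  motion <- simulate_motion_trajectory(duration, fs = 120,
                                       still_until = config$still_until,
                                       translation_range =
                                         config$translation_range,
                                       rotation_range = config$rotation_range,
                                       seed = seed + 1L)
  interf <- simulate_interference(channels, config$interference, motion,
                                  duration, fs, seed = seed + 2L)

  # bilateral correlated sources, tangential moments
  src_pos <- auditory_sources()
  onset_t <- config$still_until + config$isi * (seq_len(config$n_trials) - 1)
  onset_sample <- round(onset_t * fs) + 1
  events <- new_events(onset_sample, "tone")
  wave <- numeric(n)
  span <- round(0.4 * fs)
  base_w <- evoked_waveform((0:span) / fs)
  for (k in onset_sample) {
    idx <- k:min(n, k + span)
    wave[idx] <- wave[idx] + base_w[seq_along(idx)]
  }
  brain_pattern <- rep(0, n_ch)
  for (sp in src_pos) {
    rad <- sp / sqrt(sum(sp^2))
    tang <- c(0, 0, 1) - rad[3] * rad
    tang <- tang / sqrt(sum(tang^2))
    Lf <- sarvas_leadfield(geom, sphere, sp)
    contrib <- as.numeric(Lf %*% tang)
    brain_pattern[seq_len(nrow(geom))] <-
      brain_pattern[seq_len(nrow(geom))] + contrib
  }
  brain <- brain_pattern %o% wave
  pk <- max(abs(brain))
  if (pk > 0) brain <- brain * (config$amplitude_target / pk)

  physio <- physiological_components(channels, duration, fs,
                                     config$blink_rate, config$heart_rate,
                                     seed + 3L)

  data <- brain + interf$homogeneous + interf$gradient_motion +
    interf$lines + physio$physiological + interf$sensor_noise
  trig_i <- which(channels$name == "NI-TRIG")
  sync_i <- which(channels$name == "FluxZ-A")
  pulse_len <- max(1, round(0.01 * fs))
  for (k in onset_sample)
    data[trig_i, k:min(n, k + pulse_len - 1)] <- 1
  data[sync_i, 1:pulse_len] <- 1  # motion clock zero = recording start

  rec <- new_recording(channels, data, fs = fs,
                       history = list(list(step = "simulate_evoked_session",
                                           params = list(seed = seed))))
  truth <- structure(
    list(components = list(brain = brain,
                           homogeneous = interf$homogeneous,
                           gradient_motion = interf$gradient_motion,
                           lines = interf$lines,
                           physiological = physio$physiological,
                           sensor_noise = interf$sensor_noise),
         sources = list(positions = src_pos, waveform = base_w,
                        wave_continuous = wave,
                        peak_latency = 0.1),
         events = events, motion = motion, sphere = sphere,
         b0 = interf$b0, gradient_tensor = interf$gradient_tensor),
    class = "opm_truth")
  list(recording = rec, truth = truth, events = events, motion = motion)
}

#' Configuration for a synthetic finger-tapping session
#'
#' Emulates a stationary beta-band experiment: a left-hemisphere
#' sensorimotor source carrying a 13-30 Hz oscillation whose envelope drops
#' during movement (event-related desynchronisation) and rebounds above
#' baseline after movement stops, cued trials every 7-8 s, residual
#' involuntary motion only, line interferers of which two are invisible to
#' the references, and physiological artifacts.
#'
#' @param n_trials number of tapping trials (default 100, the full session).
#' @param n_sensors,axes array layout (default 39 dual-axis sensors, 78
#'   channels).
#' @param fs sampling rate in Hz (default 1000).
#' @param tap_duration seconds of tapping per trial (default 2.5).
#' @param iti inter-trial interval range in seconds (default 7-8, jittered).
#' @param erd_factor beta envelope factor during tapping (default 0.5).
#' @param pmbr_factor envelope factor during the rebound window (default
#'   1.5).
#' @param pmbr_window rebound window in seconds post-onset (default
#'   2.8-4.0).
#' @param beta_band oscillation band in Hz (default 13-30).
#' @param amplitude_target peak noiseless beta sensor field in tesla
#'   (default 8e-13).
#' @param translation_range residual involuntary head motion in metres
#'   (default 0.005).
#' @param interference an `opm_interference_spec`; the default uses a
#'   gentler drift than the mobile session plus the tapping line set.
#' @param blink_rate,heart_rate physiological rates (defaults 12/min and
#'   66 bpm).
#' @param lead_in seconds before the first trial (default 8).
#' @return config list for [simulate_tapping_session()].
#' @export
tapping_config <- function(n_trials = 100, n_sensors = 39, axes = "dual",
                           fs = 1000, tap_duration = 2.5, iti = c(7, 8),
                           erd_factor = 0.5, pmbr_factor = 1.5,
                           pmbr_window = c(2.8, 4.0),
                           beta_band = c(13, 30),
                           amplitude_target = 8e-13,
                           translation_range = 0.005,
                           interference = interference_spec(
                             homogeneous_peak = 5e-11,
                             lines = default_lines("tapping")),
                           blink_rate = 12, heart_rate = 66,
                           lead_in = 8) {
  if (n_trials < 1) stop("n_trials must be at least 1")
  if (erd_factor < 0) stop("erd_factor must be non-negative")
  list(kind = "tapping", n_trials = n_trials, n_sensors = n_sensors,
       axes = axes, fs = fs, tap_duration = tap_duration, iti = iti,
       erd_factor = erd_factor, pmbr_factor = pmbr_factor,
       pmbr_window = pmbr_window, beta_band = beta_band,
       amplitude_target = amplitude_target,
       translation_range = translation_range,
       interference = interference, blink_rate = blink_rate,
       heart_rate = heart_rate, lead_in = lead_in)
}

# trialwise beta envelope over a session time axis, with smooth ramps
beta_envelope <- function(t, onsets, config, ramp = 0.15) {
  env <- rep(1, length(t))
  smoothstep <- function(x) {
    y <- pmin(pmax(x, 0), 1)
    (1 - cos(pi * y)) / 2
  }
  for (on in onsets) {
    # ERD during tapping
    w_in <- smoothstep((t - on) / ramp)
    w_out <- smoothstep((t - (on + config$tap_duration)) / ramp)
    env <- env + (config$erd_factor - 1) * (w_in - w_out)
    # rebound above baseline
    r_in <- smoothstep((t - (on + config$pmbr_window[1])) / ramp)
    r_out <- smoothstep((t - (on + config$pmbr_window[2])) / ramp)
    env <- env + (config$pmbr_factor - 1) * (r_in - r_out)
  }
  env
}

#' Simulate a finger-tapping beta-band session
#'
#' Assembles a [tapping_config()] session with exact per-component truth,
#' as [simulate_evoked_session()] does for the evoked paradigm.
#'
#' @param config a [tapping_config()] list.
#' @param seed RNG seed.
#' @return list with `recording`, `truth` (`opm_truth`; `sources` carries
#'   the oscillation time course and envelope), and `events`.
#' @export
simulate_tapping_session <- function(config = tapping_config(n_trials = 12),
                                     seed = 1) {
  stopifnot(identical(config$kind, "tapping"))
  fs <- config$fs
  set.seed(seed)
  iti <- stats::runif(config$n_trials - 1, config$iti[1], config$iti[2])
  onset_t <- config$lead_in + c(0, cumsum(iti))
  duration <- onset_t[length(onset_t)] + config$pmbr_window[2] + 3
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  geom <- build_array_geometry(config$n_sensors, config$axes)
  refs <- build_reference_channels()
  channels <- rbind(geom, refs, trigger_channel_row("NI-TRIG"))
  n_ch <- nrow(channels)
  sphere <- sphere_model()

  motion <- simulate_motion_trajectory(duration, fs = 120, still_until = 0,
                                       translation_range =
                                         config$translation_range,
                                       rotation_range = 0.5,
                                       seed = seed + 1L)
  interf <- simulate_interference(channels, config$interference, motion,
                                  duration, fs, seed = seed + 2L)

  set.seed(seed + 4L)
  carrier <- stats::rnorm(n)
  carrier <- zerophase_filter_vec(carrier, fs, "bandpass",
                                  config$beta_band, 4)
  carrier <- carrier / stats::sd(carrier)
  env <- beta_envelope(t, onset_t, config)
  source_tc <- carrier * env

  sp <- sensorimotor_source()
  rad <- sp / sqrt(sum(sp^2))
  tang <- c(0, 1, 0) - rad[2] * rad
  tang <- tang / sqrt(sum(tang^2))
  Lf <- sarvas_leadfield(geom, sphere, sp)
  pattern <- rep(0, n_ch)
  pattern[seq_len(nrow(geom))] <- as.numeric(Lf %*% tang)
  brain <- pattern %o% source_tc
  pk <- max(abs(brain))
  if (pk > 0) {
    brain <- brain * (config$amplitude_target / pk)
    source_scale <- config$amplitude_target / pk
  } else source_scale <- 1

  physio <- physiological_components(channels, duration, fs,
                                     config$blink_rate, config$heart_rate,
                                     seed + 3L)

  data <- brain + interf$homogeneous + interf$gradient_motion +
    interf$lines + physio$physiological + interf$sensor_noise
  onset_sample <- round(onset_t * fs) + 1
  events <- new_events(onset_sample, "tap")
  trig_i <- which(channels$name == "NI-TRIG")
  pulse_len <- max(1, round(0.01 * fs))
  for (k in onset_sample)
    data[trig_i, k:min(n, k + pulse_len - 1)] <- 1

  rec <- new_recording(channels, data, fs = fs,
                       history = list(list(step = "simulate_tapping_session",
                                           params = list(seed = seed))))
  truth <- structure(
    list(components = list(brain = brain,
                           homogeneous = interf$homogeneous,
                           gradient_motion = interf$gradient_motion,
                           lines = interf$lines,
                           physiological = physio$physiological,
                           sensor_noise = interf$sensor_noise),
         sources = list(position = sp, moment = tang,
                        time_course = source_tc * source_scale,
                        envelope = env, carrier = carrier,
                        cardiac_tc = physio$cardiac_tc,
                        cardiac_coupling = physio$cardiac_coupling,
                        blink_tc = physio$blink_tc,
                        blink_coupling = physio$blink_coupling,
                        cardiac_times = physio$cardiac_times,
                        blink_times = physio$blink_times,
                        blink_durations = physio$blink_durations),
         events = events, motion = motion, sphere = sphere,
         b0 = interf$b0, gradient_tensor = interf$gradient_tensor),
    class = "opm_truth")
  list(recording = rec, truth = truth, events = events, motion = motion)
}

#' @export
print.opm_truth <- function(x, ...) {
  cat("<opm_truth> components: ",
      paste(names(x$components), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Residual between a recording and its truth components
#'
#' Conservation check: over magnetometer rows, the emitted data minus the
#' sum of all truth components (trigger rows carry the stimulus pulse train
#' and are excluded).
#'
#' @param rec the simulated `opm_recording`.
#' @param truth the matching `opm_truth`.
#' @return maximum absolute residual in tesla (0 up to float round-off).
#' @export
truth_residual <- function(rec, truth) {
  idx <- channel_idx(rec)
  total <- Reduce(`+`, truth$components)
  max(abs(rec$data[idx, , drop = FALSE] - total[idx, , drop = FALSE]))
}
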