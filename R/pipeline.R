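#' Pipeline presets
#'
#' The two tutorial stage orders. `"aef"` (mobile evoked-field session):
#' motion regression, homogeneous field correction, bad-channel removal,
#' spectral interpolation, 2 Hz high-pass, artifact detection, 40 Hz
#' low-pass, epoching, trial rejection, evoked t-statistics, dual-source
#' beamforming. `"tapping"` (stationary beta-band session): spectral
#' interpolation, 2 Hz high-pass, 80 Hz low-pass, synthetic gradiometry,
#' homogeneous field correction, ICA, epoching, time-frequency analysis,
#' baseline conversion to dB.
#'
#' @param which `"aef"` or `"tapping"`.
#' @return a pipeline config list (`stages`, each with `op` and `params`).
#' @export
pipeline_preset <- function(which = c("aef", "tapping")) {
  which <- match.arg(which)
  if (which == "aef") {
    stages <- list(
      list(op = "regress_motion", params = list(window_s = 10)),
      list(op = "hfc", params = list(scope = "scalp_only")),
      list(op = "drop_bad_channels", params = list()),
      list(op = "spectral_interpolate",
           params = list(targets = c(50, 100, 106, 120))),
      list(op = "highpass", params = list(cutoff = 2, order = 5)),
      list(op = "detect_artifacts", params = list()),
      list(op = "lowpass", params = list(cutoff = 40, order = 6)),
      list(op = "epoch", params = list(t_pre = 0.2, t_post = 0.5)),
      list(op = "reject_trials", params = list()),
      list(op = "evoked", params = list(baseline = c(-0.1, 0))),
      list(op = "beamform",
           params = list(sources = "auditory", lambda = 0.001,
                         cov_window = c(0, 0.5)))
    )
  } else {
    stages <- list(
      list(op = "spectral_interpolate",
           params = list(targets = c(21, 83, 100))),
      list(op = "highpass", params = list(cutoff = 2, order = 5)),
      list(op = "lowpass", params = list(cutoff = 80, order = 6)),
      list(op = "synthetic_gradiometry",
           params = list(window_s = 100, split_freqs = 20)),
      list(op = "hfc", params = list(scope = "scalp_only")),
      list(op = "ica", params = list(n_components = 50, seed = 454)),
      list(op = "epoch", params = list(t_pre = 2, t_post = 6)),
      list(op = "tfr", params = list(freqs = seq(1, 41, 2),
                                     window_s = 0.5, trim_s = 0.5)),
      list(op = "baseline_db", params = list(baseline = c(-1.5, 0)))
    )
  }
  list(stages = stages, snapshot = TRUE)
}

#' Read a pipeline config from YAML
#' @param path YAML file with a top-level `stages` list (each entry `op` +
#'   `params`) and optional `snapshot` flag.
#' @return a pipeline config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$stages)) stop("pipeline config has no stages")
  cfg
}

pipeline_ops <- function() c(
  "resample", "regress_motion", "hfc", "drop_bad_channels",
  "spectral_interpolate", "highpass", "lowpass", "bandpass", "detrend",
  "detect_artifacts", "synthetic_gradiometry", "ssp", "ica", "epoch",
  "reject_trials", "evoked", "beamform", "tfr", "baseline_db")

#' Run an interference-suppression pipeline
#'
#' Executes the configured stages in order on a session (a recording plus
#' optional events, motion trace and noise recording). After every stage
#' that returns continuous sensor data, a snapshot of the channel-mean
#' spectrum and the per-chunk maximum field change is recorded so stages
#' can be compared; [stage_report()] tabulates them. Any stage error aborts
#' the run naming the stage.
#'
#' @param session list with `recording` (required) and optionally `events`,
#'   `motion` (an `opm_motion`), `noise` (an `opm_recording` for SSP) — the
#'   return value of the simulators works directly.
#' @param config pipeline config (see [pipeline_preset()]); unknown stage
#'   names are rejected up front.
#' @param snapshot_recordings keep a full copy of the recording after every
#'   stage (memory-hungry; default `FALSE`).
#' @return object of class `opm_pipeline_run`: final `recording`, any
#'   `epochs`/`evoked`/`tfr`/`beamformer`/`virtual`/`segments` produced,
#'   `snapshots` (per-stage PSD + field-change summaries), and a `log`.
#' @export
run_pipeline <- function(session, config, snapshot_recordings = FALSE) {
  if (inherits(session, "opm_recording"))
    session <- list(recording = session)
  stopifnot(inherits(session$recording, "opm_recording"))
  stages <- config$stages
  if (length(stages) == 0) stop("pipeline config has an empty stage list")
  bad <- setdiff(vapply(stages, `[[`, "", "op"), pipeline_ops())
  if (length(bad) > 0)
    stop("unknown pipeline stage(s): ", paste(bad, collapse = ", "))
  snapshot <- isTRUE(config$snapshot) || is.null(config$snapshot)
  state <- list(recording = session$recording, events = session$events,
                motion = session$motion, noise = session$noise,
                epochs = NULL, evoked_raw = NULL, segments = NULL)
  snapshots <- list()
  log <- character(0)
  take_snapshot <- function(name, rec) {
    win <- min(10, n_seconds(rec) / 2)
    sn <- list(stage = name,
               psd = welch_asd(rec, window_s = win),
               mfc = max_field_change(rec),
               n_channels = nrow(rec$data))
    if (snapshot_recordings) sn$recording <- rec
    sn
  }
  if (snapshot)
    snapshots[["raw"]] <- take_snapshot("raw", state$recording)
  for (si in seq_along(stages)) {
    st <- stages[[si]]
    p <- st$params %||% list()
    state <- tryCatch(
      run_stage(state, st$op, p),
      error = function(e)
        stop("pipeline stage '", st$op, "' (", si, ") failed: ",
             conditionMessage(e), call. = FALSE))
    log <- c(log, paste0(si, ": ", st$op))
    if (snapshot && st$op %in% c("resample", "regress_motion", "hfc",
                                 "drop_bad_channels",
                                 "spectral_interpolate", "highpass",
                                 "lowpass", "bandpass", "detrend",
                                 "synthetic_gradiometry", "ssp", "ica"))
      snapshots[[paste0(si, "_", st$op)]] <-
        take_snapshot(st$op, state$recording)
  }
  structure(c(state, list(snapshots = snapshots, log = log,
                          config = config)),
            class = "opm_pipeline_run")
}

run_stage <- function(state, op, p) {
  rec <- state$recording
  switch(op,
    resample = {
      state$recording <- resample_recording(rec, p$fs_new)
      if (!is.null(state$events))
        state$events <- new_events(
          pmax(1, round((state$events$onset_sample - 1) *
                          p$fs_new / rec$fs) + 1),
          state$events$code)
      state
    },
    regress_motion = {
      if (is.null(state$motion)) stop("no motion trace in the session")
      m <- state$motion
      if (length(m$time) != ncol(rec$data)) {
        sync_ch <- p$sync_channel %||% "FluxZ-A"
        m <- sync_and_upsample_motion(m, rec, sync_ch)
      }
      m <- condition_motion(m, cutoff = p$motion_lowpass %||% 2)
      res <- regress_motion(rec, m, window_s = p$window_s %||% 10,
                            overlap = p$overlap %||% 0.5)
      state$recording <- res$recording
      state$motion_report <- res$report
      state
    },
    hfc = {
      state$recording <- apply_hfc(rec, scope = p$scope %||% "scalp_only")
      state
    },
    drop_bad_channels = {
      bad <- p$channels %||% detect_bad_channels(rec)
      if (length(bad) > 0)
        state$recording <- select_channels(rec, bad, drop = TRUE)
      state$bad_channels <- bad
      state
    },
    spectral_interpolate = {
      state$recording <- spectral_interpolate(
        rec, p$targets, halfwidth = p$halfwidth %||% 0.5,
        neighbour_width = p$neighbour_width %||% 1)
      state
    },
    highpass = {
      state$recording <- butter_zerophase(rec, "highpass", p$cutoff,
                                          p$order %||% 5)
      state
    },
    lowpass = {
      state$recording <- butter_zerophase(rec, "lowpass", p$cutoff,
                                          p$order %||% 6)
      state
    },
    bandpass = {
      state$recording <- butter_zerophase(rec, "bandpass", p$cutoff,
                                          p$order %||% 4)
      state
    },
    detrend = {
      state$recording <- detrend_windowed(rec, p$poly_order %||% 1,
                                          p$window_s,
                                          p$overlap %||% 0.5,
                                          robust = isTRUE(p$robust))
      state
    },
    detect_artifacts = {
      state$segments <- p$segments %||% detect_artifact_segments(
        rec,
        jump_threshold = p$jump_threshold %||% 5e-12,
        jump_window = p$jump_window %||% 0.1,
        min_channel_fraction = p$min_channel_fraction %||% 0.5)
      state
    },
    synthetic_gradiometry = {
      res <- synthetic_gradiometry(
        rec, reference_names = p$reference_names,
        split_freqs = p$split_freqs %||% 20,
        window_s = p$window_s %||% 100, overlap = p$overlap %||% 0.5)
      state$recording <- res$recording
      state$gradiometry_report <- res$report
      state
    },
    ssp = {
      if (is.null(state$noise)) stop("no noise recording in the session")
      proj <- ssp_from_noise(state$noise, p$n_components)
      state$recording <- apply_projector(rec, proj, step = "ssp")
      state
    },
    ica = {
      res <- ica_denoise(rec, n_components = p$n_components %||% 50,
                         seed = p$seed %||% 454,
                         flag_components = p$flag_components,
                         flag_rules = p$flag_rules %||%
                           list(low_freq = TRUE, lf_cut = 5,
                                lf_frac = 0.6))
      state$recording <- res$recording
      state$ica_report <- res$report
      state
    },
    epoch = {
      ev <- state$events %||% events_from_trigger(rec, p$trigger %||%
                                                    "NI-TRIG")
      state$epochs <- epoch_by_trigger(rec, ev, p$t_pre, p$t_post)
      state
    },
    reject_trials = {
      if (is.null(state$epochs)) stop("epoch before rejecting trials")
      state$epochs <- reject_artifact_trials(state$epochs,
                                             state$segments)
      state
    },
    evoked = {
      if (is.null(state$epochs)) stop("epoch before evoked statistics")
      state$evoked <- evoked_tstats(state$epochs,
                                    baseline = p$baseline %||% c(-0.1, 0))
      state
    },
    beamform = {
      if (is.null(state$epochs)) stop("epoch before beamforming")
      sphere <- p$sphere %||% sphere_model()
      src <- if (identical(p$sources, "auditory")) auditory_sources()
             else p$sources
      ep <- state$epochs
      scalp_ch <- ep$channels[ep$channels$kind == "scalp", , drop = FALSE]
      L <- dual_source_leadfield(scalp_ch, sphere, src)
      cv <- epoch_covariance(ep, p$cov_window %||% c(0, 0.5))
      bf <- lcmv_weights(L, cv, lambda_fraction = p$lambda %||% 0.001,
                         source_positions = src)
      state$beamformer <- bf
      state$virtual <- virtual_channel(bf, ep,
                                       source_index = p$source_index %||% 1,
                                       window = p$window)
      state
    },
    tfr = {
      if (is.null(state$epochs)) stop("epoch before TFR analysis")
      state$tfr <- tfr_hanning(state$epochs,
                               freqs = p$freqs %||% seq(1, 41, 2),
                               window_s = p$window_s %||% 0.5,
                               step_s = p$step_s %||% 0.05,
                               trim_s = p$trim_s %||% 0.5)
      state
    },
    baseline_db = {
      if (is.null(state$tfr)) stop("compute a TFR before baseline_db")
      state$tfr <- baseline_db(state$tfr, p$baseline)
      state
    },
    stop("unknown stage op: ", op))
}

#' @export
print.opm_pipeline_run <- function(x, ...) {
  cat("<opm_pipeline_run> ", length(x$log), " stages\n", sep = "")
  cat("  ", paste(x$log, collapse = "\n  "), "\n", sep = "")
  invisible(x)
}

#' Tabulate per-stage summaries of a pipeline run
#'
#' For each snapshotted stage: the channel-mean ASD spectrum, the gain in
#' dB relative to the previous stage (shielding factor), and the median
#' per-chunk maximum field change.
#'
#' @param run an `opm_pipeline_run` with snapshots.
#' @param band frequency band (Hz) over which `gain_band_db` is averaged
#'   (default 0-40).
#' @return list with `stages` (data.frame: stage, median and maximum field
#'   change in pT, mean in-band gain vs the previous stage in dB) and
#'   `asd` (matrix freq x stage of channel-mean ASD, fT/sqrt(Hz)).
#' @export
stage_report <- function(run, band = c(0, 40)) {
  stopifnot(inherits(run, "opm_pipeline_run"))
  sn <- run$snapshots
  if (length(sn) == 0) stop("run has no snapshots")
  freqs <- sn[[1]]$psd$freqs
  asd <- sapply(sn, function(s) {
    m <- mean_asd(s$psd)
    if (length(m) != length(freqs)) rep(NA_real_, length(freqs)) else m
  })
  sel <- freqs >= band[1] & freqs <= band[2] & freqs > 0
  gains <- rep(NA_real_, length(sn))
  for (k in seq_along(sn)[-1]) {
    a <- asd[sel, k - 1]; b <- asd[sel, k]
    if (!anyNA(a) && !anyNA(b))
      gains[k] <- mean(20 * log10(a / b))
  }
  stages <- data.frame(
    stage = vapply(sn, `[[`, "", "stage"),
    n_channels = vapply(sn, `[[`, 0, "n_channels"),
    median_mfc_pt = vapply(sn, function(s)
      stats::median(s$mfc$max_change_pt), 0),
    max_mfc_pt = vapply(sn, function(s) max(s$mfc$max_change_pt), 0),
    gain_band_db = gains,
    row.names = NULL)
  list(stages = stages, asd = asd, freqs = freqs, band = band)
}
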