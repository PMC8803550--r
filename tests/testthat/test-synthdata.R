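test_that("motion trajectories are still, band-limited and range-exact", {
  still <- simulate_motion_trajectory(10, still_until = 10, seed = 1)
  expect_true(all(motion_pose(still) == 0))

  m <- simulate_motion_trajectory(60, fs = 120, still_until = 5,
                                  translation_range = 1.0,
                                  rotation_range = 8, seed = 3)
  rng_t <- apply(m$translation, 2, function(v) diff(range(v)))
  rng_r <- apply(m$rotation, 2, function(v) diff(range(v)))
  expect_rel_equal(rng_t, rep(1.0, 3), 1e-9)
  expect_rel_equal(rng_r, rep(8, 3), 1e-9)
  expect_true(all(abs(motion_pose(m)[m$time < 5, ]) == 0))

  # spectral content above 2 Hz is negligible
  tx <- m$translation[, 1]
  p <- Mod(stats::fft(tx - mean(tx)))^2
  nf <- floor(length(tx) / 2)
  fr <- (seq_len(nf) - 1) * 120 / length(tx)
  frac_hi <- sum(p[seq_len(nf)][fr > 2]) / sum(p[seq_len(nf)][fr > 0])
  expect_lt(frac_hi, 0.01)

  expect_error(simulate_motion_trajectory(10, translation_range = -1),
               "non-negative")
})

test_that("interference components have the stated structure", {
  channels <- rbind(build_array_geometry(10, "dual"),
                    build_reference_channels())
  still <- simulate_motion_trajectory(10, still_until = 10, seed = 1)

  # homogeneous-only: exactly rank 3 across channels
  sp <- interference_spec(homogeneous_peak = 5e-10, static_field = 0,
                          gradient_scale = 0, lines = NULL,
                          sensor_noise_asd = 0)
  comp <- simulate_interference(channels, sp, still, 10, 250, seed = 2)
  sv <- svd(comp$homogeneous)$d
  expect_lt(sv[4] / sv[1], 1e-12)
  expect_gt(sv[3] / sv[1], 1e-6)
  # peak field magnitude matches the spec scale
  expect_equal(max(sqrt(colSums(comp$b0^2))), 5e-10, tolerance = 1e-12)

  # white-noise-only: per-sample sd and Welch ASD match the identity
  # sigma = ASD * sqrt(fs/2)
  fs <- 1000
  spn <- interference_spec(homogeneous_peak = 0, static_field = 0,
                           gradient_scale = 0, lines = NULL,
                           sensor_noise_asd = 15)
  compn <- simulate_interference(channels, spn,
                                 simulate_motion_trajectory(30, still_until = 30),
                                 30, fs, seed = 3)
  sig <- sd(compn$sensor_noise[1, ])
  expect_equal(sig, 15e-15 * sqrt(fs / 2), tolerance = 0.02)
  rec <- new_recording(channels, compn$sensor_noise, fs)
  psd <- welch_asd(rec, window_s = 5)
  med <- median(psd$asd[, psd$freqs > 10 & psd$freqs < 100])
  expect_lt(abs(med - 15) / 15, 0.05)

  # still motion: gradient term is identically zero
  spg <- interference_spec(homogeneous_peak = 0, gradient_scale = 1e-9,
                           lines = NULL, sensor_noise_asd = 0)
  compg <- simulate_interference(channels, spg, still, 10, 250, seed = 4)
  expect_true(all(compg$gradient_motion == 0))

  # references never see the gradient-motion term
  mv <- simulate_motion_trajectory(10, still_until = 0,
                                   translation_range = 0.5, seed = 5)
  compm <- simulate_interference(channels, spg, mv, 10, 250, seed = 5)
  refs <- which(channels$kind == "reference")
  expect_true(all(compm$gradient_motion[refs, ] == 0))
  expect_gt(max(abs(compm$gradient_motion)), 0)
})

test_that("evoked sessions conserve truth, hit the target peak, and are
           reproducible", {
  # noiseless, interference-free run: exact latency and amplitude
  quiet <- interference_spec(homogeneous_peak = 0, static_field = 0,
                             gradient_scale = 0, lines = NULL,
                             sensor_noise_asd = 0)
  cfg <- aef_config(n_trials = 5, fs = 1000, still_until = 1,
                    interference = quiet, translation_range = 0)
  ses <- simulate_evoked_session(cfg, seed = 1)
  expect_equal(max(abs(ses$recording$data[channel_idx(ses$recording), ])),
               2.2e-13, tolerance = 1e-19)
  ep <- epoch_by_trigger(ses$recording, ses$events, 0.2, 0.5)
  ev <- evoked_tstats(ep)
  pk <- which(abs(ev$mean) == max(abs(ev$mean)), arr.ind = TRUE)[1, ]
  expect_equal(ev$times[pk[2]], 0.100, tolerance = 1e-9)

  # default preset encodes the full session's trial count
  expect_equal(aef_config()$n_trials, 570)
  expect_equal(nrow(ses$events), 5)

  # conservation and bitwise reproducibility under default interference
  ses2 <- small_aef_session()
  expect_lt(truth_residual(ses2$recording, ses2$truth), 1e-18)
  cfg3 <- aef_config(n_trials = 3, fs = 250, still_until = 1)
  a <- simulate_evoked_session(cfg3, seed = 42)
  b <- simulate_evoked_session(cfg3, seed = 42)
  expect_identical(a$recording$data, b$recording$data)
  expect_error(aef_config(amplitude_target = 0), "positive")
})

test_that("tapping sessions carry the ERD/PMBR envelope and line set", {
  expect_equal(tapping_config()$n_trials, 100)
  ses <- small_tapping_session()
  expect_equal(nrow(ses$events), 8)
  expect_lt(truth_residual(ses$recording, ses$truth), 1e-18)

  # envelope ground truth: mean beta power ratio task/baseline = ERD^2
  env <- ses$truth$sources$envelope
  fs <- ses$recording$fs
  on <- (ses$events$onset_sample - 1) / fs
  task <- unlist(lapply(on, function(o) which(env > 0 &
    seq_along(env) / fs > o + 0.3 & seq_along(env) / fs < o + 2.2)))
  base <- unlist(lapply(on, function(o) which(seq_along(env) / fs > o - 1.5 &
    seq_along(env) / fs < o - 0.2)))
  # power scales as envelope squared; normalising by the carrier's own
  # power in each window removes its sampling fluctuation
  carrier <- ses$truth$sources$carrier
  ratio <- (mean((carrier[task] * env[task])^2) / mean(carrier[task]^2)) /
    (mean((carrier[base] * env[base])^2) / mean(carrier[base]^2))
  expect_equal(ratio, 0.25, tolerance = 0.25 * 0.02)

  # PMBR window envelope exceeds baseline in every trial (noiseless truth)
  for (o in on) {
    pm <- env[seq_along(env) / fs > o + 3.0 & seq_along(env) / fs < o + 3.8]
    expect_true(all(pm > 1))
  }
  expect_error(tapping_config(erd_factor = -1), "non-negative")
})

test_that("physiological artifacts have the stated rates and shapes", {
  rec <- noise_recording(n_ch = 20, seconds = 120, fs = 200, seed = 8)
  # zero rates: recording unchanged
  out0 <- inject_physiological_artifacts(rec, 0, 0, seed = 1)
  expect_identical(out0$recording$data, rec$data)

  out <- inject_physiological_artifacts(rec, blink_rate = 12,
                                        heart_rate = 66, seed = 2)
  comp <- out$components
  # mean inter-beat interval tracks 60/66 s within the jitter budget
  gaps <- diff(comp$cardiac_times)
  expect_lt(abs(mean(gaps) - 60 / 66) / (60 / 66), 0.03)
  # blink durations stay inside the stated range
  expect_true(all(comp$blink_durations >= 0.2 & comp$blink_durations <= 0.5))
  expect_gt(length(comp$blink_times), 0)
  # additivity: output = input + physiological component
  expect_equal(out$recording$data, rec$data + comp$physiological)
})
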