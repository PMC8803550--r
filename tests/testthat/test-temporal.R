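test_that("zero-phase Butterworth filtering behaves as designed", {
  fs <- 1000
  t <- (0:19999) / fs
  # DC offset into a 2 Hz high-pass: residual mean below 1 fT
  rec_dc <- vec_recording(rep(1e-12, length(t)), fs)
  hp <- butter_zerophase(rec_dc, "highpass", 2, 5)
  expect_lt(abs(mean(hp$data[1, 2000:18000])), 1e-15)

  # 10 Hz sine through the 2-40 Hz evoked band: amplitude and phase kept
  rec_s <- vec_recording(sin(2 * pi * 10 * t) * 1e-12, fs)
  bp <- butter_zerophase(butter_zerophase(rec_s, "highpass", 2, 5),
                         "lowpass", 40, 6)
  mid <- 5000:15000
  y <- bp$data[1, ] / 1e-12
  a <- 2 * mean(y[mid] * sin(2 * pi * 10 * t[mid]))
  b <- 2 * mean(y[mid] * cos(2 * pi * 10 * t[mid]))
  expect_lt(abs(sqrt(a^2 + b^2) - 1), 0.01)
  expect_lt(abs(atan2(b, a)) * 180 / pi, 0.5)

  # forward-backward application is symmetric on a symmetric pulse
  # (reflect about the pulse's own centre sample; rev() would misalign the
  # comparison by half a sample)
  pulse <- exp(-((t - 10)^2) / (2 * 0.05^2)) * 1e-12
  out <- butter_zerophase(vec_recording(pulse, fs), "lowpass", 30, 4)
  y2 <- out$data[1, ]
  k <- 1:8000
  expect_lt(max(abs(y2[10001 + k] - y2[10001 - k])) / max(abs(y2)), 1e-9)

  # trigger channels pass through untouched
  trig <- numeric(length(t)); trig[5000:5050] <- 1
  rec_t <- vec_recording(sin(2 * pi * 10 * t) * 1e-12, fs, trigger = trig)
  out_t <- butter_zerophase(rec_t, "highpass", 2, 5)
  expect_identical(out_t$data[2, ], trig)

  expect_error(butter_zerophase(rec_s, "lowpass", 600, 4), "Nyquist")
  expect_error(butter_zerophase(rec_s, "highpass", 2, 0), "order")
  ep <- structure(list(), class = "opm_epochs")
  expect_error(butter_zerophase(ep, "highpass", 2), "continuous")
})

test_that("spectral interpolation flattens target bins and leaves the rest", {
  fs <- 1000
  t <- (0:59999) / fs
  set.seed(6)
  x <- 2e-12 * sin(2 * pi * 50 * t) + 1e-12 * sin(2 * pi * 10 * t) +
    rnorm(length(t), sd = 15e-15 * sqrt(fs / 2))
  rec <- vec_recording(x, fs)
  out <- spectral_interpolate(rec, 50)
  p1 <- welch_asd(rec, 10); p2 <- welch_asd(out, 10)
  i50 <- which.min(abs(p2$freqs - 50))
  flank <- (p2$freqs >= 48.5 & p2$freqs < 49.5) |
    (p2$freqs > 50.5 & p2$freqs <= 51.5)
  expect_lte(p2$asd[1, i50], 2 * mean(p2$asd[1, flank]))
  expect_gt(p1$asd[1, i50], 20 * mean(p1$asd[1, flank]))  # it was a real line

  # the 10 Hz probe is untouched to within 0.1%
  amp10 <- function(v) {
    a <- 2 * mean(v * sin(2 * pi * 10 * t)); b <- 2 * mean(v * cos(2 * pi * 10 * t))
    sqrt(a^2 + b^2)
  }
  expect_lt(abs(amp10(out$data[1, ]) - amp10(rec$data[1, ])) /
              amp10(rec$data[1, ]), 0.001)

  # interpolation with no line present barely changes the record
  rec2 <- vec_recording(1e-12 * sin(2 * pi * 10 * t), fs)
  out2 <- spectral_interpolate(rec2, 50)
  expect_lt(max(abs(out2$data - rec2$data)), 1e-15)

  # the standard multi-target call is accepted; collisions are not
  expect_silent(spectral_interpolate(rec, c(50, 100, 106, 120)))
  expect_error(spectral_interpolate(rec, c(50, 50.8)), "collision")
  expect_error(spectral_interpolate(rec, 499.9), "Nyquist")

  # near-idempotence on the target bins
  twice <- spectral_interpolate(out, 50)
  pa <- welch_asd(out, 10); pb <- welch_asd(twice, 10)
  expect_lt(abs(pb$asd[1, i50] - pa$asd[1, i50]) / pa$asd[1, i50], 0.05)
})

test_that("windowed detrending removes polynomials and keeps oscillations", {
  fs <- 250
  t <- (0:4999) / fs
  ramp <- (2 * t - 10) * 1e-12
  rec <- vec_recording(ramp, fs)
  out <- detrend_windowed(rec, poly_order = 1, window_s = 20)
  expect_lt(max(abs(out$data[1, ])) / max(abs(ramp)), 1e-9)

  sine <- sin(2 * pi * 8 * t) * 1e-13
  rec2 <- vec_recording(ramp + sine, fs)
  out2 <- detrend_windowed(rec2, poly_order = 1, window_s = 5)
  expect_gt(cor(out2$data[1, ], sine), 0.999)

  # order 0 is windowed mean removal
  rec3 <- vec_recording(rep(4e-12, 5000) + sine, fs)
  out3 <- detrend_windowed(rec3, poly_order = 0, window_s = 5)
  expect_lt(abs(mean(out3$data[1, 1:1250])), 1e-24)

  expect_error(detrend_windowed(rec, 1, window_s = 100), "longer")
})

test_that("Welch ASD is calibrated for noise and sinusoids", {
  fs <- 500
  rec <- noise_recording(n_ch = 4, seconds = 60, fs = fs, asd = 15, seed = 2)
  psd <- welch_asd(rec, window_s = 10)
  med <- median(psd$asd[, psd$freqs > 10 & psd$freqs < 100])
  expect_lt(abs(med - 15) / 15, 0.05)

  # a bin-centred sine recovers its power A^2/2 over the peak bins
  t <- (0:29999) / fs
  A <- 1e-12
  recs <- vec_recording(A * sin(2 * pi * 20 * t), fs)
  ps <- welch_asd(recs, window_s = 10)
  i <- which.min(abs(ps$freqs - 20))
  df <- ps$freqs[2] - ps$freqs[1]
  pow <- sum((ps$asd[1, (i - 2):(i + 2)] * 1e-15)^2) * df
  expect_lt(abs(pow - A^2 / 2) / (A^2 / 2), 0.02)

  # zero channel gives a zero spectrum; short records are refused
  recz <- vec_recording(numeric(10000), fs)
  expect_true(all(welch_asd(recz, 10)$asd == 0))
  expect_error(welch_asd(vec_recording(numeric(100), fs), 10), "shorter")
})

test_that("gain_db implements the shielding-factor identity", {
  rec <- noise_recording(n_ch = 4, seconds = 20, fs = 250, seed = 3)
  p <- welch_asd(rec, 5)
  expect_true(all(gain_db(p, p) == 0))
  p10 <- p; p10$asd <- p$asd / 10
  expect_equal(max(abs(gain_db(p, p10) - 20)), 0, tolerance = 1e-10)
  expect_equal(gain_db(p, p10), -gain_db(p10, p))
  bad <- p; bad$channel_names <- rev(bad$channel_names)
  expect_error(gain_db(p, bad), "matching")
})

test_that("max field change summarises per-chunk peak-to-peak in pT", {
  fs <- 200
  geom <- tiny_geom(4)
  dat <- matrix(1e-12, 8, fs * 5)
  rec <- new_recording(geom, dat, fs)
  expect_true(all(max_field_change(rec)$max_change_pt == 0))
  dat[3, (2 * fs + 50):(2 * fs + 60)] <- 1e-12 + 3e-12  # step inside chunk 3
  rec2 <- new_recording(geom, dat, fs)
  mfc <- max_field_change(rec2)
  expect_equal(mfc$max_change_pt[3], 3, tolerance = 1e-9)
  expect_true(all(mfc$max_change_pt[-3] == 0))
})

test_that("temporal operations are homogeneous of degree one", {
  fs <- 250
  set.seed(9)
  x <- rnorm(5000, sd = 1e-12) + 2e-12 * sin(2 * pi * 21 * (0:4999) / fs)
  rec1 <- vec_recording(x, fs)
  rec3 <- vec_recording(3 * x, fs)
  for (op in list(
    function(r) butter_zerophase(r, "highpass", 2, 5)$data,
    function(r) spectral_interpolate(r, 21)$data,
    function(r) detrend_windowed(r, 1, 5)$data)) {
    expect_rel_equal(op(rec3), 3 * op(rec1), 1e-9)
  }
})
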