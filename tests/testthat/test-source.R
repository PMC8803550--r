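make_epochs <- function(data, times, channels, fs, rank_deficit = 0L) {
  structure(list(data = data, times = times, channels = channels,
                 codes = rep("x", dim(data)[1]),
                 onset_sample = seq_len(dim(data)[1]) * length(times) * 2,
                 fs = fs, t0 = 0, rank_deficit = rank_deficit,
                 dropped = NULL, rejected = integer(0)),
            class = "opm_epochs")
}

test_that("epoch covariance matches its definition and tracks rank", {
  set.seed(41)
  geom <- tiny_geom(6)
  n_ch <- nrow(geom)
  fs <- 250
  times <- seq(-0.1, 0.5, by = 1 / fs)
  nt <- length(times)
  # unit-variance independent channels: covariance ~ identity
  dat <- array(rnorm(60 * n_ch * nt), c(60, n_ch, nt))
  ep <- make_epochs(dat, times, geom, fs)
  cv <- epoch_covariance(ep, c(0, 0.5))
  off <- cv$cov[upper.tri(cv$cov)]
  # max over ~2000 sample correlations: the expected extreme is
  # sqrt(2 log(2m)) ~ 4 standard errors, so bound at 5
  expect_lt(max(abs(off)), 5 / sqrt(cv$n_samples))
  expect_lt(max(abs(diag(cv$cov) - 1)), 0.1)
  expect_equal(cv$rank, n_ch)

  # constant trials: zero covariance, rank 0
  ep0 <- make_epochs(array(5, c(2, n_ch, nt)), times, geom, fs)
  cv0 <- epoch_covariance(ep0, c(0, 0.5))
  expect_true(all(cv0$cov == 0))
  expect_equal(cv0$rank, 0)

  # a projector deficit caps the reported rank
  epd <- make_epochs(dat, times, geom, fs, rank_deficit = 3L)
  expect_lte(epoch_covariance(epd, c(0, 0.5))$rank, n_ch - 3)

  expect_error(epoch_covariance(ep, c(2, 3)), "empty")
  # both covariance conventions agree for demeaned stationary data
  cv2 <- epoch_covariance(ep, c(0, 0.5), method = "concatenated")
  expect_lt(max(abs(cv2$cov - cv$cov)), 0.05)
})

test_that("LCMV weights satisfy unit gain and the white-noise closed form", {
  geom <- build_array_geometry(30, "dual")
  sph <- sphere_model()
  L <- dual_source_leadfield(geom, sph, auditory_sources())
  n <- nrow(L)
  # white covariance: W is the pseudo-inverse of L
  C <- diag(n) * 1e-26
  bf <- lcmv_weights(L, C, lambda_fraction = 0.001)
  expect_lt(max(abs(bf$weights %*% L - diag(4))), 1e-6)
  W_ref <- solve(crossprod(L), t(L))
  expect_lt(max(abs(bf$weights - W_ref)) / max(abs(W_ref)), 1e-8)

  # regularisation shrinks the filter norm monotonically
  set.seed(8)
  X <- matrix(rnorm(n * 2000, sd = 1e-13), n)
  X[, 1:1000] <- X[, 1:1000] + as.numeric(L %*% rnorm(4, sd = 1e-9))
  Cx <- tcrossprod(X) / ncol(X)
  norms <- vapply(c(1e-4, 1e-3, 1e-2, 1e-1), function(l)
    norm(lcmv_weights(L, Cx, l)$weights, "F"), numeric(1))
  expect_true(all(diff(norms) < 0))

  expect_error(lcmv_weights(L, Cx, -1), "non-negative")
  expect_error(lcmv_weights(cbind(L, L[, 1]), Cx), "rank deficient")
})

test_that("the dual-source constraint rescues correlated bilateral sources", {
  quiet <- interference_spec(homogeneous_peak = 0, static_field = 0,
                             gradient_scale = 0, lines = NULL,
                             sensor_noise_asd = 15)
  cfg <- aef_config(n_trials = 40, fs = 500, still_until = 1,
                    translation_range = 0, interference = quiet)
  ses <- simulate_evoked_session(cfg, seed = 6)
  ep <- epoch_by_trigger(ses$recording, ses$events, 0.2, 0.5)
  cv <- epoch_covariance(ep, c(0, 0.5))
  geom <- ses$recording$channels[ses$recording$channels$kind == "scalp", ]
  sph <- ses$truth$sphere
  src <- auditory_sources()
  L2 <- dual_source_leadfield(geom, sph, src)
  bf2 <- lcmv_weights(L2, cv)
  vc2 <- virtual_channel(bf2, ep, 1, window = c(0, 0.4))
  L1 <- dual_source_leadfield(geom, sph, src[1])
  bf1 <- lcmv_weights(L1, cv)
  vc1 <- virtual_channel(bf1, ep, 1, window = c(0, 0.4))
  w <- ses$truth$sources$waveform
  tw <- seq(0, by = 1 / 500, length.out = length(w))
  truth <- approx(tw, w, xout = vc2$times, rule = 2)$y
  truth[vc2$times < 0] <- 0
  r2 <- abs(cor(vc2$mean, truth))
  r1 <- abs(cor(vc1$mean, truth))
  expect_gt(r2, 0.9)
  # fully correlated bilateral activity degrades the single-source filter
  expect_gt(r2, r1)
})

test_that("virtual channels respect orientation, sign and scale", {
  quiet <- interference_spec(homogeneous_peak = 0, static_field = 0,
                             gradient_scale = 0, lines = NULL,
                             sensor_noise_asd = 2)
  cfg <- aef_config(n_trials = 20, fs = 500, still_until = 1,
                    translation_range = 0, interference = quiet)
  ses <- simulate_evoked_session(cfg, seed = 9)
  ep <- epoch_by_trigger(ses$recording, ses$events, 0.2, 0.5)
  cv <- epoch_covariance(ep, c(0, 0.5))
  geom <- ses$recording$channels[ses$recording$channels$kind == "scalp", ]
  L <- dual_source_leadfield(geom, ses$truth$sphere, auditory_sources())
  bf <- lcmv_weights(L, cv)
  vc <- virtual_channel(bf, ep, 1, window = c(0.05, 0.15))
  # sign convention: the windowed peak is positive
  widx <- vc$times >= 0.05 & vc$times <= 0.15
  expect_gte(max(vc$mean[widx]), max(-vc$mean[widx]))
  # orientation: the collapsed moment direction matches the simulated
  # tangential moment within 5 degrees
  basis <- attr(L, "moment_basis")[[1]]
  est_moment <- basis %*% vc$orientation
  sp <- auditory_sources()[[1]]
  rad <- sp / sqrt(sum(sp^2))
  tang <- c(0, 0, 1) - rad[3] * rad
  tang <- tang / sqrt(sum(tang^2))
  ang <- acos(min(1, abs(sum(est_moment * tang)))) * 180 / pi
  expect_lt(ang, 5)
  # scale equivariance: scaling the data scales the virtual channel
  ep2 <- ep; ep2$data <- ep$data * 3
  vc3 <- virtual_channel(bf, ep2, 1, window = c(0.05, 0.15))
  expect_rel_equal(vc3$mean, 3 * vc$mean, 1e-9)
})
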