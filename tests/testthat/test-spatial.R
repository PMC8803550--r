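test_that("the HFC projector annihilates homogeneous fields only", {
  geom <- build_array_geometry(43, "dual")
  proj <- hfc_projector(geom)
  N <- orientation_matrix(geom)
  # null space by construction, for any field vector
  for (b in list(c(1, 0, 0), c(0, 1e-12, 0), c(3e-12, -2e-12, 5e-13)))
    expect_lt(max(abs(proj$matrix %*% (N %*% b))),
              1e-12 * max(abs(N %*% b)))
  # rank n - 3
  ev <- eigen(proj$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(ev > 0.5), 83)
  # matches an explicit Gram-Schmidt construction
  Q <- qr.Q(qr(N))
  P_ref <- diag(nrow(N)) - tcrossprod(Q)
  expect_lt(max(abs(proj$matrix - P_ref)), 1e-10)

  # an all-radial coplanar arrangement cannot span 3 field components
  flat <- geom[geom$axis == "RAD", ][1:6, ]
  flat[, c("ori_x", "ori_y", "ori_z")] <- matrix(rep(c(1, 0, 0), 6), 6,
                                                 byrow = TRUE)
  expect_error(hfc_projector(flat), "rank")
  expect_error(hfc_projector(geom[1:3, ]), "at least 4")
})

test_that("applying HFC removes homogeneous truth, keeps brain, idempotent", {
  ses <- small_aef_session()
  rec <- ses$recording
  idx <- channel_idx(rec, "scalp")
  proj <- hfc_projector(rec$channels[idx, , drop = FALSE])
  homog <- ses$truth$components$homogeneous[idx, ]
  brain <- ses$truth$components$brain[idx, ]
  att_h <- 10 * log10(mean(homog^2) / mean((proj$matrix %*% homog)^2))
  expect_gt(att_h, 120)
  att_b <- 10 * log10(mean(brain^2) / mean((proj$matrix %*% brain)^2))
  expect_lt(att_b, 3)

  out1 <- apply_hfc(rec)
  out2 <- apply_hfc(out1)
  expect_rel_equal(out2$data[idx, ], out1$data[idx, ], 1e-10)
  expect_equal(out1$rank_deficit, 3L)
  # reference rows untouched under the default scope
  ref <- channel_idx(rec, "reference")
  expect_identical(out1$data[ref, ], rec$data[ref, ])
})

test_that("HFC commutes with channel-wise temporal filtering", {
  rec <- noise_recording(n_ch = 12, seconds = 20, fs = 250, seed = 5)
  a <- butter_zerophase(apply_hfc(rec), "highpass", 2, 5)
  b <- apply_hfc(butter_zerophase(rec, "highpass", 2, 5))
  expect_rel_equal(a$data, b$data, 1e-8)
})

test_that("SSP projects out learned noise subspaces", {
  set.seed(21)
  geom <- tiny_geom(6)
  n_ch <- nrow(geom)
  pat <- qr.Q(qr(matrix(rnorm(n_ch * 2), n_ch)))  # two orthonormal patterns
  src <- matrix(rnorm(2 * 5000, sd = 1e-12), 2)
  noise_rec <- new_recording(geom, pat %*% src +
                               matrix(rnorm(n_ch * 5000, sd = 1e-16), n_ch),
                             250)
  proj <- ssp_from_noise(noise_rec, 2)
  expect_equal(proj$model_order, 2L)
  # the learned subspace matches an explicit eigendecomposition
  X <- noise_rec$data - rowMeans(noise_rec$data)
  U <- eigen(tcrossprod(X) / ncol(X), symmetric = TRUE)$vectors[, 1:2]
  ang <- svd(crossprod(U, pat))$d
  expect_lt(max(abs(ang - 1)), 1e-6)  # subspace angle ~ 0
  # rank-2 structure is annihilated on new data with the same patterns,
  # up to the subspace estimation error set by the training noise floor
  # (noise/signal = 1e-4 in the training record)
  test_dat <- pat %*% matrix(rnorm(2 * 1000, sd = 1e-12), 2)
  expect_lt(max(abs(proj$matrix %*% test_dat)), 1e-3 * max(abs(test_dat)))
  # zero components: identity
  proj0 <- ssp_from_noise(noise_rec, 0)
  expect_equal(proj0$matrix, diag(n_ch))
  expect_error(ssp_from_noise(noise_rec, n_ch), "below")
})

test_that("fastICA recovers a super-Gaussian mixture up to permutation", {
  set.seed(77)
  n <- 20000
  S <- rbind(rnorm(n)^3, sign(rnorm(n)) * rnorm(n)^2, rnorm(n)^3)
  S <- S / apply(S, 1, sd)
  A <- matrix(rnorm(30), 10, 3)
  geom <- tiny_geom(5)
  X <- A %*% S * 1e-12 + matrix(rnorm(10 * n, sd = 1e-14), 10)
  rec <- new_recording(geom, X, 250)
  res <- ica_denoise(rec, n_components = 3, seed = 11)
  cc <- abs(cor(t(res$report$sources), t(S)))
  # best match per true source, mean over sources
  expect_gt(mean(apply(cc, 2, max)), 0.95)
})

test_that("ICA removal is a linear operation with sane edge cases", {
  rec <- noise_recording(n_ch = 10, seconds = 40, fs = 250, seed = 6)
  res <- suppressWarnings(ica_denoise(rec, n_components = 5, seed = 2,
                                      flag_rules = list(low_freq = FALSE)))
  # nothing flagged: data unchanged up to remixing tolerance
  expect_rel_equal(res$recording$data, rec$data, 1e-8)
  # flagging everything removes the whole extracted subspace: unmixing the
  # cleaned (centred) data yields zero sources, and variance only drops
  suppressWarnings(expect_warning(
    res_all <- ica_denoise(rec, n_components = 5, seed = 2,
                           flag_components = 1:5),
    "all components"))
  Xc <- sweep(res_all$recording$data, 1, rowMeans(res_all$recording$data))
  s_after <- res_all$report$unmixing %*% Xc
  expect_lt(max(abs(s_after)), 1e-6 * max(abs(res_all$report$sources)))
  expect_lt(sum(apply(res_all$recording$data, 1, var)),
            sum(apply(rec$data, 1, var)))
  expect_error(ica_denoise(rec, n_components = 50), "more components")
})

test_that("bad-channel screening flags noisy and railing sensors", {
  set.seed(14)
  geom <- build_array_geometry(20, "dual")
  fs <- 500
  n <- 20 * fs
  dat <- matrix(rnorm(40 * n, sd = 15e-15 * sqrt(fs / 2)), 40)
  dat[7, 5001:(5000 + fs)] <- dat[7, 5001]     # rails for 1 s
  dat[12, ] <- dat[12, ] * 10                  # 10x noise
  rec <- new_recording(geom, dat, fs)
  flagged <- detect_bad_channels(rec)
  expect_setequal(flagged, geom$name[c(7, 12)])
  clean <- new_recording(geom, matrix(rnorm(40 * n, sd = 1e-13), 40), fs)
  expect_length(detect_bad_channels(clean), 0)
  expect_error(detect_bad_channels(noise_recording(seconds = 5)), "10 s")
})

test_that("artifact segments mark array-wide transient jumps", {
  set.seed(15)
  geom <- build_array_geometry(20, "dual")
  fs <- 500
  n <- 60 * fs
  base <- matrix(rnorm(40 * n, sd = 15e-15 * sqrt(fs / 2)), 40)
  dat <- base
  hit <- (30 * fs):(30 * fs + 0.05 * fs)
  dat[, hit] <- dat[, hit] + 8e-12   # 8 pT step on all channels at t = 30 s
  rec <- new_recording(geom, dat, fs)
  seg <- detect_artifact_segments(rec)
  expect_equal(nrow(seg), 1)
  expect_true(seg$start_s[1] <= 30 & seg$end_s[1] >= 30.05)
  # clean recording and an infinite threshold both give nothing
  expect_equal(nrow(detect_artifact_segments(new_recording(geom, base, fs))),
               0)
  expect_equal(nrow(detect_artifact_segments(rec, jump_threshold = Inf)), 0)
})
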