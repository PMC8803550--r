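# small builders shared across test files; everything generated in code

tiny_geom <- function(n = 6, axes = "dual") {
  per <- if (axes == "dual") 2L else 3L
  build_array_geometry(max(n, 4), axes)[seq_len(n * per), , drop = FALSE]
}

# white-noise-only recording at a stated ASD (fT/sqrt(Hz))
noise_recording <- function(n_ch = 8, seconds = 20, fs = 500, asd = 15,
                            seed = 1) {
  set.seed(seed)
  geom <- build_array_geometry(max(4, ceiling(n_ch / 2)),
                               "dual")[seq_len(n_ch), , drop = FALSE]
  sigma <- asd * 1e-15 * sqrt(fs / 2)
  new_recording(geom, matrix(stats::rnorm(n_ch * seconds * fs, sd = sigma),
                             n_ch), fs)
}

# single-channel recording from a vector (plus optional trigger row)
vec_recording <- function(x, fs, trigger = NULL) {
  geom <- build_array_geometry(4, "dual")[1, , drop = FALSE]
  dat <- matrix(x, 1)
  ch <- geom
  if (!is.null(trigger)) {
    ch <- rbind(geom, opmclean:::trigger_channel_row())
    dat <- rbind(dat, matrix(trigger, 1))
  }
  new_recording(ch, dat, fs)
}

# small evoked session reused by several files (memoised per R session)
.session_cache <- new.env(parent = emptyenv())
small_aef_session <- function() {
  if (is.null(.session_cache$aef)) {
    cfg <- aef_config(n_trials = 20, fs = 500, still_until = 4,
                      translation_range = 0.3)
    .session_cache$aef <- simulate_evoked_session(cfg, seed = 7)
  }
  .session_cache$aef
}

small_tapping_session <- function() {
  if (is.null(.session_cache$tap)) {
    cfg <- tapping_config(n_trials = 8, fs = 400)
    .session_cache$tap <- simulate_tapping_session(cfg, seed = 5)
  }
  .session_cache$tap
}

expect_rel_equal <- function(a, b, tol) {
  expect_lt(max(abs(a - b)) / max(abs(b), 1e-300), tol)
}
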