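test_that("session config enforces its invariants", {
  expect_error(session_config(n_trials = 100, trials_per_condition = 60),
               "4 \\* trials_per_condition")
  expect_error(session_config(snr = 0), "snr")
  expect_error(session_config(channels = c("C3", "C3", "Cz")), "unique")
  expect_error(session_config(coupling_strength = c("line-line" = 0.5)),
               "missing")
  cfg <- session_config(trials_per_condition = 5L, n_trials = 20L)
  expect_equal(cfg$n_trials, 20L)
})

test_that("ideal shapes have the nominal horizontal extents", {
  tr <- generate_trajectory("line-line", 0, 7, wobble_px = 0, jitter_px = 0,
                            hand_asymmetry = 1)
  expect_equal(compute_curvature(tr$left), 0)
  expect_equal(compute_curvature(tr$right), 0)

  tr <- generate_trajectory("circle-circle", 0, 7, radius_px = 190,
                            wobble_px = 0, jitter_px = 0, hand_asymmetry = 1)
  expect_equal(compute_curvature(tr$left), 380, tolerance = 1e-2)
  expect_equal(compute_curvature(tr$right), 380, tolerance = 1e-2)

  expect_error(generate_trajectory("square-circle", 0, 5), "unknown condition")
})

test_that("coupling morphs each hand toward the other shape, monotonically", {
  set.seed(21)
  # Monte-Carlo: incongruent coupled line wider than uncoupled line,
  # coupled circle narrower than uncoupled circle, over 100 seeded draws
  wins_line <- wins_circle <- 0L
  for (i in 1:100) {
    mixed <- generate_trajectory("line-circle", 0.5, 6)
    pure_l <- generate_trajectory("line-line", 0.5, 6)
    pure_c <- generate_trajectory("circle-circle", 0.5, 6)
    wins_line <- wins_line +
      (compute_curvature(mixed$left) > compute_curvature(pure_l$left))
    wins_circle <- wins_circle +
      (compute_curvature(mixed$right) < compute_curvature(pure_c$right))
  }
  expect_gt(wins_line, 90)
  expect_gt(wins_circle, 90)

  # noiseless morph amount is monotone in coupling strength
  ext <- vapply(seq(0, 1, by = 0.1), function(k) {
    compute_curvature(generate_trajectory("line-circle", k, 6, wobble_px = 0,
                                          jitter_px = 0,
                                          hand_asymmetry = 1)$left)
  }, numeric(1))
  expect_true(all(diff(ext) > 0))
})

test_that("sessions are balanced, run-limited and reproducible", {
  s <- mini_session()
  expect_equal(nrow(s$trials), 8L)
  expect_equal(as.vector(table(s$trials$condition)), rep(2L, 4))

  big <- cached("order_240", function() {
    set.seed(1)
    replicate(20, {
      ord <- coupledraw:::pseudo_random_order(60L)
      max(rle(ord)$lengths)
    })
  })
  expect_true(all(big <= 4))

  s2 <- generate_session(mini_cfg("none", seed = 42))
  expect_identical(s$eeg$signals, s2$eeg$signals)
  expect_identical(s$behaviour, s2$behaviour)

  s3 <- generate_session(mini_cfg("none", seed = 43))
  expect_false(identical(s$eeg$signals, s3$eeg$signals))
})

test_that("congruent trials show stronger coupling than incongruent ones", {
  for (seed in c(1, 2, 3)) {
    s <- cached(paste0("beh_", seed), function()
      generate_session(session_config(trials_per_condition = 15L,
                                      n_trials = 60L,
                                      encoding_mode = "none", seed = seed)))
    cong <- is_congruent(s$behaviour$condition)
    expect_gt(mean(s$behaviour$ci[cong]), mean(s$behaviour$ci[!cong]))
    expect_true(all(check_extent_ordering(summarise_conditions(s$behaviour))))
  }
})

test_that("ground truth is aligned, positive and finite", {
  s <- mini_session()
  expect_equal(nrow(s$truth), nrow(s$trials))
  expect_true(all(is.finite(s$truth$true_ci) & s$truth$true_ci > 0))
  expect_equal(s$truth$true_ci, s$behaviour$ci)
  expect_true(all(s$truth$d01 >= 0 & s$truth$d01 <= 1))
  expect_true(all(s$truth$sign %in% c(-1, 1)))
})

test_that("trial windows respect the rest period and pre-onset context", {
  s <- mini_session()
  tr <- s$trials
  gaps <- tr$onset_s[-1] - tr$offset_s[-nrow(tr)]
  expect_true(all(gaps >= s$config$rest_s - 1e-9))
  expect_gte(tr$onset_s[1], 2)
})

test_that("encodings reject montages lacking their carrier channels", {
  cfg <- session_config(n_trials = 8L, trials_per_condition = 2L,
                        channels = c("Fp1", "Fp2"),
                        encoding_mode = "univariate", seed = 1)
  trials <- data.frame(trial_id = 1:2, condition = c("line-line", "circle-line"),
                       onset_s = c(5, 20), offset_s = c(10, 25))
  truth <- data.frame(trial_id = 1:2, d01 = c(0.2, 0.8), sign = c(1, -1))
  expect_error(generate_eeg(trials, truth, cfg), "requires channels")
})

test_that("single channel-band powers are uninformative under the null encoding", {
  s <- cached("null_pow", function()
    generate_session(session_config(encoding_mode = "none", seed = 7)))
  # trial-mean band amplitude per channel, directly from the raw signal
  fs <- s$eeg$sfreq
  bands <- list(c(8, 13), c(13, 30))
  rs <- c()
  for (b in bands) {
    for (ch in c("C3", "Cz", "FC4")) {
      x <- coupledraw:::butter_bandpass(s$eeg$signals[, ch], fs, b[1], b[2])
      pow <- vapply(seq_len(nrow(s$trials)), function(k) {
        idx <- (floor(s$trials$onset_s[k] * fs) + 1):ceiling(s$trials$offset_s[k] * fs)
        mean(x[idx]^2)
      }, numeric(1))
      rs <- c(rs, cor(log10(pow), s$truth$true_ci))
    }
  }
  expect_lt(max(abs(rs)), 0.15)
})
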