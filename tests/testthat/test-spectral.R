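test_that("band specs validate edges and apply the half-open membership rule", {
  expect_error(band_spec("x", 10, 5), "lo < hi")
  expect_error(band_spec("x", 0, 5), "lo < hi|0 <")
  freqs <- c(7.9, 8, 10, 12.99, 13, 20, 30, 30.1)
  alpha <- default_bands()$alpha
  beta <- default_bands()$beta
  expect_equal(in_band(freqs, alpha),
               c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  # 13 Hz belongs to beta (its lower edge), 30 Hz included as closed top
  expect_equal(in_band(freqs, beta),
               c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))
  variant <- default_bands("results-variant")
  expect_equal(variant$alpha$hi, 12)
  expect_equal(variant$beta$lo, 15)
})

test_that("band-pass filter attenuates out-of-band and preserves mid-band content", {
  fs <- 256
  t <- seq(0, 20, by = 1 / fs)
  mk <- function(x) make_session(matrix(x, ncol = 1, dimnames = list(NULL, "C3")))

  # zero-phase 4th-order response: |H(50 Hz)|^2 ~ 0.03 for the 0.5-35 band
  out50 <- bandpass_filter(mk(sin(2 * pi * 50 * t)), 0.5, 35)
  expect_lt(max(abs(out50$signals[1000:4000, 1])), 0.05)

  out10 <- bandpass_filter(mk(sin(2 * pi * 10 * t)), 0.5, 35)
  expect_equal(max(abs(out10$signals[1000:4000, 1])), 1, tolerance = 0.05)

  set.seed(1)
  outwn <- bandpass_filter(mk(rnorm(length(t))), 0.5, 35)
  spec <- stats::spec.pgram(outwn$signals[, 1], spans = 31, plot = FALSE,
                            taper = 0)
  hz <- spec$freq * fs
  p45 <- mean(spec$spec[abs(hz - 45) < 2])
  p10 <- mean(spec$spec[abs(hz - 10) < 2])
  expect_lt(p45 / p10, 0.05)

  expect_error(bandpass_filter(mk(t), 35, 0.5), "corner")
  expect_error(bandpass_filter(mk(t), 10, 400), "corner")
})

test_that("re-referencing subtracts the reference mean and passes through when absent", {
  set.seed(4)
  sig <- matrix(rnorm(256 * 4 * 3), ncol = 3,
                dimnames = list(NULL, c("C3", "M1", "M2")))
  sig[, 2] <- sig[, 1]  # M1 is a copy of C3
  s <- make_session(sig)
  out <- rereference(s, "M1")
  expect_equal(max(abs(out$signals[, "C3"])), 0)
  out2 <- rereference(s, c("M2", "M2"))
  expect_equal(out2$signals[, "C3"], sig[, "C3"] - sig[, "M2"])
  # oracle: direct arithmetic for a two-channel reference
  out3 <- rereference(s, c("M1", "M2"))
  expect_equal(out3$signals[, "C3"], sig[, "C3"] - (sig[, "M1"] + sig[, "M2"]) / 2)
  expect_identical(rereference(s, NULL), s)
  expect_error(rereference(s, "TP9"), "not in session")
})

test_that("epochs are sample-accurate, variable-length, and exclusions are reported", {
  fs <- 256
  sig <- matrix(rnorm(fs * 40), ncol = 1, dimnames = list(NULL, "C3"))
  ev <- data.frame(trial_id = 1:3, condition = "line-line",
                   onset_s = c(1, 10, 20), offset_s = c(5, 17, 27))
  s <- make_session(sig, events = ev)
  ep <- epoch_trials(s, pre_s = 2)
  # trial 1 starts 1 s in: not enough pre-onset context
  expect_equal(ep$excluded$trial_id, 1L)
  expect_match(ep$excluded$reason, "pre-onset")
  expect_equal(length(ep$epochs), 2L)
  expect_equal(nrow(ep$epochs[[1]]$data), (7 + 2) * fs)   # 7 s trial + 2 s pre
  expect_equal(nrow(ep$epochs[[2]]$data), (7 + 2) * fs)
  # boundaries match the event table exactly
  idx <- which(abs(ep$epochs[[1]]$t_rel) < 1e-12)
  expect_equal(sig[(10 - 2) * fs + 1, 1], ep$epochs[[1]]$data[1, 1])
  expect_equal(ep$epochs[[1]]$t_rel[1], -2)
})

test_that("Morlet power localises, scales quadratically, and rejects short epochs", {
  fs <- 256
  t <- seq(0, 8, by = 1 / fs)
  freqs <- default_freqs()
  x <- sin(2 * pi * 10 * t)
  pow <- morlet_tf(x, fs, freqs)
  expect_equal(dim(pow), c(length(x), 50))
  expect_true(all(pow >= 0))
  mid <- seq(fs, length(x) - fs)
  peak <- freqs[which.max(colMeans(pow[mid, ]))]
  expect_equal(peak, freqs[which.min(abs(freqs - 10))])

  expect_equal(morlet_tf(rep(0, length(x)), fs, freqs),
               matrix(0, length(x), 50))
  pow2 <- morlet_tf(2 * x, fs, freqs)
  expect_equal(pow2, 4 * pow, tolerance = 1e-12)

  expect_error(morlet_tf(x[1:500], fs, freqs), "shorter than the longest wavelet")
})

test_that("baseline log-ratio has the stated sign convention and guards", {
  pow <- matrix(runif(200 * 50, 1, 2), 200, 50)
  base <- colMeans(pow)
  expect_equal(baseline_logratio(pow, base)[1, 1], log10(pow[1, 1] / base[1]))
  expect_equal(baseline_logratio(matrix(5, 10, 3), rep(5, 3)),
               matrix(0, 10, 3))
  expect_equal(baseline_logratio(matrix(50, 10, 3), rep(5, 3)),
               matrix(1, 10, 3))
  expect_equal(baseline_logratio(matrix(0.5, 10, 3), rep(5, 3)),
               matrix(-1, 10, 3))
  expect_error(baseline_logratio(pow, rep(0, 50)), "positive")
  expect_error(baseline_logratio(pow, base[-1]), "one value per frequency")
})

test_that("time resampling preserves constants, ramps, and matches a per-row oracle", {
  expect_equal(resample_time(matrix(3, 17, 4), 200), matrix(3, 200, 4))
  ramp <- matrix(seq(0, 1, length.out = 101), 101, 2)
  out <- resample_time(ramp, 200)
  expect_equal(out[, 1], seq(0, 1, length.out = 200))
  set.seed(5)
  m <- matrix(rnorm(40 * 3), 40, 3)
  out2 <- resample_time(m, 200)
  for (j in 1:3) {
    oracle <- approx(seq(0, 1, length.out = 40), m[, j],
                     xout = seq(0, 1, length.out = 200))$y
    expect_equal(out2[, j], oracle)
  }
  expect_error(resample_time(matrix(1, 1, 3), 200), "at least 2")
})

test_that("tf maps are 200 x 50 with finite values and ERD matches a two-loop oracle", {
  ep <- mini_epochs()
  tf <- tf_logratio_map(ep$epochs[[1]], "C3")
  expect_s3_class(tf, "tf_map")
  expect_equal(dim(tf$values), c(200, 50))
  expect_true(all(is.finite(tf$values)))

  alpha <- default_bands()$alpha
  erd <- compute_erd(tf, alpha)
  acc <- 0; nacc <- 0
  for (ti in 1:200) for (fi in 1:50) {
    if (tf$freqs[fi] >= alpha$lo && tf$freqs[fi] < alpha$hi) {
      acc <- acc + tf$values[ti, fi]; nacc <- nacc + 1
    }
  }
  expect_equal(erd, acc / nacc)

  const <- tf
  const$values[] <- -0.5
  expect_equal(compute_erd(const, alpha), -0.5)
  const$values[] <- 0
  expect_equal(compute_erd(const, alpha), 0)
  expect_error(compute_erd(tf, band_spec("narrow", 9.0, 9.1)), "no grid")
})

test_that("feature vectors are 3600-long, channel-major, and match a band-mean oracle", {
  ep <- mini_epochs()
  chans <- mini_session()$config$channels
  tfs <- lapply(chans, function(ch) tf_logratio_map(ep$epochs[[2]], ch))
  names(tfs) <- chans
  fv <- build_feature_vector(tfs)
  expect_length(fv, 3600)
  expect_equal(names(fv)[1], "FC3.alpha.t001")
  expect_equal(names(fv)[201], "FC3.beta.t001")
  expect_equal(names(fv)[401], "FCz.alpha.t001")

  bands <- default_bands()
  amask <- in_band(tfs$C4$freqs, bands$alpha)
  oracle <- rowMeans(tfs$C4$values[, amask])
  expect_equal(unname(fv[paste0("C4.alpha.t", sprintf("%03d", 1:200))]), oracle)

  # constant maps propagate the constant everywhere
  ctfs <- lapply(tfs, function(tf) { tf$values[] <- 0.25; tf })
  expect_equal(unname(build_feature_vector(ctfs)), rep(0.25, 3600),
               ignore_attr = TRUE)
  expect_error(build_feature_vector(tfs[-3], channels = chans), "missing")

  # ERD equals the time-mean of the matching 200-point band time-course
  erd <- compute_erd(tfs$C4, bands$alpha)
  expect_equal(erd, mean(fv[paste0("C4.alpha.t", sprintf("%03d", 1:200))]))
})

test_that("spectral pipeline under a null encoding yields near-zero mean ERD", {
  s <- mini_session()
  sp <- cached("mini_sp_none", function() spectral_features(s$eeg))
  erd <- as.matrix(sp$erd[, -(1:2)])
  expect_equal(dim(erd), c(8L, 18L))
  # stationary trial and baseline power: log-ratio centred on zero
  expect_lt(abs(mean(erd)), 0.06)
  expect_equal(dim(sp$features), c(3600L, 8L))
  expect_true(all(is.finite(sp$features)))
})
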