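#' Continuous Morlet wavelet transform of a single-channel epoch
#'
#' Convolves the signal with complex Morlet wavelets (default 7 cycles at
#' every frequency, Gaussian envelope truncated at `trunc_sd` standard
#' deviations and L1-normalised) and returns instantaneous power at native
#' time resolution. A unit-amplitude sinusoid at an analysis frequency maps
#' to power 0.25 at that frequency; only relative power matters downstream,
#' where power is expressed as a log ratio against baseline.
#'
#' Convolution is done in the frequency domain with zero padding; wavelet
#' spectra are cached per padded length.
#'
#' @param x numeric vector, one channel's epoch.
#' @param sfreq sampling rate, Hz.
#' @param freqs analysis frequencies, Hz (default [default_freqs()]).
#' @param n_cycles wavelet cycles (constant across frequencies).
#' @param trunc_sd Gaussian truncation, in envelope standard deviations to
#'   each side.
#' @return Matrix of power, `length(x)` rows x `length(freqs)` columns.
#' @export
morlet_tf <- function(x, sfreq, freqs = default_freqs(), n_cycles = 7,
                      trunc_sd = 2) {
  n <- length(x)
  sigma_t <- n_cycles / (2 * pi * freqs)
  half_n <- floor(trunc_sd * sigma_t * sfreq)
  max_len <- 2L * max(half_n) + 1L
  if (n < max_len) {
    stop(sprintf(paste0("epoch of %d samples is shorter than the longest ",
                        "wavelet (%d samples at %.2f Hz)"),
                 n, max_len, freqs[which.max(half_n)]), call. = FALSE)
  }
  nfft <- stats::nextn(n + max_len - 1L)
  X <- stats::fft(c(x, rep(0, nfft - n)))
  W <- morlet_bank_fft(sfreq, freqs, n_cycles, trunc_sd, nfft)
  power <- matrix(0, nrow = n, ncol = length(freqs))
  for (fi in seq_along(freqs)) {
    conv <- stats::fft(X * W[, fi], inverse = TRUE) / nfft
    h <- half_n[fi]
    power[, fi] <- Mod(conv[(h + 1L):(h + n)])^2
  }
  power
}

# FFTs of the (zero-padded) wavelet bank, cached per (nfft, grid) signature
.morlet_cache <- new.env(parent = emptyenv())

morlet_bank_fft <- function(sfreq, freqs, n_cycles, trunc_sd, nfft) {
  key <- paste0(nfft, ":", sfreq, ":", n_cycles, ":", trunc_sd, ":",
                paste(signif(range(freqs), 10), collapse = ","), ":", length(freqs))
  cached <- .morlet_cache[[key]]
  if (!is.null(cached)) return(cached)
  W <- matrix(complex(real = 0), nrow = nfft, ncol = length(freqs))
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    sigma_t <- n_cycles / (2 * pi * f)
    h <- floor(trunc_sd * sigma_t * sfreq)
    t <- (-h:h) / sfreq
    w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma_t^2))
    w <- w / sum(Mod(w))
    W[, fi] <- stats::fft(c(w, rep(0, nfft - length(w))))
  }
  .morlet_cache[[key]] <- W
  W
}

#' Express power relative to a pre-trial baseline as a log ratio
#'
#' `value(t, f) = log10(power(t, f) / baseline_mean(f))`. Negative values
#' indicate suppression of oscillatory power relative to baseline
#' (event-related desynchronization); positive values indicate enhancement.
#'
#' @param power time x frequency power matrix.
#' @param baseline_power per-frequency mean baseline power (strictly
#'   positive).
#' @return Log-ratio matrix, same shape as `power`.
#' @export
baseline_logratio <- function(power, baseline_power) {
  if (length(baseline_power) != ncol(power)) {
    stop("baseline_power must have one value per frequency", call. = FALSE)
  }
  if (any(!is.finite(baseline_power)) || any(baseline_power <= 0)) {
    stop("baseline power must be finite and strictly positive at every frequency",
         call. = FALSE)
  }
  log10(sweep(power, 2, baseline_power, "/"))
}

#' Resample a time-frequency matrix onto a fixed number of time points
#'
#' Linear interpolation of every frequency column onto `n_out` equally
#' spaced points across the input's time span; puts variable-length trials
#' on a common normalised time grid.
#'
#' @param mat time x frequency matrix with at least 2 rows.
#' @param n_out number of output time points (default 200).
#' @return `n_out` x `ncol(mat)` matrix.
#' @export
resample_time <- function(mat, n_out = 200) {
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = 1)
  if (nrow(mat) < 2L) {
    stop("need at least 2 time points to resample", call. = FALSE)
  }
  x_in <- seq(0, 1, length.out = nrow(mat))
  x_out <- seq(0, 1, length.out = n_out)
  apply(mat, 2, function(col) stats::approx(x_in, col, xout = x_out)$y)
}

#' Time-normalised log-ratio map for one trial and channel
#'
#' Runs the full single-channel time-frequency chain: Morlet power over the
#' whole epoch, per-frequency geometric-mean baseline power over the
#' pre-onset baseline window, log-ratio conversion, restriction to the trial
#' (onset to offset) and resampling onto `n_time` points.
#'
#' @param epoch one epoch from [epoch_trials()].
#' @param channel channel label.
#' @param freqs analysis frequency grid.
#' @param baseline_window window relative to onset, seconds (default
#'   -2.0 to -0.5 s).
#' @param n_time output time points (default 200).
#' @param n_cycles,trunc_sd passed to [morlet_tf()].
#' @return A `tf_map`: list with `trial_id`, `channel`, `values`
#'   (`n_time` x `length(freqs)` log-ratio matrix), `freqs`, `time01`.
#' @export
tf_logratio_map <- function(epoch, channel, freqs = default_freqs(),
                            baseline_window = c(-2, -0.5), n_time = 200,
                            n_cycles = 7, trunc_sd = 2) {
  if (!channel %in% colnames(epoch$data)) {
    stop("channel ", channel, " not present in epoch", call. = FALSE)
  }
  power <- morlet_tf(epoch$data[, channel], attr_sfreq(epoch), freqs,
                     n_cycles = n_cycles, trunc_sd = trunc_sd)
  base_idx <- epoch$t_rel >= baseline_window[1] & epoch$t_rel < baseline_window[2]
  if (!any(base_idx)) {
    stop("baseline window contains no samples", call. = FALSE)
  }
  # geometric-mean baseline: with log-ratio values averaged over time on the
  # trial side, this is the statistic that makes the map unbiased (zero mean)
  # when trial and baseline power share one stationary distribution
  baseline_power <- exp(colMeans(log(pmax(power[base_idx, , drop = FALSE],
                                          .Machine$double.xmin))))
  lr <- baseline_logratio(power, baseline_power)
  trial_idx <- epoch$t_rel >= 0
  values <- resample_time(lr[trial_idx, , drop = FALSE], n_time)
  structure(list(trial_id = epoch$trial_id, channel = channel,
                 values = values, freqs = freqs,
                 time01 = seq(0, 1, length.out = n_time)),
            class = "tf_map")
}

# epochs keep time implicitly through t_rel; recover the sampling rate
attr_sfreq <- function(epoch) {
  round(1 / stats::median(diff(epoch$t_rel)))
}
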