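#' Generate continuous multichannel EEG for a simulated session
#'
#' Builds a forward model of the recording: per-channel 1/f (pink)
#' background noise with a shared component across channels, plus sustained
#' (envelope-stabilised) alpha (8-13 Hz) and beta (13-30 Hz) oscillations on
#' every channel. During each trial the band envelopes are modulated
#' according to the session's `encoding_mode`:
#'
#' * `none` - no dependence on behaviour;
#' * `univariate` - only the C3 alpha envelope carries the trial's coupling
#'   drive, linearly in measured log power;
#' * `distributed_linear` - a single in-band source shared by all channels
#'   has its strength track the drive (raising both band power and
#'   cross-channel coherence);
#' * `distributed_nonlinear` - twelve channel-bands (FC3/FC4, CP3/CP4 and
#'   FCz/CPz, in both alpha and beta) receive measured responses
#'   `+/- s * g * drive` with a single random per-trial sign `s`
#'   (FC3/CP3/FCz positive, FC4/CP4/CPz negative), so every single
#'   channel-band is linearly uninformative about the drive while a
#'   nonlinear readout (rectified pair differences) recovers it.
#'
#' Oscillation amplitude is `snr` times the in-band standard deviation of
#' that channel's background, so `snr = 1` means band oscillations and
#' background contribute equal in-band power.
#'
#' Encoded gains are specified as the *measured* log10 power response the
#' downstream Morlet band analysis should report. The oscillation gain that
#' produces a requested response depends on how much non-modulated power
#' the analysis wavelets see; the generator calibrates this per channel and
#' band from the spectra of its own components and inverts the response
#' curve numerically. Without this compensation the measured response would
#' be a convex function of the applied gain, and the sign-balanced
#' nonlinear encoding would leak a spurious linear correlation through its
#' even part.
#'
#' Randomness comes from the current RNG stream; seed upstream.
#'
#' @param trials data.frame with `trial_id`, `condition`, `onset_s`,
#'   `offset_s` (non-overlapping, separated by at least the rest period).
#' @param truth ground-truth data.frame from [generate_session()] (needs
#'   columns `d01` and, for the nonlinear mode, `sign`).
#' @param cfg a [session_config()].
#' @return An `eeg_session`: list with `signals` (samples x channels matrix,
#'   microvolts), `sfreq`, `channels`, `events` (the trial table).
#' @export
generate_eeg <- function(trials, truth, cfg) {
  fs <- cfg$sampling_rate_hz
  channels <- cfg$channels
  mode <- cfg$encoding_mode
  required <- switch(mode,
    none = character(0),
    univariate = "C3",
    distributed_linear = channels[seq_len(min(4, length(channels)))],
    distributed_nonlinear = c("FC3", "FC4", "CP3", "CP4", "FCz", "CPz")
  )
  missing <- setdiff(required, channels)
  if (length(missing) > 0L) {
    stop("encoding '", mode, "' requires channels: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(trials) >= 2L) {
    gaps <- trials$onset_s[-1L] - trials$offset_s[-nrow(trials)]
    if (any(gaps < cfg$rest_s - 1e-9)) {
      stop("trial windows must be separated by at least rest_s", call. = FALSE)
    }
  }

  n <- ceiling((max(trials$offset_s) + 3) * fs)
  bands <- list(alpha = c(8, 13), beta = c(13, 30))
  on_i <- pmax(1L, floor(trials$onset_s * fs) + 1L)
  off_i <- pmin(n, ceiling(trials$offset_s * fs))

  shared_bg <- pink_noise(n)
  signals <- matrix(0, nrow = n, ncol = length(channels),
                    dimnames = list(NULL, channels))
  bg_sd_uv <- 10

  # shared narrowband sources for the distributed_linear encoding
  if (mode == "distributed_linear") {
    shared_osc <- lapply(bands, function(b) band_noise(n, fs, b[1], b[2]))
    shared_gain <- lapply(seq_along(bands), function(bi) {
      g <- rep(0.5, n)
      for (k in seq_len(nrow(trials))) {
        g[on_i[k]:off_i[k]] <- 0.5 + cfg$encode_gain * truth$d01[k]
      }
      g
    })
  }

  for (ci in seq_along(channels)) {
    ch <- channels[ci]
    bg <- bg_sd_uv * (sqrt(0.7) * pink_noise(n) + sqrt(0.3) * shared_bg)
    osc <- list()
    for (bi in seq_along(bands)) {
      b <- bands[[bi]]
      sigma_band <- stats::sd(butter_bandpass(bg, fs, b[1], b[2]))
      osc[[names(bands)[bi]]] <- cfg$snr * sigma_band *
        band_noise(n, fs, b[1], b[2], stabilize = TRUE)
    }
    coded <- channel_band_codes(mode, ch, truth, cfg)
    coded_bands <- names(coded)[!vapply(coded, is.null, logical(1))]
    x <- bg
    for (bn in names(bands)) {
      gain <- rep(1, n)
      if (!is.null(coded[[bn]])) {
        lg <- invert_band_response(coded[[bn]], bn, bg, osc, fs,
                                   coded_bands = coded_bands)
        for (k in seq_len(nrow(trials))) {
          gain[on_i[k]:off_i[k]] <- 10^(lg[k] / 2)
        }
      }
      x <- x + gain * osc[[bn]]
      if (mode == "distributed_linear") {
        bi <- match(bn, names(bands))
        x <- x + stats::sd(osc[[bn]]) * shared_gain[[bi]] * shared_osc[[bi]]
      }
    }
    signals[, ci] <- x
  }

  structure(list(signals = signals, sfreq = fs, channels = channels,
                 events = trials),
            class = "eeg_session")
}

# requested measured log10 responses per band for one channel (NULL when
# the encoding leaves the band untouched)
channel_band_codes <- function(mode, channel, truth, cfg) {
  g <- cfg$encode_gain
  if (mode == "univariate" && channel == "C3") {
    return(list(alpha = g * truth$d01, beta = NULL))
  }
  if (mode == "distributed_nonlinear") {
    sgn <- switch(channel, FC3 = , CP3 = , FCz = +1,
                  FC4 = , CP4 = , CPz = -1, 0)
    if (sgn != 0) {
      # responses ride on a drive-independent +0.5 enhancement: the
      # suppression arm only has log10(snr^2 + 1) of headroom, while the
      # enhancement side is unbounded, so centering the signed code above
      # zero permits a much larger swing than a code centered at zero
      m <- 0.5 + sgn * truth$sign * g * truth$d01
      return(list(alpha = m, beta = m))
    }
  }
  list(alpha = NULL, beta = NULL)
}

# Turn requested measured band responses m (log10 units) into oscillation
# log-gains, by inverting the response curve of the Morlet band analysis
# for this channel: each analysis frequency j sees modulated power P_code_j
# and unmodulated power P_other_j (Gaussian wavelet weighting of the
# component spectra), responding with
#   r_j(lg) = log10((P_code_j * 10^lg + P_other_j) / (P_code_j + P_other_j));
# the band response is the mean of r_j over in-band grid frequencies.
# coded_bands lists every oscillation carrying (approximately) this same
# gain: wavelets near a band boundary see the neighbouring band's power,
# and treating co-modulated power as unmodulated would leave the response
# convex in the gain, leaking a spurious correlation through its even part.
invert_band_response <- function(m, band_name, bg, osc, fs,
                                 coded_bands = band_name,
                                 freqs = default_freqs(), n_cycles = 7) {
  bands <- default_bands()
  mask <- in_band(freqs, bands[[band_name]])
  fj <- freqs[mask]
  seg <- seq_len(min(length(bg), 240 * fs))
  psd_bg <- welch_cross_spectra(bg[seg], bg[seg], fs, window_s = 2)
  psds <- lapply(osc, function(o) welch_cross_spectra(o[seg], o[seg], fs,
                                                      window_s = 2))
  wavelet_weight <- function(f0) {
    sigma_f <- f0 / n_cycles
    exp(-((psd_bg$freqs - f0) / sigma_f)^2)
  }
  p_code <- p_other <- numeric(length(fj))
  for (j in seq_along(fj)) {
    w <- wavelet_weight(fj[j])
    p_code[j] <- sum(vapply(coded_bands,
                            function(o) sum(w * psds[[o]]$sxx), numeric(1)))
    p_other[j] <- sum(w * psd_bg$sxx) +
      sum(vapply(setdiff(names(osc), coded_bands),
                 function(o) sum(w * psds[[o]]$sxx), numeric(1)))
  }
  # The measured statistic is a time-mean of log power. For power that is a
  # mix of a stable (envelope-stabilised, share 1 - b) and an exponentially
  # fluctuating (background, share b) component, E[log10 P] carries a
  # share-dependent Jensen term J(b) = E[log10((1 - b) + b E)], E ~ Exp(1).
  # The background share changes with the applied gain, so J does not cancel
  # between trial and rest; omitting it leaves an even-in-gain residual.
  rho <- p_code / p_other
  lg_grid <- seq(-8, 6, by = 0.05)
  resp <- vapply(lg_grid, function(lg) {
    b_trial <- 1 / (rho * 10^lg + 1)
    b_rest <- 1 / (rho + 1)
    mean(log10((p_code * 10^lg + p_other) / (p_code + p_other)) +
           jensen_log10(b_trial) - jensen_log10(b_rest))
  }, numeric(1))
  if (any(m < min(resp) + 1e-6 | m > max(resp) - 1e-6)) {
    stop("encode_gain too large for this snr: requested band response ",
         "outside the achievable range [", signif(min(resp), 3), ", ",
         signif(max(resp), 3), "]", call. = FALSE)
  }
  inv <- stats::splinefun(resp, lg_grid, method = "monoH.FC")
  inv(m)
}

# E[log10((1 - b) + b * E)] for E ~ Exp(1), tabulated once and splined
.jensen_env <- new.env(parent = emptyenv())

jensen_log10 <- function(b) {
  if (is.null(.jensen_env$fun)) {
    grid <- seq(0, 1, by = 0.01)
    vals <- vapply(grid, function(bb) {
      stats::integrate(function(e) log10((1 - bb) + bb * e) * exp(-e),
                       0, 50, rel.tol = 1e-9)$value
    }, numeric(1))
    .jensen_env$fun <- stats::splinefun(grid, vals, method = "natural")
  }
  .jensen_env$fun(pmin(pmax(b, 0), 1))
}

#' @export
print.eeg_session <- function(x, ...) {
  cat(sprintf("<eeg_session> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              ncol(x$signals), nrow(x$signals), x$sfreq,
              nrow(x$signals) / x$sfreq, nrow(x$events)))
  invisible(x)
}

# 1/f-amplitude-shaped Gaussian noise, unit variance
pink_noise <- function(n) {
  m <- stats::nextn(n)
  x <- stats::rnorm(m)
  X <- stats::fft(x)
  f <- c(1, seq_len(m - 1))
  f <- pmin(f, m - f + 1)  # two-sided spectrum symmetry
  X <- X / sqrt(f)
  out <- Re(stats::fft(X, inverse = TRUE)) / m
  out <- out[seq_len(n)]
  (out - mean(out)) / stats::sd(out)
}

# Band-limited Gaussian noise, unit variance. With stabilize = TRUE the
# slow analytic envelope is divided out, modelling a sustained rhythm whose
# power is set by its (externally applied) gain rather than by random
# envelope fluctuation.
band_noise <- function(n, fs, lo, hi, stabilize = FALSE) {
  # work at a highly composite length: the analytic-signal FFT degrades to
  # O(n * p) when n has a large prime factor
  m <- stats::nextn(n)
  x <- butter_bandpass(stats::rnorm(m), fs, lo, hi)
  if (stabilize) {
    env <- Mod(analytic_signal(x))
    bf <- signal::butter(2, min(1, lo / 4) / (fs / 2), type = "low")
    env_slow <- signal::filtfilt(bf, env)
    env_slow <- pmax(env_slow, 0.1 * stats::median(env_slow))
    x <- x / env_slow
  }
  x <- x[seq_len(n)]
  (x - mean(x)) / stats::sd(x)
}

analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# zero-phase 4th-order Butterworth band-pass on a plain vector
butter_bandpass <- function(x, fs, lo, hi, order = 4) {
  stopifnot(lo > 0, hi > lo, hi < fs / 2)
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}
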