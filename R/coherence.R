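#' Magnitude-squared coherence between two channels in one band
#'
#' Welch-style estimator: the epoch is split into `window_s`-second Hann
#' windows with `overlap` fractional overlap, cross- and auto-spectra are
#' averaged over windows, and coherence
#' `|S_xy|^2 / (S_xx * S_yy)` is averaged over the in-band frequency bins.
#' At least 2 windows are required (one window gives coherence identically
#' 1).
#'
#' @param x,y numeric vectors of equal length, one trial epoch each.
#' @param sfreq sampling rate, Hz.
#' @param band a [band_spec()].
#' @param window_s window length, seconds.
#' @param overlap fractional window overlap in `[0, 1)`.
#' @return Scalar coherence in `[0, 1]`.
#' @export
pair_coherence <- function(x, y, sfreq, band, window_s = 1, overlap = 0.5) {
  stopifnot(length(x) == length(y))
  spec <- welch_cross_spectra(x, y, sfreq, window_s, overlap)
  coh <- Mod(spec$sxy)^2 / (spec$sxx * spec$syy)
  mask <- in_band(spec$freqs, band)
  if (!any(mask)) {
    stop("band ", band$name, " contains no spectral bins at this window length",
         call. = FALSE)
  }
  mean(coh[mask])
}

welch_cross_spectra <- function(x, y, sfreq, window_s = 1, overlap = 0.5) {
  nwin <- round(window_s * sfreq)
  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, length(x) - nwin + 1L, by = step)
  if (length(x) < nwin || length(starts) < 2L) {
    stop("epoch too short for >= 2 estimation windows (",
         length(x), " samples, window ", nwin, ")", call. = FALSE)
  }
  w <- hann_window(nwin)
  nf <- floor(nwin / 2) + 1L
  sxx <- syy <- numeric(nf)
  sxy <- complex(nf)
  for (s in starts) {
    idx <- s:(s + nwin - 1L)
    xs <- (x[idx] - mean(x[idx])) * w
    ys <- (y[idx] - mean(y[idx])) * w
    X <- stats::fft(xs)[seq_len(nf)]
    Y <- stats::fft(ys)[seq_len(nf)]
    sxx <- sxx + Mod(X)^2
    syy <- syy + Mod(Y)^2
    sxy <- sxy + X * Conj(Y)
  }
  list(freqs = (seq_len(nf) - 1L) * sfreq / nwin,
       sxx = sxx / length(starts), syy = syy / length(starts),
       sxy = sxy / length(starts))
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

#' Default motor channel groups for coherence averaging
#'
#' Three groups of three channel pairs each: frontal-central
#' (FC3-FC4, FC3-FCz, FCz-FC4), central (C3-C4, C3-Cz, C4-Cz) and
#' central-parietal (CP3-CP4, CP3-CPz, CP4-CPz).
#'
#' @return Named list; each element a 3 x 2 character matrix of channel
#'   pairs.
#' @export
default_channel_groups <- function() {
  list(
    "frontal-central" = rbind(c("FC3", "FC4"), c("FC3", "FCz"), c("FCz", "FC4")),
    "central" = rbind(c("C3", "C4"), c("C3", "Cz"), c("C4", "Cz")),
    "central-parietal" = rbind(c("CP3", "CP4"), c("CP3", "CPz"), c("CP4", "CPz"))
  )
}

#' Group-averaged coherence of one trial epoch
#'
#' For each channel group and band, the arithmetic mean of the three pair
#' coherences: 3 groups x 2 bands = 6 values per trial.
#'
#' @param epoch_data samples x channels matrix with channel column names.
#' @param sfreq sampling rate, Hz.
#' @param groups channel groups, see [default_channel_groups()].
#' @param bands named list of [band_spec()]s.
#' @param window_s,overlap Welch parameters, see [pair_coherence()].
#' @return Named numeric vector of `length(groups) * length(bands)` values
#'   (`group.band` names), each in `[0, 1]`.
#' @export
group_coherence <- function(epoch_data, sfreq,
                            groups = default_channel_groups(),
                            bands = default_bands(),
                            window_s = 1, overlap = 0.5) {
  needed <- unique(unlist(groups))
  missing <- setdiff(needed, colnames(epoch_data))
  if (length(missing) > 0L) {
    stop("missing channel(s) for coherence groups: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- numeric(0)
  for (gn in names(groups)) {
    pairs <- groups[[gn]]
    for (bn in names(bands)) {
      vals <- vapply(seq_len(nrow(pairs)), function(p) {
        pair_coherence(epoch_data[, pairs[p, 1]], epoch_data[, pairs[p, 2]],
                       sfreq, bands[[bn]], window_s, overlap)
      }, numeric(1))
      out[paste(gn, bn, sep = ".")] <- mean(vals)
    }
  }
  out
}

#' Per-trial coherence table for a session
#'
#' Epochs the session (trial onset to offset only) and computes the 6
#' group x band coherence values per trial. Trials too short for 2 Welch
#' windows are excluded and reported.
#'
#' @param session an `eeg_session`.
#' @param groups,bands,window_s,overlap see [group_coherence()].
#' @param filter apply the 0.5-35 Hz band-pass first.
#' @return List with `coherence` (data.frame: `trial_id`, `condition`, six
#'   `group.band` columns) and `excluded`.
#' @export
coherence_table <- function(session, groups = default_channel_groups(),
                            bands = default_bands(),
                            window_s = 1, overlap = 0.5, filter = TRUE) {
  stopifnot(inherits(session, "eeg_session"))
  if (filter) session <- bandpass_filter(session, 0.5, 35)
  ep <- epoch_trials(session, pre_s = 0)
  rows <- list()
  excluded <- ep$excluded
  for (epoch in ep$epochs) {
    vals <- tryCatch(
      group_coherence(epoch$data, session$sfreq, groups, bands,
                      window_s, overlap),
      error = function(e) e)
    if (inherits(vals, "error")) {
      excluded <- rbind(excluded, data.frame(trial_id = epoch$trial_id,
                                             reason = conditionMessage(vals)))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      trial_id = epoch$trial_id, condition = epoch$condition,
      as.list(vals), check.names = FALSE)
  }
  list(coherence = do.call(rbind, rows), excluded = excluded)
}
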