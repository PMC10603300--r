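#' Frequency band specifications
#'
#' `band_spec()` defines one analysis band. Band membership of a frequency
#' grid point is half-open, `lo <= f < hi`, except for a band flagged
#' `closed_top` (the highest band), which also includes `f == hi`; a grid
#' point sitting exactly on a shared edge (e.g. 13 Hz) therefore belongs to
#' the lower band only.
#'
#' `default_bands()` returns the alpha/beta pair. The `"methods"` preset is
#' alpha 8-13 Hz, beta 13-30 Hz; the `"results-variant"` preset
#' (alpha 8-12 Hz, beta 15-30 Hz) is an alternative definition in circulation
#' for the same motor bands.
#'
#' @param name band name.
#' @param lo,hi band edges in Hz, `0 < lo < hi <= 35`.
#' @param closed_top include the upper edge in the band.
#' @return `band_spec()`: a `band_spec` object; `default_bands()`: named list
#'   of two `band_spec`s.
#' @export
band_spec <- function(name, lo, hi, closed_top = FALSE) {
  if (!(lo > 0 && lo < hi && hi <= 35)) {
    stop("band edges must satisfy 0 < lo < hi <= 35", call. = FALSE)
  }
  structure(list(name = name, lo = lo, hi = hi, closed_top = closed_top),
            class = "band_spec")
}

#' @rdname band_spec
#' @param preset which band definition to use.
#' @export
default_bands <- function(preset = c("methods", "results-variant")) {
  preset <- match.arg(preset)
  if (preset == "methods") {
    list(alpha = band_spec("alpha", 8, 13),
         beta = band_spec("beta", 13, 30, closed_top = TRUE))
  } else {
    list(alpha = band_spec("alpha", 8, 12),
         beta = band_spec("beta", 15, 30, closed_top = TRUE))
  }
}

#' @rdname band_spec
#' @param freqs numeric frequency grid, Hz.
#' @param band a `band_spec`.
#' @return `in_band()`: logical mask over `freqs`.
#' @export
in_band <- function(freqs, band) {
  stopifnot(inherits(band, "band_spec"))
  freqs >= band$lo & (freqs < band$hi | (band$closed_top & freqs <= band$hi))
}

#' Analysis frequency grid
#'
#' 50 linearly spaced frequencies from 1 to 35 Hz (the upper edge of the
#' acquisition band-pass).
#' @return Numeric vector of length 50.
#' @export
default_freqs <- function() seq(1, 35, length.out = 50)

#' Zero-phase Butterworth band-pass of an EEG session
#'
#' 4th-order Butterworth (24 dB/octave roll-off) applied forward and backward
#' per channel, removing DC and everything outside `[lo, hi]`.
#'
#' @param session an `eeg_session`.
#' @param lo,hi corner frequencies, Hz; `0 < lo < hi < sfreq / 2`.
#' @param order filter order.
#' @return The filtered `eeg_session`.
#' @export
bandpass_filter <- function(session, lo = 0.5, hi = 35, order = 4) {
  stopifnot(inherits(session, "eeg_session"))
  if (!(lo > 0 && lo < hi && hi < session$sfreq / 2)) {
    stop("invalid corner frequencies: need 0 < lo < hi < sfreq/2", call. = FALSE)
  }
  bf <- signal::butter(order, c(lo, hi) / (session$sfreq / 2), type = "pass")
  session$signals <- apply(session$signals, 2, function(x) signal::filtfilt(bf, x))
  session
}

#' Re-reference an EEG session to the mean of reference channels
#'
#' Subtracts the sample-wise mean of the reference channels from every
#' channel. With `reference_channels = NULL` the session is passed through
#' unchanged (the synthetic generator emits already-referenced data).
#'
#' @param session an `eeg_session`.
#' @param reference_channels labels of the reference channels, or `NULL`.
#' @return The re-referenced `eeg_session`.
#' @export
rereference <- function(session, reference_channels = NULL) {
  stopifnot(inherits(session, "eeg_session"))
  if (is.null(reference_channels) || length(reference_channels) == 0L) {
    return(session)
  }
  missing <- setdiff(reference_channels, session$channels)
  if (length(missing) > 0L) {
    stop("reference channel(s) not in session: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ref <- rowMeans(session$signals[, reference_channels, drop = FALSE])
  session$signals <- session$signals - ref
  session
}

#' Ocular-artifact removal hook
#'
#' Placeholder for ICA-based ocular artifact removal. The synthetic
#' generator produces no ocular artifacts, so the default implementation is
#' an identity pass-through; real-data pipelines can supply their own
#' cleaner.
#'
#' @param session an `eeg_session`.
#' @param method `"none"` (identity) is the only built-in method.
#' @return The (unchanged) session.
#' @export
remove_ocular_artifacts <- function(session, method = "none") {
  stopifnot(inherits(session, "eeg_session"))
  if (!identical(method, "none")) {
    stop("only the pass-through method 'none' is implemented", call. = FALSE)
  }
  session
}

#' Cut variable-length trial epochs from a continuous session
#'
#' Each epoch runs from `pre_s` seconds before trial onset to the trial
#' offset, so epoch lengths follow trial durations. Trials without enough
#' pre-onset recording are excluded and reported, not silently dropped.
#'
#' @param session an `eeg_session` with an `events` table (`trial_id`,
#'   `onset_s`, `offset_s`, `condition`).
#' @param pre_s pre-onset context in seconds.
#' @return List with `epochs` (each: `trial_id`, `condition`, `data` =
#'   samples x channels matrix, `t_rel` = time relative to onset in seconds)
#'   and `excluded` (data.frame `trial_id`, `reason`).
#' @export
epoch_trials <- function(session, pre_s = 2) {
  stopifnot(inherits(session, "eeg_session"))
  fs <- session$sfreq
  ev <- session$events
  n <- nrow(session$signals)
  pre_n <- round(pre_s * fs)
  epochs <- list()
  excluded <- data.frame(trial_id = integer(0), reason = character(0))
  for (k in seq_len(nrow(ev))) {
    i_on <- round(ev$onset_s[k] * fs)
    i_off <- round(ev$offset_s[k] * fs)
    idx <- (i_on - pre_n + 1L):min(i_off, n)
    if (idx[1] < 1L) {
      excluded <- rbind(excluded, data.frame(
        trial_id = ev$trial_id[k],
        reason = sprintf("only %.2f s of pre-onset data (need %.2f s)",
                         ev$onset_s[k], pre_s)))
      next
    }
    epochs[[length(epochs) + 1L]] <- list(
      trial_id = ev$trial_id[k],
      condition = ev$condition[k],
      data = session$signals[idx, , drop = FALSE],
      t_rel = (idx - 1L) / fs - ev$onset_s[k]
    )
  }
  list(epochs = epochs, excluded = excluded)
}
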