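#' Event-related desynchronization value of one trial/channel/band
#'
#' The mean of the log-ratio cells whose frequency lies in the band, over
#' all time points of the time-normalised map. Negative values indicate
#' in-band power suppression relative to baseline.
#'
#' @param tf a `tf_map` from [tf_logratio_map()].
#' @param band a [band_spec()].
#' @return Scalar ERD value (log10 units).
#' @export
compute_erd <- function(tf, band) {
  stopifnot(inherits(tf, "tf_map"))
  mask <- in_band(tf$freqs, band)
  if (!any(mask)) {
    stop("band ", band$name, " [", band$lo, ", ", band$hi,
         "] contains no grid frequencies", call. = FALSE)
  }
  mean(tf$values[, mask])
}

#' Multivariate feature vector of one trial
#'
#' For each channel and band, the log-ratio values are averaged over in-band
#' frequencies *at each time point*, keeping the temporal dynamics: 200
#' values per channel-band. Concatenated channel-major (then band, then
#' time) over 9 channels and 2 bands this yields the 3600-dimensional input
#' of the shallow network.
#'
#' @param tfs named list of `tf_map`s, one per channel.
#' @param bands named list of [band_spec()]s (default [default_bands()]).
#' @param channels channel order; defaults to `names(tfs)`.
#' @return Named numeric vector of length
#'   `length(channels) * length(bands) * n_time`, with an `ordering`
#'   attribute describing the layout.
#' @export
build_feature_vector <- function(tfs, bands = default_bands(),
                                 channels = names(tfs)) {
  missing <- setdiff(channels, names(tfs))
  if (length(missing) > 0L) {
    stop("missing time-frequency map for channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  parts <- list()
  for (ch in channels) {
    tf <- tfs[[ch]]
    for (bn in names(bands)) {
      mask <- in_band(tf$freqs, bands[[bn]])
      if (!any(mask)) {
        stop("band ", bn, " contains no grid frequencies", call. = FALSE)
      }
      v <- rowMeans(tf$values[, mask, drop = FALSE])
      names(v) <- sprintf("%s.%s.t%03d", ch, bn, seq_along(v))
      parts[[paste(ch, bn, sep = ".")]] <- v
    }
  }
  out <- unlist(parts, use.names = TRUE)
  names(out) <- sub("^[^.]+\\.[^.]+\\.", "", names(out))
  names(out) <- unlist(lapply(parts, names), use.names = FALSE)
  attr(out, "ordering") <- "channel-major, then band, then time point"
  out
}

#' Spectral features of a whole session
#'
#' The full univariate + multivariate spectral chain: band-pass filter
#' (0.5-35 Hz), optional re-referencing, epoching (-2 s to offset), Morlet
#' log-ratio maps per trial and channel, ERD table (channels x bands per
#' trial) and the trial x 3600 feature matrix.
#'
#' @param session an `eeg_session` (e.g. `generate_session()$eeg`).
#' @param bands named list of [band_spec()]s.
#' @param freqs analysis frequency grid.
#' @param channels channels to analyse (default: all in the session).
#' @param reference_channels passed to [rereference()] (`NULL`: pass-through).
#' @param filter apply the 0.5-35 Hz band-pass first.
#' @param pre_s pre-onset epoch context, seconds.
#' @param baseline_window baseline window relative to onset, seconds.
#' @param n_time time points per trial after normalisation.
#' @param n_cycles,trunc_sd Morlet parameters, see [morlet_tf()].
#' @return List with `erd` (data.frame: `trial_id`, `condition`, one column
#'   per channel.band), `features` (matrix `n_features` x `n_trials`,
#'   columns named by trial id), `excluded` (from [epoch_trials()]),
#'   `channels`, `bands`, `freqs`.
#' @export
spectral_features <- function(session,
                              bands = default_bands(),
                              freqs = default_freqs(),
                              channels = session$channels,
                              reference_channels = NULL,
                              filter = TRUE,
                              pre_s = 2,
                              baseline_window = c(-2, -0.5),
                              n_time = 200,
                              n_cycles = 7,
                              trunc_sd = 2) {
  stopifnot(inherits(session, "eeg_session"))
  if (filter) session <- bandpass_filter(session, 0.5, 35)
  session <- rereference(session, reference_channels)
  ep <- epoch_trials(session, pre_s = pre_s)

  n_feat <- length(channels) * length(bands) * n_time
  features <- matrix(NA_real_, nrow = n_feat, ncol = length(ep$epochs))
  erd_cols <- as.vector(outer(names(bands), channels,
                              function(b, ch) paste(ch, b, sep = ".")))
  erd <- matrix(NA_real_, nrow = length(ep$epochs), ncol = length(erd_cols),
                dimnames = list(NULL, erd_cols))
  trial_id <- integer(length(ep$epochs))
  condition <- character(length(ep$epochs))

  for (i in seq_along(ep$epochs)) {
    epoch <- ep$epochs[[i]]
    tfs <- lapply(channels, function(ch) {
      tf_logratio_map(epoch, ch, freqs = freqs,
                      baseline_window = baseline_window, n_time = n_time,
                      n_cycles = n_cycles, trunc_sd = trunc_sd)
    })
    names(tfs) <- channels
    fv <- build_feature_vector(tfs, bands = bands, channels = channels)
    features[, i] <- fv
    if (i == 1L) rownames(features) <- names(fv)
    for (ch in channels) {
      for (bn in names(bands)) {
        erd[i, paste(ch, bn, sep = ".")] <- compute_erd(tfs[[ch]], bands[[bn]])
      }
    }
    trial_id[i] <- epoch$trial_id
    condition[i] <- epoch$condition
  }
  colnames(features) <- as.character(trial_id)
  erd_df <- data.frame(trial_id = trial_id, condition = condition,
                       erd, check.names = FALSE)
  list(erd = erd_df, features = features, excluded = ep$excluded,
       channels = channels, bands = bands, freqs = freqs)
}
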