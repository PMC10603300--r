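#' Configuration of a simulated drawing session
#'
#' Bundles every parameter of the synthetic circle-line session: trial
#' structure, EEG montage and sampling, trial-duration distribution, the
#' encoding mode that couples EEG band envelopes to the behavioural coupling
#' index, and the master seed. Defaults reproduce the study conditions the
#' pipeline is designed for: 240 trials (60 per condition) in pseudo-random
#' order, trial durations around 7.26 +/- 1.91 s, 5 s of rest between trials,
#' and nine motor channels sampled at 256 Hz.
#'
#' @param n_trials total number of trials; must equal
#'   `4 * trials_per_condition`.
#' @param trials_per_condition trials per condition (default 60).
#' @param sampling_rate_hz EEG sampling rate in Hz.
#' @param channels ordered EEG channel labels (unique, non-empty).
#' @param trial_duration_mean,trial_duration_sd,trial_duration_min parameters
#'   (seconds) of the truncated-normal trial-duration distribution.
#' @param rest_s rest period between trials, seconds.
#' @param encoding_mode how the EEG carries the trial's coupling drive:
#'   `"none"` (no dependence), `"univariate"` (C3 alpha envelope only,
#'   linear), `"distributed_linear"` (a shared in-band source over all
#'   channels whose strength tracks the drive), or `"distributed_nonlinear"`
#'   (sign-balanced gain pattern over twelve channel-bands; recoverable
#'   only through a nonlinear readout; see [generate_eeg()]).
#' @param snr amplitude of the band-limited oscillations relative to the
#'   in-band 1/f background (1 = equal amplitude).
#' @param coupling_strength named numeric in `[0, 1]`, nominal coupling per
#'   condition.
#' @param coupling_sd trial-to-trial standard deviation of realized coupling.
#' @param encode_gain peak measured log10 power response evoked by the
#'   encoding (at full drive). Default depends on the mode: 0.8 for
#'   `univariate` (enhancement only), 0.6 for `distributed_nonlinear`
#'   (the signed swing around its +0.5 enhancement pedestal; the pedestal
#'   keeps the suppression arm above what silencing the oscillation can
#'   remove, about `-log10(snr^2 + 1)`), 0.6 for `distributed_linear`,
#'   0 for `none`.
#' @param pen_rate_hz tablet pen sampling rate, Hz.
#' @param radius_px nominal circle radius in pixels.
#' @param wobble_px standard deviation of the slow lateral drawing wobble,
#'   pixels.
#' @param jitter_px standard deviation of white pixel jitter added to every
#'   pen sample.
#' @param hand_asymmetry horizontal scale factor of the dominant hand's
#'   trace, see [generate_trajectory()].
#' @param ci_floor_px curvature-difference floor (pixels) used when
#'   converting curvature differences to the coupling index.
#' @param seed master seed; all stage randomness is derived from it.
#'
#' @return An object of class `session_config` (a validated list).
#' @export
session_config <- function(n_trials = 240L,
                           trials_per_condition = 60L,
                           sampling_rate_hz = 256,
                           channels = c("FC3", "FCz", "FC4",
                                        "C3", "Cz", "C4",
                                        "CP3", "CPz", "CP4"),
                           trial_duration_mean = 7.26,
                           trial_duration_sd = 1.91,
                           trial_duration_min = 3,
                           rest_s = 5,
                           encoding_mode = c("distributed_nonlinear", "none",
                                             "univariate", "distributed_linear"),
                           snr = 1,
                           coupling_strength = c("line-line" = 0.85,
                                                 "circle-circle" = 0.85,
                                                 "line-circle" = 0.45,
                                                 "circle-line" = 0.45),
                           coupling_sd = 0.12,
                           encode_gain = NULL,
                           pen_rate_hz = 60,
                           radius_px = 140,
                           wobble_px = 30,
                           jitter_px = 1,
                           hand_asymmetry = 1.05,
                           ci_floor_px = 3,
                           seed = 1L) {
  encoding_mode <- match.arg(encoding_mode)
  n_trials <- as.integer(n_trials)
  trials_per_condition <- as.integer(trials_per_condition)
  if (n_trials != 4L * trials_per_condition) {
    stop("n_trials must equal 4 * trials_per_condition", call. = FALSE)
  }
  if (length(channels) == 0L || anyDuplicated(channels) > 0L) {
    stop("channels must be a non-empty list of unique labels", call. = FALSE)
  }
  if (!is.numeric(snr) || length(snr) != 1L || snr <= 0) {
    stop("snr must be a positive scalar", call. = FALSE)
  }
  missing_cond <- setdiff(drawing_conditions(), names(coupling_strength))
  if (length(missing_cond) > 0L) {
    stop("coupling_strength must be named for every condition; missing: ",
         paste(missing_cond, collapse = ", "), call. = FALSE)
  }
  if (any(coupling_strength < 0 | coupling_strength > 1)) {
    stop("coupling_strength values must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(encode_gain)) {
    encode_gain <- switch(encoding_mode, univariate = 0.8,
                          distributed_nonlinear = 0.6,
                          distributed_linear = 0.6, none = 0)
  }
  stopifnot(is.numeric(encode_gain), encode_gain >= 0)
  stopifnot(trial_duration_mean > 0, trial_duration_sd >= 0,
            trial_duration_min > 0, rest_s >= 0, ci_floor_px > 0,
            pen_rate_hz > 0, radius_px > 0, wobble_px >= 0, jitter_px >= 0)
  cfg <- list(
    n_trials = n_trials,
    trials_per_condition = trials_per_condition,
    sampling_rate_hz = sampling_rate_hz,
    channels = channels,
    trial_duration_mean = trial_duration_mean,
    trial_duration_sd = trial_duration_sd,
    trial_duration_min = trial_duration_min,
    rest_s = rest_s,
    encoding_mode = encoding_mode,
    snr = snr,
    coupling_strength = coupling_strength[drawing_conditions()],
    coupling_sd = coupling_sd,
    encode_gain = encode_gain,
    pen_rate_hz = pen_rate_hz,
    radius_px = radius_px,
    wobble_px = wobble_px,
    jitter_px = jitter_px,
    hand_asymmetry = hand_asymmetry,
    ci_floor_px = ci_floor_px,
    seed = as.integer(seed)
  )
  structure(cfg, class = "session_config")
}

#' @export
print.session_config <- function(x, ...) {
  cat("<session_config>\n")
  cat(sprintf("  trials: %d (%d per condition), durations ~ %.2f +/- %.2f s (min %.1f), rest %.1f s\n",
              x$n_trials, x$trials_per_condition, x$trial_duration_mean,
              x$trial_duration_sd, x$trial_duration_min, x$rest_s))
  cat(sprintf("  EEG: %d channels @ %g Hz [%s]\n", length(x$channels),
              x$sampling_rate_hz, paste(x$channels, collapse = ", ")))
  cat(sprintf("  encoding: %s (snr %.2f, gain %.2f), seed %d\n",
              x$encoding_mode, x$snr, x$encode_gain, x$seed))
  invisible(x)
}
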