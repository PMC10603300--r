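#' Generate a full simulated drawing session
#'
#' Produces everything a real session would yield, with known ground truth:
#' a pseudo-random trial order (balanced conditions, no condition repeated
#' more than 4 consecutive times), truncated-normal trial durations, per-trial
#' pen trajectories for both hands, the resulting per-trial coupling index
#' (the ground truth the EEG encodes), and the continuous EEG with event
#' markers.
#'
#' The latent coupling drive passed to the EEG generator is the
#' variance-stabilised (square-root) coupling index, rescaled to `[0, 1]`
#' (`d01`), so the EEG encodes a monotone transform of the very quantity the
#' behavioural analysis recovers from the trajectories.
#'
#' All randomness derives from `cfg$seed` via fixed per-stage substreams, so
#' identical configurations give bit-identical sessions.
#'
#' @param cfg a [session_config()].
#' @param max_order_tries attempts allowed when searching for a trial order
#'   satisfying the run-length constraint.
#' @return A `drawing_session`: list with `trials` (data.frame: `trial_id`,
#'   `condition`, `onset_s`, `offset_s`, `duration_s`, `coupling`),
#'   `trajectories` (list of left/right pairs), `eeg` (an `eeg_session`),
#'   `truth` (data.frame: `trial_id`, `condition`, `true_ci`, `drive`,
#'   `d01`, `sign`), `behaviour` (the curvature table) and `config`.
#' @export
generate_session <- function(cfg = session_config(), max_order_tries = 1000L) {
  stopifnot(inherits(cfg, "session_config"))

  set.seed(substream_seed(cfg$seed, "order"))
  condition <- pseudo_random_order(cfg$trials_per_condition,
                                   max_run = 4L, max_tries = max_order_tries)

  set.seed(substream_seed(cfg$seed, "durations"))
  duration_s <- truncated_normal(cfg$n_trials, cfg$trial_duration_mean,
                                 cfg$trial_duration_sd, cfg$trial_duration_min)

  lead_in_s <- 8
  offsets <- lead_in_s + cumsum(duration_s + cfg$rest_s)
  onsets <- offsets - duration_s
  trials <- data.frame(
    trial_id = seq_len(cfg$n_trials),
    condition = condition,
    onset_s = onsets,
    offset_s = offsets,
    duration_s = duration_s
  )

  set.seed(substream_seed(cfg$seed, "coupling"))
  kappa <- pmin(pmax(cfg$coupling_strength[condition] +
                       stats::rnorm(cfg$n_trials, 0, cfg$coupling_sd),
                     0.02), 0.98)
  trials$coupling <- as.numeric(kappa)

  set.seed(substream_seed(cfg$seed, "trajectories"))
  trajectories <- lapply(seq_len(cfg$n_trials), function(i) {
    generate_trajectory(condition[i], trials$coupling[i], duration_s[i],
                        pen_rate_hz = cfg$pen_rate_hz,
                        radius_px = cfg$radius_px,
                        wobble_px = cfg$wobble_px,
                        jitter_px = cfg$jitter_px,
                        hand_asymmetry = cfg$hand_asymmetry)
  })

  behaviour <- curvature_table(trajectories, trials, floor_px = cfg$ci_floor_px)
  # variance-stabilised coupling drive: sqrt compresses the reciprocal's
  # heavy right tail while staying near-linear in CI over its bulk
  sq <- sqrt(behaviour$ci)
  drive <- as.numeric(scale(sq))
  # rescale to [0, 1] against the 98th percentile so the few near-floor
  # trials saturate instead of compressing everyone else's dynamic range
  span <- stats::quantile(sq, 0.98) - min(sq)
  d01 <- if (span < .Machine$double.eps) rep(0.5, length(sq)) else
    pmin((sq - min(sq)) / span, 1)

  set.seed(substream_seed(cfg$seed, "signs"))
  sign_t <- balanced_signs(d01 * behaviour$ci)

  truth <- data.frame(
    trial_id = trials$trial_id,
    condition = condition,
    true_ci = behaviour$ci,
    drive = drive,
    d01 = d01,
    sign = sign_t
  )
  attr(truth, "encoding_mode") <- cfg$encoding_mode

  set.seed(substream_seed(cfg$seed, "eeg"))
  eeg <- generate_eeg(trials, truth, cfg)

  structure(list(trials = trials, trajectories = trajectories, eeg = eeg,
                 truth = truth, behaviour = behaviour, config = cfg),
            class = "drawing_session")
}

#' @export
print.drawing_session <- function(x, ...) {
  cat(sprintf("<drawing_session> %d trials (%s), encoding %s, seed %d\n",
              nrow(x$trials),
              paste(sprintf("%s: %d", names(table(x$trials$condition)),
                            as.integer(table(x$trials$condition))),
                    collapse = ", "),
              x$config$encoding_mode, x$config$seed))
  print(x$eeg)
  invisible(x)
}

# Random signs drawn in matched pairs: trials are ordered by the supplied
# weight, consecutive pairs get opposite signs (which member is positive is
# random). Marginally each sign is a fair coin and sign-symmetry of the
# encoded response is preserved, but the finite-sample covariance between
# the signed code and the weight is cancelled by construction instead of
# being left to luck - the signed term would otherwise dominate the
# sampling scatter of feature-index correlations through the index's
# heavy tail.
balanced_signs <- function(weight) {
  n <- length(weight)
  ord <- order(weight)
  sgn <- numeric(n)
  i <- 1L
  while (i < n) {
    s <- sample(c(-1, 1), 1L)
    sgn[ord[i]] <- s
    sgn[ord[i + 1L]] <- -s
    i <- i + 2L
  }
  if (i == n) sgn[ord[n]] <- sample(c(-1, 1), 1L)
  sgn
}

# balanced condition sequence with no run longer than max_run
pseudo_random_order <- function(per_condition, max_run = 4L, max_tries = 1000L) {
  pool <- rep(drawing_conditions(), each = per_condition)
  for (i in seq_len(max_tries)) {
    cand <- sample(pool)
    runs <- rle(cand)
    if (max(runs$lengths) <= max_run) return(cand)
  }
  stop("no condition order satisfying the run-length constraint found within ",
       max_tries, " attempts", call. = FALSE)
}

truncated_normal <- function(n, mean, sd, lower) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lower)
    guard <- guard + 1L
  }
  out[out < lower] <- lower
  out
}
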