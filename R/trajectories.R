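#' Generate one trial's pair of pen trajectories
#'
#' Simulates the two hands drawing six iterations of their condition-specific
#' shapes. Lines are drawn vertically, so an ideal line has horizontal extent
#' 0 and a circle of radius `radius_px` has extent `2 * radius_px`.
#' Interlimb coupling is modelled as a convex morph of each hand's shape
#' toward the *other* hand's shape with weight `coupling_strength / 2`
#' (at full coupling both hands converge on the average shape), plus a slow
#' lateral drawing wobble whose shared-across-hands fraction grows with the
#' coupling, and white pixel jitter. The morph is monotone in
#' `coupling_strength`.
#'
#' Randomness is drawn from the current R RNG stream; seed upstream for
#' reproducibility.
#'
#' @param condition one of [drawing_conditions()].
#' @param coupling_strength realized coupling in `[0, 1]` for this trial.
#' @param duration_s trial duration in seconds (> 0).
#' @param pen_rate_hz pen sampling rate, Hz.
#' @param radius_px nominal circle radius, pixels.
#' @param n_iterations number of shape repetitions per trial.
#' @param wobble_px standard deviation of the slow lateral wobble, pixels
#'   (0 disables it).
#' @param jitter_px standard deviation of white pixel jitter (0 disables).
#' @param hand_asymmetry horizontal scale factor applied to the right
#'   (dominant) hand's trace; real drawings are never perfectly symmetric
#'   between hands, and this keeps the curvature difference away from the
#'   quantisation floor (1 disables).
#'
#' @return List with elements `left` and `right`, each a data.frame with
#'   columns `t_s`, `x_px`, `y_px`; attributes `condition` and
#'   `coupling_strength`.
#' @export
generate_trajectory <- function(condition, coupling_strength, duration_s,
                                pen_rate_hz = 60, radius_px = 140,
                                n_iterations = 6,
                                wobble_px = 38, jitter_px = 1,
                                hand_asymmetry = 1.05) {
  condition <- match_condition(condition)
  stopifnot(duration_s > 0, coupling_strength >= 0, coupling_strength <= 1)
  shapes <- condition_shapes(condition)
  t_s <- seq(0, duration_s, by = 1 / pen_rate_hz)
  theta <- 2 * pi * n_iterations * t_s / duration_s

  nominal_x <- function(shape) {
    if (shape == "circle") radius_px * cos(theta) else rep(0, length(theta))
  }
  # y is traversed identically for both shapes (vertical line of length 2R)
  y <- radius_px * sin(theta)

  w <- coupling_strength / 2
  x_left  <- (1 - w) * nominal_x(shapes[["left"]])  + w * nominal_x(shapes[["right"]])
  x_right <- (1 - w) * nominal_x(shapes[["right"]]) + w * nominal_x(shapes[["left"]])

  if (wobble_px > 0) {
    shared <- smooth_wobble(t_s, wobble_px)
    rho <- 0.35 * coupling_strength
    x_left  <- x_left  + sqrt(rho) * shared + sqrt(1 - rho) * smooth_wobble(t_s, wobble_px)
    x_right <- x_right + sqrt(rho) * shared + sqrt(1 - rho) * smooth_wobble(t_s, wobble_px)
  }
  x_right <- x_right * hand_asymmetry
  if (jitter_px > 0) {
    x_left  <- x_left  + stats::rnorm(length(t_s), 0, jitter_px)
    x_right <- x_right + stats::rnorm(length(t_s), 0, jitter_px)
    y_left  <- y + stats::rnorm(length(t_s), 0, jitter_px)
    y_right <- y + stats::rnorm(length(t_s), 0, jitter_px)
  } else {
    y_left <- y_right <- y
  }

  out <- list(
    left  = data.frame(t_s = t_s, x_px = x_left,  y_px = y_left),
    right = data.frame(t_s = t_s, x_px = x_right, y_px = y_right)
  )
  attr(out, "condition") <- condition
  attr(out, "coupling_strength") <- coupling_strength
  out
}

# Smooth zero-mean lateral drift: a few random slow sinusoids, rescaled to
# the requested standard deviation over the trial.
smooth_wobble <- function(t_s, sd_px, n_components = 4) {
  freqs <- stats::runif(n_components, 0.08, 0.5)
  amps <- abs(stats::rnorm(n_components))
  phases <- stats::runif(n_components, 0, 2 * pi)
  w <- rep(0, length(t_s))
  for (k in seq_len(n_components)) {
    w <- w + amps[k] * sin(2 * pi * freqs[k] * t_s + phases[k])
  }
  s <- stats::sd(w)
  if (s < .Machine$double.eps) return(rep(0, length(t_s)))
  (w - mean(w)) / s * sd_px
}
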