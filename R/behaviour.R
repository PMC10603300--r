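#' Horizontal-extent curvature of a drawn shape
#'
#' The behavioural curvature measure: the distance between the right-most and
#' left-most points of the trace on the horizontal axis,
#' `|max(x) - min(x)|`, in pixels, pooled over all samples (all six shape
#' iterations) of the trial. An ideal vertical line scores 0; an ideal circle
#' scores its diameter. Interference between the hands moves each hand's
#' curvature toward the other shape's value.
#'
#' @param traj data.frame with at least an `x_px` column (one pen
#'   trajectory), or a numeric vector of x coordinates.
#' @return Curvature in pixels (non-negative scalar).
#' @export
compute_curvature <- function(traj) {
  x <- if (is.data.frame(traj)) traj$x_px else traj
  if (is.null(x) || length(x) == 0L) {
    stop("empty trajectory: cannot compute curvature", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("trajectory contains non-finite x values", call. = FALSE)
  abs(max(x) - min(x))
}

#' Trialwise coupling index from left/right curvature
#'
#' The coupling index is the reciprocal of the absolute curvature difference
#' between the hands: `CI = 1 / max(|c_left - c_right|, floor_px)`. The
#' greater its value, the more similar the two drawn shapes, i.e. the
#' stronger the interlimb coupling. The floor keeps the index finite when
#' both hands draw equally curved shapes; its default of 3 px reflects the
#' resolution limit of extent differences under pixel-level pen jitter —
#' smaller differences are indistinguishable from measurement noise.
#'
#' @param c_left,c_right per-hand curvature in pixels (non-negative).
#' @param floor_px positive floor on the curvature difference, pixels.
#' @return Coupling index, a positive scalar bounded by `1 / floor_px`.
#' @export
compute_ci <- function(c_left, c_right, floor_px = 3) {
  if (any(c_left < 0) || any(c_right < 0)) {
    stop("curvature values must be non-negative", call. = FALSE)
  }
  if (floor_px <= 0) stop("floor_px must be positive", call. = FALSE)
  1 / pmax(abs(c_left - c_right), floor_px)
}

#' Curvature and coupling index for every trial of a session
#'
#' @param trajectories list of per-trial trajectory pairs as returned by
#'   [generate_trajectory()] (or read from a trajectory table with
#'   [trajectories_from_table()]).
#' @param trials data.frame with columns `trial_id` and `condition`,
#'   aligned with `trajectories`.
#' @param floor_px see [compute_ci()].
#' @return data.frame: `trial_id`, `condition`, `c_left_px`, `c_right_px`,
#'   `ci`.
#' @export
curvature_table <- function(trajectories, trials, floor_px = 3) {
  stopifnot(length(trajectories) == nrow(trials))
  c_left <- vapply(trajectories, function(tr) compute_curvature(tr$left), numeric(1))
  c_right <- vapply(trajectories, function(tr) compute_curvature(tr$right), numeric(1))
  data.frame(
    trial_id = trials$trial_id,
    condition = trials$condition,
    c_left_px = c_left,
    c_right_px = c_right,
    ci = compute_ci(c_left, c_right, floor_px)
  )
}

#' Per-condition summary of curvature and coupling index
#'
#' @param results curvature table as from [curvature_table()]; must carry a
#'   `condition` column or be joinable to `trials` by `trial_id`.
#' @param trials optional data.frame with `trial_id` and `condition`, used
#'   when `results` lacks conditions.
#' @return data.frame keyed by condition with mean/sd of `c_left_px`,
#'   `c_right_px` and `ci`, plus `n`.
#' @export
summarise_conditions <- function(results, trials = NULL) {
  if (is.null(results$condition)) {
    if (is.null(trials)) stop("no condition column and no trials table given", call. = FALSE)
    idx <- match(results$trial_id, trials$trial_id)
    if (anyNA(idx)) {
      stop("unknown trial_id(s): ",
           paste(results$trial_id[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    results$condition <- trials$condition[idx]
  }
  if (nrow(results) == 0L) {
    return(data.frame(condition = character(0), n = integer(0),
                      c_left_mean = numeric(0), c_left_sd = numeric(0),
                      c_right_mean = numeric(0), c_right_sd = numeric(0),
                      ci_mean = numeric(0), ci_sd = numeric(0)))
  }
  split_res <- split(results, results$condition)
  out <- do.call(rbind, lapply(names(split_res), function(cond) {
    r <- split_res[[cond]]
    data.frame(
      condition = cond, n = nrow(r),
      c_left_mean = mean(r$c_left_px), c_left_sd = stats::sd(r$c_left_px),
      c_right_mean = mean(r$c_right_px), c_right_sd = stats::sd(r$c_right_px),
      ci_mean = mean(r$ci), ci_sd = stats::sd(r$ci)
    )
  }))
  rownames(out) <- NULL
  present <- intersect(drawing_conditions(), out$condition)
  out[match(present, out$condition), , drop = FALSE]
}

#' Does mean curvature follow the expected condition ordering?
#'
#' Checks, separately for each hand, that mean curvature is smallest in
#' line-line, intermediate in the two incongruent conditions, and largest in
#' circle-circle.
#'
#' @param condition_summary output of [summarise_conditions()] containing all
#'   four conditions.
#' @return Named logical: `left`, `right`.
#' @export
check_extent_ordering <- function(condition_summary) {
  s <- condition_summary
  need <- drawing_conditions()
  if (!all(need %in% s$condition)) {
    stop("condition summary must contain all four conditions", call. = FALSE)
  }
  m <- function(cond, col) s[s$condition == cond, col]
  chk <- function(col) {
    ll <- m("line-line", col); cc <- m("circle-circle", col)
    inc <- c(m("line-circle", col), m("circle-line", col))
    all(ll < inc) && all(inc < cc)
  }
  c(left = chk("c_left_mean"), right = chk("c_right_mean"))
}

#' Flatten / rebuild per-trial trajectories as a long table
#'
#' The on-disk interchange format: one row per pen sample with columns
#' `trial_id`, `hand`, `t_s`, `x_px`, `y_px`.
#'
#' @param trajectories list of trajectory pairs aligned with `trials`.
#' @param trials data.frame with `trial_id`.
#' @return `trajectories_to_table()`: the long data.frame.
#' @export
trajectories_to_table <- function(trajectories, trials) {
  stopifnot(length(trajectories) == nrow(trials))
  parts <- lapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    rbind(
      data.frame(trial_id = trials$trial_id[i], hand = "left", tr$left),
      data.frame(trial_id = trials$trial_id[i], hand = "right", tr$right)
    )
  })
  do.call(rbind, parts)
}

#' @rdname trajectories_to_table
#' @param tab long trajectory table.
#' @return `trajectories_from_table()`: list of per-trial `left`/`right`
#'   trajectory pairs, ordered by first appearance of `trial_id`.
#' @export
trajectories_from_table <- function(tab) {
  ids <- unique(tab$trial_id)
  out <- lapply(ids, function(id) {
    sub <- tab[tab$trial_id == id, , drop = FALSE]
    list(
      left = sub[sub$hand == "left", c("t_s", "x_px", "y_px")],
      right = sub[sub$hand == "right", c("t_s", "x_px", "y_px")]
    )
  })
  names(out) <- as.character(ids)
  out
}
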