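#' Condition labels of the circle-line drawing task
#'
#' The four bimanual drawing conditions. A label `"a-b"` means the left hand
#' draws shape `a` and the right hand draws shape `b`. `line-line` and
#' `circle-circle` are the congruent conditions; `line-circle` and
#' `circle-line` are incongruent.
#'
#' @return Character vector of the four condition labels.
#' @export
drawing_conditions <- function() {
  c("line-line", "circle-circle", "line-circle", "circle-line")
}

#' @rdname drawing_conditions
#' @param condition a condition label
#' @return `condition_shapes()`: named character vector with the shape drawn
#'   by each hand (`left`, `right`).
#' @export
condition_shapes <- function(condition) {
  condition <- match_condition(condition)
  parts <- strsplit(condition, "-", fixed = TRUE)[[1]]
  c(left = parts[1], right = parts[2])
}

#' @rdname drawing_conditions
#' @return `is_congruent()`: logical, `TRUE` when both hands draw the same
#'   shape.
#' @export
is_congruent <- function(condition) {
  vapply(condition, function(cond) {
    shapes <- condition_shapes(cond)
    shapes[["left"]] == shapes[["right"]]
  }, logical(1), USE.NAMES = FALSE)
}

match_condition <- function(condition) {
  if (length(condition) != 1L || !condition %in% drawing_conditions()) {
    stop("unknown condition label: ", paste(condition, collapse = ", "),
         "; expected one of ", paste(drawing_conditions(), collapse = ", "),
         call. = FALSE)
  }
  condition
}

# Deterministic per-stage seed derived from a master seed, kept within the
# 32-bit integer range expected by set.seed().
substream_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(master) %% 50021) * 40993 + (h * 7919) %% 1048573)
}
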