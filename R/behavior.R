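#' Score the Satisfaction With Life Scale
#'
#' Sums the five SWLS item ratings.  Each item is rated on a 7-point Likert
#' scale (1 = strongly disagree ... 7 = strongly agree), so totals span 5-35.
#'
#' @param items Numeric vector of exactly five integer ratings in `[1, 7]`.
#' @return Integer total in `[5, 35]`.
#' @examples
#' score_swls(c(7, 7, 7, 7, 7)) # 35
#' score_swls(c(4, 5, 6, 3, 7)) # 25
#' @export
score_swls <- function(items) {
  if (length(items) != 5L) {
    abort("`items` must contain exactly five SWLS ratings.")
  }
  if (anyNA(items) || any(items != as.integer(items)) ||
      any(items < 1) || any(items > 7)) {
    abort("SWLS ratings must be integers between 1 and 7.")
  }
  as.integer(sum(items))
}

#' Local and global task-switching costs
#'
#' Local switch cost is the mean reaction-time difference between switch and
#' non-switch trials within mixed blocks; global switch cost is the mean
#' reaction-time difference between mixed and single-task blocks.
#'
#' @param trials Data frame with columns `condition` (one of `"single"`,
#'   `"mixed_switch"`, `"mixed_nonswitch"`) and `rt` (reaction time, ms).
#' @return One-row tibble with `local_cost` and `global_cost` in ms.
#' @examples
#' trials <- tibble::tibble(
#'   condition = c("mixed_switch", "mixed_switch",
#'                 "mixed_nonswitch", "mixed_nonswitch", "single", "single"),
#'   rt = c(900, 1100, 700, 900, 500, 600)
#' )
#' switch_costs(trials)
#' @export
switch_costs <- function(trials) {
  stopifnot(is.data.frame(trials), all(c("condition", "rt") %in% names(trials)))
  lv <- c("single", "mixed_switch", "mixed_nonswitch")
  bad <- setdiff(unique(trials$condition), lv)
  if (length(bad)) {
    abort(paste0("Unknown trial condition(s): ", paste(bad, collapse = ", ")))
  }
  if (any(trials$rt <= 0)) abort("Reaction times must be positive.")
  for (cond in lv) {
    if (!any(trials$condition == cond)) {
      abort(paste0("No trials in category '", cond, "'."))
    }
  }
  sw <- trials$rt[trials$condition == "mixed_switch"]
  ns <- trials$rt[trials$condition == "mixed_nonswitch"]
  sg <- trials$rt[trials$condition == "single"]
  tibble(
    local_cost = mean(sw) - mean(ns),
    global_cost = mean(c(sw, ns)) - mean(sg)
  )
}

#' Spatial working-memory summary and cohort-standardized composite
#'
#' Summarizes per-trial spatial working-memory data (set sizes 1-3) into a
#' per-subject mean reaction time and mean accuracy across the three set
#' sizes, then forms a composite as the average of z-scored accuracy and
#' negated z-scored reaction time, standardized over the supplied cohort.
#' The standardization scheme is recorded in the `"standardization"`
#' attribute so it is auditable.
#'
#' @param trials Data frame with columns `subject`, `set_size` (1, 2, or 3),
#'   `rt` (ms) and `correct` (0/1 or logical).
#' @return Tibble with one row per subject: `spwm_rt`, `spwm_accuracy`,
#'   `wm_composite`.  When the cohort has no variance in a component (or only
#'   one subject) the composite is `NA`.
#' @export
spatial_wm_composite <- function(trials) {
  stopifnot(is.data.frame(trials),
            all(c("subject", "set_size", "rt", "correct") %in% names(trials)))
  if (!all(trials$set_size %in% 1:3)) {
    abort("`set_size` must be 1, 2, or 3.")
  }
  per_ss <- trials |>
    group_by(.data$subject, .data$set_size) |>
    summarise(rt = mean(.data$rt), acc = mean(as.numeric(.data$correct)),
              .groups = "drop")
  counts <- per_ss |> dplyr::count(.data$subject)
  if (any(counts$n != 3L)) {
    miss <- counts$subject[counts$n != 3L]
    abort(paste0("Missing set size(s) for subject(s): ",
                 paste(miss, collapse = ", ")))
  }
  out <- per_ss |>
    group_by(.data$subject) |>
    summarise(spwm_rt = mean(.data$rt), spwm_accuracy = mean(.data$acc),
              .groups = "drop")
  zsafe <- function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) return(rep(NA_real_, length(x)))
    (x - mean(x)) / s
  }
  out$wm_composite <- (zsafe(out$spwm_accuracy) - zsafe(out$spwm_rt)) / 2
  # rescale so the composite itself has unit SD over the cohort
  if (!anyNA(out$wm_composite) && sd(out$wm_composite) > 0) {
    out$wm_composite <- out$wm_composite / sd(out$wm_composite)
  }
  attr(out, "standardization") <- paste(
    "cohort z-scores: composite = (z(accuracy) - z(mean RT)) / 2,",
    "rescaled to unit SD over the cohort"
  )
  out
}
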