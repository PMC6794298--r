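#' Outcome threshold from water-maze performance
#'
#' Either the median of the survivors' post-2-week swim times (the
#' derivation used to dichotomize the motivating cohort) or a fixed value.
#' The fixed default of 50 s reproduces the published operational grouping,
#' whose survivor median (49.1 s) was applied as a round 50-second rule.
#'
#' @param records behavioral data frame with columns `survived` and
#'   `post2w_swim_time_s` (NA for dead subjects).
#' @param mode `"fixed"` (default) or `"median"`.
#' @param fixed_value_s threshold in seconds for fixed mode.
#' @return Scalar threshold in seconds.
#' @export
derive_threshold <- function(records, mode = c("fixed", "median"),
                             fixed_value_s = 50) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    .assert_number(fixed_value_s, "fixed_value_s", positive = TRUE)
    return(fixed_value_s)
  }
  times <- records$post2w_swim_time_s[records$survived]
  times <- times[!is.na(times)]
  if (!length(times))
    stop("median mode needs at least one surviving record")
  stats::median(times)
}

#' Assign good/poor neurological outcome labels
#'
#' Survivors completing the post-2-week water maze in strictly less than the
#' threshold are labeled `good`; survivors at or above the threshold are
#' labeled `poor` (the boundary case is poor, from the strict "less than"
#' rule); subjects that died before the test are labeled `poor` with rule
#' `death`. Swim distance is recorded but never used for labeling.
#'
#' @param records behavioral data frame with columns `subject_id`,
#'   `survived`, `post2w_swim_time_s`.
#' @param threshold_s positive threshold in seconds.
#' @return Data frame with columns `subject_id`, `label` (`"good"` /
#'   `"poor"`), and `rule_applied` (`"swim-time-threshold"` / `"death"`).
#' @examples
#' rec <- data.frame(subject_id = c("a", "b", "c"),
#'                   survived = c(TRUE, TRUE, FALSE),
#'                   post2w_swim_time_s = c(10.1, 114.7, NA))
#' assign_outcomes(rec, 50)
#' @export
assign_outcomes <- function(records, threshold_s = 50) {
  .assert_number(threshold_s, "threshold_s", positive = TRUE)
  if (anyDuplicated(records$subject_id))
    stop("duplicate subject ids in behavioral records")
  surv <- as.logical(records$survived)
  times <- records$post2w_swim_time_s
  if (any(surv & is.na(times)))
    stop("surviving subjects must have a post-2-week swim time")
  label <- ifelse(!surv, "poor",
                  ifelse(times < threshold_s, "good", "poor"))
  rule <- ifelse(surv, "swim-time-threshold", "death")
  data.frame(subject_id = records$subject_id, label = label,
             rule_applied = rule, stringsAsFactors = FALSE)
}
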