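## Published group-level calibration tables for the PCAS rat cohort:
## per-region median (q1-q3) by outcome group, post-3-hour timepoint.
## "suv"   - regional and whole-brain SUV on the post-3-hour scan
## "delta" - SUV change, baseline minus post-3-hour
## "suvr"  - regional SUV normalized to whole-brain SUV, post-3-hour
## (good outcome n = 8, poor outcome n = 10)

.cal_rows <- function(measure, group, region, median, q1, q3) {
  data.frame(measure = measure, group = group, region = region,
             median = median, q1 = q1, q3 = q3, stringsAsFactors = FALSE)
}

.build_calibration <- function() {
  reg <- c(.CORTICAL_REGIONS, .SUBCORTICAL_PAIRED, .MIDLINE_REGIONS, .WHOLE_BRAIN)
  suv_good <- rbind(
    c(4.55, 4.03, 5.35), c(4.01, 3.75, 5.54), c(5.24, 4.84, 6.52),
    c(4.73, 3.50, 5.36), c(5.34, 5.15, 6.36), c(4.84, 4.12, 5.92),
    c(5.22, 4.54, 5.97), c(4.41, 4.12, 5.91), c(4.53, 3.83, 5.46),
    c(4.48, 4.23, 5.90), c(4.55, 3.63, 5.58), c(3.78, 3.51, 4.43),
    c(4.80, 4.47, 5.84), c(4.36, 4.17, 5.29), c(3.49, 2.84, 4.30),
    c(3.76, 3.06, 4.67), c(5.94, 5.43, 6.88))
  suv_poor <- rbind(
    c(2.84, 2.46, 3.85), c(2.66, 2.27, 3.43), c(3.22, 2.49, 4.02),
    c(2.43, 1.76, 3.06), c(3.48, 2.67, 4.61), c(2.67, 2.03, 3.40),
    c(3.12, 2.37, 4.23), c(2.60, 2.19, 3.40), c(2.79, 2.32, 3.54),
    c(2.70, 2.25, 3.56), c(2.66, 2.26, 3.50), c(2.65, 2.07, 3.37),
    c(3.20, 2.43, 4.27), c(3.07, 2.38, 4.23), c(2.30, 1.82, 3.42),
    c(2.54, 2.13, 3.86), c(3.02, 2.28, 3.77))
  delta_good <- rbind(
    c(1.33, 0.90, 1.75), c(1.46, 0.63, 1.87), c(1.71, 0.64, 2.79),
    c(1.29, 0.08, 1.89), c(1.34, 0.36, 2.53), c(1.15, 0.66, 2.31),
    c(1.28, 0.48, 2.28), c(1.48, 0.48, 2.34), c(1.62, 0.18, 2.44),
    c(1.47, 0.77, 2.24), c(1.42, 0.22, 2.63), c(0.76, -0.08, 2.16),
    c(1.39, 0.08, 2.16), c(1.17, 0.19, 2.04), c(1.17, 0.47, 1.67),
    c(1.03, -0.05, 1.60), c(1.41, 0.39, 1.73))
  delta_poor <- rbind(
    c(2.46, 1.81, 3.41), c(2.56, 2.22, 3.11), c(3.85, 2.86, 4.47),
    c(2.70, 1.61, 3.16), c(3.78, 2.37, 4.41), c(3.49, 2.54, 3.95),
    c(3.30, 1.99, 3.91), c(3.27, 2.76, 3.96), c(3.14, 2.35, 3.92),
    c(3.33, 2.56, 3.82), c(3.17, 2.38, 3.95), c(2.04, 1.33, 2.61),
    c(2.89, 1.90, 3.59), c(2.50, 1.38, 3.12), c(1.71, 1.17, 2.31),
    c(1.56, 1.08, 2.23), c(2.85, 1.85, 3.44))
  ## SUVR has no whole-brain row (identically 1 by construction)
  suvr_good <- rbind(
    c(0.99, 0.97, 1.09), c(1.00, 0.91, 1.07), c(1.25, 1.15, 1.30),
    c(1.02, 0.88, 1.11), c(1.24, 1.20, 1.28), c(1.12, 1.04, 1.18),
    c(1.14, 1.10, 1.22), c(1.03, 1.00, 1.21), c(1.02, 0.97, 1.09),
    c(1.08, 1.03, 1.21), c(1.04, 0.96, 1.14), c(0.85, 0.81, 0.89),
    c(1.12, 1.05, 1.17), c(1.01, 0.94, 1.05), c(0.75, 0.62, 0.84),
    c(0.83, 0.65, 0.92))
  suvr_poor <- rbind(
    c(0.99, 0.96, 1.03), c(0.92, 0.88, 0.99), c(1.06, 0.98, 1.10),
    c(0.80, 0.66, 0.92), c(1.16, 1.10, 1.19), c(0.88, 0.80, 0.97),
    c(1.04, 0.96, 1.11), c(0.84, 0.79, 0.95), c(0.87, 0.84, 0.99),
    c(0.92, 0.88, 0.99), c(0.84, 0.81, 0.99), c(0.89, 0.84, 0.92),
    c(1.08, 1.00, 1.13), c(1.04, 1.00, 1.12), c(1.04, 0.75, 1.10),
    c(1.03, 0.88, 1.19))
  rbind(
    .cal_rows("suv",   "good", reg, suv_good[, 1],  suv_good[, 2],  suv_good[, 3]),
    .cal_rows("suv",   "poor", reg, suv_poor[, 1],  suv_poor[, 2],  suv_poor[, 3]),
    .cal_rows("delta", "good", reg, delta_good[, 1], delta_good[, 2], delta_good[, 3]),
    .cal_rows("delta", "poor", reg, delta_poor[, 1], delta_poor[, 2], delta_poor[, 3]),
    .cal_rows("suvr",  "good", reg[reg != .WHOLE_BRAIN],
              suvr_good[, 1], suvr_good[, 2], suvr_good[, 3]),
    .cal_rows("suvr",  "poor", reg[reg != .WHOLE_BRAIN],
              suvr_poor[, 1], suvr_poor[, 2], suvr_poor[, 3])
  )
}

#' Published calibration distributions for the PCAS rat cohort
#'
#' Group-level medians and interquartile ranges of regional uptake in the
#' post-cardiac-arrest rat cohort that the simulator is calibrated to:
#' post-3-hour SUV (`"suv"`), SUV change between baseline and post-3-hour
#' scans (`"delta"`), and post-3-hour whole-brain-normalized SUVR (`"suvr"`),
#' for the good (n = 8) and poor (n = 10) neurological outcome groups.
#'
#' @param measure one of `"suv"`, `"delta"`, `"suvr"`, or `"all"`.
#' @return A data frame with columns `measure`, `group`, `region`, `median`,
#'   `q1`, `q3`.
#' @examples
#' head(pcas_calibration("suvr"))
#' @export
pcas_calibration <- function(measure = c("all", "suv", "delta", "suvr")) {
  measure <- match.arg(measure)
  out <- .build_calibration()
  if (measure != "all") out <- out[out$measure == measure, ]
  rownames(out) <- NULL
  out
}

## IQR -> normal sd under the (median, IQR) parameterization.
## qnorm(0.75) - qnorm(0.25) = 1.34898...
.iqr_to_sd <- function(q1, q3) (q3 - q1) / (stats::qnorm(0.75) - stats::qnorm(0.25))
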