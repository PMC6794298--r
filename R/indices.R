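#' SUV change between timepoints
#'
#' Regional SUV change, computed as baseline SUV minus post-insult SUV, so
#' positive values indicate a metabolic decrease after the insult. Increases
#' (negative change) are allowed. The whole-brain value is included.
#'
#' @param baseline,post3h [regional_uptake()] objects for the same subject.
#' @return Named numeric vector of SUV change per region, with the whole
#'   brain as the last element.
#' @examples
#' # delta = 6 - 4 = 2 for a region measured at 6 then 4
#' @export
suv_delta <- function(baseline, post3h) {
  stopifnot(inherits(baseline, "regional_uptake"),
            inherits(post3h, "regional_uptake"))
  if (!identical(baseline$subject_id, post3h$subject_id))
    stop("timepoints belong to different subjects: '", baseline$subject_id,
         "' vs '", post3h$subject_id, "'")
  if (!identical(names(baseline$suv_by_region), names(post3h$suv_by_region)))
    stop("the two timepoints cover different region sets")
  out <- c(baseline$suv_by_region - post3h$suv_by_region,
           stats::setNames(baseline$whole_brain_suv - post3h$whole_brain_suv,
                           baseline$scheme$whole_brain))
  out
}

#' Whole-brain-normalized SUV ratio (SUVR)
#'
#' Each regional SUV divided by the whole-brain SUV of the same scan; the
#' whole-brain entry is identically 1. SUVR removes global metabolic
#' scaling: multiplying every SUV by a constant leaves all SUVRs unchanged.
#'
#' @param uptake a [regional_uptake()] object.
#' @return Named numeric vector of SUVR per region, whole brain last (== 1).
#' @export
suvr <- function(uptake) {
  stopifnot(inherits(uptake, "regional_uptake"))
  if (uptake$whole_brain_suv <= 0)
    stop("whole-brain SUV must be > 0")
  c(uptake$suv_by_region / uptake$whole_brain_suv,
    stats::setNames(1, uptake$scheme$whole_brain))
}

#' Forebrain-to-hindbrain ratio (FHR)
#'
#' The unweighted mean over the forebrain region set divided by the
#' unweighted mean over the hindbrain region set. Because whole-brain
#' normalization divides every region by the same scalar, the FHR of an SUV
#' table equals the FHR of the corresponding SUVR table exactly.
#'
#' @param values named numeric vector of regional values (SUV or SUVR) or a
#'   [regional_uptake()] object.
#' @param scheme a [region_scheme()] defining the two sets.
#' @return Positive scalar.
#' @examples
#' sch <- region_scheme()
#' vals <- setNames(rep(2, length(sch$analysis_regions)),
#'                  sch$analysis_regions)
#' fhr(vals, sch)  # 1
#' @export
fhr <- function(values, scheme = region_scheme()) {
  if (inherits(values, "regional_uptake")) {
    scheme <- values$scheme
    values <- values$suv_by_region
  }
  missing <- setdiff(c(scheme$forebrain, scheme$hindbrain), names(values))
  if (length(missing))
    stop("missing region(s) for FHR: ", paste(missing, collapse = ", "))
  v <- values[c(scheme$forebrain, scheme$hindbrain)]
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all forebrain/hindbrain values must be finite and > 0")
  mean(values[scheme$forebrain]) / mean(values[scheme$hindbrain])
}

#' Derived indices for a cohort uptake table
#'
#' Computes per-subject SUV change, SUVR, and the FHR for each timepoint
#' from a tidy regional-uptake table.
#'
#' @param uptake_table data frame with columns `subject_id`, `timepoint`,
#'   `region`, `suv` (the whole-brain region included as a row).
#' @param scheme a [region_scheme()].
#' @return A list of tidy data frames: `suv_delta` (`subject_id`, `region`,
#'   `value`), `suvr` (`subject_id`, `timepoint`, `region`, `value`), and
#'   `fhr` (`subject_id`, `timepoint`, `fhr`).
#' @export
derive_indices <- function(uptake_table, scheme = region_scheme()) {
  need <- c("subject_id", "timepoint", "region", "suv")
  missing <- setdiff(need, names(uptake_table))
  if (length(missing))
    stop("uptake table lacks column(s): ", paste(missing, collapse = ", "))
  subjects <- unique(uptake_table$subject_id)
  ups <- list()
  for (s in subjects) {
    for (tp in unique(uptake_table$timepoint[uptake_table$subject_id == s])) {
      sub <- uptake_table[uptake_table$subject_id == s &
                            uptake_table$timepoint == tp, ]
      vals <- stats::setNames(sub$suv, sub$region)
      wb <- vals[[scheme$whole_brain]]
      if (is.null(wb) || is.na(wb))
        stop("no whole-brain row for subject '", s, "', timepoint '", tp, "'")
      ups[[paste(s, tp)]] <- regional_uptake(
        s, tp, vals[scheme$analysis_regions], wb, scheme)
    }
  }
  suvr_rows <- list(); fhr_rows <- list(); delta_rows <- list()
  for (key in names(ups)) {
    u <- ups[[key]]
    sr <- suvr(u)
    suvr_rows[[key]] <- data.frame(subject_id = u$subject_id,
                                   timepoint = u$timepoint,
                                   region = names(sr), value = as.numeric(sr),
                                   stringsAsFactors = FALSE)
    fhr_rows[[key]] <- data.frame(subject_id = u$subject_id,
                                  timepoint = u$timepoint,
                                  fhr = fhr(u), stringsAsFactors = FALSE)
  }
  for (s in subjects) {
    kb <- paste(s, "baseline"); kp <- paste(s, "post3h")
    if (!is.null(ups[[kb]]) && !is.null(ups[[kp]])) {
      d <- suv_delta(ups[[kb]], ups[[kp]])
      delta_rows[[s]] <- data.frame(subject_id = s, region = names(d),
                                    value = as.numeric(d),
                                    stringsAsFactors = FALSE)
    }
  }
  rbind_reset <- function(lst) {
    if (!length(lst)) return(NULL)
    out <- do.call(rbind, lst); rownames(out) <- NULL; out
  }
  list(suv_delta = rbind_reset(delta_rows),
       suvr = rbind_reset(suvr_rows),
       fhr = rbind_reset(fhr_rows))
}
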