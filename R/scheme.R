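#' @keywords internal
"_PACKAGE"

## Canonical analysis-region names, in the order the study tables list them.
.CORTICAL_REGIONS <- c(
  "insular cortex", "auditory cortex", "cingulate cortex",
  "frontal association cortex", "medial prefrontal cortex", "motor cortex",
  "orbitofrontal cortex", "parietal association cortex",
  "retro-splenial cortex", "somatosensory cortex", "visual cortex"
)
.SUBCORTICAL_PAIRED <- c("hippocampus", "thalamus")
.MIDLINE_REGIONS    <- c("midbrain", "pons", "medulla")
.WHOLE_BRAIN        <- "whole brain"

#' Analysis region scheme
#'
#' Defines the analysis-level volumes of interest (VOIs): the 16 named brain
#' regions quantified per subject, plus the whole-brain reference region, and
#' the forebrain / hindbrain membership used by the forebrain-to-hindbrain
#' ratio ([fhr()]).
#'
#' The default membership places the 11 cortical VOIs together with the
#' hippocampus and thalamus in the forebrain set, and the pons and medulla in
#' the hindbrain set. The midbrain belongs anatomically to neither the
#' forebrain nor the hindbrain proper and is excluded from both sets by
#' default. Both sets are fully configurable; any report derived from a
#' scheme should print the sets actually used.
#'
#' @param analysis_regions character vector of analysis region names
#'   (excluding the whole brain).
#' @param forebrain character vector, subset of `analysis_regions`.
#' @param hindbrain character vector, subset of `analysis_regions`, disjoint
#'   from `forebrain`.
#' @return An object of class `region_scheme`: a list with elements
#'   `analysis_regions`, `forebrain`, `hindbrain` and `whole_brain`.
#' @examples
#' sch <- region_scheme()
#' sch$hindbrain
#' @export
region_scheme <- function(analysis_regions = c(.CORTICAL_REGIONS,
                                               .SUBCORTICAL_PAIRED,
                                               .MIDLINE_REGIONS),
                          forebrain = c(.CORTICAL_REGIONS, .SUBCORTICAL_PAIRED),
                          hindbrain = c("pons", "medulla")) {
  analysis_regions <- as.character(analysis_regions)
  forebrain <- as.character(forebrain)
  hindbrain <- as.character(hindbrain)
  if (anyDuplicated(analysis_regions))
    stop("duplicate analysis region names")
  if (.WHOLE_BRAIN %in% c(analysis_regions, forebrain, hindbrain))
    stop("the whole brain is the normalization reference, not an analysis region")
  bad_f <- setdiff(forebrain, analysis_regions)
  bad_h <- setdiff(hindbrain, analysis_regions)
  if (length(bad_f) || length(bad_h))
    stop("forebrain/hindbrain members not in analysis_regions: ",
         paste(c(bad_f, bad_h), collapse = ", "))
  both <- intersect(forebrain, hindbrain)
  if (length(both))
    stop("regions in both forebrain and hindbrain sets: ",
         paste(both, collapse = ", "))
  if (!length(forebrain) || !length(hindbrain))
    stop("forebrain and hindbrain sets must be nonempty")
  structure(
    list(analysis_regions = analysis_regions,
         forebrain = forebrain,
         hindbrain = hindbrain,
         whole_brain = .WHOLE_BRAIN),
    class = "region_scheme"
  )
}

#' @export
print.region_scheme <- function(x, ...) {
  cat("Region scheme:", length(x$analysis_regions),
      "analysis regions + whole brain\n")
  cat("  forebrain (", length(x$forebrain), "): ",
      paste(x$forebrain, collapse = ", "), "\n", sep = "")
  cat("  hindbrain (", length(x$hindbrain), "): ",
      paste(x$hindbrain, collapse = ", "), "\n", sep = "")
  excl <- setdiff(x$analysis_regions, c(x$forebrain, x$hindbrain))
  if (length(excl))
    cat("  in neither set: ", paste(excl, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname region_scheme
#' @export
cortical_regions <- function() .CORTICAL_REGIONS

#' @rdname region_scheme
#' @export
whole_brain_region <- function() .WHOLE_BRAIN
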