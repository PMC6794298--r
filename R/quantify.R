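#' Convert an activity-concentration volume to SUV
#'
#' Standardized uptake value: voxel activity concentration divided by
#' injected dose per body weight, assuming 1 g/ml tissue density, so
#' `SUV = conc_kBq_per_ml * body_weight_g / (injected_dose_MBq * 1000)`.
#' The injected dose is taken as already decay-corrected to scan start; no
#' decay-correction operator is applied here.
#'
#' @param vol a `volume_grid` of kind `"concentration"` (kBq/ml).
#' @param meta one-row data frame or list with `injected_dose_MBq` and
#'   `body_weight_g`.
#' @return A `volume_grid` of kind `"suv"`.
#' @examples
#' v <- volume_grid(array(25.5034, c(2, 2, 2)))
#' s <- compute_suv_volume(v, list(injected_dose_MBq = 9.5,
#'                                 body_weight_g = 372.5))
#' s$voxels[1]  # ~1
#' @export
compute_suv_volume <- function(vol, meta) {
  stopifnot(inherits(vol, "volume_grid"))
  if (vol$value_kind != "concentration")
    stop("volume is already SUV-scaled (value_kind = '", vol$value_kind, "')")
  dose <- as.numeric(meta$injected_dose_MBq)
  weight <- as.numeric(meta$body_weight_g)
  .assert_number(dose, "injected_dose_MBq", positive = TRUE)
  .assert_number(weight, "body_weight_g", positive = TRUE)
  volume_grid(vol$voxels * weight / (dose * 1000),
              spacing_mm = vol$spacing_mm, value_kind = "suv")
}

#' Per-label mean SUV
#'
#' Unweighted mean over each label's voxels. Labels with no voxels in the
#' volume are absent from the result, not reported as zero.
#'
#' @param suv_vol a `volume_grid` of kind `"suv"`.
#' @param atlas a `label_atlas` on the identical grid (no resampling is
#'   performed; co-registration is out of scope).
#' @return Named numeric vector, mean SUV per label id.
#' @export
extract_regional_means <- function(suv_vol, atlas) {
  stopifnot(inherits(suv_vol, "volume_grid"), inherits(atlas, "label_atlas"))
  if (suv_vol$value_kind != "suv")
    stop("expected an SUV volume; call compute_suv_volume() first")
  if (!identical(dim(suv_vol$voxels), dim(atlas$labels)))
    stop("volume and atlas grids differ: ",
         paste(dim(suv_vol$voxels), collapse = "x"), " vs ",
         paste(dim(atlas$labels), collapse = "x"))
  if (!isTRUE(all.equal(suv_vol$spacing_mm, atlas$spacing_mm)))
    stop("volume and atlas voxel spacings differ")
  nz <- atlas$labels != 0L
  means <- tapply(suv_vol$voxels[nz], atlas$labels[nz], mean)
  stats::setNames(as.numeric(means), names(means))
}

#' Regional uptake record
#'
#' Per-subject, per-timepoint mapping from analysis region to mean SUV plus
#' the whole-brain mean SUV.
#'
#' @param subject_id subject identifier.
#' @param timepoint `"baseline"` or `"post3h"`.
#' @param suv_by_region named numeric vector covering every analysis region
#'   of `scheme`.
#' @param whole_brain_suv positive scalar.
#' @param scheme a [region_scheme()].
#' @return An object of class `regional_uptake`.
#' @export
regional_uptake <- function(subject_id, timepoint, suv_by_region,
                            whole_brain_suv, scheme = region_scheme()) {
  missing <- setdiff(scheme$analysis_regions, names(suv_by_region))
  if (length(missing))
    stop("missing analysis regions: ", paste(missing, collapse = ", "))
  suv_by_region <- suv_by_region[scheme$analysis_regions]
  if (any(!is.finite(suv_by_region)) || any(suv_by_region <= 0))
    stop("all regional SUVs must be finite and > 0")
  .assert_number(whole_brain_suv, "whole_brain_suv", positive = TRUE)
  structure(list(subject_id = subject_id, timepoint = timepoint,
                 suv_by_region = suv_by_region,
                 whole_brain_suv = as.numeric(whole_brain_suv),
                 scheme = scheme),
            class = "regional_uptake")
}

#' @export
print.regional_uptake <- function(x, ...) {
  cat("Regional uptake:", x$subject_id, "/", x$timepoint, "\n")
  cat("  whole brain SUV:", format(x$whole_brain_suv, digits = 4), "\n")
  print(round(x$suv_by_region, 3))
  invisible(x)
}

#' Merge labels into analysis VOIs
#'
#' Reduces raw per-label means to analysis-level regional uptake: the left
#' and right labels of paired structures are averaged, subregion labels
#' (e.g. of the hippocampus) sharing a merge group are merged, and the
#' whole-brain value is the mean over the dedicated whole-brain label set.
#' Averaging is unweighted by default, matching an atlas workflow in which
#' hemisphere means are simply averaged; volume-weighted averaging (weights
#' proportional to label voxel counts) is available via `weighting`.
#'
#' @param raw_means named numeric vector from [extract_regional_means()].
#' @param atlas a `label_atlas`.
#' @param scheme a [region_scheme()].
#' @param subject_id,timepoint identifiers carried into the result.
#' @param weighting `"unweighted"` (default) or `"volume"`.
#' @return A [regional_uptake()] object.
#' @export
merge_and_pair <- function(raw_means, atlas, scheme = region_scheme(),
                           subject_id = "subject", timepoint = "post3h",
                           weighting = c("unweighted", "volume")) {
  weighting <- match.arg(weighting)
  lk <- atlas$lookup
  counts <- if (weighting == "volume") atlas_voxel_counts(atlas) else NULL
  agg <- function(region_name) {
    labs <- lk$label[lk$merge_group == region_name]
    if (!length(labs))
      stop("no contributing label for analysis region '", region_name, "'")
    have <- as.character(labs) %in% names(raw_means)
    if (!all(have))
      stop("missing contributing label(s) for analysis region '",
           region_name, "'")
    vals <- raw_means[as.character(labs)]
    if (weighting == "volume") {
      w <- counts[as.character(labs)]
      sum(vals * w) / sum(w)
    } else mean(vals)
  }
  suv <- vapply(scheme$analysis_regions, agg, numeric(1))
  wb <- agg(scheme$whole_brain)
  regional_uptake(subject_id, timepoint, suv, wb, scheme)
}

#' Quantify one rendered scan
#'
#' Convenience wrapper: SUV scaling, per-label extraction, and
#' pairing/merging in one call.
#'
#' @inheritParams compute_suv_volume
#' @inheritParams merge_and_pair
#' @param vol a `volume_grid` of kind `"concentration"`.
#' @return A [regional_uptake()] object.
#' @export
quantify_scan <- function(vol, atlas, meta, scheme = region_scheme(),
                          subject_id = "subject", timepoint = "post3h",
                          weighting = "unweighted") {
  suv_vol <- compute_suv_volume(vol, meta)
  raw <- extract_regional_means(suv_vol, atlas)
  merge_and_pair(raw, atlas, scheme, subject_id = subject_id,
                 timepoint = timepoint, weighting = weighting)
}
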