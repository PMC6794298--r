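#' Read and write volumes and atlases
#'
#' Volumes are stored as NIfTI-1 (`.nii.gz`) with voxel spacing in the
#' header; atlas lookups as tab-separated text with columns `label`,
#' `region`, `hemisphere`, `merge_group`.
#'
#' @param vol a `volume_grid`.
#' @param path file path (`.nii` or `.nii.gz`).
#' @name volume_io
NULL

#' @rdname volume_io
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_grid"))
  img <- RNifti::asNifti(vol$voxels)
  img <- RNifti::`pixdim<-`(img, vol$spacing_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname volume_io
#' @param value_kind value kind to tag the volume with on read.
#' @export
read_volume <- function(path, value_kind = "concentration") {
  img <- RNifti::readNifti(path)
  volume_grid(array(as.numeric(img), dim = dim(img)),
              spacing_mm = RNifti::pixdim(img)[1:3],
              value_kind = value_kind)
}

#' @rdname volume_io
#' @param atlas a `label_atlas`.
#' @param nifti_path,lookup_path output paths for the label volume and
#'   lookup table.
#' @export
write_atlas <- function(atlas, nifti_path, lookup_path) {
  stopifnot(inherits(atlas, "label_atlas"))
  img <- RNifti::asNifti(atlas$labels)
  img <- RNifti::`pixdim<-`(img, atlas$spacing_mm)
  RNifti::writeNifti(img, nifti_path, datatype = "int16")
  utils::write.table(atlas$lookup, lookup_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(nifti_path)
}

#' @rdname volume_io
#' @export
read_atlas <- function(nifti_path, lookup_path) {
  img <- RNifti::readNifti(nifti_path)
  lookup <- utils::read.delim(lookup_path, stringsAsFactors = FALSE)
  atl <- structure(list(labels = array(as.integer(img), dim = dim(img)),
                        spacing_mm = RNifti::pixdim(img)[1:3],
                        lookup = lookup),
                   class = "label_atlas")
  .validate_atlas(atl)
  atl
}

.check_columns <- function(df, need, what) {
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(what, " lacks required column(s): ", paste(missing, collapse = ", "))
  invisible(df)
}

#' Read a tidy regional-uptake table
#'
#' Schema: one row per subject, timepoint and region with columns
#' `subject_id`, `timepoint`, `region`, `suv`; the whole-brain VOI appears
#' as a region row. This matches the tables written by [write_report()] and
#' lets externally quantified exports (e.g. from a VOI-template workstation)
#' enter the analysis in place of the imaging stage.
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_uptake_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("subject_id", "timepoint", "region", "suv"),
                 "uptake table")
  if (!nrow(df)) stop("uptake table is empty")
  df
}

#' Read a behavioral-record table
#'
#' Schema: columns `subject_id`, `survived`, `baseline_swim_time_s`,
#' `baseline_distance_cm`, `post2w_swim_time_s`, `post2w_distance_cm`
#' (post-2-week fields NA for dead subjects).
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_behavior_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("subject_id", "survived", "post2w_swim_time_s"),
                 "behavior table")
  if (!nrow(df)) stop("behavior table is empty")
  df$survived <- as.logical(df$survived)
  df
}
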