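#' Pipeline run configuration
#'
#' Bundles every choice the end-to-end runner needs: the cohort simulation
#' spec, the region scheme, the imaging grid, the outcome rule, and the
#' ROC conventions. One root seed passed to [run_experiment()] is split
#' deterministically per stage (atlas, cohort, per-scan noise), so a config
#' plus a seed fully determines every output.
#'
#' @param cohort a [cohort_spec()].
#' @param scheme a [region_scheme()].
#' @param grid_shape imaging grid dimensions.
#' @param outcome_mode `"fixed"` (50-second rule) or `"median"` (survivor
#'   median), see [derive_threshold()].
#' @param outcome_threshold_s threshold for fixed mode, seconds.
#' @param positive_class ROC positive class (default `"good"`).
#' @param cutoff_convention `"midpoint"` or `"observed"`, see
#'   [youden_cutoff()].
#' @param image_mode if `TRUE`, scans are rendered and quantified through
#'   the imaging stage; if `FALSE`, the simulator's true regional tables
#'   feed the analysis directly (table mode).
#' @param weighting label-averaging mode for [merge_and_pair()].
#' @param p_adjust `"none"` (default: per-region p-values are reported
#'   unadjusted, as is conventional for these exploratory regional tables)
#'   or `"holm"` to add a familywise-adjusted column per table.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(),
                       scheme = region_scheme(),
                       grid_shape = c(64L, 64L, 32L),
                       outcome_mode = c("fixed", "median"),
                       outcome_threshold_s = 50,
                       positive_class = "good",
                       cutoff_convention = c("midpoint", "observed"),
                       image_mode = TRUE,
                       weighting = c("unweighted", "volume"),
                       p_adjust = c("none", "holm")) {
  structure(list(cohort = cohort, scheme = scheme,
                 grid_shape = as.integer(grid_shape),
                 outcome_mode = match.arg(outcome_mode),
                 outcome_threshold_s = outcome_threshold_s,
                 positive_class = positive_class,
                 cutoff_convention = match.arg(cutoff_convention),
                 image_mode = isTRUE(image_mode),
                 weighting = match.arg(weighting),
                 p_adjust = match.arg(p_adjust)),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' Accepts a flat JSON object with any of: `n_good`, `n_poor`, `n_dead`,
#' `calibration`, `family`, `noise_cv`, `psf_fwhm_mm`, `grid_shape`,
#' `outcome_mode`, `outcome_threshold_s`, `positive_class`,
#' `cutoff_convention`, `image_mode`, `weighting`, `forebrain`,
#' `hindbrain`. Unspecified fields keep package defaults.
#'
#' @param path JSON file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec_args <- cfg[intersect(names(cfg),
    c("n_good", "n_poor", "n_dead", "calibration", "family",
      "subject_effect", "noise_cv", "psf_fwhm_mm", "dose_MBq", "weight_g"))]
  cohort <- do.call(cohort_spec, spec_args)
  scheme_args <- cfg[intersect(names(cfg), c("forebrain", "hindbrain"))]
  scheme <- do.call(region_scheme, scheme_args)
  run_args <- cfg[intersect(names(cfg),
    c("grid_shape", "outcome_mode", "outcome_threshold_s", "positive_class",
      "cutoff_convention", "image_mode", "weighting", "p_adjust"))]
  do.call(run_config, c(list(cohort = cohort, scheme = scheme), run_args))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

## Regional two-group comparison table (one row per region), in the layout
## of the published group tables: median (q1-q3) per group plus the
## Mann-Whitney p-value.
.group_table <- function(values, labels_df, regions) {
  rows <- lapply(regions, function(r) {
    v <- values[values$region == r, ]
    m <- match(v$subject_id, labels_df$subject_id)
    lab <- labels_df$label[m]
    g <- v$value[lab == "good"]; p <- v$value[lab == "poor"]
    mw <- mann_whitney(g, p)
    sg <- median_iqr(g); sp <- median_iqr(p)
    data.frame(region = r,
               good_median = sg$median, good_q1 = sg$q1, good_q3 = sg$q3,
               good_n = sg$n,
               poor_median = sp$median, poor_q1 = sp$q1, poor_q3 = sp$q3,
               poor_n = sp$n,
               U = mw$statistic, p = mw$p_two_sided,
               method = mw$method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Core analysis shared by image mode and table mode: indices -> outcomes ->
## group statistics -> ROC.
.analyze <- function(uptake_table, behavior, config) {
  scheme <- config$scheme
  idx <- .stage("indices", derive_indices(uptake_table, scheme))
  threshold <- .stage("outcomes", derive_threshold(
    behavior, mode = config$outcome_mode,
    fixed_value_s = config$outcome_threshold_s))
  outcomes <- .stage("outcomes", assign_outcomes(behavior, threshold))

  post_suv <- uptake_table[uptake_table$timepoint == "post3h", ]
  post_suv <- data.frame(subject_id = post_suv$subject_id,
                         region = post_suv$region, value = post_suv$suv)
  suvr_post <- idx$suvr[idx$suvr$timepoint == "post3h" &
                          idx$suvr$region != scheme$whole_brain, ]
  regions_wb <- c(scheme$analysis_regions, scheme$whole_brain)
  tables <- .stage("statistics", list(
    suv_post3h = .group_table(post_suv, outcomes, regions_wb),
    suv_delta = .group_table(
      data.frame(subject_id = idx$suv_delta$subject_id,
                 region = idx$suv_delta$region,
                 value = idx$suv_delta$value),
      outcomes, regions_wb),
    suvr_post3h = .group_table(
      data.frame(subject_id = suvr_post$subject_id,
                 region = suvr_post$region, value = suvr_post$value),
      outcomes, scheme$analysis_regions)))
  if (!identical(config$p_adjust, "none"))
    tables <- lapply(tables, function(tb) {
      tb$p_adj <- stats::p.adjust(tb$p, method = config$p_adjust)
      tb
    })

  ## paired whole-brain test: global metabolic change baseline vs post-3h
  wb <- uptake_table[uptake_table$region == scheme$whole_brain, ]
  wb_wide <- merge(wb[wb$timepoint == "baseline", c("subject_id", "suv")],
                   wb[wb$timepoint == "post3h", c("subject_id", "suv")],
                   by = "subject_id", suffixes = c("_baseline", "_post3h"))
  paired_wb <- .stage("statistics", wilcoxon_signed_rank(
    wb_wide$suv_baseline, wb_wide$suv_post3h))

  fhr_post <- idx$fhr[idx$fhr$timepoint == "post3h", ]
  scores <- stats::setNames(fhr_post$fhr, fhr_post$subject_id)
  roc <- .stage("roc", roc_curve(scores, outcomes,
                                 positive_class = config$positive_class))
  youden <- .stage("roc", youden_cutoff(roc,
                                        convention = config$cutoff_convention))
  cls <- .stage("roc", classify(scores, youden$cutoff, outcomes,
                                positive_class = config$positive_class,
                                negative_class = setdiff(
                                  unique(outcomes$label),
                                  config$positive_class)[1] %||% "poor"))
  list(indices = idx, threshold = threshold, outcomes = outcomes,
       tables = tables, paired_whole_brain = paired_wb,
       fhr_scores = scores, roc = roc, youden = youden,
       classification = cls)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Run the full simulated study
#'
#' End-to-end pipeline reproducing the shape of the motivating analysis:
#' simulate a cohort (atlas phantom, true uptake, behavior), render and
#' quantify PET scans at both timepoints (or pass the true tables straight
#' through in table mode), derive SUV change / SUVR / FHR, assign outcome
#' labels from post-2-week water-maze performance, compare groups per
#' region with Mann-Whitney tests, and evaluate the post-3-hour FHR as a
#' prognostic index by ROC with a Youden-optimal cutoff.
#'
#' Identical `config` and `seed` produce identical reports; when `outdir`
#' is given every intermediate artifact is written to disk
#' (see [write_report()]).
#'
#' @param config a [run_config()].
#' @param seed integer root seed, split deterministically per stage.
#' @param outdir optional output directory.
#' @param write_volumes if `TRUE` (and `outdir` is set), rendered per-scan
#'   NIfTI volumes are written too.
#' @return An object of class `study_report`.
#' @examples
#' \donttest{
#' rep <- run_experiment(run_config(image_mode = FALSE), seed = 1)
#' rep$roc$auc
#' }
#' @export
run_experiment <- function(config = run_config(), seed = 1L,
                           outdir = NULL, write_volumes = FALSE) {
  stopifnot(inherits(config, "run_config"))
  atlas <- NULL
  cohort <- .stage("simulate", sample_cohort(config$cohort,
                                             derive_seed(seed, 2L)))
  if (config$image_mode) {
    atlas <- .stage("simulate", build_atlas(config$scheme, config$grid_shape,
                                            seed = derive_seed(seed, 1L)))
    uptake <- .stage("quantify", .quantify_cohort(cohort, atlas, config,
                                                  seed, outdir, write_volumes))
  } else {
    uptake <- cohort$true_suv[, c("subject_id", "timepoint", "region", "suv")]
  }
  res <- .analyze(uptake, cohort$behavior, config)
  report <- structure(
    c(list(uptake = uptake, behavior = cohort$behavior,
           true_groups = cohort$groups, atlas = atlas, config = config),
      res,
      list(provenance = list(
        seed = as.integer(seed),
        image_mode = config$image_mode,
        calibration = config$cohort$calibration,
        package = as.character(utils::packageVersion("fhrpet")),
        forebrain = config$scheme$forebrain,
        hindbrain = config$scheme$hindbrain))),
    class = "study_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

.quantify_cohort <- function(cohort, atlas, config, seed, outdir = NULL,
                             write_volumes = FALSE) {
  ids <- cohort$groups$subject_id
  rows <- list()
  for (i in seq_along(ids)) {
    s <- ids[i]
    for (j in c(1L, 2L)) {
      tp <- c("baseline", "post3h")[j]
      tr <- cohort$true_suv[cohort$true_suv$subject_id == s &
                              cohort$true_suv$timepoint == tp, ]
      true_vec <- stats::setNames(tr$suv, tr$region)
      meta <- cohort$metadata[cohort$metadata$subject_id == s &
                                cohort$metadata$timepoint == tp, ]
      if (nrow(meta) != 1L)
        stop("subject ", s, ": expected one metadata row for ", tp)
      vol <- render_scan(true_vec, atlas, meta,
                         noise_cv = cohort$spec$noise_cv,
                         psf_fwhm_mm = cohort$spec$psf_fwhm_mm,
                         seed = derive_seed(seed, 100L + 2L * i + j))
      if (!is.null(outdir) && write_volumes) {
        dir.create(file.path(outdir, "volumes"), recursive = TRUE,
                   showWarnings = FALSE)
        write_volume(vol, file.path(outdir, "volumes",
                                    sprintf("%s_%s.nii.gz", s, tp)))
      }
      u <- tryCatch(
        quantify_scan(vol, atlas, meta, config$scheme, subject_id = s,
                      timepoint = tp, weighting = config$weighting),
        error = function(e) stop("subject ", s, " (", tp, "): ",
                                 conditionMessage(e), call. = FALSE))
      rows[[paste(s, tp)]] <- data.frame(
        subject_id = s, timepoint = tp,
        region = c(names(u$suv_by_region), config$scheme$whole_brain),
        suv = c(as.numeric(u$suv_by_region), u$whole_brain_suv),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Analyze precomputed regional tables (table mode)
#'
#' Bypasses the imaging stage: accepts a tidy regional SUV table and a
#' behavioral table (file paths or data frames) and runs the identical
#' downstream analysis as [run_experiment()], so externally quantified VOI
#' exports can be analyzed directly.
#'
#' @param uptake tidy uptake table (data frame or CSV path), see
#'   [read_uptake_table()].
#' @param behavior behavioral table (data frame or CSV path), see
#'   [read_behavior_table()].
#' @param config a [run_config()] (its cohort/imaging fields are ignored).
#' @param outdir optional output directory.
#' @return A `study_report`.
#' @export
analyze_tables <- function(uptake, behavior, config = run_config(),
                           outdir = NULL) {
  if (is.character(uptake)) uptake <- read_uptake_table(uptake)
  if (is.character(behavior)) behavior <- read_behavior_table(behavior)
  .check_columns(uptake, c("subject_id", "timepoint", "region", "suv"),
                 "uptake table")
  .check_columns(behavior, c("subject_id", "survived", "post2w_swim_time_s"),
                 "behavior table")
  if (!nrow(behavior)) stop("behavior table is empty")
  res <- .analyze(uptake, behavior, config)
  report <- structure(
    c(list(uptake = uptake, behavior = behavior, true_groups = NULL,
           atlas = NULL, config = config),
      res,
      list(provenance = list(seed = NA_integer_, image_mode = FALSE,
                             calibration = "external tables",
                             package = as.character(
                               utils::packageVersion("fhrpet")),
                             forebrain = config$scheme$forebrain,
                             hindbrain = config$scheme$hindbrain))),
    class = "study_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("PCAS FDG-PET study report\n")
  cat("  subjects:", length(unique(x$uptake$subject_id)),
      "| outcome threshold:", format(x$threshold, digits = 4), "s\n")
  g <- table(x$outcomes$label)
  cat("  outcomes:", paste(names(g), g, sep = " = ", collapse = ", "), "\n")
  cat("  whole-brain baseline vs post-3h: W =",
      format(x$paired_whole_brain$statistic, digits = 4), ", p =",
      format(x$paired_whole_brain$p_two_sided, digits = 3), "\n")
  cat("  post-3h FHR ROC: AUC =", format(x$roc$auc, digits = 4),
      "| Youden cutoff =", format(x$youden$cutoff, digits = 4),
      "(J =", format(x$youden$j, digits = 3), ")\n")
  if (!is.null(x$classification$sensitivity))
    cat("  at cutoff: sensitivity =",
        format(x$classification$sensitivity, digits = 3),
        ", specificity =",
        format(x$classification$specificity, digits = 3), "\n")
  cat("  forebrain set:", paste(x$provenance$forebrain, collapse = ", "), "\n")
  cat("  hindbrain set:", paste(x$provenance$hindbrain, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.study_report <- function(object, ...) {
  print(object)
  cat("\nPost-3-hour SUVR by region:\n")
  print(object$tables$suvr_post3h[, c("region", "good_median", "poor_median",
                                      "p")], digits = 3)
  invisible(object)
}

#' Write a study report to disk
#'
#' Writes every report table as CSV (regional group tables, ROC points,
#' per-subject indices, outcome labels, behavior), the confusion matrix as
#' JSON, and a provenance block (seed, conventions, region sets, package
#' version) as JSON. Output is byte-identical for identical reports: no
#' timestamps are embedded.
#'
#' @param report a `study_report`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
  wcsv(report$tables$suv_post3h, "table_suv_post3h.csv")
  wcsv(report$tables$suv_delta, "table_suv_delta.csv")
  wcsv(report$tables$suvr_post3h, "table_suvr_post3h.csv")
  wcsv(report$uptake, "regional_suv.csv")
  wcsv(report$indices$suvr, "suvr_by_subject.csv")
  wcsv(report$indices$suv_delta, "suv_delta_by_subject.csv")
  wcsv(report$indices$fhr, "fhr_by_subject.csv")
  wcsv(report$outcomes, "outcome_labels.csv")
  wcsv(report$behavior, "behavior.csv")
  roc_df <- data.frame(threshold = report$roc$thresholds,
                       sensitivity = report$roc$sensitivity,
                       specificity = report$roc$specificity)
  wcsv(roc_df, "roc_points.csv")
  summary_json <- list(
    auc = report$roc$auc,
    youden_cutoff = report$youden$cutoff,
    youden_j = report$youden$j,
    sensitivity = report$classification$sensitivity,
    specificity = report$classification$specificity,
    threshold_s = report$threshold,
    confusion = if (!is.null(report$classification$confusion))
      as.data.frame(report$classification$confusion) else NULL)
  jsonlite::write_json(summary_json, file.path(outdir, "roc_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(report$provenance, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(report$atlas))
    write_atlas(report$atlas, file.path(outdir, "atlas.nii.gz"),
                file.path(outdir, "atlas_lookup.tsv"))
  invisible(outdir)
}
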