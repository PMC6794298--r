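#' Cohort simulation specification
#'
#' Describes a synthetic post-cardiac-arrest rat cohort: group sizes, the
#' per-group / per-region uptake distributions the sampler draws from, the
#' behavioral (water-maze) distributions, and the imaging forward-model
#' parameters used when scans are rendered.
#'
#' Two calibration modes are supported, because the published group tables
#' are not mutually consistent (per-region medians taken across animals do
#' not compose into ratio medians, and the whole-brain median exceeds every
#' regional median):
#'
#' * `"ratio"` (default): each subject receives a whole-brain SUV drawn from
#'   the published whole-brain SUV distribution and an independent regional
#'   SUVR profile drawn from the published SUVR distributions; regional SUV
#'   is their product. The whole-brain draw acts as the shared per-subject
#'   global-metabolism effect, so regional values are correlated within
#'   animal and the within-animal ratio structure that carries the
#'   prognostic signal is preserved.
#' * `"direct"`: regional SUVs are drawn directly from the published
#'   per-region SUV distributions, with a shared standard-normal subject
#'   effect of weight `subject_effect` inducing within-animal correlation
#'   while leaving each region's marginal distribution unchanged.
#'
#' In both modes baseline uptake is reconstructed as post-3-hour SUV plus a
#' draw from the published SUV-change distributions (no baseline group table
#' is published), and distributions are parameterized by median and IQR with
#' `sd = IQR / 1.349` under the default normal family.
#'
#' @param n_good,n_poor subjects destined for the good / poor outcome group.
#' @param n_dead subjects (from the poor-destined pool) dying before the
#'   post-2-week behavioral test; they keep both PET timepoints but have no
#'   post-2-week water-maze record.
#' @param calibration `"ratio"` or `"direct"` (see Details).
#' @param family `"normal"` (default) or `"lognormal"` distribution family
#'   for uptake draws (SUV-change draws are always normal since they can be
#'   negative).
#' @param region_distributions optional data frame in the layout of
#'   [pcas_calibration()] overriding the built-in calibration.
#' @param swim_time_distributions data frame with columns `group`, `median`,
#'   `iqr` for post-2-week swim times (seconds).
#' @param subject_effect shared-effect weight in `[0, 1)` for `"direct"`
#'   calibration.
#' @param noise_cv voxelwise noise coefficient of variation used when
#'   rendering scans.
#' @param psf_fwhm_mm scanner point-spread FWHM in mm (default 1.3, the
#'   motivating scanner's central spatial resolution).
#' @param dose_MBq mean and sd of injected dose in MBq.
#' @param weight_g mean and sd of body weight in grams.
#' @return An object of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec()
#' spec$n_good + spec$n_poor
#' @export
cohort_spec <- function(n_good = 8L, n_poor = 10L, n_dead = 3L,
                        calibration = c("ratio", "direct"),
                        family = c("normal", "lognormal"),
                        region_distributions = NULL,
                        swim_time_distributions = data.frame(
                          group = c("good", "poor"),
                          median = c(40, 90),
                          iqr = c(8, 30)),
                        subject_effect = 0.5,
                        noise_cv = 0.05,
                        psf_fwhm_mm = 1.3,
                        dose_MBq = c(9.5, 0.7),
                        weight_g = c(372.5, 23.68)) {
  calibration <- match.arg(calibration)
  family <- match.arg(family)
  n_good <- as.integer(n_good); n_poor <- as.integer(n_poor)
  n_dead <- as.integer(n_dead)
  if (n_good < 0 || n_poor < 0 || n_dead < 0)
    stop("cohort counts must be >= 0")
  if (n_dead > n_poor)
    stop("n_dead cannot exceed n_poor (deaths come from the poor-destined pool)")
  cal <- if (is.null(region_distributions)) pcas_calibration() else region_distributions
  need <- c("measure", "group", "region", "median", "q1", "q3")
  if (!all(need %in% names(cal)))
    stop("region_distributions must have columns: ", paste(need, collapse = ", "))
  if (any(cal$q3 <= cal$q1))
    stop("all calibration IQRs must be > 0")
  if (!all(c("group", "median", "iqr") %in% names(swim_time_distributions)))
    stop("swim_time_distributions needs columns group, median, iqr")
  if (subject_effect < 0 || subject_effect >= 1)
    stop("subject_effect must be in [0, 1)")
  .assert_number(noise_cv, "noise_cv"); if (noise_cv < 0) stop("noise_cv must be >= 0")
  .assert_number(psf_fwhm_mm, "psf_fwhm_mm"); if (psf_fwhm_mm < 0) stop("psf_fwhm_mm must be >= 0")
  structure(
    list(n_good = n_good, n_poor = n_poor, n_dead = n_dead,
         calibration = calibration, family = family,
         region_distributions = cal,
         swim_time_distributions = swim_time_distributions,
         behavior_baseline = list(time = c(median = 10.1, iqr = 11.6 - 8.1),
                                  distance = c(median = 202.9, iqr = 271.5 - 174.5)),
         behavior_distance_post2w = data.frame(
           group = c("good", "poor"), median = c(1300, 2400), iqr = c(500, 700)),
         subject_effect = subject_effect,
         noise_cv = noise_cv, psf_fwhm_mm = psf_fwhm_mm,
         dose_MBq = as.numeric(dose_MBq), weight_g = as.numeric(weight_g),
         uptake_interval_min = 60),
    class = "cohort_spec")
}

## Truncated-at-zero draws by rejection; errors after 100 rounds, naming the
## offending region.
.rtrunc_pos <- function(n, draw_fun, what) {
  x <- draw_fun(n)
  tries <- 0L
  while (any(bad <- x <= 0)) {
    tries <- tries + 1L
    if (tries > 100L)
      stop("could not draw a positive value for '", what,
           "' after 100 rejection attempts")
    x[bad] <- draw_fun(sum(bad))
  }
  x
}

.draw_uptake <- function(n, med, q1, q3, family, what) {
  if (family == "lognormal") {
    if (q1 <= 0)
      stop("lognormal family needs positive quartiles for '", what, "'")
    sdlog <- (log(q3) - log(q1)) / (stats::qnorm(0.75) - stats::qnorm(0.25))
    stats::rlnorm(n, meanlog = log(med), sdlog = sdlog)
  } else {
    sd <- .iqr_to_sd(q1, q3)
    .rtrunc_pos(n, function(m) stats::rnorm(m, med, sd), what)
  }
}

.cal_lookup <- function(cal, measure, group) {
  sub <- cal[cal$measure == measure & cal$group == group, ]
  if (!nrow(sub)) stop("no calibration rows for measure '", measure,
                       "', group '", group, "'")
  sub
}

#' Simulate a post-cardiac-arrest rat cohort
#'
#' Draws per-subject true regional SUV tables for the baseline and
#' post-3-hour timepoints, scan metadata (injected dose, body weight), and
#' behavioral water-maze records, for a two-outcome-group cohort calibrated
#' to published group distributions (see [cohort_spec()]). Dead subjects are
#' drawn from the poor-destined pool; they retain both PET timepoints but
#' have no post-2-week behavioral record. All draws are a pure function of
#' `spec` and `seed`.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return An object of class `pcas_cohort`: list with data frames
#'   `true_suv` (`subject_id`, `group`, `timepoint`, `region`, `suv`),
#'   `metadata` (`subject_id`, `timepoint`, `injected_dose_MBq`,
#'   `body_weight_g`, `uptake_interval_min`), `behavior` (`subject_id`,
#'   `survived`, baseline and post-2-week swim time/distance), and `groups`
#'   (`subject_id`, `true_group`, `dead`), plus the `spec` and `seed`.
#' @examples
#' coh <- sample_cohort(cohort_spec(), seed = 7)
#' table(coh$groups$true_group)
#' @export
sample_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_good + spec$n_poor
  if (n == 0L) stop("empty cohort")
  ids <- sprintf("R%02d", seq_len(n))
  group <- c(rep("good", spec$n_good), rep("poor", spec$n_poor))
  cal <- spec$region_distributions
  scheme_regions <- unique(cal$region[cal$measure == "suv"])
  analysis_regions <- setdiff(scheme_regions, whole_brain_region())

  with_seed(seed, {
    dead_ids <- if (spec$n_dead > 0)
      sample(ids[group == "poor"], spec$n_dead) else character()

    suv_rows <- vector("list", 2 * length(unique(group)))
    out <- list()
    for (g in unique(group)) {
      idx <- which(group == g)
      ng <- length(idx)
      post <- matrix(NA_real_, nrow = ng, ncol = length(analysis_regions) + 1L,
                     dimnames = list(ids[idx],
                                     c(analysis_regions, whole_brain_region())))
      if (spec$calibration == "ratio") {
        wb_cal <- .cal_lookup(cal, "suv", g)
        wb_cal <- wb_cal[wb_cal$region == whole_brain_region(), ]
        if (!nrow(wb_cal)) stop("ratio calibration needs a whole-brain SUV row")
        G <- .draw_uptake(ng, wb_cal$median, wb_cal$q1, wb_cal$q3,
                          spec$family, whole_brain_region())
        suvr_cal <- .cal_lookup(cal, "suvr", g)
        for (r in analysis_regions) {
          row <- suvr_cal[suvr_cal$region == r, ]
          if (!nrow(row)) stop("no SUVR calibration for region '", r, "'")
          post[, r] <- G * .draw_uptake(ng, row$median, row$q1, row$q3,
                                        spec$family, r)
        }
        post[, whole_brain_region()] <- G
      } else {
        z_subj <- stats::rnorm(ng)
        rho <- spec$subject_effect
        suv_cal <- .cal_lookup(cal, "suv", g)
        for (r in c(analysis_regions, whole_brain_region())) {
          row <- suv_cal[suv_cal$region == r, ]
          if (!nrow(row)) stop("no SUV calibration for region '", r, "'")
          sd_r <- .iqr_to_sd(row$q1, row$q3)
          ## rejection redraws touch only the independent component; the
          ## shared subject effect stays fixed
          x <- row$median + sd_r * (rho * z_subj + sqrt(1 - rho^2) * stats::rnorm(ng))
          tries <- 0L
          while (any(bad <- x <= 0)) {
            tries <- tries + 1L
            if (tries > 100L)
              stop("could not draw a positive value for '", r,
                   "' after 100 rejection attempts")
            x[bad] <- row$median + sd_r * (rho * z_subj[bad] +
                                             sqrt(1 - rho^2) * stats::rnorm(sum(bad)))
          }
          post[, r] <- x
        }
      }

      ## baseline = post-3-hour + SUV-change draw (reconstructed: no baseline
      ## group table is published)
      delta_cal <- .cal_lookup(cal, "delta", g)
      base <- post
      for (r in colnames(post)) {
        row <- delta_cal[delta_cal$region == r, ]
        if (!nrow(row)) stop("no SUV-change calibration for region '", r, "'")
        sd_r <- .iqr_to_sd(row$q1, row$q3)
        d <- stats::rnorm(ng, row$median, sd_r)
        b <- post[, r] + d
        tries <- 0L
        while (any(bad <- b <= 0)) {
          tries <- tries + 1L
          if (tries > 100L)
            stop("could not draw a positive baseline value for '", r,
                 "' after 100 rejection attempts")
          b[bad] <- post[bad, r] + stats::rnorm(sum(bad), row$median, sd_r)
        }
        base[, r] <- b
      }
      out[[g]] <- list(post = post, base = base, ids = ids[idx])
    }

    to_long <- function(mat, g, tp, sub_ids) {
      data.frame(subject_id = rep(sub_ids, times = ncol(mat)),
                 group = g, timepoint = tp,
                 region = rep(colnames(mat), each = nrow(mat)),
                 suv = as.vector(mat), stringsAsFactors = FALSE)
    }
    true_suv <- do.call(rbind, c(
      lapply(names(out), function(g)
        to_long(out[[g]]$base, g, "baseline", out[[g]]$ids)),
      lapply(names(out), function(g)
        to_long(out[[g]]$post, g, "post3h", out[[g]]$ids))))
    ord <- order(true_suv$subject_id, true_suv$timepoint, true_suv$region)
    true_suv <- true_suv[ord, ]
    rownames(true_suv) <- NULL

    ## scan metadata: one injection per scan, one body weight per subject
    weight <- .rtrunc_pos(n, function(m)
      stats::rnorm(m, spec$weight_g[1], spec$weight_g[2]), "body weight")
    metadata <- do.call(rbind, lapply(c("baseline", "post3h"), function(tp) {
      dose <- .rtrunc_pos(n, function(m)
        stats::rnorm(m, spec$dose_MBq[1], spec$dose_MBq[2]), "injected dose")
      data.frame(subject_id = ids, timepoint = tp,
                 injected_dose_MBq = dose, body_weight_g = weight,
                 uptake_interval_min = spec$uptake_interval_min,
                 stringsAsFactors = FALSE)
    }))
    rownames(metadata) <- NULL

    ## behavior: baseline for everyone, post-2-week for survivors only
    bl <- spec$behavior_baseline
    bl_time <- pmin(120, .rtrunc_pos(n, function(m)
      stats::rnorm(m, bl$time[["median"]], bl$time[["iqr"]] / 1.349), "baseline swim time"))
    bl_dist <- .rtrunc_pos(n, function(m)
      stats::rnorm(m, bl$distance[["median"]], bl$distance[["iqr"]] / 1.349),
      "baseline swim distance")
    p2_time <- rep(NA_real_, n); p2_dist <- rep(NA_real_, n)
    for (g in unique(group)) {
      alive <- which(group == g & !(ids %in% dead_ids))
      if (!length(alive)) next
      st <- spec$swim_time_distributions
      st <- st[st$group == g, ]
      p2_time[alive] <- pmin(120, .rtrunc_pos(length(alive), function(m)
        stats::rnorm(m, st$median, st$iqr / 1.349), paste(g, "swim time")))
      dd <- spec$behavior_distance_post2w
      dd <- dd[dd$group == g, ]
      p2_dist[alive] <- .rtrunc_pos(length(alive), function(m)
        stats::rnorm(m, dd$median, dd$iqr / 1.349), paste(g, "swim distance"))
    }
    behavior <- data.frame(subject_id = ids,
                           survived = !(ids %in% dead_ids),
                           baseline_swim_time_s = bl_time,
                           baseline_distance_cm = bl_dist,
                           post2w_swim_time_s = p2_time,
                           post2w_distance_cm = p2_dist,
                           stringsAsFactors = FALSE)
    groups <- data.frame(subject_id = ids, true_group = group,
                         dead = ids %in% dead_ids, stringsAsFactors = FALSE)

    structure(list(true_suv = true_suv, metadata = metadata,
                   behavior = behavior, groups = groups,
                   spec = spec, seed = as.integer(seed)),
              class = "pcas_cohort")
  })
}

#' @export
print.pcas_cohort <- function(x, ...) {
  g <- table(x$groups$true_group)
  cat("Synthetic PCAS cohort:", nrow(x$groups), "subjects (",
      paste(names(g), g, sep = " = ", collapse = ", "), "),",
      sum(x$groups$dead), "dead before follow-up\n")
  cat("  calibration:", x$spec$calibration, "| family:", x$spec$family,
      "| seed:", x$seed, "\n")
  invisible(x)
}
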