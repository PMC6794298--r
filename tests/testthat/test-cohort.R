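# Minimal two-region calibration used to exercise the sampler without the
# full 16-region scheme.
tiny_calibration <- function(wb_median = 5, bad_region = NULL) {
  rows <- function(measure, group, region, med, q1, q3)
    data.frame(measure = measure, group = group, region = region,
               median = med, q1 = q1, q3 = q3, stringsAsFactors = FALSE)
  reg <- c("a", "b")
  cal <- rbind(
    rows("suv", "good", c(reg, "whole brain"), c(4, 3, wb_median),
         c(3.5, 2.5, wb_median - 0.5), c(4.5, 3.5, wb_median + 0.5)),
    rows("suv", "poor", c(reg, "whole brain"), c(2, 2, 3),
         c(1.5, 1.5, 2.5), c(2.5, 2.5, 3.5)),
    rows("delta", "good", c(reg, "whole brain"), c(1, 1, 1),
         c(0.5, 0.5, 0.5), c(1.5, 1.5, 1.5)),
    rows("delta", "poor", c(reg, "whole brain"), c(2, 2, 2),
         c(1.5, 1.5, 1.5), c(2.5, 2.5, 2.5)),
    rows("suvr", "good", reg, c(1.2, 0.8), c(1.1, 0.7), c(1.3, 0.9)),
    rows("suvr", "poor", reg, c(0.9, 1.1), c(0.8, 1.0), c(1.0, 1.2)))
  if (!is.null(bad_region))
    cal$median[cal$measure == "suv" & cal$region == bad_region] <- -50
  cal
}

test_that("default cohort reproduces the study structure: 18 rats, 15 with follow-up", {
  coh <- sample_cohort(cohort_spec(), seed = 1)
  expect_equal(nrow(coh$groups), 18L)
  expect_equal(sum(coh$groups$true_group == "good"), 8L)
  expect_equal(sum(coh$groups$true_group == "poor"), 10L)
  expect_equal(sum(coh$groups$dead), 3L)
  # dead subjects come from the poor-destined pool and lack follow-up behavior
  expect_true(all(coh$groups$true_group[coh$groups$dead] == "poor"))
  expect_equal(sum(!is.na(coh$behavior$post2w_swim_time_s)), 15L)
  expect_identical(is.na(coh$behavior$post2w_swim_time_s),
                   !coh$behavior$survived)
  # both timepoints present for everyone (deaths occurred after imaging)
  tp <- table(coh$true_suv$subject_id, coh$true_suv$timepoint)
  expect_true(all(tp == 17L))   # 16 analysis regions + whole brain
  expect_true(all(coh$true_suv$suv > 0))
  # swim times respect the 120 s trial cap
  expect_true(all(coh$behavior$post2w_swim_time_s <= 120, na.rm = TRUE))
})

test_that("degenerate group sizes behave", {
  coh <- sample_cohort(cohort_spec(n_good = 0, n_poor = 5, n_dead = 0),
                       seed = 2)
  expect_true(all(coh$groups$true_group == "poor"))
  expect_error(cohort_spec(n_dead = 11), "n_dead")
  expect_error(cohort_spec(n_good = -1), ">= 0")
})

test_that("cohort sampling is a pure function of spec and seed", {
  c1 <- sample_cohort(cohort_spec(), seed = 99)
  c2 <- sample_cohort(cohort_spec(), seed = 99)
  expect_identical(c1$true_suv, c2$true_suv)
  expect_identical(c1$behavior, c2$behavior)
  expect_identical(c1$metadata, c2$metadata)
  c3 <- sample_cohort(cohort_spec(), seed = 100)
  expect_false(identical(c1$true_suv$suv, c3$true_suv$suv))
})

test_that("impossible positive draws error naming the region", {
  spec <- cohort_spec(region_distributions = tiny_calibration(wb_median = -50))
  expect_error(sample_cohort(spec, seed = 1), "whole brain")
  spec2 <- cohort_spec(calibration = "direct",
                       region_distributions = tiny_calibration(bad_region = "b"))
  expect_error(sample_cohort(spec2, seed = 1), "'b'")
})

test_that("ratio calibration preserves the whole-brain identity and FHR signal", {
  coh <- sample_cohort(cohort_spec(), seed = 5)
  post <- coh$true_suv[coh$true_suv$timepoint == "post3h", ]
  sch <- region_scheme()
  fhrs <- vapply(split(post, post$subject_id), function(d) {
    fhr(stats::setNames(d$suv, d$region), sch)
  }, numeric(1))
  g <- coh$groups$true_group[match(names(fhrs), coh$groups$subject_id)]
  expect_gt(mean(fhrs[g == "good"]), mean(fhrs[g == "poor"]))
})

test_that("lognormal family draws positive values with the programmed median", {
  spec <- cohort_spec(family = "lognormal", n_good = 60, n_poor = 0, n_dead = 0)
  coh <- sample_cohort(spec, seed = 8)
  wb <- coh$true_suv[coh$true_suv$region == "whole brain" &
                       coh$true_suv$timepoint == "post3h", "suv"]
  expect_true(all(wb > 0))
  expect_equal(median(wb), 5.94, tolerance = 0.15)
})
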