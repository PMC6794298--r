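mk_uptake <- function(vals, wb, id = "r1", tp = "post3h",
                      sch = region_scheme()) {
  regional_uptake(id, tp, vals, wb, sch)
}

test_that("SUV change is baseline minus post, increases allowed, conservation holds", {
  sch <- region_scheme()
  set.seed(11)
  post_v <- make_uptake_vec(sch)
  base_v <- post_v + stats::rnorm(length(post_v), 1, 0.5)
  base_v <- pmax(base_v, 0.1)
  base <- mk_uptake(base_v, 6, tp = "baseline")
  post <- mk_uptake(post_v, 4)
  d <- suv_delta(base, post)
  expect_equal(d[["whole brain"]], 2)
  expect_equal(d[sch$analysis_regions],
               (base_v - post_v)[sch$analysis_regions])
  # conservation: delta + post reconstructs baseline exactly
  expect_equal(d[sch$analysis_regions] + post_v[sch$analysis_regions],
               base_v[sch$analysis_regions])
  # identical timepoints give all zeros; decreasing baseline gives negatives
  expect_true(all(suv_delta(mk_uptake(post_v, 4, tp = "baseline"), post) == 0))
  lower <- mk_uptake(post_v * 0.9, 3.6, tp = "baseline")
  expect_true(all(suv_delta(lower, post) < 0))
  # mismatched subjects are rejected
  other <- mk_uptake(base_v, 6, id = "r2", tp = "baseline")
  expect_error(suv_delta(other, post), "different subjects")
})

test_that("SUVR divides by whole brain, is 1 for whole brain, and is scale invariant", {
  sch <- region_scheme()
  vals <- stats::setNames(rep(3, 16), sch$analysis_regions)
  u <- mk_uptake(vals, 6)
  r <- suvr(u)
  expect_equal(unname(r[sch$analysis_regions[1]]), 0.5)
  expect_identical(unname(r[["whole brain"]]), 1)
  set.seed(12)
  vals2 <- make_uptake_vec(sch)
  u1 <- mk_uptake(vals2, 5.2)
  uk <- mk_uptake(vals2 * 7, 5.2 * 7)
  expect_equal(suvr(u1), suvr(uk), tolerance = 1e-12)
})

test_that("FHR is the forebrain mean over the hindbrain mean", {
  sch <- region_scheme()
  # all regions equal -> 1
  eq <- stats::setNames(rep(2.5, 16), sch$analysis_regions)
  expect_equal(fhr(eq, sch), 1)
  # published group-level SUVR medians: (13.90/13) / (0.79) for good outcome
  cal <- pcas_calibration("suvr")
  g <- stats::setNames(cal$median[cal$group == "good"],
                       cal$region[cal$group == "good"])
  expect_equal(fhr(g, sch),
               mean(g[sch$forebrain]) / mean(g[sch$hindbrain]))
  expect_equal(fhr(g, sch), 1.3535, tolerance = 1e-4)
  p <- stats::setNames(cal$median[cal$group == "poor"],
                       cal$region[cal$group == "poor"])
  expect_equal(fhr(p, sch), 0.9134, tolerance = 1e-4)
  # homogeneity: scaling the forebrain by k scales FHR by k
  sc <- g
  sc[sch$forebrain] <- sc[sch$forebrain] * 3
  expect_equal(fhr(sc, sch), 3 * fhr(g, sch), tolerance = 1e-12)
  expect_error(fhr(g[-1], sch), "missing region")
})

test_that("FHR of an SUV table equals FHR of the SUVR table (normalization cancels)", {
  sch <- region_scheme()
  set.seed(13)
  for (i in 1:20) {
    vals <- make_uptake_vec(sch)
    wb <- stats::runif(1, 2, 8)
    u <- mk_uptake(vals, wb)
    r <- suvr(u)
    expect_equal(fhr(u), fhr(r[sch$analysis_regions], sch),
                 tolerance = 1e-12)
  }
})

test_that("derive_indices produces tidy per-subject tables", {
  coh <- sample_cohort(cohort_spec(n_good = 2, n_poor = 2, n_dead = 0),
                       seed = 3)
  idx <- derive_indices(coh$true_suv, region_scheme())
  expect_equal(nrow(idx$fhr), 4 * 2)           # 4 subjects x 2 timepoints
  expect_equal(nrow(idx$suv_delta), 4 * 17)    # 16 regions + whole brain
  expect_true(all(idx$suvr$value[idx$suvr$region == "whole brain"] == 1))
  # conservation at table level: baseline = post3h + delta
  base <- coh$true_suv[coh$true_suv$timepoint == "baseline", ]
  post <- coh$true_suv[coh$true_suv$timepoint == "post3h", ]
  key <- function(d) paste(d$subject_id, d$region)
  m <- match(key(idx$suv_delta), key(post))
  expect_equal(idx$suv_delta$value + post$suv[m],
               base$suv[match(key(idx$suv_delta), key(base))],
               tolerance = 1e-12)
})
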