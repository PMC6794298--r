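# A hand-built two-label "atlas" for arithmetic checks.
toy_atlas <- function() {
  labels <- array(0L, c(4, 4, 2))
  labels[1, 1, 1] <- 1L; labels[2, 1, 1] <- 1L
  labels[3:4, 3:4, ] <- 2L
  structure(list(labels = labels, spacing_mm = c(1, 1, 1),
                 lookup = data.frame(
                   label = 1:2, region = c("roi", "whole brain (rest)"),
                   hemisphere = "midline",
                   merge_group = c("roi", "whole brain"),
                   stringsAsFactors = FALSE)),
            class = "label_atlas")
}

test_that("SUV conversion follows dose-per-weight scaling", {
  meta <- list(injected_dose_MBq = 9.5, body_weight_g = 372.5)
  v <- volume_grid(array(9500 / 372.5, c(2, 2, 2)))
  s <- compute_suv_volume(v, meta)
  expect_equal(as.vector(s$voxels), rep(1, 8), tolerance = 1e-12)
  expect_identical(s$value_kind, "suv")
  # all-zero volume stays zero; doubling dose halves every SUV
  z <- compute_suv_volume(volume_grid(array(0, c(2, 2, 2))), meta)
  expect_true(all(z$voxels == 0))
  s2 <- compute_suv_volume(v, list(injected_dose_MBq = 19, body_weight_g = 372.5))
  expect_equal(as.vector(s2$voxels), rep(0.5, 8), tolerance = 1e-12)
  expect_error(compute_suv_volume(v, list(injected_dose_MBq = 0,
                                          body_weight_g = 372.5)), "> 0")
  expect_error(compute_suv_volume(s, meta), "already SUV")
})

test_that("rendered concentration equals SUV times dose over weight", {
  atl <- toy_atlas()
  meta <- list(injected_dose_MBq = 9.5, body_weight_g = 372.5)
  vol <- render_scan(c("roi" = 1, "whole brain" = 1), atl, meta,
                     noise_cv = 0, psf_fwhm_mm = 0)
  inside <- vol$voxels[atl$labels == 1L]
  expect_equal(unique(inside), 9500 / 372.5, tolerance = 1e-12)  # 25.5034 kBq/ml
  expect_true(all(vol$voxels[atl$labels == 0L] == 0))
  expect_error(render_scan(c("roi" = 1), atl, meta, 0, 0), "whole brain")
})

test_that("render is deterministic under a seed and noise perturbs around truth", {
  atl <- build_atlas(seed = 2)
  groups <- unique(atl$lookup$merge_group)
  tv <- stats::setNames(seq(2, 6, length.out = length(groups)), groups)
  meta <- list(injected_dose_MBq = 9.5, body_weight_g = 372.5)
  v1 <- render_scan(tv, atl, meta, noise_cv = 0.05, psf_fwhm_mm = 1.3, seed = 7)
  v2 <- render_scan(tv, atl, meta, noise_cv = 0.05, psf_fwhm_mm = 1.3, seed = 7)
  expect_identical(v1$voxels, v2$voxels)
  v3 <- render_scan(tv, atl, meta, noise_cv = 0.05, psf_fwhm_mm = 1.3, seed = 8)
  expect_false(identical(v1$voxels, v3$voxels))
})

test_that("per-label means are unweighted voxel means; absent labels are absent", {
  atl <- toy_atlas()
  vox <- array(0, c(4, 4, 2))
  vox[1, 1, 1] <- 2; vox[2, 1, 1] <- 4   # label 1: mean 3
  vox[3:4, 3:4, ] <- 7
  s <- volume_grid(vox, c(1, 1, 1), "suv")
  m <- extract_regional_means(s, atl)
  expect_equal(m[["1"]], 3)
  expect_equal(m[["2"]], 7)
  # uniform volume: every label mean equals the constant
  u <- extract_regional_means(volume_grid(array(5, c(4, 4, 2)), c(1, 1, 1),
                                          "suv"), atl)
  expect_true(all(u == 5))
  # a label with no voxels is reported absent, not zero
  atl2 <- toy_atlas()
  atl2$lookup <- rbind(atl2$lookup,
                       data.frame(label = 3L, region = "ghost",
                                  hemisphere = "midline", merge_group = "ghost"))
  expect_false("3" %in% names(extract_regional_means(s, atl2)))
  # grid mismatch is an error
  bad <- volume_grid(array(1, c(3, 3, 2)), c(1, 1, 1), "suv")
  expect_error(extract_regional_means(bad, atl), "differ")
})

test_that("pairing averages hemispheres and merging averages subregions", {
  labels <- array(0L, c(6, 2, 1))
  labels[1:6, 1, 1] <- 1:6
  lookup <- data.frame(
    label = 1:6,
    region = c("motor cortex", "motor cortex", "hippocampus (a)",
               "hippocampus (b)", "pons", "whole brain (rest)"),
    hemisphere = c("left", "right", "left", "left", "midline", "midline"),
    merge_group = c("motor cortex", "motor cortex", "hippocampus",
                    "hippocampus", "pons", "whole brain"),
    stringsAsFactors = FALSE)
  atl <- structure(list(labels = labels, spacing_mm = c(1, 1, 1),
                        lookup = lookup), class = "label_atlas")
  raw <- c("1" = 4, "2" = 6, "3" = 3, "4" = 3, "5" = 2.5, "6" = 5)
  sch <- region_scheme(analysis_regions = c("motor cortex", "hippocampus", "pons"),
                       forebrain = c("motor cortex", "hippocampus"),
                       hindbrain = "pons")
  u <- merge_and_pair(raw, atl, sch)
  expect_equal(u$suv_by_region[["motor cortex"]], 5)      # (4 + 6) / 2
  expect_equal(u$suv_by_region[["hippocampus"]], 3)       # merged subregions
  expect_equal(u$suv_by_region[["pons"]], 2.5)            # single label unchanged
  expect_equal(u$whole_brain_suv, 5)
  expect_error(merge_and_pair(raw[-3], atl, sch), "hippocampus")
})

test_that("noise-free render/quantify round trip is exact and scale-equivariant", {
  sch <- region_scheme()
  atl <- build_atlas(sch, seed = 4)
  meta <- list(injected_dose_MBq = 8.7, body_weight_g = 401.2)
  set.seed(31)
  tv <- c(make_uptake_vec(sch), stats::setNames(stats::runif(1, 2, 8),
                                                whole_brain_region()))
  vol <- render_scan(tv, atl, meta, noise_cv = 0, psf_fwhm_mm = 0)
  u <- quantify_scan(vol, atl, meta, sch)
  rec <- c(u$suv_by_region, stats::setNames(u$whole_brain_suv,
                                            whole_brain_region()))
  expect_equal(rec, tv[names(rec)], tolerance = 1e-11)
  # multiplying the activity volume by k multiplies every regional SUV by k
  vol2 <- volume_grid(vol$voxels * 3, vol$spacing_mm, "concentration")
  u2 <- quantify_scan(vol2, atl, meta, sch)
  expect_equal(as.numeric(u2$suv_by_region), 3 * as.numeric(u$suv_by_region),
               tolerance = 1e-11)
})

test_that("partial-volume bias shrinks as the region grows (nested spheres)", {
  # single hot sphere of increasing radius inside a warm background
  bias_for_radius <- function(rad) {
    n <- 48L
    labels <- array(0L, c(n, n, n))
    ctr <- (n + 1) / 2
    d2 <- outer(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`),
                (seq_len(n) - ctr)^2, `+`)
    labels[d2 <= rad^2] <- 1L
    labels[labels == 0L] <- 2L
    atl <- structure(list(labels = labels, spacing_mm = c(1, 1, 1),
                          lookup = data.frame(
                            label = 1:2, region = c("sphere", "rest"),
                            hemisphere = "midline",
                            merge_group = c("sphere", "whole brain"),
                            stringsAsFactors = FALSE)),
                     class = "label_atlas")
    meta <- list(injected_dose_MBq = 10, body_weight_g = 400)
    vol <- render_scan(c("sphere" = 2, "whole brain" = 1), atl, meta,
                       noise_cv = 0, psf_fwhm_mm = 3)
    m <- extract_regional_means(compute_suv_volume(vol, meta), atl)
    abs(m[["1"]] - 2)
  }
  biases <- vapply(c(3, 6, 12), bias_for_radius, numeric(1))
  expect_true(all(diff(biases) < 0))
})
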