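test_that("Mann-Whitney: worked examples and conventions", {
  m <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(m$statistic, 0)                 # first sample entirely below
  expect_equal(m$p_two_sided, 0.1)             # 2/20 labelings as extreme
  expect_identical(m$method, "exact")
  # complete overlap with ties: U = n1*n2/2, p = 1
  m2 <- mann_whitney(c(1, 2), c(1, 2))
  expect_equal(m2$statistic, 2)
  expect_equal(m2$p_two_sided, 1)
  expect_error(mann_whitney(numeric(), 1:3), "nonempty")
  expect_error(mann_whitney(c(1, 1, 2), c(1, 3), method = "exact"), "ties")
})

test_that("exact Mann-Whitney agrees with enumeration and with wilcox.test", {
  set.seed(21)
  for (i in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(seq_len(50), n1 + n2)      # distinct values: no ties
    a <- x[seq_len(n1)]; b <- x[-seq_len(n1)]
    p <- mann_whitney(a, b, method = "exact")$p_two_sided
    expect_equal(p, enum_mw_p(a, b), tolerance = 1e-12)
    expect_equal(p, stats::wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("exact Mann-Whitney matches seeded permutation within Monte-Carlo error", {
  set.seed(22)
  for (i in 1:5) {
    a <- stats::rnorm(6); b <- stats::rnorm(6, 0.8)
    p_exact <- mann_whitney(a, b, method = "exact")$p_two_sided
    p_perm <- mann_whitney(a, b, method = "permutation",
                           n_perm = 20000, seed = i)$p_two_sided
    tail <- p_exact / 2
    se <- 2 * sqrt(tail * (1 - tail) / 20000)
    expect_lt(abs(p_perm - p_exact), 3 * se + 2 / 20001)
  }
})

test_that("Wilcoxon signed rank: worked examples and conventions", {
  w <- wilcoxon_signed_rank(c(1, 2, 3), c(2, 4, 6))   # diffs -1, -2, -3
  expect_equal(w$statistic, 0)
  expect_equal(w$p_two_sided, 0.25)                   # 2/8 sign patterns
  expect_identical(w$method, "exact")
  # symmetric tied magnitudes: p = 1
  w2 <- wilcoxon_signed_rank(c(2, 1), c(1, 2))
  expect_equal(w2$p_two_sided, 1)
  expect_error(wilcoxon_signed_rank(c(1, 2), c(1, 2)), "undefined")
  expect_error(wilcoxon_signed_rank(1:3, 1:2), "equal length")
})

test_that("exact signed-rank agrees with sign-pattern enumeration and wilcox.test", {
  set.seed(23)
  for (i in 1:25) {
    n <- sample(3:9, 1)
    d <- sample(seq_len(40), n) * sample(c(-1, 1), n, replace = TRUE)
    before <- stats::runif(n, 10, 20)
    after <- before - d
    p <- wilcoxon_signed_rank(before, after, method = "exact")$p_two_sided
    expect_equal(p, enum_wsr_p(d), tolerance = 1e-12)
    expect_equal(p, stats::wilcox.test(before, after, paired = TRUE,
                                       exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("paired whole-brain decline is detected in nearly every seeded cohort", {
  # the simulator programs a global post-insult metabolic decrease; the
  # paired test on 15 survivors should reject at 0.05 almost always
  sig <- 0L
  for (s in 1:100) {
    coh <- sample_cohort(cohort_spec(), seed = s)
    wb <- coh$true_suv[coh$true_suv$region == "whole brain", ]
    surv <- coh$behavior$subject_id[coh$behavior$survived]
    b <- wb$suv[wb$timepoint == "baseline"][match(surv, wb$subject_id[wb$timepoint == "baseline"])]
    a <- wb$suv[wb$timepoint == "post3h"][match(surv, wb$subject_id[wb$timepoint == "post3h"])]
    p <- wilcoxon_signed_rank(b, a)$p_two_sided
    if (p < 0.05) sig <- sig + 1L
  }
  expect_gte(sig, 95L)
})

test_that("median and quartiles use linear interpolation and resist outliers", {
  s <- median_iqr(c(1, 2, 3, 4, 5))
  expect_equal(c(s$median, s$q1, s$q3), c(3, 2, 4))
  s1 <- median_iqr(7)
  expect_equal(c(s1$median, s1$q1, s1$q3), c(7, 7, 7))
  expect_equal(median_iqr(c(1, 1, 1, 9))$median, 1)
  expect_match(s$convention, "interpolation")
  expect_error(median_iqr(numeric()), "nonempty")
})
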