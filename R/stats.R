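#' Median and interquartile range
#'
#' Summary convention used throughout: median with first and third quartiles
#' computed by linear interpolation (R quantile type 7). The convention name
#' is recorded in the output for auditability.
#'
#' @param x nonempty numeric vector.
#' @return List with `median`, `q1`, `q3`, `n`, `convention`.
#' @examples
#' median_iqr(c(1, 2, 3, 4, 5))  # 3 (2-4)
#' @export
median_iqr <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("median_iqr needs a nonempty sample")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3], n = length(x),
       convention = "linear interpolation (R type 7)")
}

.tie_counts <- function(r) {
  tab <- table(r)
  as.numeric(tab[tab > 1])
}

.two_sided <- function(p_low, p_high) min(1, 2 * min(p_low, p_high))

#' Mann-Whitney U test
#'
#' Two-sample rank-sum test for independent groups. The U statistic is
#' computed with mid-ranks for ties and refers to the first sample
#' (`U = R1 - n1(n1+1)/2`, in `[0, n1*n2]`). The two-sided p-value is twice
#' the smaller one-sided tail, capped at 1. Methods:
#'
#' * `"exact"`: exact null distribution over all `choose(n1+n2, n1)`
#'   labelings (via the exact Wilcoxon distribution); valid only without
#'   ties. Selected automatically when `n1 + n2 <= 16` and no ties.
#' * `"normal"`: tie-corrected normal approximation with continuity
#'   correction.
#' * `"permutation"`: seeded Monte-Carlo relabeling.
#'
#' @param a,b numeric samples.
#' @param method `"auto"`, `"exact"`, `"normal"`, or `"permutation"`.
#' @param n_perm number of permutations for the permutation method.
#' @param seed seed for the permutation method.
#' @return A `group_comparison` list: `statistic_name`, `statistic` (U),
#'   `p_two_sided`, `group_summaries`, `method`, `conventions`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_two_sided  # 0.1
#' @export
mann_whitney <- function(a, b, method = c("auto", "exact", "normal",
                                          "permutation"),
                         n_perm = 10000L, seed = 1L) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(a, b)) > 0L
  if (method == "auto")
    method <- if (!has_ties && N <= 16L) "exact" else "normal"
  if (method == "exact") {
    if (has_ties)
      stop("exact method is undefined with ties; use 'normal' or 'permutation'")
    p_low <- stats::pwilcox(U, n1, n2)
    p_high <- 1 - stats::pwilcox(U - 1, n1, n2)
    p <- .two_sided(p_low, p_high)
  } else if (method == "normal") {
    mu <- n1 * n2 / 2
    ties <- .tie_counts(r)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) stop("degenerate samples: all values identical")
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    if (U == mu) z <- 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  } else {
    p <- with_seed(seed, {
      u_perm <- vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(N, n1)
        sum(r[idx]) - n1 * (n1 + 1) / 2
      }, numeric(1))
      p_low <- (1 + sum(u_perm <= U)) / (n_perm + 1)
      p_high <- (1 + sum(u_perm >= U)) / (n_perm + 1)
      .two_sided(p_low, p_high)
    })
  }
  structure(list(
    statistic_name = "MannWhitneyU", statistic = U, p_two_sided = p,
    group_summaries = list(a = median_iqr(a), b = median_iqr(b)),
    method = switch(method, exact = "exact",
                    normal = "tie-corrected-normal", "permutation"),
    conventions = c("mid-ranks for ties",
                    "two-sided p = 2 x one-sided tail, capped at 1")),
    class = "group_comparison")
}

#' Wilcoxon signed-rank test
#'
#' Paired-sample test. Zero differences are dropped (Wilcoxon convention);
#' the reported statistic is the smaller of the positive and negative
#' signed-rank sums. Exact enumeration of the `2^n` sign patterns (via the
#' exact signed-rank distribution) is used when `n <= 14` and the absolute
#' differences are untied; otherwise a tie-corrected normal approximation
#' with continuity correction, or a seeded sign-flip permutation.
#'
#' @param before,after equal-length numeric vectors of paired observations.
#' @inheritParams mann_whitney
#' @return A `group_comparison` list with `statistic_name = "WilcoxonW"`.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3), c(2, 4, 6))$p_two_sided  # 0.25
#' @export
wilcoxon_signed_rank <- function(before, after,
                                 method = c("auto", "exact", "normal",
                                            "permutation"),
                                 n_perm = 10000L, seed = 1L) {
  method <- match.arg(method)
  before <- as.numeric(before); after <- as.numeric(after)
  if (length(before) != length(after))
    stop("paired samples must have equal length")
  d <- before - after
  d <- d[d != 0]
  n <- length(d)
  if (!n) stop("all differences are zero; the signed-rank test is undefined")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  W <- min(w_plus, w_minus)
  has_ties <- anyDuplicated(abs(d)) > 0L
  if (method == "auto")
    method <- if (!has_ties && n <= 14L) "exact" else "normal"
  if (method == "exact") {
    if (has_ties)
      stop("exact method is undefined with tied magnitudes; use 'normal' or 'permutation'")
    p_low <- stats::psignrank(w_plus, n)
    p_high <- 1 - stats::psignrank(w_plus - 1, n)
    p <- .two_sided(p_low, p_high)
  } else if (method == "normal") {
    mu <- n * (n + 1) / 4
    ties <- .tie_counts(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    if (sigma2 <= 0) stop("degenerate differences: zero variance")
    z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sqrt(sigma2)
    if (w_plus == mu) z <- 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  } else {
    p <- with_seed(seed, {
      w_perm <- vapply(seq_len(n_perm), function(i) {
        sum(r[stats::runif(n) < 0.5])
      }, numeric(1))
      p_low <- (1 + sum(w_perm <= w_plus)) / (n_perm + 1)
      p_high <- (1 + sum(w_perm >= w_plus)) / (n_perm + 1)
      .two_sided(p_low, p_high)
    })
  }
  structure(list(
    statistic_name = "WilcoxonW", statistic = W, p_two_sided = p,
    group_summaries = list(before = median_iqr(before),
                           after = median_iqr(after)),
    method = switch(method, exact = "exact",
                    normal = "tie-corrected-normal", "permutation"),
    conventions = c("zero differences dropped", "mid-ranks for tied magnitudes",
                    "two-sided p = 2 x one-sided tail, capped at 1")),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(x$statistic_name, "=", format(x$statistic, digits = 4),
      ", p =", format(x$p_two_sided, digits = 4),
      " (", x$method, ")\n", sep = "")
  for (nm in names(x$group_summaries)) {
    s <- x$group_summaries[[nm]]
    cat("  ", nm, ": median ", format(s$median, digits = 4), " (",
        format(s$q1, digits = 4), "-", format(s$q3, digits = 4),
        "), n = ", s$n, "\n", sep = "")
  }
  invisible(x)
}
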