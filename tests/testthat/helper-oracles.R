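# Independent brute-force oracles used to validate the analytic
# implementations. These deliberately enumerate rather than reuse any
# closed-form distribution function.

# Exact two-sided Mann-Whitney p by enumerating all C(n1+n2, n1) labelings.
enum_mw_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  vals <- c(a, b)
  r <- rank(vals)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_low <- mean(u_all <= u_obs)
  p_high <- mean(u_all >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# Exact two-sided signed-rank p by enumerating all 2^n sign patterns.
enum_wsr_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_low <- mean(w_all <= w_obs)
  p_high <- mean(w_all >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

# AUC through the rank-sum identity: U (mid-ranks, positive group first)
# divided by n_pos * n_neg.
auc_via_u <- function(scores, labels, positive = "good") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  r <- rank(c(pos, neg))
  u <- sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2
  u / (length(pos) * length(neg))
}

# Exhaustive Youden scan over every candidate threshold (all midpoints and
# sentinels), ties broken toward the largest cutoff.
brute_youden <- function(scores, labels, positive = "good") {
  s <- sort(unique(scores))
  cand <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  j <- vapply(cand, function(t) {
    sens <- mean(scores[labels == positive] >= t)
    spec <- mean(scores[labels != positive] < t)
    sens + spec - 1
  }, numeric(1))
  best <- max(j)
  list(cutoff = max(cand[j == best]), j = best)
}

# Small tidy uptake table for a single subject/timepoint pair.
make_uptake_vec <- function(scheme, lo = 1, hi = 6) {
  stats::setNames(stats::runif(length(scheme$analysis_regions), lo, hi),
                  scheme$analysis_regions)
}
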