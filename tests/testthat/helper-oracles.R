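# Independent oracles used to cross-check the package's statistics.

# Two-sided Fisher p by explicit hypergeometric enumeration over all tables
# with the observed margins (probability-at-most-observed definition).
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  lo <- max(0, r1 + c1 - n)
  hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Two-sided exact rank-sum p by complete subset enumeration (tiny n only).
mann_whitney_oracle <- function(x, y) {
  m <- length(x)
  n <- m + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(m)])
  subsets <- utils::combn(n, m)
  w_all <- apply(subsets, 2, function(idx) sum(r[idx]))
  lower <- mean(w_all <= w_obs + 1e-9)
  upper <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

# Youden-optimal threshold by direct recount at every candidate threshold.
roc_oracle_threshold <- function(scores, labels) {
  sorted <- sort(unique(scores))
  thr <- c(-Inf,
           if (length(sorted) > 1) (sorted[-1] + sorted[-length(sorted)]) / 2,
           Inf)
  youden <- vapply(thr, function(t) {
    sens <- sum(scores >= t & labels) / sum(labels)
    spec <- sum(scores < t & !labels) / sum(!labels)
    sens + spec - 1
  }, numeric(1))
  min(thr[youden >= max(youden) - 1e-12])
}
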