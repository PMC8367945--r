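# Independent brute-force oracles used to pin down the statistical
# operations. These deliberately avoid the code paths they check.

# Exhaustive enumeration of every window of length 3, 4, 5 on a read.
oracle_classify <- function(states) {
  n <- length(states)
  if (n < 3) {
    return("ineligible")
  }
  for (w in 3:5) {
    if (w > n) next
    for (s in 1:(n - w + 1)) {
      if (sum(states[s:(s + w - 1)]) >= 3) {
        return("co_methylated")
      }
    }
  }
  "background"
}

# Exact two-sided rank-sum p-value by enumerating all C(m+n, m) group
# assignments of the joint ranks (no ties assumed).
oracle_ranksum_p <- function(a, b) {
  m <- length(a)
  r <- rank(c(a, b))
  obs <- sum(r[seq_len(m)])
  mu <- m * (m + length(b) + 1) / 2
  combs <- utils::combn(m + length(b), m)
  sums <- colSums(matrix(r[combs], nrow = m))
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# Literal step-up Benjamini-Hochberg: q_i = min over thresholds t >= p_i of
# t * m / #(p <= t), clipped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    cand <- p[p >= pi - 1e-15]
    min(1, min(vapply(cand, function(t) t * m / sum(p <= t + 1e-15), numeric(1))))
  }, numeric(1))
}

# AUROC by counting concordant case/control pairs (ties worth 1/2).
oracle_auc <- function(scores, is_pos) {
  pos <- scores[is_pos]
  neg <- scores[!is_pos]
  total <- 0
  for (sp in pos) {
    total <- total + sum(sp > neg) + 0.5 * sum(sp == neg)
  }
  total / (length(pos) * length(neg))
}

# One-way ANOVA F from explicit sums of squares.
oracle_anova_f <- function(groups) {
  v <- unlist(groups)
  k <- length(groups)
  n <- length(v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - mean(v))^2, numeric(1)))
  ssw <- sum(unlist(lapply(groups, function(g) (g - mean(g))^2)))
  (ssb / (k - 1)) / (ssw / (n - k))
}

random_read <- function(max_len = 20L, p = 0.4) {
  stats::rbinom(sample(1:max_len, 1), 1L, p)
}
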