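# Independent brute-force oracles used to freeze expected values. These are
# deliberately naive and share no code with the package implementation.

# Exhaustive label-permutation null of the related-vs-unrelated rank sum:
# p = fraction of the choose(n, m) label assignments whose related rank sum
# is at most the observed one.
oracle_perm_wilcox_p <- function(d_related, d_unrelated) {
  pooled <- c(d_related, d_unrelated)
  r <- rank(pooled)
  m <- length(d_related)
  obs <- sum(r[seq_len(m)])
  combos <- utils::combn(length(pooled), m)
  stats_all <- apply(combos, 2, function(ix) sum(r[ix]))
  mean(stats_all <= obs)
}

# Partial Pearson correlation via linear-model residuals (independent of the
# closed-form implementation in the package).
oracle_partial_cor <- function(v, b, cc) {
  stats::cor(stats::resid(stats::lm(v ~ cc)), stats::resid(stats::lm(b ~ cc)))
}

# Exhaustive partial-Mantel null over all n! simultaneous row/column
# permutations of M_v; one-sided p for positive association.
oracle_partial_mantel_p <- function(M_v, M_b, C) {
  n <- nrow(M_v)
  ut <- upper.tri(M_v)
  b <- M_b[ut]; cc <- C[ut]
  perms <- gtools_permutations(n)
  r_all <- apply(perms, 1, function(p) {
    Mp <- M_v[p, p]
    oracle_partial_cor(Mp[ut], b, cc)
  })
  r_obs <- oracle_partial_cor(M_v[ut], b, cc)
  mean(r_all >= r_obs - 1e-12)
}

# All permutations of 1..n as rows (tiny n), written independently of the
# package's generator.
gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(first) {
    rest <- sub + (sub >= first)
    cbind(first, rest, deparse.level = 0)
  }))
}

# One-sided hypergeometric tail P(X >= a) for a 2x2 table with margins fixed,
# a = successes in group 1 of size n1, total successes k, total n.
oracle_fisher_tail <- function(a, n1, k, n) {
  sum(stats::dhyper(a:min(n1, k), k, n - k, n1))
}

# Random symmetric 0/1 matrix with zero diagonal.
random_binary_sym <- function(n, p = 0.5) {
  M <- matrix(0L, n, n)
  M[upper.tri(M)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  M + t(M)
}
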