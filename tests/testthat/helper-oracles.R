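# Independent brute-force oracles and small fixture builders. These are
# deliberately naive (pairwise counting, exhaustive enumeration) and share
# no code with the implementation paths they check.

# O(N^2) pairwise-comparison percentile oracle: midrank_i =
# #(x_j < x_i) + (#(x_j == x_i) + 1) / 2, percentile = midrank / N.
oracle_percentiles <- function(means) {
  n <- length(means)
  vapply(seq_len(n), function(i) {
    less <- sum(means < means[i])
    eq <- sum(means == means[i])
    (less + (eq + 1) / 2) / n
  }, numeric(1L))
}

# Midranks by pairwise counting (used inside the test oracles only).
oracle_midranks <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1L))
}

# Exhaustive signed-rank two-sided p: every sign vector enumerated via
# expand.grid; zeros dropped; two-sided p doubles the smaller tail, cap 1.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1.0)
  r <- oracle_midranks(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  tol <- 1e-9
  min(1, 2 * min(mean(w_all <= w_obs + tol), mean(w_all >= w_obs - tol)))
}

# Exhaustive Mann-Whitney two-sided p over all C(n+m, n) labelings of the
# pooled values; U computed by direct pair counting, not via rank sums.
oracle_mw_u <- function(a, b) {
  sum(vapply(a, function(x) sum(x > b) + 0.5 * sum(x == b), numeric(1L)))
}

oracle_mw_p <- function(a, b) {
  n <- length(a)
  pooled <- c(a, b)
  u_obs <- oracle_mw_u(a, b)
  combos <- utils::combn(length(pooled), n)
  u_all <- apply(combos, 2L, function(idx) {
    oracle_mw_u(pooled[idx], pooled[-idx])
  })
  tol <- 1e-9
  min(1, 2 * min(mean(u_all <= u_obs + tol), mean(u_all >= u_obs - tol)))
}

# Tiny expression matrix fixture with explicit gene means.
make_matrix <- function(means, n_samples = 3L, unit = "FPKM",
                        species = "human", dataset_id = "fix",
                        region = NULL, genes = NULL) {
  genes <- genes %||% sprintf("G%03d", seq_along(means))
  values <- matrix(rep(means, n_samples), ncol = n_samples,
                   dimnames = list(genes, sprintf("S%d", seq_len(n_samples))))
  expression_matrix(values, unit = unit, species = species,
                    dataset_id = dataset_id, region = region)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Profile with prescribed percentiles (bypassing simulation) for consensus
# tests: builds a matrix whose distinct means realize the wanted ranks.
make_profile <- function(percentiles, genes, n_total = 100L, dataset_id = "p",
                         species = "human", region = NULL) {
  stopifnot(length(percentiles) == length(genes))
  ranks <- round(percentiles * n_total)
  stopifnot(!anyDuplicated(ranks), all(ranks >= 1), all(ranks <= n_total))
  means <- seq_len(n_total)       # distinct values; rank k has mean k
  all_genes <- sprintf("BG%04d", seq_len(n_total))
  all_genes[ranks] <- genes
  m <- make_matrix(means, n_samples = 2L, dataset_id = dataset_id,
                   species = species, region = region, genes = all_genes)
  gene_percentiles(m)
}
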