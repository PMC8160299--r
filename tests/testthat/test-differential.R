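test_that("signed-rank worked examples match enumeration", {
  r <- wilcoxon_signed_rank(c(1, 2, 3))
  expect_equal(r$statistic, 6)
  expect_equal(r$p_value, 0.25)
  expect_equal(r$method, "wilcoxon_signed_rank_exact")

  ## tie in |d|: midranks 1.5/1.5, p = 1 after capping
  r2 <- wilcoxon_signed_rank(c(1, -1))
  expect_equal(r2$p_value, 1.0)

  ## all zero differences: degenerate, not an error
  r3 <- wilcoxon_signed_rank(c(0, 0, 0))
  expect_true(r3$degenerate)
  expect_equal(r3$p_value, 1.0)
  expect_equal(r3$n_effective, 0L)

  ## zeros dropped before ranking
  r4 <- wilcoxon_signed_rank(c(0, 1, 2, 3))
  expect_equal(r4$n_effective, 3L)
  expect_equal(r4$p_value, 0.25)
})

test_that("mann-whitney worked examples match enumeration", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1 / 3)
  expect_equal(r$method, "mann_whitney_exact")

  ## identical multisets: p = 1 by symmetry (tie-corrected normal path)
  r2 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r2$p_value, 1.0)
})

test_that("exact tests agree with brute-force oracles on random instances", {
  set.seed(2024)
  for (i in 1:150) {
    n <- sample(1:12, 1)
    d <- sample(c(-3:3), n, replace = TRUE)
    if (all(d == 0)) d[1] <- 1
    mine <- wilcoxon_signed_rank(d)
    expect_equal(mine$p_value, oracle_signed_rank_p(d), tolerance = 1e-12)
  }
  for (i in 1:150) {
    n <- sample(1:8, 1)
    m <- sample(1:8, 1)
    repeat {   # regenerate until no tie spans the groups (exact-path contract)
      a <- round(rnorm(n, 0, 2), 3)
      b <- round(rnorm(m, 0, 2), 3)
      if (!length(intersect(a, b))) break
    }
    mine <- mann_whitney_u(a, b)
    expect_equal(mine$method, "mann_whitney_exact")
    expect_equal(mine$p_value, oracle_mw_p(a, b), tolerance = 1e-12)
  }
})

test_that("exact p-values agree with wilcox.test on tie-free data", {
  set.seed(9)
  for (i in 1:25) {
    d <- rnorm(sample(4:12, 1))
    expect_equal(wilcoxon_signed_rank(d)$p_value,
                 suppressWarnings(wilcox.test(d, exact = TRUE)$p.value),
                 tolerance = 1e-10)
    a <- rnorm(sample(2:8, 1))
    b <- rnorm(sample(2:8, 1))
    expect_equal(mann_whitney_u(a, b)$p_value,
                 suppressWarnings(wilcox.test(a, b, exact = TRUE)$p.value),
                 tolerance = 1e-10)
  }
})

test_that("large samples switch to the corrected normal approximation", {
  set.seed(31)
  d <- rnorm(40, mean = 0.6)
  r <- wilcoxon_signed_rank(d)
  expect_equal(r$method, "wilcoxon_signed_rank_normal")
  ref <- wilcox.test(d, exact = FALSE, correct = TRUE)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-8)

  a <- rnorm(25)
  b <- rnorm(30, mean = 0.5)
  r2 <- mann_whitney_u(a, b)
  expect_equal(r2$method, "mann_whitney_normal")
  ref2 <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(r2$p_value, ref2$p.value, tolerance = 1e-8)
})

test_that("fold change obeys identity, doubling, and pseudocount symmetry", {
  expect_equal(fold_change(10, 10), 0)
  expect_equal(fold_change(20, 10, pseudocount = 1e-12), 1.0, tolerance = 1e-9)
  expect_equal(fold_change(0, 0), 0)
  expect_error(fold_change(-1, 2), "non-negative")
})

test_that("BH adjustment matches the hand-derived step-up and is sane", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  p <- c(0.001, 0.2, 0.04, 0.9, 0.04)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  ## permutation invariance
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_adjust(p[perm]), q[perm])
  ## adjusted flat outputs are fixed points of the step-up procedure
  expect_equal(bh_adjust(c(0.03, 0.03, 0.03)), c(0.03, 0.03, 0.03))
})

test_that("regional differential calls planted effects by fold change", {
  spec <- synthetic_region_spec(
    base = synthetic_bulk_spec(n_genes = 500, seed = 21,
                               planted = data.frame(
                                 gene = c("CXCR4", "PTGER4", "GPR34"),
                                 percentile = c(0.9, 0.8, 0.7))),
    n_donors = 6,
    region_effects = data.frame(gene = c("CXCR4", "PTGER4"),
                                fold = c(2.5, 1.5)))
  sim <- simulate_paired_regions(spec)
  res <- region_differential(sim$matrix, sim$samples)
  expect_true(attr(res, "paired"))
  get_dir <- function(g) res$direction[res$gene == g]
  expect_equal(get_dir("CXCR4"), "WM_higher")   # 2.5x beats the 2-fold bar
  expect_equal(get_dir("PTGER4"), "none")       # 1.5x does not
  expect_equal(get_dir("GPR34"), "none")
  ## paired signed-rank picks up the consistent within-donor shift
  expect_lt(res$p_value[res$gene == "CXCR4"], 0.05)
})

test_that("identical WM/GM expression yields no calls and zero fold changes", {
  v <- matrix(rep(c(4, 8, 2), 4), nrow = 3,
              dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:4)))
  m <- expression_matrix(v, "count", "human", "same")
  st <- sample_table(sprintf("s%d", 1:4), donor_id = c("d1", "d1", "d2", "d2"),
                     region = c("WM", "GM", "WM", "GM"))
  res <- region_differential(m, st)
  expect_true(all(res$direction == "none"))
  expect_true(all(res$log2_fold_change == 0))
})

test_that("swapping regions negates fold changes and preserves p", {
  spec <- synthetic_region_spec(
    base = synthetic_bulk_spec(n_genes = 200, seed = 8,
                               planted = data.frame(gene = "CXCR4",
                                                    percentile = 0.9)),
    n_donors = 5,
    region_effects = data.frame(gene = "CXCR4", fold = 3))
  sim <- simulate_paired_regions(spec)
  res <- region_differential(sim$matrix, sim$samples)
  swapped <- sim$samples
  swapped$region <- ifelse(swapped$region == "WM", "GM", "WM")
  res_sw <- region_differential(sim$matrix, swapped)
  expect_equal(res_sw$log2_fold_change, -res$log2_fold_change)
  expect_equal(res_sw$p_value, res$p_value)
  expect_equal(res_sw$direction[res$direction == "WM_higher"], "GM_higher")
})

test_that("paired analysis demands matched donors", {
  v <- matrix(1:12, nrow = 3,
              dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:4)))
  m <- expression_matrix(v, "count", "human", "x")
  st <- sample_table(sprintf("s%d", 1:4),
                     donor_id = c("d1", "d2", "d3", "d4"),
                     region = c("WM", "GM", "WM", "GM"))
  expect_error(region_differential(m, st, paired = TRUE), "unmatched.*d1")
  ## unpaired mode works on the same data
  res <- region_differential(m, st, paired = FALSE)
  expect_true(all(is.finite(res$log2_fold_change)))
})
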