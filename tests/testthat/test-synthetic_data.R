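test_that("percentile planting brackets the target rank exactly", {
  set.seed(3)
  bg <- rlnorm(199, 1, 1.5)
  ## target 1.0 -> strictly above the background maximum
  expect_gt(plant_percentile(bg, 1.0), max(bg))
  ## lowest feasible target -> strictly below the background minimum
  expect_lt(plant_percentile(bg, 1 / 200), min(bg))
  ## any feasible target is recovered exactly by gene_percentiles
  for (target in c(0.1, 0.25, 0.5, 0.75, 0.9, 1.0)) {
    val <- plant_percentile(bg, target)
    means <- c(bg, planted = val)
    m <- make_matrix(means, n_samples = 2)
    prof <- gene_percentiles(m)
    expect_equal(prof$percentile[length(means)], target)
  }
  ## a tie block makes the slot infeasible
  tied <- rep(5, 99)
  expect_error(plant_percentile(tied, 0.5), "tie block")
  expect_error(plant_percentile(bg, 1.5), "0, 1")
})

test_that("simulated bulk datasets honor planted percentiles and the seed", {
  planted <- data.frame(gene = c("CX3CR1", "CXCR4", "GPR34"),
                        percentile = c(1.0, 0.9, 0.5))
  spec <- synthetic_bulk_spec(n_genes = 1000, n_samples = 6, seed = 99,
                              planted = planted, noise_sd = 0)
  sim <- simulate_bulk(spec)
  expect_equal(sim$truth$achieved_percentile, planted$percentile)
  prof <- gene_percentiles(sim$matrix)
  got <- profile_percentile(prof, planted$gene)
  expect_equal(unname(got), planted$percentile)  # exact in noise-free mode
  ## planted at 1.0 owns the maximum mean
  expect_equal(unname(which.max(rowMeans(sim$matrix$values))),
               which(rownames(sim$matrix$values) == "CX3CR1"))

  ## same seed -> byte-identical output
  sim2 <- simulate_bulk(spec)
  expect_identical(sim$matrix$values, sim2$matrix$values)
  f1 <- tempfile(); f2 <- tempfile()
  write_bulk_matrix(sim$matrix, f1)
  write_bulk_matrix(sim2$matrix, f2)
  expect_identical(readLines(f1), readLines(f2))

  ## rank-slot collisions between planted genes are rejected
  expect_error(simulate_bulk(synthetic_bulk_spec(
    n_genes = 100, planted = data.frame(gene = c("A", "B"),
                                        percentile = c(0.501, 0.504)))),
    "same rank slot")
})

test_that("default-noise planting stays within 1.5/N of the target", {
  n <- 1000
  targets <- data.frame(gene = c("HI", "MID", "LOW"),
                        percentile = c(0.9, 0.7, 0.3))
  errs <- vapply(1:25, function(s) {
    spec <- synthetic_bulk_spec(n_genes = n, n_samples = 8, seed = s,
                                planted = targets)
    prof <- gene_percentiles(simulate_bulk(spec)$matrix)
    max(abs(profile_percentile(prof, targets$gene) - targets$percentile))
  }, numeric(1))
  expect_lte(max(errs), 1.5 / n)
})

test_that("paired-region simulation plants donor-shared regional effects", {
  spec <- synthetic_region_spec(
    base = synthetic_bulk_spec(n_genes = 300, seed = 4,
                               planted = data.frame(gene = "CXCR4",
                                                    percentile = 0.85)),
    n_donors = 5,
    region_effects = data.frame(gene = "CXCR4", fold = 2.5))
  sim <- simulate_paired_regions(spec)
  expect_equal(ncol(sim$matrix$values), 10L)
  expect_setequal(sim$samples$region, c("WM", "GM"))
  expect_equal(sim$truth$region_effects$expected_direction, "WM_higher")
  ## every donor contributes one WM and one GM sample
  expect_true(all(table(sim$samples$donor_id) == 2))
  ## determinism
  sim2 <- simulate_paired_regions(spec)
  expect_identical(sim$matrix$values, sim2$matrix$values)
  expect_error(synthetic_region_spec(n_donors = 1), ">= 2")
  expect_error(synthetic_region_spec(
    region_effects = data.frame(gene = "X", fold = -1)), "> 0")
})

test_that("single-cell simulation respects proportions, shifts, and seed", {
  spec <- synthetic_sc_spec(seed = 55)
  sim <- simulate_single_cell(spec)
  expect_equal(nrow(sim$dataset$counts), 1602L)
  props <- table(sim$dataset$cluster_labels) / 1602
  ## binomial tolerance: 4 sd of a binomial proportion
  for (cl in names(spec$cluster_proportions)) {
    p0 <- spec$cluster_proportions[[cl]]
    expect_lt(abs(props[[cl]] - p0), 4 * sqrt(p0 * (1 - p0) / 1602))
  }
  ## same seed -> identical matrix.mtx bytes
  d1 <- tempfile(); d2 <- tempfile()
  write_single_cell(sim$dataset, d1)
  write_single_cell(simulate_single_cell(spec)$dataset, d2)
  expect_identical(readBin(file.path(d1, "matrix.mtx"), "raw", 1e6),
                   readBin(file.path(d2, "matrix.mtx"), "raw", 1e6))

  expect_error(synthetic_sc_spec(cluster_proportions = c(a = 0.5, b = 0.4)),
               "sum to 1")
  expect_error(synthetic_sc_spec(n_cells = 20,
                                 cluster_proportions = c(a = 0.99, b = 0.01)),
               "expected zero cells")
  expect_error(synthetic_sc_spec(marker_shifts = data.frame(
    gene = "NOT_THERE", cluster = "disease", fold = 2)), "absent")
})

test_that("null simulations produce no spurious strong regional calls", {
  ## no planted effects: expected |log2FC| >= 1 calls are rare with the
  ## default technical noise and donor variability
  n_calls <- vapply(1:20, function(s) {
    spec <- synthetic_region_spec(
      base = synthetic_bulk_spec(n_genes = 300, seed = 200 + s),
      n_donors = 6)
    sim <- simulate_paired_regions(spec)
    res <- region_differential(sim$matrix, sim$samples, fc_threshold = 2)
    sum(res$direction != "none")
  }, numeric(1))
  expect_lt(mean(n_calls) / 300, 0.01)
})
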