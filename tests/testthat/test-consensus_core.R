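make_tier_profiles <- function(tiers_by_dataset, genes, regions = NULL,
                               species = "human") {
  ## translate tier names into representative percentiles
  tier_pct <- c(below_cutoff = 0.20, low = 0.55, medium = 0.75, high = 0.95)
  profs <- list()
  for (i in seq_along(tiers_by_dataset)) {
    tiers <- tiers_by_dataset[[i]]
    pct <- tier_pct[tiers] + seq_along(tiers) * 1e-2  # distinct rank slots
    profs[[i]] <- make_profile(pct, genes, n_total = 400L,
                               dataset_id = names(tiers_by_dataset)[i],
                               species = species,
                               region = if (is.null(regions)) NULL
                                        else regions[i])
  }
  profs
}

test_that("consensus membership follows the min-tier / min-fraction rule", {
  cat <- load_catalog()
  genes <- c("CX3CR1", "P2RY12", "CXCR4")
  profs <- make_tier_profiles(
    list(d1 = c(CX3CR1 = "high", P2RY12 = "high", CXCR4 = "below_cutoff"),
         d2 = c(CX3CR1 = "high", P2RY12 = "high", CXCR4 = "high"),
         d3 = c(CX3CR1 = "high", P2RY12 = "below_cutoff", CXCR4 = "high")),
    genes)
  res <- derive_core_set(profs, cat, consensus_config())
  memb <- res$membership
  get <- function(g, col) memb[[col]][memb$gene == g]
  ## unanimous high -> member, not rescued
  expect_true(get("CX3CR1", "consensus_member"))
  expect_false(get("CX3CR1", "rescued"))
  ## 2 of 3 fails unanimity...
  expect_false(get("CXCR4", "consensus_member"))
  expect_false(get("P2RY12", "consensus_member"))
  ## ...but passes at min_fraction 0.6 (ceil(0.6 * 3) = 2)
  res2 <- derive_core_set(profs, cat, consensus_config(min_fraction = 0.6))
  expect_true(res2$membership$consensus_member[res2$membership$gene == "CXCR4"])

  expect_error(derive_core_set(profs[1], cat), "at least 2")
})

test_that("relaxing the rule never shrinks the core set", {
  cat <- load_catalog()
  set.seed(5)
  genes <- catalog_gpcr_genes(cat, "human")[1:10]
  profs <- lapply(1:4, function(i) {
    make_profile(sample(seq(0.1, 0.99, by = 0.02), length(genes)), genes,
                 n_total = 200L, dataset_id = paste0("d", i))
  })
  strict <- derive_core_set(profs, cat,
                            consensus_config("high", 1.0, FALSE))$membership
  for (cfg in list(consensus_config("medium", 1.0, FALSE),
                   consensus_config("high", 0.5, FALSE),
                   consensus_config("low", 0.25, FALSE))) {
    relaxed <- derive_core_set(profs, cat, cfg)$membership
    expect_true(all(relaxed$consensus_member[strict$consensus_member]))
  }
})

test_that("consensus output is independent of profile ordering", {
  cat <- load_catalog()
  genes <- c("CX3CR1", "GPR34", "CXCR4")
  profs <- make_tier_profiles(
    list(a = c(CX3CR1 = "high", GPR34 = "medium", CXCR4 = "medium"),
         b = c(CX3CR1 = "high", GPR34 = "high", CXCR4 = "medium"),
         c = c(CX3CR1 = "medium", GPR34 = "high", CXCR4 = "high")),
    genes, regions = c("GM", "other", "WM"))
  r1 <- derive_core_set(profs, cat)
  r2 <- derive_core_set(rev(profs), cat)
  expect_identical(r1$membership, r2$membership)
  expect_identical(r1$tiers, r2$tiers)
})

test_that("regional rescue admits GM-medium / WM-high genes only", {
  cat <- load_catalog()
  genes <- c("CXCR4", "PTGER4", "CX3CR1", "GPR34")
  gm <- make_profile(c(0.80, 0.90, 0.91, 0.81), genes, dataset_id = "gm",
                     region = "GM")
  wm <- make_profile(c(0.90, 0.92, 0.93, 0.80), genes, dataset_id = "wm",
                     region = "WM")
  rescued <- region_rescue(gm, wm, cat)
  ## GM 0.80 (medium) + WM 0.90 (high) -> rescued
  expect_true("CXCR4" %in% rescued)
  ## GM already high -> membership via the main rule, not rescue
  expect_false("PTGER4" %in% rescued)
  expect_false("CX3CR1" %in% rescued)
  ## GM medium + WM medium -> not rescued
  expect_false("GPR34" %in% rescued)

  no_region <- make_profile(c(0.80, 0.90, 0.91, 0.81), genes, dataset_id = "x")
  expect_error(region_rescue(no_region, wm, cat), "GM and WM")
})

test_that("rescued genes are flagged and included in the derived set", {
  cat <- load_catalog()
  genes <- c("CX3CR1", "CXCR4")
  profs <- make_tier_profiles(
    list(gm1 = c(CX3CR1 = "high", CXCR4 = "medium"),
         gm2 = c(CX3CR1 = "high", CXCR4 = "low"),
         wm1 = c(CX3CR1 = "high", CXCR4 = "high")),
    genes, regions = c("GM", "GM", "WM"))
  res <- derive_core_set(profs, cat, consensus_config())
  memb <- res$membership
  ## CXCR4 fails unanimity (low in gm2) but is rescued via the (gm1, wm1) pair
  expect_true(memb$consensus_member[memb$gene == "CXCR4"])
  expect_true(memb$rescued[memb$gene == "CXCR4"])
  ## rescue disabled -> not a member
  res_off <- derive_core_set(profs, cat, consensus_config(rescue_enabled = FALSE))
  expect_false(res_off$membership$consensus_member[
    res_off$membership$gene == "CXCR4"])
  ## invariants: rescued => member; member => support or rescued
  expect_true(all(memb$consensus_member[memb$rescued]))
  D <- ncol(res$tiers)
  expect_true(all(memb$n_support >= ceiling(1.0 * D) | memb$rescued |
                    !memb$consensus_member))
})

test_that("consensus TSV/JSON export lists members and config", {
  cat <- load_catalog()
  genes <- c("CX3CR1", "CXCR4")
  profs <- make_tier_profiles(
    list(d1 = c(CX3CR1 = "high", CXCR4 = "medium"),
         d2 = c(CX3CR1 = "high", CXCR4 = "medium")),
    genes)
  res <- derive_core_set(profs, cat)
  tsv <- tempfile(fileext = ".tsv")
  js <- tempfile(fileext = ".json")
  write_consensus(res, tsv, js)
  tab <- read.table(tsv, sep = "\t", header = TRUE)
  expect_true(all(c("gene", "d1", "d2", "consensus_member") %in% names(tab)))
  summ <- jsonlite::read_json(js)
  expect_setequal(unlist(summ$members), c("CX3CR1", "CXCR4"))
  expect_equal(summ$config$min_tier, "medium")
})
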