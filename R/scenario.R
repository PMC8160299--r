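## The shipped end-to-end scenario: a narrative fixture mirroring the
## structure of the cross-dataset core-signature analysis, fully synthetic.

#' Load a scenario definition from YAML
#'
#' @param path Scenario YAML path; default the shipped
#'   `core_signature_mirror` scenario.
#' @return A list of class `gpcrome_scenario`.
#' @export
load_scenario <- function(path = system.file("extdata", "mirror_scenario.yaml",
                                             package = "gpcrome")) {
  if (!file.exists(path)) stopf("scenario file not found: %s", path)
  sc <- yaml::read_yaml(path)
  for (field in c("name", "species", "unit", "bulk", "single_cell")) {
    if (is.null(sc[[field]])) stopf("scenario is missing field '%s'", field)
  }
  structure(sc, class = "gpcrome_scenario")
}

#' Build the bulk dataset specs of a scenario
#'
#' Expands a scenario definition into one [synthetic_bulk_spec()] per
#' dataset: core genes planted at high percentiles everywhere, rescue genes
#' at medium targets in GM datasets and high targets in the WM dataset, and
#' every remaining catalog receptor gene planted strictly below the medium
#' tier. Each dataset draws its own sub-seed from `seed`.
#'
#' @param scenario A `gpcrome_scenario` (default: shipped).
#' @param seed Integer master seed.
#' @param catalog Catalog supplying the receptor gene universe.
#' @return Named list of `synthetic_bulk_spec`s.
#' @export
scenario_bulk_specs <- function(scenario = load_scenario(), seed = 1L,
                                catalog = load_catalog()) {
  b <- scenario$bulk
  core <- unlist(b$core_genes)
  rescue <- unlist(b$rescue_genes)
  gpcr <- catalog_gpcr_genes(catalog, scenario$species)
  background_genes <- sort(setdiff(gpcr, c(core, rescue)))
  core_targets <- seq(b$core_targets_low, b$core_targets_high,
                      length.out = length(core))
  bg_targets <- seq(b$background_targets_low, b$background_targets_high,
                    length.out = length(background_genes))
  specs <- list()
  for (i in seq_along(b$datasets)) {
    ds <- b$datasets[[i]]
    rescue_targets <- if (identical(ds$region, "WM")) {
      unlist(b$rescue_wm_targets)
    } else {
      unlist(b$rescue_gm_targets)
    }
    planted <- data.frame(
      gene = c(core, rescue, background_genes),
      percentile = c(core_targets, rescue_targets, bg_targets),
      stringsAsFactors = FALSE)
    specs[[ds$id]] <- synthetic_bulk_spec(
      n_genes = b$n_genes, n_samples = b$n_samples,
      meanlog = b$meanlog, sdlog = b$sdlog, planted = planted,
      noise_sd = b$noise_sd, seed = derive_seed(seed, i),
      dataset_id = ds$id, species = scenario$species, unit = scenario$unit,
      region = ds$region)
  }
  specs
}

#' Build the single-cell spec of a scenario
#'
#' @inheritParams scenario_bulk_specs
#' @return A [synthetic_sc_spec()].
#' @export
scenario_sc_spec <- function(scenario = load_scenario(), seed = 1L) {
  s <- scenario$single_cell
  down <- unlist(s$down_markers)
  up <- unlist(s$up_markers)
  shifts <- data.frame(
    gene = c(down, up),
    cluster = "disease",
    fold = c(rep(s$down_fold, length(down)), rep(s$up_fold, length(up))),
    stringsAsFactors = FALSE)
  if (isTRUE(s$up_also_in_monocyte)) {
    shifts <- rbind(shifts, data.frame(gene = up, cluster = "monocyte",
                                       fold = s$up_fold))
  }
  synthetic_sc_spec(n_cells = s$n_cells,
                    cluster_proportions = unlist(s$proportions),
                    marker_shifts = shifts,
                    dispersion = s$dispersion, depth_sdlog = s$depth_sdlog,
                    seed = derive_seed(seed, 101L))
}

#' Run the shipped scenario end to end
#'
#' Simulates the scenario's bulk datasets and single-cell dataset, profiles
#' each bulk dataset, derives the consensus core set with the regional
#' rescue rule, runs the disease-vs-homeostatic cluster contrast on the
#' planted marker panel, and returns everything with the planted truth.
#'
#' @inheritParams scenario_bulk_specs
#' @param config [consensus_config()] for the core-set derivation.
#' @return List: `profiles`, `consensus`, `sc`, `contrast`, `truth`.
#' @export
run_scenario <- function(scenario = load_scenario(), seed = 1L,
                         catalog = load_catalog(),
                         config = consensus_config()) {
  specs <- scenario_bulk_specs(scenario, seed, catalog)
  sims <- lapply(specs, simulate_bulk)
  profiles <- lapply(sims, function(s) gene_percentiles(s$matrix))
  consensus <- derive_core_set(profiles, catalog, config)
  sc_spec <- scenario_sc_spec(scenario, seed)
  sc <- simulate_single_cell(sc_spec)
  panel <- unique(sc_spec$marker_shifts$gene)
  contrast <- contrast_clusters(sc$dataset, "disease", "homeostatic",
                                gene_panel = panel)
  expected_members <- sort(c(unlist(scenario$bulk$core_genes),
                             unlist(scenario$bulk$rescue_genes)))
  list(profiles = profiles, consensus = consensus, sc = sc,
       contrast = contrast,
       truth = list(expected_members = expected_members,
                    expected_rescued = sort(unlist(scenario$bulk$rescue_genes)),
                    bulk = lapply(sims, `[[`, "truth"),
                    sc = sc$truth))
}
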