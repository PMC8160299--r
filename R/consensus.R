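#' Consensus configuration for core-set derivation
#'
#' @param min_tier Minimum tier a gene must reach in a dataset to count as
#'   supporting ("medium" by default).
#' @param min_fraction Fraction of datasets that must support a gene for
#'   membership (default 1.0, i.e. unanimity).
#' @param rescue_enabled Whether the regional rescue rule (medium in the
#'   grey-matter profile, high in the white-matter profile) may add members.
#' @return A list of class `consensus_config`.
#' @export
consensus_config <- function(min_tier = "medium", min_fraction = 1.0,
                             rescue_enabled = TRUE) {
  min_tier <- match.arg(min_tier, TIER_LEVELS)
  if (!(min_fraction > 0 && min_fraction <= 1)) {
    stopf("min_fraction must lie in (0, 1]")
  }
  structure(list(min_tier = min_tier, min_fraction = min_fraction,
                 rescue_enabled = isTRUE(rescue_enabled)),
            class = "consensus_config")
}

tier_at_least <- function(tier, min_tier) {
  !is.na(tier) & as.integer(tier) >= match(min_tier, TIER_LEVELS)
}

#' Derive the cross-dataset core receptor gene set
#'
#' A catalog receptor gene is a consensus member when it reaches
#' `config$min_tier` in at least `ceiling(min_fraction * D)` of the D
#' profiles. When rescue is enabled and the profile list contains a
#' grey-matter and a white-matter profile (region attributes `"GM"` and
#' `"WM"`), genes that are medium in the designated GM profile and high in
#' the WM profile are additionally flagged `rescued` and included. The full
#' per-dataset tier table is retained for audit; output is independent of
#' profile ordering.
#'
#' @param profiles List of `percentile_profile`s (same species, >= 2).
#' @param catalog A `gene_catalog`.
#' @param config A [consensus_config()].
#' @param gm_dataset,wm_dataset Optional dataset ids designating the rescue
#'   pair; by default the first GM-region and first WM-region profile
#'   (by dataset id order) are used.
#' @return Object of class `consensus_result`: list with `tiers` (genes x
#'   datasets data.frame of ordered tier factors), `membership` (data.frame
#'   gene, n_support, consensus_member, rescued), and `config`.
#' @export
derive_core_set <- function(profiles, catalog, config = consensus_config(),
                            gm_dataset = NULL, wm_dataset = NULL) {
  stopifnot(inherits(config, "consensus_config"))
  if (length(profiles) < 2L) stopf("need at least 2 profiles for a consensus")
  if (!all(vapply(profiles, inherits, TRUE, "percentile_profile"))) {
    stopf("profiles must be percentile_profile objects")
  }
  species <- unique(vapply(profiles, profile_meta, "", what = "species"))
  if (length(species) != 1L) {
    stopf("consensus requires profiles from a single species")
  }
  ids <- vapply(profiles, profile_meta, "", what = "dataset_id")
  if (anyDuplicated(ids)) stopf("duplicate dataset_ids among profiles")
  ## determinism: canonical dataset order
  ord <- order(ids)
  profiles <- profiles[ord]
  ids <- ids[ord]
  gene_sets <- lapply(profiles, `[[`, "gene")
  for (i in seq_along(profiles)[-1L]) {
    if (!length(intersect(gene_sets[[1L]], gene_sets[[i]]))) {
      stopf("profiles %s and %s have disjoint gene universes", ids[1L], ids[i])
    }
  }
  universe <- sort(catalog_gpcr_genes(catalog, species))
  tiers <- data.frame(row.names = universe)
  for (i in seq_along(profiles)) {
    idx <- match(universe, profiles[[i]]$gene)
    tiers[[ids[i]]] <- factor(as.character(profiles[[i]]$tier[idx]),
                              levels = TIER_LEVELS, ordered = TRUE)
  }
  D <- length(profiles)
  support <- Reduce(`+`, lapply(tiers, tier_at_least, min_tier = config$min_tier))
  needed <- ceiling(config$min_fraction * D - 1e-9)
  member <- support >= needed

  rescued <- rep(FALSE, length(universe))
  regions <- vapply(profiles, function(p) profile_meta(p, "region") %||%
                      NA_character_, "")
  gm_id <- gm_dataset %||% ids[which(regions == "GM")[1L]]
  wm_id <- wm_dataset %||% ids[which(regions == "WM")[1L]]
  if (config$rescue_enabled && length(gm_id) && length(wm_id) &&
      !is.na(gm_id) && !is.na(wm_id)) {
    gm_prof <- profiles[[match(gm_id, ids)]]
    wm_prof <- profiles[[match(wm_id, ids)]]
    res <- region_rescue(gm_prof, wm_prof, catalog, config)
    rescued <- universe %in% res
    member <- member | rescued
  }
  membership <- data.frame(gene = universe, n_support = support,
                           consensus_member = member, rescued = rescued,
                           row.names = NULL, stringsAsFactors = FALSE)
  structure(list(tiers = tiers, membership = membership, config = config,
                 species = species, gm_dataset = gm_id, wm_dataset = wm_id),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cfg <- x$config
  cat("consensus_result over ", ncol(x$tiers), " datasets (",
      x$species, ")\n", sep = "")
  cat("  rule: tier >= ", cfg$min_tier, " in >= ",
      round(cfg$min_fraction * 100), "% of datasets; rescue ",
      if (cfg$rescue_enabled) "on" else "off", "\n", sep = "")
  memb <- x$membership
  cat("  members: ", sum(memb$consensus_member), " (",
      sum(memb$rescued), " rescued) of ", nrow(memb),
      " catalog receptor genes\n", sep = "")
  invisible(x)
}

#' Regional rescue rule
#'
#' Returns receptor genes with medium expression tier in the grey-matter
#' profile but high tier in the white-matter profile — the rule that admits
#' white-matter-enriched receptors into the core set even when they do not
#' reach the abundance bar in grey-matter datasets. Genes already high in
#' grey matter are not "rescued" (their membership flows from the main
#' rule).
#'
#' @param gm_profile,wm_profile `percentile_profile`s with region
#'   attributes `"GM"` and `"WM"`, same species.
#' @param catalog A `gene_catalog`.
#' @param config A [consensus_config()] (rescue must be enabled).
#' @return Character vector of rescued gene symbols.
#' @export
region_rescue <- function(gm_profile, wm_profile, catalog,
                          config = consensus_config()) {
  reg_gm <- profile_meta(gm_profile, "region")
  reg_wm <- profile_meta(wm_profile, "region")
  if (!identical(reg_gm, "GM") || !identical(reg_wm, "WM")) {
    stopf("rescue requires profiles labeled with regions GM and WM (got %s, %s)",
          reg_gm %||% "<none>", reg_wm %||% "<none>")
  }
  sp_gm <- profile_meta(gm_profile, "species")
  if (!identical(sp_gm, profile_meta(wm_profile, "species"))) {
    stopf("rescue profiles must share a species")
  }
  universe <- catalog_gpcr_genes(catalog, sp_gm)
  gm_tier <- gm_profile$tier[match(universe, gm_profile$gene)]
  wm_tier <- wm_profile$tier[match(universe, wm_profile$gene)]
  hit <- !is.na(gm_tier) & !is.na(wm_tier) &
    gm_tier == "medium" & wm_tier == "high"
  sort(universe[hit])
}

#' Write a consensus result as a TSV tier table plus JSON summary
#'
#' @param result A `consensus_result`.
#' @param tsv_path Output path for the genes x datasets tier table.
#' @param json_path Output path for the summary
#'   (`{members, rescued, config}`).
#' @return Invisibly, `tsv_path`.
#' @export
write_consensus <- function(result, tsv_path, json_path) {
  stopifnot(inherits(result, "consensus_result"))
  tiers <- result$tiers
  memb <- result$membership
  hdr <- paste(c("gene", colnames(tiers), "n_support", "consensus_member",
                 "rescued"), collapse = "\t")
  body <- vapply(seq_len(nrow(tiers)), function(i) {
    paste(c(rownames(tiers)[i],
            vapply(tiers[i, , drop = FALSE], as.character, ""),
            memb$n_support[i], memb$consensus_member[i], memb$rescued[i]),
          collapse = "\t")
  }, character(1L))
  con <- file(tsv_path, open = "wb")
  writeLines(c(hdr, body), con, sep = "\n", useBytes = TRUE)
  close(con)
  jsonlite::write_json(
    list(members = memb$gene[memb$consensus_member],
         rescued = memb$gene[memb$rescued],
         config = list(min_tier = result$config$min_tier,
                       min_fraction = result$config$min_fraction,
                       rescue_enabled = result$config$rescue_enabled,
                       gm_dataset = result$gm_dataset %||% NA,
                       wm_dataset = result$wm_dataset %||% NA)),
    json_path, auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null")
  invisible(tsv_path)
}
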