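#' Expression tier scheme
#'
#' Percentile boundaries for the four expression tiers used throughout:
#' genes below the inclusion cutoff are `below_cutoff`; `low` runs from the
#' cutoff to `low_upper`, `medium` from `low_upper` to `medium_upper`, and
#' `high` from `medium_upper` to 1. Defaults (0.50, 0.68, 0.86) realize the
#' published 0.5-0.67 / 0.68-0.85 / 0.86-1.0 bands as half-open intervals on
#' unrounded percentiles (the one-hundredth gaps in the printed bands are
#' two-decimal rounding of continuous boundaries).
#'
#' @param cutoff Inclusion threshold, default 0.50.
#' @param low_upper Lower bound of the medium tier, default 0.68.
#' @param medium_upper Lower bound of the high tier, default 0.86.
#' @return A list of class `tier_scheme`.
#' @export
tier_scheme <- function(cutoff = 0.50, low_upper = 0.68, medium_upper = 0.86) {
  if (!(0 < cutoff && cutoff < low_upper && low_upper < medium_upper &&
        medium_upper <= 1)) {
    stopf("tier boundaries must satisfy 0 < cutoff < low_upper < medium_upper <= 1")
  }
  structure(list(cutoff = cutoff, low_upper = low_upper,
                 medium_upper = medium_upper),
            class = "tier_scheme")
}

#' Assign expression tiers to percentiles
#'
#' Deterministic, vectorized mapping from whole-transcriptome percentile to
#' tier: `below_cutoff` if p < cutoff, `low` if cutoff <= p < low_upper,
#' `medium` if low_upper <= p < medium_upper, `high` if p >= medium_upper.
#'
#' @param percentile Numeric vector of percentiles in (0, 1].
#' @param scheme A [tier_scheme()].
#' @return Ordered factor with levels
#'   `below_cutoff < low < medium < high`.
#' @export
assign_tier <- function(percentile, scheme = tier_scheme()) {
  stopifnot(inherits(scheme, "tier_scheme"))
  if (any(is.na(percentile)) || any(percentile <= 0) || any(percentile > 1)) {
    stopf("percentiles must lie in (0, 1]")
  }
  tier <- cut(percentile,
              breaks = c(0, scheme$cutoff, scheme$low_upper,
                         scheme$medium_upper, 1),
              labels = TIER_LEVELS, right = FALSE,
              include.lowest = FALSE)
  ## cut() with right = FALSE leaves p = 1 unassigned; it belongs to 'high'
  tier[percentile >= scheme$medium_upper] <- "high"
  factor(tier, levels = TIER_LEVELS, ordered = TRUE)
}

#' Whole-transcriptome percentile ranks for a dataset
#'
#' Ranks every gene of a dataset against all genes of that dataset and
#' expresses the rank as a percentile (midrank / N, so the top gene is at
#' exactly 1.0 and tied genes share their midrank). Two aggregation orders
#' are offered: `mean_then_rank` (default) averages expression across
#' samples first and ranks the means once; `rank_then_mean` ranks each
#' sample separately and averages the per-sample percentiles. The
#' denominator N counts every gene present in the matrix, including
#' zero-expression genes; pre-filter the matrix if a different background is
#' wanted.
#'
#' @param matrix An `expr_matrix`.
#' @param aggregation `"mean_then_rank"` or `"rank_then_mean"`.
#' @param scheme [tier_scheme()] used to attach tiers.
#' @return An object of class `percentile_profile`: a data.frame with
#'   columns `gene`, `mean_expression`, `midrank`, `percentile`, `tier`, and
#'   attributes `dataset_id`, `species`, `region`, `aggregation`.
#' @export
gene_percentiles <- function(matrix,
                             aggregation = c("mean_then_rank", "rank_then_mean"),
                             scheme = tier_scheme()) {
  stopifnot(inherits(matrix, "expr_matrix"))
  aggregation <- match.arg(aggregation)
  v <- matrix$values
  n <- nrow(v)
  if (n < 2L) {
    stopf("percentile rank is undefined for a single-gene matrix")
  }
  means <- rowMeans(v)
  if (aggregation == "mean_then_rank") {
    midrank <- rank(means, ties.method = "average")
    percentile <- midrank / n
  } else {
    per_sample <- apply(v, 2L, function(col) rank(col, ties.method = "average") / n)
    percentile <- rowMeans(per_sample)
    midrank <- percentile * n
  }
  out <- data.frame(gene = rownames(v), mean_expression = means,
                    midrank = midrank, percentile = percentile,
                    tier = assign_tier(percentile, scheme),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out,
            dataset_id = matrix$dataset_id, species = matrix$species,
            region = matrix$region, aggregation = aggregation,
            class = c("percentile_profile", "data.frame"))
}

profile_meta <- function(profile, what) attr(profile, what, exact = TRUE)

#' Percentile of named genes within a profile
#'
#' @param profile A `percentile_profile`.
#' @param genes Gene symbols.
#' @return Named numeric vector of percentiles (`NA` for absent genes).
#' @export
profile_percentile <- function(profile, genes) {
  idx <- match(genes, profile$gene)
  stats::setNames(profile$percentile[idx], genes)
}

#' Cross-species union filter for catalog receptor genes
#'
#' Implements the "expressed in at least one species" inclusion rule: a
#' catalog receptor gene is kept when its whole-transcriptome percentile
#' meets the cutoff in the human profile and/or the mouse profile (OR
#' semantics). Genes cataloged for only one species are evaluated on that
#' species alone and flagged `species_specific`.
#'
#' @param profile_a,profile_b `percentile_profile`s from two different
#'   species.
#' @param catalog A `gene_catalog`.
#' @param cutoff Inclusion percentile, default 0.50.
#' @return data.frame with one row per catalog receptor gene pair: symbols
#'   and percentiles per species, `included`, and `species_specific`.
#' @export
species_union_filter <- function(profile_a, profile_b, catalog, cutoff = 0.50) {
  sp_a <- profile_meta(profile_a, "species")
  sp_b <- profile_meta(profile_b, "species")
  if (identical(sp_a, sp_b)) {
    stopf("profiles must come from different species (both are %s)", sp_a)
  }
  profiles <- stats::setNames(list(profile_a, profile_b), c(sp_a, sp_b))
  human_prof <- profiles[["human"]]
  mouse_prof <- profiles[["mouse"]]
  hs <- catalog_gpcr_genes(catalog, "human")
  mm <- catalog_gpcr_genes(catalog, "mouse")
  mm_of_hs <- vapply(hs, map_ortholog, "", from_species = "human",
                     to_species = "mouse", catalog = catalog)
  mouse_only <- setdiff(mm, mm_of_hs[!is.na(mm_of_hs)])
  rows <- data.frame(
    human_symbol = c(hs, rep(NA_character_, length(mouse_only))),
    mouse_symbol = c(unname(mm_of_hs), mouse_only),
    stringsAsFactors = FALSE)
  rows$percentile_human <- ifelse(is.na(rows$human_symbol), NA_real_,
                                  profile_percentile(human_prof, rows$human_symbol))
  rows$percentile_mouse <- ifelse(is.na(rows$mouse_symbol), NA_real_,
                                  profile_percentile(mouse_prof, rows$mouse_symbol))
  rows$species_specific <- is.na(rows$human_symbol) | is.na(rows$mouse_symbol)
  pmax_pct <- pmax(rows$percentile_human, rows$percentile_mouse, na.rm = TRUE)
  pmax_pct[is.na(rows$percentile_human) & is.na(rows$percentile_mouse)] <- NA_real_
  rows$included <- !is.na(pmax_pct) & pmax_pct >= cutoff
  rows
}

#' Relative expression intensity against the per-sample gene average
#'
#' The heatmap statistic: for gene g in sample s,
#' `r(g, s) = log2((x(g, s) + eps) / (mu(s) + eps))` where `mu(s)` is the
#' mean over all genes in sample s. A gene at the sample average maps to 0,
#' genes above it to positive values (red end), genes below to negative
#' values (white end). Within a sample, ordering by `r` equals ordering by
#' expression. With the default pseudocount (half the smallest nonzero value
#' of the matrix) a gene at exactly twice the sample mean is close to, but
#' not exactly, 1.0.
#'
#' @param matrix An `expr_matrix`.
#' @param pseudocount Additive stabilizer; default half the smallest nonzero
#'   matrix value.
#' @return Numeric genes-by-samples matrix of log2 relative intensities.
#' @export
relative_intensity <- function(matrix, pseudocount = NULL) {
  stopifnot(inherits(matrix, "expr_matrix"))
  v <- matrix$values
  nz <- v[v > 0]
  if (!length(nz)) stopf("all-zero matrix: relative intensity undefined")
  eps <- pseudocount %||% (min(nz) / 2)
  mu <- colMeans(v)
  log2(sweep(v + eps, 2L, mu + eps, "/"))
}

#' Export a percentile profile as TSV
#'
#' Writes the per-gene table with columns gene, mean_expression, midrank,
#' percentile, tier; profile metadata (dataset_id, species, region,
#' aggregation) is stored in leading `#` header lines so the profile can be
#' read back with [read_profile()].
#'
#' @param profile A `percentile_profile`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "percentile_profile"))
  hdr <- c(
    sprintf("# dataset_id: %s", profile_meta(profile, "dataset_id")),
    sprintf("# species: %s", profile_meta(profile, "species")),
    sprintf("# region: %s", profile_meta(profile, "region") %||% "NA"),
    sprintf("# aggregation: %s", profile_meta(profile, "aggregation")))
  body <- paste(profile$gene,
                sprintf("%.6g", profile$mean_expression),
                sprintf("%.6g", profile$midrank),
                sprintf("%.10g", profile$percentile),
                as.character(profile$tier), sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, paste("gene", "mean_expression", "midrank", "percentile",
                          "tier", sep = "\t"), body),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a percentile profile written by [write_profile()]
#'
#' @param path Profile TSV path.
#' @return A `percentile_profile`.
#' @export
read_profile <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    ln <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    val <- trimws(sub(sprintf("^# %s:", key), "", ln[1L]))
    if (identical(val, "NA")) NULL else val
  }
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  tab$tier <- factor(tab$tier, levels = TIER_LEVELS, ordered = TRUE)
  structure(tab,
            dataset_id = get_meta("dataset_id"), species = get_meta("species"),
            region = get_meta("region"),
            aggregation = get_meta("aggregation") %||% "mean_then_rank",
            class = c("percentile_profile", "data.frame"))
}
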