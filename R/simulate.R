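## Synthetic bulk and single-cell generators with planted ground truth.
##
## Design: gene-level mean profiles are drawn from a heavy-tailed log-normal
## (like FPKM/TPM distributions); genes can be planted at exact target
## percentiles of the final gene universe; per-sample multiplicative
## log-noise (one scaling factor per sample, i.e. library-size jitter)
## perturbs samples around the dataset-level mean profile, while gene-level
## biological donor-to-donor variability is modeled separately in the
## paired-region generator. All randomness flows from the spec seed; no
## global state is consulted.

#' Specification for a synthetic bulk dataset
#'
#' @param n_genes Total genes in the final matrix (background + planted).
#' @param n_samples Number of samples.
#' @param meanlog,sdlog Log-normal parameters of the background gene-mean
#'   distribution (defaults 1.0 and 1.5: heavy-tailed like FPKM/TPM).
#' @param planted data.frame with columns `gene`, `percentile`: symbols to
#'   plant at exact target percentiles of the final universe.
#' @param noise_sd Per-sample multiplicative log-noise: one log-normal
#'   scaling factor per sample (library-size jitter), sd on the log scale,
#'   default 0.05. A common factor per sample rescales every gene alike, so
#'   dataset-level gene ranks (and planted percentiles) are preserved;
#'   gene-level biological variability is modeled separately at the donor
#'   level (see [synthetic_region_spec()]).
#' @param seed Integer seed; all generator output is reproducible from it.
#' @param dataset_id,species,unit,region Metadata for the generated matrix.
#' @return List of class `synthetic_bulk_spec`.
#' @export
synthetic_bulk_spec <- function(n_genes = 2000L, n_samples = 8L,
                                meanlog = 1.0, sdlog = 1.5,
                                planted = NULL, noise_sd = 0.05,
                                seed = 1L, dataset_id = "synthetic",
                                species = "human", unit = "FPKM",
                                region = NULL) {
  planted <- planted %||% data.frame(gene = character(0),
                                     percentile = numeric(0))
  stopifnot(is.data.frame(planted), all(c("gene", "percentile") %in%
                                          names(planted)))
  if (anyDuplicated(planted$gene)) stopf("planted gene symbols must be unique")
  if (any(planted$percentile <= 0) || any(planted$percentile > 1)) {
    stopf("target percentiles must lie in (0, 1]")
  }
  if (n_genes <= nrow(planted)) stopf("n_genes must exceed the number of planted genes")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 meanlog = meanlog, sdlog = sdlog, planted = planted,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 dataset_id = dataset_id, species = species, unit = unit,
                 region = region),
            class = "synthetic_bulk_spec")
}

#' Plant a value at an exact percentile of a background
#'
#' Returns a value that, inserted into `background_means`, attains midrank
#' `round(target * N) / N` exactly, where N is the post-insertion universe
#' size: the value lies strictly between the background order statistics
#' bracketing the target rank (strictly above the maximum for target 1.0,
#' strictly below the minimum for the lowest rank). A target whose rank slot
#' falls inside a tie block of the background is infeasible and raises an
#' error.
#'
#' @param background_means Positive background values (the existing genes).
#' @param target_percentile Target in (0, 1].
#' @return The planted value.
#' @export
plant_percentile <- function(background_means, target_percentile) {
  if (target_percentile <= 0 || target_percentile > 1) {
    stopf("target percentile must lie in (0, 1]")
  }
  n_total <- length(background_means) + 1L
  r <- max(1L, as.integer(round(target_percentile * n_total)))
  s <- sort(background_means)
  lo <- if (r == 1L) NA_real_ else s[r - 1L]
  hi <- if (r == n_total) NA_real_ else s[r]
  planted_between(lo, hi, 1L, 1L)
}

## value(s) strictly inside the open interval (lo, hi); NA bounds mean
## unbounded below/above. k values at positions idx of 1..k are spread evenly.
planted_between <- function(lo, hi, idx, k) {
  if (is.na(lo) && is.na(hi)) return(1.0)
  if (is.na(lo)) return(hi * 0.5^((k - idx + 1L)))
  if (is.na(hi)) return(lo * 2^idx)
  if (!(lo < hi)) {
    stopf("infeasible target percentile: rank slot falls inside a tie block")
  }
  val <- lo + (hi - lo) * idx / (k + 1L)
  if (!(val > lo && val < hi)) {
    stopf("infeasible target percentile: bracketing values too close")
  }
  val
}

## Joint planting: gene means for the full universe with planted genes at
## exact ranks round(target * n_genes). Returns named mean vector
## (background genes first, planted genes last) plus achieved percentiles.
plant_means <- function(spec, background) {
  n <- spec$n_genes
  planted <- spec$planted
  k <- nrow(planted)
  bg_names <- sprintf("BG%05d", seq_len(n - k))
  means <- stats::setNames(background, bg_names)
  if (k == 0L) {
    return(list(means = means, truth = data.frame(gene = character(0),
                                                  target_percentile = numeric(0),
                                                  achieved_percentile = numeric(0))))
  }
  ranks <- as.integer(round(planted$percentile * n))
  ranks[ranks < 1L] <- 1L
  if (anyDuplicated(ranks)) {
    stopf("two planted genes imply the same rank slot (targets %s)",
          paste(planted$percentile[duplicated(ranks) |
                                     duplicated(ranks, fromLast = TRUE)],
                collapse = ", "))
  }
  ord <- order(ranks)
  s <- sort(background)
  n_bg <- length(s)
  values <- numeric(k)
  ## planted gene with overall rank r, i-th smallest planted, sits above
  ## r - i background genes
  below <- ranks[ord] - seq_len(k)
  if (any(below < 0L) || any(below > n_bg)) {
    stopf("infeasible planted percentile configuration")
  }
  for (gap in unique(below)) {
    in_gap <- which(below == gap)
    lo <- if (gap == 0L) NA_real_ else s[gap]
    hi <- if (gap == n_bg) NA_real_ else s[gap + 1L]
    for (j in seq_along(in_gap)) {
      values[ord[in_gap[j]]] <- planted_between(lo, hi, j, length(in_gap))
    }
  }
  means <- c(means, stats::setNames(values, planted$gene))
  truth <- data.frame(gene = planted$gene,
                      target_percentile = planted$percentile,
                      achieved_percentile = ranks / n,
                      planted_mean = values,
                      stringsAsFactors = FALSE)
  list(means = means, truth = truth)
}

#' Simulate a bulk expression matrix with planted percentiles
#'
#' Background gene means are drawn log-normal; planted genes are inserted so
#' that their mean attains the target percentile exactly among the final
#' gene universe; per-sample multiplicative log-noise is applied around the
#' mean profile. Output is byte-reproducible from the spec seed.
#'
#' @param spec A [synthetic_bulk_spec()].
#' @return List with elements `matrix` (an `expr_matrix`) and `truth`
#'   (data.frame: gene, target_percentile, achieved_percentile,
#'   planted_mean).
#' @export
simulate_bulk <- function(spec) {
  stopifnot(inherits(spec, "synthetic_bulk_spec"))
  set.seed(spec$seed)
  n_bg <- spec$n_genes - nrow(spec$planted)
  background <- stats::rlnorm(n_bg, spec$meanlog, spec$sdlog)
  pm <- plant_means(spec, background)
  sample_factors <- exp(stats::rnorm(spec$n_samples, sd = spec$noise_sd))
  values <- outer(pm$means, sample_factors)
  dimnames(values) <- list(names(pm$means),
                           sprintf("S%02d", seq_len(spec$n_samples)))
  m <- expression_matrix(values, unit = spec$unit, species = spec$species,
                         dataset_id = spec$dataset_id, region = spec$region)
  list(matrix = m, truth = pm$truth)
}

#' Specification for a paired-region synthetic dataset
#'
#' @param base A [synthetic_bulk_spec()] describing the grey-matter mean
#'   profile (its `n_samples` is ignored; one WM and one GM sample is
#'   generated per donor).
#' @param n_donors Number of donors (>= 2), default 6.
#' @param region_effects data.frame with columns `gene`, `fold`: WM/GM
#'   multiplicative effects (> 0) applied to the WM mean of those genes.
#' @param donor_sd Donor-level biological variability: sd of a per-donor,
#'   per-gene log-normal baseline shared between the donor's WM and GM
#'   samples, default 0.3.
#' @return List of class `synthetic_region_spec`.
#' @export
synthetic_region_spec <- function(base = synthetic_bulk_spec(),
                                  n_donors = 6L, region_effects = NULL,
                                  donor_sd = 0.3) {
  stopifnot(inherits(base, "synthetic_bulk_spec"))
  if (n_donors < 2L) stopf("n_donors must be >= 2")
  region_effects <- region_effects %||% data.frame(gene = character(0),
                                                   fold = numeric(0))
  stopifnot(all(c("gene", "fold") %in% names(region_effects)))
  if (any(region_effects$fold <= 0)) stopf("region fold changes must be > 0")
  structure(list(base = base, n_donors = as.integer(n_donors),
                 region_effects = region_effects, donor_sd = donor_sd),
            class = "synthetic_region_spec")
}

#' Simulate paired white-/grey-matter samples
#'
#' Per donor, one GM and one WM sample share a donor-specific per-gene
#' baseline (log-normal, `donor_sd`); WM means are the GM means multiplied
#' by the planted region effects; per-sample log-noise from the base spec is
#' applied on top. Reproducible from the base spec seed.
#'
#' @param spec A [synthetic_region_spec()].
#' @return List with `matrix` (an `expr_matrix`, columns D01_GM, D01_WM,
#'   ...), `samples` (a [sample_table()]), and `truth` (region effects with
#'   the direction expected at a given 2-fold threshold plus the base
#'   planting truth).
#' @export
simulate_paired_regions <- function(spec) {
  stopifnot(inherits(spec, "synthetic_region_spec"))
  base <- spec$base
  set.seed(base$seed)
  n_bg <- base$n_genes - nrow(base$planted)
  background <- stats::rlnorm(n_bg, base$meanlog, base$sdlog)
  pm <- plant_means(base, background)
  genes <- names(pm$means)
  eff <- stats::setNames(rep(1.0, length(genes)), genes)
  unknown <- setdiff(spec$region_effects$gene, genes)
  if (length(unknown)) {
    stopf("region effect genes absent from universe: %s",
          paste(unknown, collapse = ", "))
  }
  eff[spec$region_effects$gene] <- spec$region_effects$fold
  n_g <- length(genes)
  nd <- spec$n_donors
  donor_base <- matrix(stats::rnorm(n_g * nd, sd = spec$donor_sd), nrow = n_g)
  values <- matrix(0, nrow = n_g, ncol = 2L * nd)
  sample_ids <- character(2L * nd)
  regions <- character(2L * nd)
  donors <- character(2L * nd)
  for (d in seq_len(nd)) {
    baseline <- pm$means * exp(donor_base[, d])
    gm_col <- 2L * d - 1L
    wm_col <- 2L * d
    values[, gm_col] <- baseline *
      exp(stats::rnorm(1L, sd = base$noise_sd))
    values[, wm_col] <- baseline * eff *
      exp(stats::rnorm(1L, sd = base$noise_sd))
    donors[c(gm_col, wm_col)] <- sprintf("D%02d", d)
    regions[c(gm_col, wm_col)] <- c("GM", "WM")
    sample_ids[c(gm_col, wm_col)] <- sprintf("D%02d_%s", d, c("GM", "WM"))
  }
  dimnames(values) <- list(genes, sample_ids)
  m <- expression_matrix(values, unit = base$unit, species = base$species,
                         dataset_id = base$dataset_id)
  samples <- sample_table(sample_id = sample_ids, donor_id = donors,
                          region = regions, condition = "control",
                          species = base$species)
  truth_eff <- spec$region_effects
  truth_eff$expected_direction <- ifelse(truth_eff$fold >= 2, "WM_higher",
                                         ifelse(truth_eff$fold <= 0.5,
                                                "GM_higher", "none"))
  list(matrix = m, samples = samples,
       truth = list(region_effects = truth_eff, planted = pm$truth))
}

#' Specification for a synthetic single-cell dataset
#'
#' Emulates a cluster-labeled microglia single-cell experiment: a large
#' homeostatic cluster, a minority disease-associated cluster, plus
#' monocyte and lymphocyte clusters; negative-binomial counts per cluster
#' with per-gene means, a per-cell log-normal depth factor, and planted
#' marker shifts (fold changes on cluster means).
#'
#' @param n_cells Total cells, default 1602.
#' @param cluster_proportions Named proportions summing to 1; default
#'   homeostatic 0.75, disease 0.10, monocyte 0.10, lymphocyte 0.05.
#' @param base_means Named per-gene baseline negative-binomial means (all
#'   clusters); default: 7 signature genes at informative levels plus 293
#'   log-normal background genes.
#' @param marker_shifts data.frame with columns `gene`, `cluster`, `fold`:
#'   multiplicative shifts of that cluster's mean.
#' @param dispersion Negative-binomial size parameter, default 2.
#' @param depth_sdlog sd of the per-cell log-normal depth factor, default 0.3.
#' @param seed Integer seed.
#' @return List of class `synthetic_sc_spec`.
#' @export
synthetic_sc_spec <- function(n_cells = 1602L,
                              cluster_proportions = c(homeostatic = 0.75,
                                                      disease = 0.10,
                                                      monocyte = 0.10,
                                                      lymphocyte = 0.05),
                              base_means = NULL,
                              marker_shifts = NULL,
                              dispersion = 2.0, depth_sdlog = 0.3,
                              seed = 1L) {
  if (abs(sum(cluster_proportions) - 1) > 1e-8) {
    stopf("cluster proportions must sum to 1")
  }
  if (is.null(names(cluster_proportions))) stopf("cluster proportions must be named")
  if (any(cluster_proportions * n_cells < 1)) {
    stopf("cluster(s) with expected zero cells at n_cells = %d: %s", n_cells,
          paste(names(cluster_proportions)[cluster_proportions * n_cells < 1],
                collapse = ", "))
  }
  base_means <- base_means %||% default_sc_base_means()
  if (is.null(names(base_means)) || any(base_means < 0)) {
    stopf("base_means must be a named non-negative vector")
  }
  marker_shifts <- marker_shifts %||% data.frame(gene = character(0),
                                                 cluster = character(0),
                                                 fold = numeric(0))
  stopifnot(all(c("gene", "cluster", "fold") %in% names(marker_shifts)))
  if (any(marker_shifts$fold <= 0)) stopf("marker shift folds must be > 0")
  if (length(bad <- setdiff(marker_shifts$gene, names(base_means)))) {
    stopf("marker shift gene(s) absent from base_means: %s",
          paste(bad, collapse = ", "))
  }
  if (length(bad <- setdiff(marker_shifts$cluster,
                            names(cluster_proportions)))) {
    stopf("marker shift cluster(s) unknown: %s", paste(bad, collapse = ", "))
  }
  if (dispersion <= 0) stopf("dispersion must be > 0")
  structure(list(n_cells = as.integer(n_cells),
                 cluster_proportions = cluster_proportions,
                 base_means = base_means, marker_shifts = marker_shifts,
                 dispersion = dispersion, depth_sdlog = depth_sdlog,
                 seed = as.integer(seed)),
            class = "synthetic_sc_spec")
}

default_sc_base_means <- function(n_background = 293L) {
  sig <- c(CX3CR1 = 2.0, GPR34 = 1.5, GPR183 = 1.5, P2RY12 = 2.5,
           P2RY13 = 1.5, ADGRG1 = 2.0, CXCR4 = 0.8)
  ## fixed background levels: deterministic grid on a log scale, heavy tail
  bg <- exp(seq(log(0.05), log(3), length.out = n_background))
  names(bg) <- sprintf("BG%04d", seq_len(n_background))
  c(sig, bg)
}

#' Simulate a cluster-labeled single-cell dataset
#'
#' Cluster labels are drawn per cell from the spec proportions;
#' negative-binomial counts use the per-cluster shifted means scaled by a
#' per-cell depth factor; a deterministic pseudo-embedding places clusters
#' as separated Gaussian blobs (a stand-in for a precomputed t-SNE, clearly
#' synthetic). Reproducible from the seed.
#'
#' @param spec A [synthetic_sc_spec()].
#' @return List with `dataset` (an `sc_dataset`) and `truth` (marker shifts
#'   with expected contrast directions vs the homeostatic cluster).
#' @export
simulate_single_cell <- function(spec) {
  stopifnot(inherits(spec, "synthetic_sc_spec"))
  set.seed(spec$seed)
  clusters <- names(spec$cluster_proportions)
  labels <- sample(clusters, spec$n_cells, replace = TRUE,
                   prob = spec$cluster_proportions)
  genes <- names(spec$base_means)
  n_g <- length(genes)
  shift <- matrix(1.0, nrow = length(clusters), ncol = n_g,
                  dimnames = list(clusters, genes))
  ms <- spec$marker_shifts
  for (i in seq_len(nrow(ms))) {
    shift[ms$cluster[i], ms$gene[i]] <- ms$fold[i]
  }
  depth <- exp(stats::rnorm(spec$n_cells, sd = spec$depth_sdlog))
  mu <- (depth * shift[labels, , drop = FALSE]) *
    rep(spec$base_means, each = spec$n_cells)
  counts <- matrix(stats::rnbinom(spec$n_cells * n_g, mu = as.numeric(mu),
                                  size = spec$dispersion),
                   nrow = spec$n_cells,
                   dimnames = list(sprintf("CELL%05d", seq_len(spec$n_cells)),
                                   genes))
  centers <- matrix(c(0, 0, 8, 0, 0, 8, 8, 8), ncol = 2L, byrow = TRUE)
  centers <- centers[rep_len(seq_len(4L), length(clusters)), , drop = FALSE]
  rownames(centers) <- clusters
  emb <- centers[labels, , drop = FALSE] +
    matrix(stats::rnorm(2L * spec$n_cells), ncol = 2L)
  rownames(emb) <- rownames(counts)
  ds <- single_cell_dataset(Matrix::Matrix(counts, sparse = TRUE), labels,
                            embedding = emb)
  truth <- ms
  truth$expected_direction <- ifelse(truth$fold > 1, "up_in_a", "down_in_a")
  list(dataset = ds, truth = truth)
}
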