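## Exact nonparametric tests and regional differential analysis.
##
## Conventions fixed here (and relied on by the rest of the package):
##  - Wilcoxon signed-rank: zero differences dropped; |d| midranked; exact
##    two-sided p by full enumeration of the 2^n sign assignments for
##    n_effective <= 12, normal approximation with continuity and tie
##    correction above.
##  - Mann-Whitney: pooled midranks; exact two-sided p by enumeration of all
##    C(n+m, n) group labelings when n, m <= 8 and no tie spans the two
##    groups; normal approximation with tie and continuity correction
##    otherwise.
##  - Two-sided p = twice the smaller tail probability, capped at 1.

WILCOXON_EXACT_LIMIT <- 12L
MANNWHITNEY_EXACT_LIMIT <- 8L

test_result <- function(statistic, n_effective, p_value, method,
                        degenerate = FALSE) {
  structure(list(statistic = statistic, n_effective = n_effective,
                 p_value = p_value, method = method, sided = "two_sided",
                 degenerate = degenerate),
            class = "gpcr_test")
}

#' @export
print.gpcr_test <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic), ", n = ",
      x$n_effective, ", two-sided p = ", format(x$p_value),
      if (x$degenerate) " (degenerate)" else "", "\n", sep = "")
  invisible(x)
}

two_sided_from_tails <- function(lower, upper) min(1, 2 * min(lower, upper))

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped (classical zero-drop convention); absolute
#' differences receive midranks; the statistic is W+, the rank sum of
#' positive differences. For `n_effective` at most 12 the two-sided p-value
#' is exact, from the full enumeration of all sign assignments conditional
#' on the observed midranks; above that a normal approximation with
#' continuity and tie correction is used. All differences zero is not an
#' error: it returns p = 1 flagged degenerate.
#'
#' @param paired_differences Numeric vector of paired differences.
#' @return A test result list: `statistic` (W+), `n_effective`, `p_value`,
#'   `method`, `sided`, `degenerate`.
#' @export
wilcoxon_signed_rank <- function(paired_differences) {
  d <- paired_differences
  if (!length(d) || anyNA(d)) stopf("differences must be non-empty and non-missing")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(test_result(0, 0L, 1.0, "wilcoxon_signed_rank_exact",
                       degenerate = TRUE))
  }
  r <- rank(abs(d), ties.method = "average")
  w_plus <- sum(r[d > 0])
  if (n <= WILCOXON_EXACT_LIMIT) {
    ## distribution of W+ over all 2^n equally likely sign assignments
    dist <- 0
    for (ri in r) dist <- c(dist, dist + ri)
    tol <- 1e-9
    lower <- mean(dist <= w_plus + tol)
    upper <- mean(dist >= w_plus - tol)
    p <- two_sided_from_tails(lower, upper)
    return(test_result(w_plus, n, p, "wilcoxon_signed_rank_exact"))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  test_result(w_plus, n, p, "wilcoxon_signed_rank_normal")
}

#' Mann-Whitney U test for two independent groups
#'
#' Pooled values are midranked; the statistic is U for group A. The
#' two-sided p-value is exact (enumeration of all `choose(n + m, n)` group
#' labelings of the observed pooled midranks) when both groups have at most
#' 8 observations and no tied value spans the two groups; otherwise a normal
#' approximation with tie and continuity correction is used.
#'
#' @param group_a,group_b Numeric vectors (both non-empty).
#' @return A test result list as in [wilcoxon_signed_rank()]; `statistic`
#'   is U for `group_a`, `n_effective` the pooled sample size.
#' @export
mann_whitney_u <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stopf("both groups must be non-empty")
  if (anyNA(group_a) || anyNA(group_b)) stopf("groups must be non-missing")
  n <- length(group_a)
  m <- length(group_b)
  pooled <- c(group_a, group_b)
  r <- rank(pooled, ties.method = "average")
  u_a <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  cross_tie <- length(intersect(group_a, group_b)) > 0
  if (n <= MANNWHITNEY_EXACT_LIMIT && m <= MANNWHITNEY_EXACT_LIMIT &&
      !cross_tie) {
    combos <- utils::combn(n + m, n)
    u_all <- colSums(matrix(r[combos], nrow = n)) - n * (n + 1) / 2
    tol <- 1e-9
    lower <- mean(u_all <= u_a + tol)
    upper <- mean(u_all >= u_a - tol)
    p <- two_sided_from_tails(lower, upper)
    return(test_result(u_a, n + m, p, "mann_whitney_exact"))
  }
  N <- n + m
  mu <- n * m / 2
  tie_tab <- table(r)
  sigma2 <- n * m / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  if (sigma2 <= 0) {
    return(test_result(u_a, N, 1.0, "mann_whitney_normal", degenerate = TRUE))
  }
  z <- (u_a - mu - sign(u_a - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  test_result(u_a, N, p, "mann_whitney_normal")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate q-values over a panel of p-values.
#' Validates the (0, 1] domain and delegates to [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (anyNA(p_values) || any(p_values <= 0) || any(p_values > 1)) {
    stopf("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Log2 fold change with pseudocount
#'
#' `log2((mean_a + eps) / (mean_b + eps))`; the default pseudocount is half
#' the smallest nonzero mean among the inputs, so (0, 0) maps to 0 by
#' symmetry.
#'
#' @param mean_a,mean_b Non-negative mean expression values (vectorized).
#' @param pseudocount Additive stabilizer; `NULL` for the default.
#' @return log2 ratio(s).
#' @export
fold_change <- function(mean_a, mean_b, pseudocount = NULL) {
  if (any(mean_a < 0) || any(mean_b < 0)) stopf("means must be non-negative")
  nz <- c(mean_a, mean_b)
  nz <- nz[nz > 0]
  eps <- pseudocount %||% (if (length(nz)) min(nz) / 2 else 1e-8)
  log2((mean_a + eps) / (mean_b + eps))
}

#' Regional differential expression (white vs grey matter)
#'
#' Computes per-gene mean expression in each region, the log2 fold change
#' (WM over GM, shared pseudocount = half the smallest nonzero per-region
#' mean in the analysis), and a direction call at the fold-change threshold:
#' `WM_higher` when the fold change is at least `fc_threshold` with WM
#' above GM, symmetrically `GM_higher`, otherwise `none`. The direction call
#' is purely fold-change-based; hypothesis tests (paired Wilcoxon
#' signed-rank on per-donor differences when donors are matched and at
#' least 4 pairs exist, Mann-Whitney across samples otherwise) and
#' Benjamini-Hochberg q-values are reported alongside, not used to gate the
#' call.
#'
#' @param matrix An `expr_matrix` containing both regions' samples.
#' @param samples A [sample_table()] covering the matrix columns.
#' @param genes Genes to analyze (default: all genes in the matrix).
#' @param fc_threshold Linear fold-change threshold, default 2.
#' @param paired `TRUE`/`FALSE`/`NULL`; `NULL` (default) selects paired mode
#'   when every donor has exactly one WM and one GM sample.
#' @return data.frame of class `region_diff` with columns `gene`,
#'   `mean_WM`, `mean_GM`, `log2_fold_change`, `direction`, `p_value`,
#'   `q_value`, plus attributes `fc_threshold`, `paired`, `n_donors`.
#' @export
region_differential <- function(matrix, samples, genes = NULL,
                                fc_threshold = 2.0, paired = NULL) {
  stopifnot(inherits(matrix, "expr_matrix"))
  v <- matrix$values
  idx <- match(colnames(v), samples$sample_id)
  if (anyNA(idx)) {
    stopf("sample table is missing rows for: %s",
          paste(utils::head(colnames(v)[is.na(idx)], 5L), collapse = ", "))
  }
  meta <- samples[idx, , drop = FALSE]
  wm <- meta$region == "WM"
  gm <- meta$region == "GM"
  if (!any(wm) || !any(gm)) stopf("both WM and GM samples are required")
  genes <- genes %||% rownames(v)
  missing_genes <- setdiff(genes, rownames(v))
  if (length(missing_genes)) {
    stopf("genes absent from matrix: %s",
          paste(utils::head(missing_genes, 5L), collapse = ", "))
  }
  sub <- v[genes, , drop = FALSE]
  mean_wm <- rowMeans(sub[, wm, drop = FALSE])
  mean_gm <- rowMeans(sub[, gm, drop = FALSE])
  nz <- c(mean_wm, mean_gm)
  nz <- nz[nz > 0]
  eps <- if (length(nz)) min(nz) / 2 else 1e-8
  lfc <- fold_change(mean_wm, mean_gm, pseudocount = eps)
  thr <- log2(fc_threshold)
  direction <- ifelse(lfc >= thr, "WM_higher",
                      ifelse(lfc <= -thr, "GM_higher", "none"))

  wm_donors <- meta$donor_id[wm]
  gm_donors <- meta$donor_id[gm]
  donors <- sort(intersect(wm_donors, gm_donors))
  matched <- length(donors) > 0 && !anyNA(donors) &&
    !anyDuplicated(wm_donors) && !anyDuplicated(gm_donors) &&
    setequal(wm_donors, gm_donors)
  if (is.null(paired)) paired <- matched
  if (paired && !matched) {
    unmatched <- union(setdiff(wm_donors, gm_donors),
                       setdiff(gm_donors, wm_donors))
    stopf("paired analysis requested but donors are unmatched: %s",
          paste(utils::head(unique(c(unmatched,
                                     if (anyDuplicated(c(wm_donors, gm_donors)))
                                       "duplicated donor ids")), 8L),
                collapse = ", "))
  }
  p <- rep(NA_real_, length(genes))
  if (paired && length(donors) >= 4L) {
    wm_cols <- colnames(v)[wm][match(donors, wm_donors)]
    gm_cols <- colnames(v)[gm][match(donors, gm_donors)]
    for (i in seq_along(genes)) {
      diffs <- sub[i, wm_cols] - sub[i, gm_cols]
      p[i] <- wilcoxon_signed_rank(diffs)$p_value
    }
  } else if (!paired) {
    for (i in seq_along(genes)) {
      p[i] <- mann_whitney_u(sub[i, wm], sub[i, gm])$p_value
    }
  }
  q <- if (all(is.na(p))) p else bh_adjust(p)
  out <- data.frame(gene = genes, mean_WM = mean_wm, mean_GM = mean_gm,
                    log2_fold_change = lfc, direction = direction,
                    p_value = p, q_value = q,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, fc_threshold = fc_threshold, paired = paired,
            n_donors = length(donors),
            class = c("region_diff", "data.frame"))
}

#' Write a regional differential table with a JSON config sidecar
#'
#' @param result A `region_diff` data.frame.
#' @param tsv_path Output TSV path.
#' @param json_path Output path for the config echo.
#' @return Invisibly, `tsv_path`.
#' @export
write_region_diff <- function(result, tsv_path, json_path) {
  stopifnot(inherits(result, "region_diff"))
  body <- paste(result$gene,
                sprintf("%.6g", result$mean_WM),
                sprintf("%.6g", result$mean_GM),
                sprintf("%.6g", result$log2_fold_change),
                result$direction,
                ifelse(is.na(result$p_value), "NA",
                       sprintf("%.6g", result$p_value)),
                ifelse(is.na(result$q_value), "NA",
                       sprintf("%.6g", result$q_value)), sep = "\t")
  con <- file(tsv_path, open = "wb")
  writeLines(c(paste("gene", "mean_WM", "mean_GM", "log2FC", "direction",
                     "p", "q", sep = "\t"), body),
             con, sep = "\n", useBytes = TRUE)
  close(con)
  jsonlite::write_json(list(fc_threshold = attr(result, "fc_threshold"),
                            paired = attr(result, "paired"),
                            n_donors = attr(result, "n_donors")),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(tsv_path)
}
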