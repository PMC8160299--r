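#' Depth-normalize single-cell counts
#'
#' Per cell, counts are scaled to a fixed library size of 10,000 and
#' transformed with `log(1 + x)`. The transform is depth-invariant: doubling
#' all counts of a cell leaves its normalized vector unchanged. Cells with a
#' zero total count are excluded with a warning naming how many were
#' dropped; a dataset where every cell is zero is an error.
#'
#' @param dataset An `sc_dataset`.
#' @param scale_factor Target library size, default 1e4.
#' @return Cells-by-genes normalized matrix (sparse when the input is
#'   sparse), carrying only the retained cells.
#' @export
normalize_counts <- function(dataset, scale_factor = 1e4) {
  stopifnot(inherits(dataset, "sc_dataset"))
  counts <- dataset$counts
  totals <- Matrix::rowSums(counts)
  if (all(totals == 0)) stopf("all cells have zero total count")
  drop <- totals == 0
  if (any(drop)) {
    warnf("excluding %d cell(s) with zero total count", sum(drop))
    counts <- counts[!drop, , drop = FALSE]
    totals <- totals[!drop]
  }
  if (inherits(counts, "Matrix")) {
    scaled <- Matrix::Diagonal(x = scale_factor / totals) %*% counts
    scaled <- methods::as(scaled, "CsparseMatrix")
    scaled@x <- log1p(scaled@x)
    dimnames(scaled) <- dimnames(counts)
    scaled
  } else {
    log1p(counts / totals * scale_factor)
  }
}

sc_norm_and_labels <- function(dataset, scale_factor = 1e4) {
  norm <- normalize_counts(dataset, scale_factor)
  labels <- dataset$cluster_labels[match(rownames(norm),
                                         rownames(dataset$counts))]
  list(norm = norm, labels = labels)
}

#' Per-cluster summary of a gene panel
#'
#' For every (cluster, gene) pair: mean normalized expression, fraction of
#' cells expressing the gene (raw count > 0), and cluster size. Invariant to
#' cell ordering and to cluster label renaming. Panel genes absent from the
#' dataset are reported in a warning, not fatal.
#'
#' @param dataset An `sc_dataset`.
#' @param gene_panel Gene symbols to summarize (default: all genes).
#' @return data.frame with columns `cluster`, `gene`,
#'   `mean_normalized_expression`, `fraction_expressing`, `n_cells`.
#' @export
cluster_summary <- function(dataset, gene_panel = NULL) {
  stopifnot(inherits(dataset, "sc_dataset"))
  gene_panel <- gene_panel %||% colnames(dataset$counts)
  missing_genes <- setdiff(gene_panel, colnames(dataset$counts))
  if (length(missing_genes)) {
    warnf("panel gene(s) absent from dataset: %s",
          paste(missing_genes, collapse = ", "))
    gene_panel <- setdiff(gene_panel, missing_genes)
  }
  if (!length(gene_panel)) stopf("no panel genes present in dataset")
  nl <- sc_norm_and_labels(dataset)
  clusters <- sort(unique(nl$labels))
  n_cells <- table(factor(nl$labels, levels = clusters))
  if (any(n_cells == 0)) {
    stopf("empty cluster: %s", names(n_cells)[n_cells == 0][1L])
  }
  counts <- dataset$counts[rownames(nl$norm), gene_panel, drop = FALSE]
  norm <- nl$norm[, gene_panel, drop = FALSE]
  rows <- lapply(clusters, function(cl) {
    in_cl <- nl$labels == cl
    data.frame(cluster = cl, gene = gene_panel,
               mean_normalized_expression =
                 as.numeric(Matrix::colMeans(norm[in_cl, , drop = FALSE])),
               fraction_expressing =
                 as.numeric(Matrix::colMeans(counts[in_cl, , drop = FALSE] > 0)),
               n_cells = sum(in_cl),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Contrast a gene panel between two clusters
#'
#' Per gene: Mann-Whitney test on normalized expression across the cells of
#' the two clusters, log2 fold change of cluster means (pseudocount = half
#' the smallest nonzero cluster mean over the panel), Benjamini-Hochberg
#' q-values over the panel, and a direction call: `up_in_a` /
#' `down_in_a` when both the absolute fold change reaches `fc_threshold`
#' and q < `alpha`, otherwise `none`.
#'
#' @param dataset An `sc_dataset`.
#' @param cluster_a,cluster_b Cluster labels to contrast (A vs B).
#' @param gene_panel Genes to test (default: all).
#' @param fc_threshold Linear fold-change threshold, default 1.5.
#' @param alpha FDR level for the direction call, default 0.05.
#' @return data.frame of class `cluster_contrast` with columns `gene`,
#'   `mean_a`, `mean_b`, `log2_fold_change`, `p_value`, `q_value`,
#'   `direction`.
#' @export
contrast_clusters <- function(dataset, cluster_a, cluster_b,
                              gene_panel = NULL, fc_threshold = 1.5,
                              alpha = 0.05) {
  stopifnot(inherits(dataset, "sc_dataset"))
  gene_panel <- gene_panel %||% colnames(dataset$counts)
  missing_genes <- setdiff(gene_panel, colnames(dataset$counts))
  if (length(missing_genes)) {
    warnf("panel gene(s) absent from dataset: %s",
          paste(missing_genes, collapse = ", "))
    gene_panel <- setdiff(gene_panel, missing_genes)
  }
  nl <- sc_norm_and_labels(dataset)
  for (cl in c(cluster_a, cluster_b)) {
    if (!cl %in% nl$labels) stopf("cluster label absent from dataset: %s", cl)
  }
  in_a <- nl$labels == cluster_a
  in_b <- nl$labels == cluster_b
  norm <- nl$norm[, gene_panel, drop = FALSE]
  mean_a <- as.numeric(Matrix::colMeans(norm[in_a, , drop = FALSE]))
  mean_b <- as.numeric(Matrix::colMeans(norm[in_b, , drop = FALSE]))
  nz <- c(mean_a, mean_b)
  nz <- nz[nz > 0]
  eps <- if (length(nz)) min(nz) / 2 else 1e-8
  lfc <- fold_change(mean_a, mean_b, pseudocount = eps)
  p <- vapply(seq_along(gene_panel), function(i) {
    mann_whitney_u(as.numeric(norm[in_a, i]), as.numeric(norm[in_b, i]))$p_value
  }, numeric(1L))
  q <- bh_adjust(p)
  thr <- log2(fc_threshold)
  direction <- ifelse(abs(lfc) < thr | q >= alpha, "none",
                      ifelse(lfc > 0, "up_in_a", "down_in_a"))
  out <- data.frame(gene = gene_panel, mean_a = mean_a, mean_b = mean_b,
                    log2_fold_change = lfc, p_value = p, q_value = q,
                    direction = direction,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, cluster_a = cluster_a, cluster_b = cluster_b,
            fc_threshold = fc_threshold, alpha = alpha,
            class = c("cluster_contrast", "data.frame"))
}

#' Per-cell overlay table for one gene on a precomputed embedding
#'
#' Export table for plotting gene expression on a supplied 2-D embedding
#' (t-SNE/UMAP coordinates are inputs to this package, never computed by
#' it). Values equal the [normalize_counts()] output for that gene.
#'
#' @param dataset An `sc_dataset` with embedding coordinates.
#' @param gene Gene symbol to overlay.
#' @return data.frame with columns `cell`, `x`, `y`, `value`, `cluster`.
#' @export
embedding_overlay_table <- function(dataset, gene) {
  stopifnot(inherits(dataset, "sc_dataset"))
  if (is.null(dataset$embedding)) {
    stopf("dataset has no embedding; embeddings are inputs (e.g. a precomputed t-SNE), not computed here")
  }
  if (!gene %in% colnames(dataset$counts)) {
    stopf("gene absent from dataset: %s", gene)
  }
  nl <- sc_norm_and_labels(dataset)
  cells <- rownames(nl$norm)
  emb <- dataset$embedding[match(cells, rownames(dataset$counts)), ,
                           drop = FALSE]
  data.frame(cell = cells, x = emb[, 1L], y = emb[, 2L],
             value = as.numeric(nl$norm[, gene]),
             cluster = nl$labels,
             row.names = NULL, stringsAsFactors = FALSE)
}
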