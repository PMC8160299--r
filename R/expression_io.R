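#' Construct a bulk expression matrix object
#'
#' Container for a genes-by-samples non-negative expression matrix with its
#' unit (FPKM, TPM, or count), species, and dataset identity. For TPM
#' matrices, per-sample column sums are expected near 1e6; deviations beyond
#' 1% raise a validation warning (not an error) to tolerate gene-filtered
#' matrices.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids).
#' @param unit One of `"FPKM"`, `"TPM"`, `"count"`.
#' @param species `"human"` or `"mouse"`.
#' @param dataset_id Dataset identifier string.
#' @param region Optional region label (`"WM"`, `"GM"`, `"whole"`,
#'   `"other"`) describing the dataset as a whole; used by the rescue rule.
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, unit, species, dataset_id,
                              region = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("values must be a numeric matrix")
  }
  if (nrow(values) == 0L || ncol(values) == 0L) stopf("empty expression matrix")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("values must carry gene rownames and sample colnames")
  }
  if (anyNA(values)) stopf("expression matrix contains missing values")
  if (any(values < 0)) stopf("expression matrix contains negative values")
  if (anyDuplicated(rownames(values))) {
    stopf("duplicate gene_ids: %s",
          paste(unique(rownames(values)[duplicated(rownames(values))])[1:3],
                collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) stopf("duplicate sample_ids")
  unit <- match.arg(unit, UNITS)
  check_species(species)
  if (unit == "TPM") {
    cs <- colSums(values)
    off <- abs(cs - 1e6) / 1e6 > 0.01
    if (any(off)) {
      warnf("TPM column sums deviate >1%% from 1e6 for %d sample(s) (filtered matrix?)",
            sum(off))
    }
  }
  structure(list(values = values, unit = unit, species = species,
                 dataset_id = as.character(dataset_id), region = region),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix '", x$dataset_id, "': ", nrow(x$values), " genes x ",
      ncol(x$values), " samples [", x$unit, ", ", x$species,
      if (!is.null(x$region)) paste0(", ", x$region) else "", "]\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

detect_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a bulk expression matrix from delimited text
#'
#' First column gene symbols, header row sample ids; tab- or comma-delimited
#' (auto-detected from the file extension). Duplicate gene rows are
#' collapsed by summation with a warning reporting the number collapsed.
#' Non-numeric cells are a hard error citing the location. Row order of the
#' input is preserved (first occurrence for collapsed duplicates).
#'
#' @inheritParams expression_matrix
#' @param path Input file path.
#' @param id_map Optional two-column data.frame (`from`, `to`) translating
#'   row identifiers to gene symbols on read.
#' @return An `expr_matrix`.
#' @export
read_bulk_matrix <- function(path, unit, species, dataset_id,
                             region = NULL, id_map = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  sep <- detect_sep(path)
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (nrow(raw) == 0L || ncol(raw) < 2L) stopf("empty expression matrix in %s", path)
  genes <- raw[[1L]]
  if (!is.null(id_map)) {
    stopifnot(ncol(id_map) >= 2L)
    idx <- match(genes, id_map[[1L]])
    genes <- ifelse(is.na(idx), genes, id_map[[2L]][idx])
  }
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = dimnames(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("non-numeric value '%s' at data row %d, column '%s'",
          vals[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L],
          colnames(vals)[bad[1L, 2L]])
  }
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)
    stopf("missing value at data row %d, column '%s'", bad[1L, 1L],
          colnames(num)[bad[1L, 2L]])
  }
  if (anyDuplicated(genes)) {
    n_dup <- sum(duplicated(genes))
    num <- rowsum(num, group = genes, reorder = FALSE)
    genes <- rownames(num)
    warnf("collapsed %d duplicate gene row(s) by sum", n_dup)
  }
  rownames(num) <- genes
  expression_matrix(num, unit = unit, species = species,
                    dataset_id = dataset_id, region = region)
}

#' Write a bulk expression matrix to delimited text
#'
#' Deterministic output: columns in stored order, values formatted with
#' `%.6g`, UTF-8, LF line endings. Re-reading yields values equal within the
#' declared text precision; writing the same matrix twice yields
#' byte-identical files.
#'
#' @param matrix An `expr_matrix`.
#' @param path Output path (`.csv` for comma-delimited, otherwise tab).
#' @return Invisibly, `path`.
#' @export
write_bulk_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "expr_matrix"))
  v <- matrix$values
  if (ncol(v) == 0L) stopf("matrix has no samples")
  sep <- detect_sep(path)
  header <- paste(c("gene", colnames(v)), collapse = sep)
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(rownames(v)[i], sprintf("%.6g", v[i, ])), collapse = sep)
  }, character(1L))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Construct a sample metadata table
#'
#' @param sample_id Unique sample identifiers.
#' @param donor_id Donor identifiers (required for paired regional analyses).
#' @param region Per-sample region: `"WM"`, `"GM"`, `"whole"`, or `"other"`.
#' @param condition Per-sample condition: `"control"`, `"MS"`, or `"other"`.
#' @param species `"human"` or `"mouse"` (recycled).
#' @return A data.frame of class `sample_table`.
#' @export
sample_table <- function(sample_id, donor_id = NA_character_, region = "other",
                         condition = "control", species = "human") {
  n <- length(sample_id)
  if (anyDuplicated(sample_id)) stopf("duplicate sample_ids in sample table")
  region <- rep_len(region, n)
  condition <- rep_len(condition, n)
  if (!all(region %in% c("WM", "GM", "whole", "other"))) {
    stopf("region must be WM, GM, whole, or other")
  }
  if (!all(condition %in% c("control", "MS", "other"))) {
    stopf("condition must be control, MS, or other")
  }
  out <- data.frame(sample_id = as.character(sample_id),
                    donor_id = rep_len(as.character(donor_id), n),
                    region = region, condition = condition,
                    species = rep_len(species, n),
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_table", "data.frame")
  out
}

#' Construct a single-cell dataset object
#'
#' @param counts Cells-by-genes non-negative integer matrix; dense or sparse
#'   (`Matrix`). Rownames = cell barcodes, colnames = gene symbols.
#' @param cluster_labels Per-cell cluster label (e.g. `"homeostatic"`,
#'   `"disease"`, `"monocyte"`, `"lymphocyte"`).
#' @param embedding Optional per-cell 2-column (x, y) matrix of precomputed
#'   embedding coordinates (embeddings are inputs here, never computed).
#' @return An object of class `sc_dataset`.
#' @export
single_cell_dataset <- function(counts, cluster_labels, embedding = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stopf("counts must carry cell rownames and gene colnames")
  }
  x <- if (inherits(counts, "Matrix")) counts@x else counts
  if (any(x < 0)) stopf("counts contain negative values")
  if (any(x != round(x))) stopf("counts must be integral")
  if (length(cluster_labels) != nrow(counts)) {
    stopf("cluster_labels length (%d) != number of cells (%d)",
          length(cluster_labels), nrow(counts))
  }
  if (!is.null(embedding)) {
    embedding <- as.matrix(embedding)
    if (nrow(embedding) != nrow(counts) || ncol(embedding) != 2L) {
      stopf("embedding must be a cells x 2 coordinate matrix")
    }
  }
  structure(list(counts = counts,
                 cluster_labels = as.character(cluster_labels),
                 embedding = embedding),
            class = "sc_dataset")
}

#' @export
print.sc_dataset <- function(x, ...) {
  cat("sc_dataset: ", nrow(x$counts), " cells x ", ncol(x$counts), " genes; ",
      length(unique(x$cluster_labels)), " clusters",
      if (!is.null(x$embedding)) "; embedding present" else "", "\n", sep = "")
  invisible(x)
}

#' Read a single-cell dataset from a sidecar-file directory
#'
#' Expects `matrix.mtx` (Matrix Market coordinate; genes as rows, cells as
#' columns, the CellRanger convention), `features.tsv` (gene symbols),
#' `barcodes.tsv` (cell barcodes), `clusters.tsv` (barcode, label), and
#' optionally `embedding.tsv` (barcode, x, y).
#'
#' @param dir_path Directory containing the files.
#' @return An `sc_dataset` (counts stored cells-by-genes).
#' @export
read_single_cell <- function(dir_path) {
  need <- c("matrix.mtx", "features.tsv", "barcodes.tsv", "clusters.tsv")
  paths <- file.path(dir_path, need)
  miss <- need[!file.exists(paths)]
  if (length(miss)) stopf("missing file(s) in %s: %s", dir_path,
                          paste(miss, collapse = ", "))
  m <- Matrix::readMM(paths[1L])
  genes <- readLines(paths[2L])
  barcodes <- readLines(paths[3L])
  if (nrow(m) != length(genes)) {
    stopf("matrix.mtx has %d rows but features.tsv lists %d genes",
          nrow(m), length(genes))
  }
  if (ncol(m) != length(barcodes)) {
    stopf("matrix.mtx has %d columns but barcodes.tsv lists %d barcodes",
          ncol(m), length(barcodes))
  }
  if (any(m@x != round(m@x))) {
    stopf("matrix.mtx contains non-integer counts")
  }
  clu <- utils::read.table(file.path(dir_path, "clusters.tsv"), sep = "\t",
                           header = FALSE, colClasses = "character")
  idx <- match(barcodes, clu[[1L]])
  if (anyNA(idx)) {
    stopf("clusters.tsv is missing label(s) for barcode(s): %s",
          paste(utils::head(barcodes[is.na(idx)], 5L), collapse = ", "))
  }
  labels <- clu[[2L]][idx]
  emb <- NULL
  emb_path <- file.path(dir_path, "embedding.tsv")
  if (file.exists(emb_path)) {
    e <- utils::read.table(emb_path, sep = "\t", header = FALSE)
    eidx <- match(barcodes, as.character(e[[1L]]))
    if (anyNA(eidx)) stopf("embedding.tsv is missing coordinates for some barcodes")
    emb <- as.matrix(e[eidx, 2:3])
    dimnames(emb) <- list(barcodes, c("x", "y"))
  }
  counts <- Matrix::t(m)          # cells x genes
  counts <- methods::as(counts, "CsparseMatrix")
  dimnames(counts) <- list(barcodes, genes)
  single_cell_dataset(counts, labels, emb)
}

#' Write a single-cell dataset as a sidecar-file directory
#'
#' Inverse of [read_single_cell()]: writes `matrix.mtx` (genes as rows),
#' `features.tsv`, `barcodes.tsv`, `clusters.tsv` and, when present,
#' `embedding.tsv`. Output is deterministic for a given dataset.
#'
#' @param dataset An `sc_dataset`.
#' @param dir_path Output directory (created if needed).
#' @return Invisibly, `dir_path`.
#' @export
write_single_cell <- function(dataset, dir_path) {
  stopifnot(inherits(dataset, "sc_dataset"))
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  m <- Matrix::t(methods::as(Matrix::Matrix(dataset$counts, sparse = TRUE),
                             "CsparseMatrix"))
  Matrix::writeMM(m, file.path(dir_path, "matrix.mtx"))
  writeLines(colnames(dataset$counts), file.path(dir_path, "features.tsv"))
  writeLines(rownames(dataset$counts), file.path(dir_path, "barcodes.tsv"))
  writeLines(paste(rownames(dataset$counts), dataset$cluster_labels,
                   sep = "\t"),
             file.path(dir_path, "clusters.tsv"))
  if (!is.null(dataset$embedding)) {
    writeLines(paste(rownames(dataset$counts),
                     sprintf("%.6g", dataset$embedding[, 1L]),
                     sprintf("%.6g", dataset$embedding[, 2L]), sep = "\t"),
               file.path(dir_path, "embedding.tsv"))
  }
  invisible(dir_path)
}
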