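#' Load a curated GPCR / G-protein-signaling gene catalog
#'
#' Reads a comma-delimited catalog of receptor and signaling-molecule genes
#' with GRAFS family labels, category (receptor, G protein, GRK, arrestin),
#' aliases, and optional explicit cross-species ortholog overrides. The
#' package ships a frozen snapshot covering the microglia core signature
#' genes, further genes discussed in the microglia GPCRome literature, the
#' major signaling mediators, and a padding set spanning all five GRAFS
#' families; it does not claim completeness relative to the live
#' IUPHAR/Guide to Pharmacology database.
#'
#' File schema: header row with columns `species,symbol,aliases,family,
#' category,protein_name,ortholog`; aliases are semicolon-joined; `#` lines
#' are comments; a comment of the form `# version: <tag>` sets the catalog
#' version tag.
#'
#' @param path Path to the catalog file. Defaults to the shipped snapshot.
#' @return An object of class `gene_catalog`: a list with elements
#'   `records` (data.frame, one row per (species, gene)) and `version_tag`.
#' @examples
#' cat <- load_catalog()
#' lookup_gene(cat, "human", "ADGRG1")$family
#' @export
load_catalog <- function(path = system.file("extdata", "gpcr_catalog.csv",
                                            package = "gpcrome")) {
  if (!file.exists(path)) stopf("catalog file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  version_tag <- "unversioned"
  vline <- grep("^#\\s*version:", lines, value = TRUE)
  if (length(vline)) {
    version_tag <- trimws(sub("^#\\s*version:", "", vline[1L]))
  }
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  records <- utils::read.csv(text = lines[keep], header = TRUE,
                             colClasses = "character", check.names = FALSE)
  required <- c("species", "symbol", "aliases", "family", "category",
                "protein_name", "ortholog")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stopf("catalog is missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  ## line numbers of data rows in the original file (header is first kept line)
  data_lines <- line_no[-1L]

  bad_sp <- which(!records$species %in% SPECIES)
  if (length(bad_sp)) {
    stopf("unknown species token '%s' at line %d", records$species[bad_sp[1L]],
          data_lines[bad_sp[1L]])
  }
  bad_fam <- which(!records$family %in% FAMILIES)
  if (length(bad_fam)) {
    stopf("unknown family token '%s' at line %d", records$family[bad_fam[1L]],
          data_lines[bad_fam[1L]])
  }
  bad_cat <- which(!records$category %in% CATEGORIES)
  if (length(bad_cat)) {
    stopf("unknown category token '%s' at line %d", records$category[bad_cat[1L]],
          data_lines[bad_cat[1L]])
  }
  ## family = none iff category != gpcr
  viol <- which((records$category == "gpcr") == (records$family == "none"))
  if (length(viol)) {
    stopf("family/category mismatch for %s at line %d (family 'none' is for non-receptor categories only)",
          records$symbol[viol[1L]], data_lines[viol[1L]])
  }
  key <- paste(records$species, norm_symbol(records$symbol))
  dup <- key[duplicated(key)]
  if (length(dup)) {
    sym <- sub("^\\S+ ", "", dup[1L])
    stopf("duplicate catalog entry for symbol %s", sym)
  }
  ## alias collisions: an alias may not equal a primary symbol of another gene
  alias_list <- strsplit(records$aliases, ";", fixed = TRUE)
  for (i in seq_along(alias_list)) {
    al <- norm_symbol(trimws(alias_list[[i]]))
    al <- al[nzchar(al)]
    clash <- al[paste(records$species[i], al) %in% setdiff(key, key[i])]
    if (length(clash)) {
      stopf("alias %s of gene %s collides with a primary symbol", clash[1L],
            records$symbol[i])
    }
    alias_list[[i]] <- al
  }
  records$alias_norm <- vapply(alias_list, paste, "", collapse = ";")
  catalog <- structure(list(records = records, version_tag = version_tag),
                       class = "gene_catalog")
  catalog
}

#' @export
print.gene_catalog <- function(x, ...) {
  r <- x$records
  cat("gene_catalog (version ", x$version_tag, ")\n", sep = "")
  cat("  ", nrow(r), " records across ",
      length(unique(r$species)), " species\n", sep = "")
  gp <- r[r$category == "gpcr", ]
  tab <- table(factor(gp$family, levels = setdiff(FAMILIES, "none")), gp$species)
  print(tab)
  invisible(x)
}

#' Look up a gene record by species and symbol or alias
#'
#' Symbols are compared case-insensitively; an alias resolves to its primary
#' record. Returns `NULL` when no record matches.
#'
#' @param catalog A `gene_catalog`.
#' @param species `"human"` or `"mouse"`.
#' @param symbol Gene symbol or alias.
#' @return A one-row data.frame (the record) or `NULL`.
#' @export
lookup_gene <- function(catalog, species, symbol) {
  stopifnot(inherits(catalog, "gene_catalog"))
  check_species(species)
  r <- catalog$records
  q <- norm_symbol(symbol)
  hit <- which(r$species == species & norm_symbol(r$symbol) == q)
  if (!length(hit)) {
    aliases <- strsplit(r$alias_norm, ";", fixed = TRUE)
    hit <- which(r$species == species &
                   vapply(aliases, function(a) q %in% a, logical(1L)))
  }
  if (!length(hit)) return(NULL)
  if (length(hit) > 1L) stopf("lookup for %s/%s is ambiguous", species, symbol)
  r[hit, , drop = FALSE]
}

#' Map a gene symbol between human and mouse
#'
#' Default mapping is case-normalized symbol equality (e.g. human `P2RY12`
#' to mouse `P2ry12`); an explicit `ortholog` column in the catalog
#' overrides it for genes whose cross-species counterpart carries a
#' different symbol. When the target species has no counterpart, the
#' absent-marker `NA` is returned (not an error).
#'
#' @param symbol Gene symbol in `from_species`.
#' @param from_species,to_species Distinct species identifiers.
#' @param catalog A `gene_catalog`.
#' @return The counterpart symbol in `to_species` display casing, or
#'   `NA_character_` when no counterpart exists.
#' @export
map_ortholog <- function(symbol, from_species, to_species, catalog) {
  check_species(from_species)
  check_species(to_species)
  if (from_species == to_species) stopf("from_species and to_species must differ")
  rec <- lookup_gene(catalog, from_species, symbol)
  if (is.null(rec)) {
    stopf("symbol %s not in catalog for species %s", symbol, from_species)
  }
  if (nzchar(rec$ortholog)) {
    tgt <- lookup_gene(catalog, to_species, rec$ortholog)
    if (is.null(tgt)) return(NA_character_)
    return(tgt$symbol)
  }
  tgt <- lookup_gene(catalog, to_species, norm_symbol(rec$symbol))
  if (is.null(tgt)) return(NA_character_)
  tgt$symbol
}

#' GPCR gene symbols of a catalog for one species
#'
#' @param catalog A `gene_catalog`.
#' @param species `"human"` or `"mouse"`.
#' @return Character vector of receptor (category `gpcr`) symbols.
#' @export
catalog_gpcr_genes <- function(catalog, species) {
  stopifnot(inherits(catalog, "gene_catalog"))
  check_species(species)
  r <- catalog$records
  r$symbol[r$species == species & r$category == "gpcr"]
}

#' Per-family receptor counts of a catalog
#'
#' @param catalog A `gene_catalog`.
#' @param species Species to tabulate.
#' @return Named integer vector over the five GRAFS families.
#' @export
catalog_family_counts <- function(catalog, species) {
  r <- catalog$records
  gp <- r[r$species == species & r$category == "gpcr", ]
  table(factor(gp$family, levels = setdiff(FAMILIES, "none")))
}
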