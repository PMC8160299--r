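## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

SPECIES <- c("human", "mouse")
FAMILIES <- c("rhodopsin", "adhesion", "glutamate", "secretin", "frizzled", "none")
CATEGORIES <- c("gpcr", "g_protein", "grk", "arrestin")
UNITS <- c("FPKM", "TPM", "count")
TIER_LEVELS <- c("below_cutoff", "low", "medium", "high")

check_species <- function(species) {
  if (length(species) != 1L || !species %in% SPECIES) {
    stop("species must be one of: ", paste(SPECIES, collapse = ", "), call. = FALSE)
  }
  species
}

norm_symbol <- function(x) toupper(x)

## Display casing: human symbols all-caps, mouse first-letter-caps (HGNC/MGI).
display_symbol <- function(symbol, species) {
  up <- toupper(symbol)
  if (species == "mouse") {
    paste0(substr(up, 1L, 1L), tolower(substr(up, 2L, nchar(up))))
  } else {
    up
  }
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == round(x) && x >= 0

#' Derive a stream-specific sub-seed from a master seed
#'
#' Deterministic arithmetic derivation that keeps the result inside the
#' 32-bit integer range; used to give every simulated dataset of a scenario
#' its own independent seed while staying reproducible from one master
#' seed.
#'
#' @param seed Integer master seed.
#' @param stream Integer stream index.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stream) {
  ## double arithmetic: intermediate products stay exact below 2^53
  as.integer((as.numeric(seed) * 1103 + as.numeric(stream) * 12289) %%
               2147483647)
}
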