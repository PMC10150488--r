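#' Normalize entity identifiers
#'
#' Identifiers from the source databases (HMDD disease names, miRTarBase
#' miRNA names, DisGeNET gene symbols) come in inconsistent case and
#' spacing.  Normalization is deliberately mechanical -- lowercase, trim,
#' collapse internal whitespace -- with no fuzzy matching; genuine name
#' variants are resolved through an explicit two-column mapping table
#' (raw identifier, canonical identifier) accepted by every reader.
#'
#' @param ids Character vector of raw identifiers.
#' @param mapping Optional data frame with columns `raw` and `canonical`
#'   (applied after mechanical normalization of both sides).
#' @return Character vector of normalized identifiers.
#' @export
#' @examples
#' normalize_ids(c("  hsa-miR-21 ", "HSA-MIR-21"))
normalize_ids <- function(ids, mapping = NULL) {
  out <- tolower(trimws(as.character(ids)))
  out <- gsub("[[:space:]]+", " ", out)
  if (!is.null(mapping)) {
    stopifnot(all(c("raw", "canonical") %in% names(mapping)))
    raw <- normalize_ids(mapping$raw)
    canonical <- normalize_ids(mapping$canonical)
    hit <- match(out, raw)
    out[!is.na(hit)] <- canonical[hit[!is.na(hit)]]
  }
  out
}

#' Build an entity registry
#'
#' A registry fixes a deterministic (lexicographic) ordering of unique
#' normalized identifiers so that matrix row/column layouts are
#' reproducible across runs and machines.
#'
#' @param ids Character vector of (already normalized) identifiers.
#' @param kind One of `"miRNA"`, `"disease"`, `"gene"`.
#' @return An object of class `entity_registry` with fields `kind`, `ids`
#'   (sorted unique identifiers) and `index` (named integer vector,
#'   identifier to 1-based position).
#' @export
entity_registry <- function(ids, kind = c("miRNA", "disease", "gene")) {
  kind <- match.arg(kind)
  ids <- sort(unique(as.character(ids)), method = "radix")
  structure(
    list(kind = kind, ids = ids,
         index = stats::setNames(seq_along(ids), ids)),
    class = "entity_registry"
  )
}

#' @export
length.entity_registry <- function(x) length(x$ids)

#' @export
print.entity_registry <- function(x, ...) {
  cat("<entity_registry> kind=", x$kind, " n=", length(x$ids), "\n", sep = "")
  invisible(x)
}

registry_identical <- function(a, b) {
  identical(a$ids, b$ids)
}
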