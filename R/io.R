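#' Read a miRNA-disease association list
#'
#' Parses a two-column TSV of known associations (miRNA identifier,
#' disease identifier), e.g. an HMDD v2.0 export, into a binary adjacency
#' matrix `A` (rows = miRNAs, columns = diseases).  Duplicate pairs after
#' identifier normalization collapse to a single 1-entry, so the number
#' of ones in `A` equals the number of distinct associations.
#'
#' @param path Path to a TSV file; lines starting with `#` are skipped.
#' @param mapping Optional identifier mapping table, see [normalize_ids()].
#' @return An `association_table`: list with `mirnas` and `diseases`
#'   registries, the binary matrix `A`, and a `pairs` tibble of the
#'   distinct associations.
#' @export
read_associations <- function(path, mapping = NULL) {
  tab <- read_two_column_tsv(path)
  if (nrow(tab) == 0L) abort(paste0("no associations parsed from '", path, "'"))
  pairs <- distinct(tibble(
    mirna = normalize_ids(tab[[1]], mapping),
    disease = normalize_ids(tab[[2]], mapping)
  ))
  association_table(pairs)
}

#' Construct an association table from a pair data frame
#'
#' @param pairs Data frame with columns `mirna` and `disease` (assumed
#'   normalized); duplicates are dropped.
#' @param mirna_ids,disease_ids Optional identifier vectors fixing the
#'   registries explicitly (superset of the identifiers in `pairs`); use
#'   this to keep entities with zero known associations in scope.
#' @return An `association_table`.
#' @export
association_table <- function(pairs, mirna_ids = NULL, disease_ids = NULL) {
  pairs <- distinct(as_tibble(pairs[, c("mirna", "disease")]))
  mirnas <- entity_registry(c(pairs$mirna, mirna_ids), "miRNA")
  diseases <- entity_registry(c(pairs$disease, disease_ids), "disease")
  A <- matrix(0L, nrow = length(mirnas), ncol = length(diseases),
              dimnames = list(mirnas$ids, diseases$ids))
  A[cbind(mirnas$index[pairs$mirna], diseases$index[pairs$disease])] <- 1L
  structure(list(mirnas = mirnas, diseases = diseases, A = A, pairs = pairs),
            class = "association_table")
}

#' @export
print.association_table <- function(x, ...) {
  cat("<association_table> ", nrow(x$A), " miRNAs x ", ncol(x$A),
      " diseases, ", sum(x$A), " known associations\n", sep = "")
  invisible(x)
}

#' Read an entity-to-gene interaction list
#'
#' Parses a two-column TSV of (entity identifier, gene identifier) pairs:
#' miRNA-target interactions (miRTarBase style) or disease-gene
#' interactions (DisGeNET style).  Duplicate pairs are collapsed; the
#' deduplicated pair count defines the corpus size `N` used by the
#' entropy computation.
#'
#' @param path Path to a TSV file; `#` lines are skipped.
#' @param entity_kind `"miRNA"` or `"disease"`.
#' @param mapping Optional identifier mapping table, see [normalize_ids()].
#' @return An `interaction_table`: list with `entity_kind`, a `pairs`
#'   tibble (`entity`, `gene`), and `entities`/`genes` registries.
#' @export
read_interactions <- function(path, entity_kind = c("miRNA", "disease"),
                              mapping = NULL) {
  entity_kind <- match.arg(entity_kind)
  tab <- read_two_column_tsv(path)
  pairs <- distinct(tibble(
    entity = normalize_ids(tab[[1]], mapping),
    gene = normalize_ids(tab[[2]], mapping)
  ))
  interaction_table(pairs, entity_kind)
}

#' Construct an interaction table from a pair data frame
#'
#' @param pairs Data frame with columns `entity` and `gene`.
#' @param entity_kind `"miRNA"` or `"disease"`.
#' @return An `interaction_table`.
#' @export
interaction_table <- function(pairs, entity_kind = c("miRNA", "disease")) {
  entity_kind <- match.arg(entity_kind)
  pairs <- distinct(as_tibble(pairs[, c("entity", "gene")]))
  structure(
    list(entity_kind = entity_kind, pairs = pairs,
         entities = entity_registry(pairs$entity,
                                    if (entity_kind == "miRNA") "miRNA" else "disease"),
         genes = entity_registry(pairs$gene, "gene")),
    class = "interaction_table"
  )
}

#' @export
print.interaction_table <- function(x, ...) {
  cat("<interaction_table> kind=", x$entity_kind, " ",
      length(x$entities), " entities, ", length(x$genes), " genes, ",
      nrow(x$pairs), " interactions\n", sep = "")
  invisible(x)
}

#' Read a square similarity matrix
#'
#' Reads a TSV whose header row and first column carry the same entity
#' identifiers (the layout of the precomputed disease semantic-similarity
#' matrix).  The matrix must be square and symmetric; values outside
#' \[0, 1\] by more than `1e-9` trigger a warning and all values are
#' clipped into \[0, 1\].  Tiny asymmetries (at most `1e-9`) are
#' symmetrized; larger ones are an error.
#'
#' @param path Path to the TSV file.
#' @param mapping Optional identifier mapping table.
#' @return A numeric matrix with normalized identifiers as dimnames.
#' @export
read_similarity_matrix <- function(path, mapping = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: '", path, "'"))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) < 2L) abort("similarity matrix file has no data rows")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- normalize_ids(cells[[1]][-1], mapping)
  body <- cells[-1]
  row_ids <- normalize_ids(vapply(body, `[`, character(1), 1L), mapping)
  if (length(body) != length(header)) {
    abort("similarity matrix is not square: header/row count mismatch")
  }
  if (!identical(row_ids, header)) {
    abort("similarity matrix header and first column identifiers differ")
  }
  vals <- t(vapply(body, function(r) as.numeric(r[-1]), numeric(length(header))))
  if (anyNA(vals)) abort("similarity matrix contains non-numeric entries")
  dimnames(vals) <- list(row_ids, header)
  gap <- max(abs(vals - t(vals)))
  if (gap > 1e-9) {
    abort(sprintf("similarity matrix is asymmetric (max |a_ij - a_ji| = %.3g)", gap))
  }
  vals <- (vals + t(vals)) / 2
  out_of_range <- max(0, max(vals) - 1, -min(vals))
  if (out_of_range > 1e-9) {
    warn(sprintf("similarity values outside [0, 1] by up to %.3g; clipping", out_of_range))
  }
  pmin(pmax(vals, 0), 1)
}

#' Write a square similarity matrix
#'
#' Writes the TSV layout read back by [read_similarity_matrix()], with
#' full double precision so a write/read round trip reproduces values to
#' well below `1e-12`.
#'
#' @param m Numeric matrix with identifier dimnames.
#' @param path Output path.
#' @param header_lines Optional `#`-prefixed provenance lines.
#' @return Invisibly, `path`.
#' @export
write_similarity_matrix <- function(m, path, header_lines = character()) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), !is.null(rownames(m)))
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header_lines,
               paste(c("id", colnames(m)), collapse = "\t"), rows), path)
  invisible(path)
}

#' Write a ranked prediction table
#'
#' Sorts records by descending score, breaking ties lexicographically on
#' (miRNA, disease) so output is deterministic, assigns 1-based ranks
#' over the sorted order, and writes a TSV shaped like the case-study
#' tables (rank, miRNA, disease, score, known flag).
#'
#' @param records Data frame with columns `mirna`, `disease`, `score` and
#'   optionally `known` (logical).
#' @param path Output path.
#' @param header_lines Optional `#`-prefixed provenance lines.
#' @return Invisibly, the sorted tibble that was written (with `rank`).
#' @export
write_rankings <- function(records, path, header_lines = character()) {
  records <- as_tibble(records)
  if (!"known" %in% names(records)) records$known <- FALSE
  if (nrow(records) > 0 && any(!is.finite(records$score))) {
    abort("ranking scores must be finite")
  }
  out <- rank_records(records)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(header_lines, con)
  writeLines("rank\tmirna\tdisease\tscore\tknown", con)
  if (nrow(out) > 0) {
    writeLines(sprintf("%d\t%s\t%s\t%.17g\t%s", out$rank, out$mirna,
                       out$disease, out$score, out$known), con)
  }
  invisible(out)
}

rank_records <- function(records) {
  out <- arrange(as_tibble(records), dplyr::desc(.data$score),
                 .data$mirna, .data$disease)
  out$rank <- seq_len(nrow(out))
  out[, c("rank", setdiff(names(out), "rank"))]
}

# Shared two-column TSV reader: skips '#' comments and blank lines,
# reports 1-based file line numbers on malformed rows.
read_two_column_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: '", path, "'"))
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  cells <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(cells) < 2L)
  if (length(bad)) {
    abort(sprintf("malformed row at line %d of '%s': expected >= 2 tab-separated fields",
                  which(keep)[bad[1]], path))
  }
  tibble(V1 = vapply(cells, `[`, character(1), 1L),
         V2 = vapply(cells, `[`, character(1), 2L))
}
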