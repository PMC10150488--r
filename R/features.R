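#' Structural features of one miRNA-disease pair
#'
#' Seventeen hand-crafted descriptors: for the miRNA, its target-gene
#' count (f1) and density (f2, count over the distinct genes in the miRNA
#' interaction corpus), the mean (f3) and population variance (f4) of its
#' similarity-matrix row with the self entry excluded, and the mean
#' similarity of its top-ranked neighbour groups (f5-f8: ranks 1-50,
#' 51-100, 101-150, 151-200 by default); f9-f16 are the analogous
#' disease descriptors over `SD`; f17 is the number of genes shared by
#' the miRNA's target set and the disease's gene set.
#'
#' When fewer than `top_k` comparators exist (always true for small
#' registries), the `K = min(top_k, n - 1)` ranked neighbours are split
#' into 4 contiguous groups of `ceiling(K / 4)`; an empty group
#' contributes 0.  Similarity ties are broken by ascending entity index
#' for determinism.
#'
#' @param i,j 1-based miRNA and disease indices into `SM` / `SD`.
#' @param SM,SD Similarity matrices (see [functional_similarity()]).
#' @param mirna_corpus,disease_corpus Interaction corpora
#'   (see [build_corpus()]).
#' @param top_k Number of top-similar neighbours considered.
#' @param group_size Neighbours averaged per group.
#' @return Named numeric vector of length 17 (`f1` ... `f17`).
#' @export
structural_features <- function(i, j, SM, SD, mirna_corpus, disease_corpus,
                                top_k = 200, group_size = 50) {
  pairs <- tibble(mirna = rownames(SM)[i], disease = rownames(SD)[j])
  drop(structural_feature_matrix(pairs, SM, SD, mirna_corpus, disease_corpus,
                                 top_k = top_k, group_size = group_size))
}

# All-pairs version: one 8-feature block per distinct miRNA and disease,
# plus the shared-gene count from an incidence-matrix product.
structural_feature_matrix <- function(pairs, SM, SD, mirna_corpus,
                                      disease_corpus, top_k = 200,
                                      group_size = 50) {
  mb <- entity_feature_block(SM, mirna_corpus, top_k, group_size)
  db <- entity_feature_block(SD, disease_corpus, top_k, group_size)
  shared <- shared_gene_counts(mirna_corpus, disease_corpus)
  out <- cbind(mb[pairs$mirna, , drop = FALSE],
               db[pairs$disease, , drop = FALSE],
               shared_count_lookup(shared, pairs$mirna, pairs$disease))
  colnames(out) <- paste0("f", 1:17)
  rownames(out) <- NULL
  out
}

# Per-entity 8-vector: gene count, density, row mean/population variance
# (self excluded), and 4 top-neighbour group means.
entity_feature_block <- function(S, corpus, top_k, group_size) {
  n <- nrow(S)
  ids <- rownames(S)
  out <- matrix(0, nrow = n, ncol = 8, dimnames = list(ids, NULL))
  K <- min(top_k, n - 1L)
  gs <- if (K >= top_k) group_size else ceiling(K / 4)
  for (idx in seq_len(n)) {
    gset <- unique(corpus_set(corpus, ids[idx]))
    out[idx, 1] <- length(gset)
    out[idx, 2] <- length(gset) / corpus$n_genes
    if (n > 1L) {
      row <- S[idx, -idx]
      out[idx, 3] <- mean(row)
      out[idx, 4] <- mean((row - mean(row))^2)
      ord <- order(-row, seq_along(row))
      vals <- row[ord][seq_len(K)]
      for (g in 1:4) {
        lo <- (g - 1L) * gs + 1L
        if (lo <= K) out[idx, 4 + g] <- mean(vals[lo:min(g * gs, K)])
      }
    }
  }
  out
}

shared_gene_counts <- function(mirna_corpus, disease_corpus) {
  common <- intersect(names(mirna_corpus$p), names(disease_corpus$p))
  mids <- names(mirna_corpus$sets)
  dids <- names(disease_corpus$sets)
  Bm <- matrix(0, length(mids), length(common), dimnames = list(mids, common))
  Bd <- matrix(0, length(dids), length(common), dimnames = list(dids, common))
  for (e in mids) {
    g <- intersect(unique(mirna_corpus$sets[[e]]), common)
    if (length(g)) Bm[e, g] <- 1
  }
  for (e in dids) {
    g <- intersect(unique(disease_corpus$sets[[e]]), common)
    if (length(g)) Bd[e, g] <- 1
  }
  counts <- Bm %*% t(Bd)
  # entities absent from a corpus share no genes with anything
  counts
}

# Shared-gene count with a lookup that tolerates missing entities.
shared_count_lookup <- function(shared, mirna, disease) {
  ok_m <- mirna %in% rownames(shared)
  ok_d <- disease %in% colnames(shared)
  out <- numeric(length(mirna))
  idx <- ok_m & ok_d
  if (any(idx)) out[idx] <- shared[cbind(mirna[idx], disease[idx])]
  out
}

#' Raw similarity-row encoding of miRNA-disease pairs
#'
#' Each pair (i, j) is encoded as the concatenation of row i of the
#' miRNA similarity matrix and row j of the disease similarity matrix,
#' width `m + d`.  Over all m x d pairs this is the initial sample set
#' that PCA subsequently reduces.
#'
#' @param pairs Data frame with columns `mirna` and `disease`
#'   (identifiers present in the matrix dimnames).
#' @param SM,SD Similarity matrices.
#' @return Numeric matrix, one row per pair.
#' @export
encode_raw_samples <- function(pairs, SM, SD) {
  pairs <- as_tibble(pairs)
  bad <- !(pairs$mirna %in% rownames(SM)) | !(pairs$disease %in% rownames(SD))
  if (any(bad)) abort("pair references an entity absent from the similarity matrices")
  out <- cbind(SM[pairs$mirna, , drop = FALSE],
               SD[pairs$disease, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' All miRNA-disease pairs of an association table
#'
#' @param assoc An `association_table`.
#' @return Tibble with columns `mirna`, `disease`, `label` (the entry of
#'   the adjacency matrix), ordered miRNA-major.
#' @export
all_pairs <- function(assoc) {
  tibble(
    mirna = rep(rownames(assoc$A), times = ncol(assoc$A)),
    disease = rep(colnames(assoc$A), each = nrow(assoc$A)),
    label = as.integer(assoc$A)
  )[order(rep(seq_len(nrow(assoc$A)), times = ncol(assoc$A)),
          rep(seq_len(ncol(assoc$A)), each = nrow(assoc$A))), ]
}

#' Fit per-block PCA models on the similarity rows
#'
#' One PCA model per block (miRNA, disease), fitted on the unique rows of
#' the corresponding similarity matrix -- the m (resp. d) distinct row
#' vectors that every sample's block is drawn from.  The component count
#' is the smallest k whose cumulative explained-variance fraction reaches
#' `variance_threshold` (default 0.80).  Loadings are sign-fixed so each
#' component's largest-magnitude coordinate is positive, making the
#' encoding bit-reproducible.
#'
#' @param SM,SD Similarity matrices.
#' @param variance_threshold Fraction of variance to retain, in (0, 1\].
#' @return List with elements `mirna` and `disease`, each a `pca_model`
#'   (fields `block`, `rotation`, `center`, `n_components`,
#'   `explained_fraction`, `sdev`).
#' @export
fit_block_pca <- function(SM, SD, variance_threshold = 0.8) {
  if (!is.numeric(variance_threshold) || length(variance_threshold) != 1 ||
      is.na(variance_threshold) || variance_threshold <= 0 ||
      variance_threshold > 1) {
    abort("`variance_threshold` must be a single number in (0, 1]")
  }
  list(mirna = fit_pca_block(SM, "miRNA", variance_threshold),
       disease = fit_pca_block(SD, "disease", variance_threshold))
}

fit_pca_block <- function(S, block, threshold) {
  pc <- prcomp(S, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  total <- sum(ev)
  if (total < 1e-300) {                     # degenerate: constant rows
    n_comp <- 1L
    frac <- 1
  } else {
    rank_num <- max(1L, sum(ev > total * 1e-12))   # numerical rank
    cumfrac <- cumsum(ev) / total
    n_comp <- min(which(cumfrac >= threshold - 1e-12)[1], rank_num)
    frac <- cumfrac[n_comp]
  }
  rot <- pc$rotation[, seq_len(n_comp), drop = FALSE]
  for (k in seq_len(ncol(rot))) {           # sign convention
    pivot <- which.max(abs(rot[, k]))
    if (rot[pivot, k] < 0) rot[, k] <- -rot[, k]
  }
  structure(
    list(block = block, rotation = rot, center = pc$center,
         n_components = n_comp, explained_fraction = frac, sdev = pc$sdev),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model> block=", x$block, " components=", x$n_components,
      sprintf(" explained=%.3f\n", x$explained_fraction), sep = "")
  invisible(x)
}

pca_transform <- function(model, rows) {
  sweep(rows, 2, model$center, "-") %*% model$rotation
}

#' Assemble the final per-pair feature table
#'
#' Each row is the PCA-reduced miRNA similarity row, the PCA-reduced
#' disease similarity row, and the 17 structural features, in that order;
#' total width = miRNA components + disease components + 17.
#'
#' @param pairs Data frame with columns `mirna`, `disease`.
#' @param labels Integer/logical vector (0/1) or `NULL` for unlabeled
#'   candidate pairs.
#' @param SM,SD Similarity matrices.
#' @param pca Output of [fit_block_pca()].
#' @param mirna_corpus,disease_corpus Interaction corpora.
#' @param top_k,group_size Structural-feature parameters, see
#'   [structural_features()].
#' @return A `feature_table`: list with `pairs` (tibble `mirna`,
#'   `disease`, `label`), the numeric matrix `x`, and `block_bounds`
#'   (column spans of the three blocks).
#' @export
assemble_feature_table <- function(pairs, labels, SM, SD, pca,
                                   mirna_corpus, disease_corpus,
                                   top_k = 200, group_size = 50) {
  pairs <- as_tibble(pairs)[, c("mirna", "disease")]
  if (is.null(labels)) {
    labels <- rep(NA_integer_, nrow(pairs))
  } else if (length(labels) != nrow(pairs)) {
    abort("`labels` length must match the number of pairs")
  }
  if (anyDuplicated(paste(pairs$mirna, pairs$disease, sep = "\r"))) {
    abort("duplicate (miRNA, disease) pairs in feature table")
  }
  m_pc <- pca_transform(pca$mirna, SM[pairs$mirna, rownames(SM), drop = FALSE])
  d_pc <- pca_transform(pca$disease, SD[pairs$disease, rownames(SD), drop = FALSE])
  sf <- structural_feature_matrix(pairs, SM, SD, mirna_corpus, disease_corpus,
                                  top_k = top_k, group_size = group_size)
  x <- cbind(m_pc, d_pc, sf)
  a <- ncol(m_pc); b <- ncol(d_pc)
  colnames(x) <- c(paste0("pcm", seq_len(a)), paste0("pcd", seq_len(b)),
                   paste0("f", 1:17))
  rownames(x) <- NULL
  structure(
    list(pairs = mutate(pairs, label = as.integer(labels)), x = x,
         block_bounds = list(mirna = seq_len(a), disease = a + seq_len(b),
                             structural = a + b + 1:17)),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$x), " pairs x ", ncol(x$x), " features (",
      length(x$block_bounds$mirna), " miRNA PC + ",
      length(x$block_bounds$disease), " disease PC + 17 structural)\n",
      sep = "")
  invisible(x)
}

#' @describeIn assemble_feature_table Tidy view: one row per pair with
#'   feature columns.
#' @param x A `feature_table`.
#' @param ... Unused.
#' @export
tidy.feature_table <- function(x, ...) {
  dplyr::bind_cols(x$pairs, as_tibble(x$x))
}
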