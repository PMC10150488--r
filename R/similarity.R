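#' Build an interaction corpus
#'
#' The corpus summarizes one entity-to-gene interaction table: the set of
#' target genes per entity, the total deduplicated interaction count `N`,
#' and per-gene occurrence counts `n(t)` across all entities, giving the
#' empirical gene frequency `p(t) = n(t) / N`.  These global frequencies
#' weight the information-entropy terms of the set-similarity measure.
#'
#' @param interactions An `interaction_table` (see [read_interactions()]).
#' @return An `interaction_corpus`: list with `sets` (named list,
#'   entity -> character vector of genes), `N`, `freq`, `p`, and
#'   `n_genes` (distinct genes in the corpus, the density denominator of
#'   the structural features).
#' @export
build_corpus <- function(interactions) {
  pairs <- distinct(as_tibble(interactions$pairs))
  if (nrow(pairs) == 0L) abort("empty interaction corpus")
  N <- nrow(pairs)
  freq_tab <- table(pairs$gene)
  freq <- stats::setNames(as.integer(freq_tab), names(freq_tab))
  sets <- split(pairs$gene, pairs$entity)
  structure(
    list(sets = sets, N = N, freq = freq, p = freq / N,
         n_genes = length(freq), entity_kind = interactions$entity_kind),
    class = "interaction_corpus"
  )
}

#' @export
print.interaction_corpus <- function(x, ...) {
  cat("<interaction_corpus> ", length(x$sets), " entities, ", x$n_genes,
      " genes, N=", x$N, "\n", sep = "")
  invisible(x)
}

corpus_set <- function(corpus, entity) {
  s <- corpus$sets[[entity]]
  if (is.null(s)) character() else s
}

#' Information entropy of a gene set
#'
#' For a gene set T, returns `H(T) = sum over t in T of -p(t) log2 p(t)`
#' where `p(t)` is the gene's global frequency in the interaction corpus.
#' Every term is non-negative (p <= 1), so H is monotone under set
#' inclusion.  The empty set has entropy 0, as does a set whose only
#' member occurs in every interaction (p = 1).
#'
#' @param corpus An `interaction_corpus`.
#' @param genes Character vector (treated as a set) of gene identifiers.
#'   Genes absent from the corpus have no defined frequency and are
#'   ignored with a warning.
#' @return Non-negative entropy in bits.
#' @export
set_entropy <- function(corpus, genes) {
  genes <- unique(as.character(genes))
  p <- corpus$p[genes]
  if (anyNA(p)) {
    warn(sprintf("%d gene(s) absent from the interaction corpus ignored",
                 sum(is.na(p))))
    p <- p[!is.na(p)]
  }
  if (length(p) == 0L) return(0)
  sum(-p * log2(p))
}

#' Normalized-mutual-information similarity of two gene sets
#'
#' `2 * H(A intersect B) / (H(A) + H(B))`, with the intersection entropy
#' weighted by the same global corpus frequencies as the marginals.
#' Since `H(A intersect B) <= min(H(A), H(B))`, the value lies in
#' \[0, 1\]; it is 1 for identical sets with positive entropy and 0 for
#' disjoint sets.  When `H(A) + H(B) = 0` (both sets empty or all member
#' genes ubiquitous) the similarity is defined as 0, so unannotated
#' entities carry no signal.
#'
#' @param corpus An `interaction_corpus`.
#' @param set_a,set_b Character vectors of gene identifiers.
#' @return Similarity in \[0, 1\].
#' @export
nmi_similarity <- function(corpus, set_a, set_b) {
  denom <- set_entropy(corpus, set_a) + set_entropy(corpus, set_b)
  if (denom == 0) return(0)
  2 * set_entropy(corpus, intersect(set_a, set_b)) / denom
}

#' All-pairs functional similarity matrix
#'
#' Computes the NMI set similarity between every pair of registry
#' entities from their corpus gene sets.  Entities present in the
#' registry but missing from the corpus (no annotated targets) get an
#' empty set, hence a zero row and column -- including the diagonal, so
#' they contribute no fake self-signal.
#'
#' Implementation note: with `B` the entity-by-gene incidence matrix and
#' `w(t) = -p(t) log2 p(t)` the per-gene entropy weight, all pairwise
#' intersection entropies are `B diag(w) t(B)`, so the full matrix is two
#' matrix products rather than a quadratic loop over set intersections.
#'
#' @param corpus An `interaction_corpus`.
#' @param registry An `entity_registry` fixing row/column order.
#' @return Symmetric numeric matrix in \[0, 1\] with registry identifiers
#'   as dimnames.
#' @export
functional_similarity <- function(corpus, registry) {
  ids <- registry$ids
  genes <- names(corpus$p)
  B <- matrix(0, nrow = length(ids), ncol = length(genes),
              dimnames = list(ids, genes))
  for (id in ids) {
    s <- corpus_set(corpus, id)
    if (length(s)) B[id, unique(s)] <- 1
  }
  w <- -corpus$p * log2(corpus$p)
  inter_h <- B %*% (t(B) * as.vector(w))     # H(T_i intersect T_j)
  h <- diag(inter_h)                          # marginal entropies H(T_i)
  denom <- outer(h, h, `+`)
  sim <- ifelse(denom > 0, 2 * inter_h / denom, 0)
  sim <- (sim + t(sim)) / 2                   # exact symmetry
  dimnames(sim) <- list(ids, ids)
  pmin(pmax(sim, 0), 1)
}

#' Blend semantic and functional disease similarity
#'
#' Convex combination `SD = alpha * SD1 + (1 - alpha) * SD2` of the
#' precomputed semantic similarity `SD1` and the target-set functional
#' similarity `SD2`.  With the default `alpha = 0.5` the two sources
#' contribute equally.
#'
#' @param sd1,sd2 Square numeric matrices with identical identifier
#'   dimnames.
#' @param alpha Weight of the semantic component, in \[0, 1\].
#' @return Blended similarity matrix.
#' @export
integrate_similarity <- function(sd1, sd2, alpha = 0.5) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    abort("`alpha` must be a single number in [0, 1]")
  }
  if (!identical(dim(sd1), dim(sd2)) ||
      !identical(rownames(sd1), rownames(sd2))) {
    abort("semantic and functional similarity matrices must share the same registry")
  }
  alpha * sd1 + (1 - alpha) * sd2
}

#' Align a semantic similarity matrix onto a disease registry
#'
#' Reindexes a (possibly larger or differently ordered) semantic
#' similarity matrix onto the registry used by the association table.
#' Diseases absent from the semantic matrix get zero similarity to every
#' other disease and self-similarity 1; a warning reports how many.
#'
#' @param semantic Square numeric matrix with identifier dimnames.
#' @param registry Disease `entity_registry`.
#' @return Square matrix over `registry$ids`.
#' @export
align_semantic <- function(semantic, registry) {
  ids <- registry$ids
  out <- diag(1, length(ids))
  dimnames(out) <- list(ids, ids)
  hit <- intersect(ids, rownames(semantic))
  if (length(hit) < length(ids)) {
    warn(sprintf("%d disease(s) absent from the semantic similarity matrix; their semantic similarity is 0",
                 length(ids) - length(hit)))
  }
  out[hit, hit] <- semantic[hit, hit]
  out
}
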