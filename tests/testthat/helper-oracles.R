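# Independent brute-force oracles written directly from the defining
# formulas, kept deliberately naive (loops over elements/thresholds) so
# they share no code path with the implementation they check.

# entropy of a gene set under global frequencies p(t) = n(t)/N
brute_entropy <- function(pairs, genes) {
  N <- nrow(unique(pairs))
  h <- 0
  for (g in unique(genes)) {
    n_t <- sum(unique(pairs)$gene == g)
    if (n_t > 0) {
      p <- n_t / N
      h <- h - p * log2(p)
    }
  }
  h
}

brute_nmi <- function(pairs, set_a, set_b) {
  denom <- brute_entropy(pairs, set_a) + brute_entropy(pairs, set_b)
  if (denom == 0) return(0)
  2 * brute_entropy(pairs, intersect(set_a, set_b)) / denom
}

brute_similarity_matrix <- function(pairs, ids) {
  sets <- lapply(ids, function(e) unique(pairs$gene[pairs$entity == e]))
  n <- length(ids)
  out <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    out[i, j] <- brute_nmi(pairs, sets[[i]], sets[[j]])
  }
  out
}

# trapezoidal area under the empirical ROC curve
trapezoid_auc <- function(labels, scores) {
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- 0; fpr <- 0; auc <- 0
  P <- sum(labels == 1); N <- sum(labels == 0)
  for (t in thr) {
    tpr_new <- sum(scores >= t & labels == 1) / P
    fpr_new <- sum(scores >= t & labels == 0) / N
    auc <- auc + (fpr_new - fpr) * (tpr_new + tpr) / 2
    tpr <- tpr_new; fpr <- fpr_new
  }
  auc + (1 - fpr) * (1 + tpr) / 2
}

# step-wise AUPR by explicit threshold sweep
brute_pr_auc <- function(labels, scores) {
  thr <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  auc <- 0; recall_prev <- 0
  for (t in thr) {
    tp <- sum(scores >= t & labels == 1)
    fp <- sum(scores >= t & labels == 0)
    precision <- tp / (tp + fp)
    recall <- tp / P
    auc <- auc + (recall - recall_prev) * precision
    recall_prev <- recall
  }
  auc
}

# the 4-interaction toy corpus used in the worked entropy/NMI examples
toy_interactions <- function() {
  interaction_table(
    tibble::tibble(entity = c("a", "a", "b", "b"),
                   gene = c("g1", "g2", "g2", "g3")),
    "disease"
  )
}

random_interactions <- function(n_entities = 5, n_genes = 6, kind = "disease") {
  entities <- paste0("e", seq_len(n_entities))
  genes <- paste0("g", seq_len(n_genes))
  pairs <- tibble::tibble(
    entity = sample(entities, n_entities * 3, replace = TRUE),
    gene = sample(genes, n_entities * 3, replace = TRUE)
  )
  interaction_table(pairs, kind)
}

small_fixture_config <- function(seed = 1) {
  fixture_config(n_mirna = 30, n_disease = 16, n_genes = 120, n_clusters = 3,
                 genes_per_entity = 30, seed = seed)
}

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
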