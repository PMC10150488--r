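#' Configuration of the synthetic fixture generator
#'
#' The generator emulates the statistical structure the whole method
#' relies on -- entities that share target-gene clusters are
#' preferentially associated.  Genes are partitioned into `n_clusters`
#' pools; each miRNA and disease is assigned a cluster and draws its
#' gene annotations mostly from its own pool; associations between a
#' miRNA and a disease are more likely when their clusters match.
#'
#' Defaults are a desk-scale study: 60 miRNAs, 40 diseases, 300 genes in
#' 4 clusters, a mean of 60 gene draws per entity with an 80/20
#' within/between split (the dense-annotation regime in which an entity
#' covers most of its functional module, so target-set overlap identifies
#' the module), and association probabilities 0.3 (cluster match) versus
#' 0.02 (mismatch).
#'
#' @param n_mirna,n_disease,n_genes,n_clusters Entity counts.
#' @param genes_per_entity Mean number of gene draws per entity
#'   (Poisson, at least 1).
#' @param p_gene_within,p_gene_between Relative probability that a draw
#'   comes from the entity's own versus another cluster's gene pool
#'   (normalized to sum to 1).
#' @param p_assoc_within,p_assoc_between Association probability for
#'   same-/different-cluster (miRNA, disease) pairs.
#' @param seed Integer seed.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_mirna = 60, n_disease = 40, n_genes = 300,
                           n_clusters = 4, genes_per_entity = 60,
                           p_gene_within = 0.8, p_gene_between = 0.2,
                           p_assoc_within = 0.3, p_assoc_between = 0.02,
                           seed = 1) {
  cfg <- as.list(environment())
  if (n_clusters < 1 || n_genes < n_clusters || n_mirna < 1 || n_disease < 1) {
    abort("impossible fixture configuration: need >= 1 cluster, >= 1 gene per cluster")
  }
  probs <- c(p_gene_within, p_gene_between, p_assoc_within, p_assoc_between)
  if (any(probs < 0) || any(probs > 1)) abort("probabilities must lie in [0, 1]")
  structure(cfg, class = "fixture_config")
}

#' Generate a synthetic planted-cluster fixture
#'
#' Produces the four inputs of the pipeline -- miRNA-gene and
#' disease-gene interaction tables, a semantic-similarity surrogate
#' (0.9 within cluster, 0.1 between, plus symmetric Gaussian noise of
#' sd 0.05, clipped to \[0, 1\], unit diagonal) and a binary association
#' table -- together with the planted cluster labels.  Entities that
#' happen to draw no genes or no associations are retained (empty sets
#' are part of the contract).  Bit-reproducible under
#' `config$seed`.
#'
#' @param config A [fixture_config()].
#' @return List with `mirna_interactions`, `disease_interactions`
#'   (`interaction_table`), `semantic` (matrix over the disease
#'   registry), `assoc` (`association_table`), and `truth` (tibble:
#'   `id`, `kind`, `cluster`).
#' @export
generate_fixture <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  withr::with_seed(config$seed, generate_fixture_impl(config))
}

generate_fixture_impl <- function(cfg) {
  pad <- function(prefix, n) sprintf("%s-%0*d", prefix, nchar(n), seq_len(n))
  mirna_ids <- pad("mir", cfg$n_mirna)
  disease_ids <- pad("dis", cfg$n_disease)
  gene_ids <- pad("gene", cfg$n_genes)
  gene_cluster <- rep_len(seq_len(cfg$n_clusters), cfg$n_genes)
  m_cluster <- rep_len(seq_len(cfg$n_clusters), cfg$n_mirna)
  d_cluster <- rep_len(seq_len(cfg$n_clusters), cfg$n_disease)
  p_within <- cfg$p_gene_within / (cfg$p_gene_within + cfg$p_gene_between)

  draw_entity_genes <- function(ids, clusters) {
    rows <- purrr::map2(ids, clusters, function(id, cl) {
      k <- max(1L, rpois(1, cfg$genes_per_entity))
      own <- stats::runif(k) < p_within
      pool_own <- gene_ids[gene_cluster == cl]
      pool_other <- gene_ids[gene_cluster != cl]
      if (length(pool_other) == 0L) own[] <- TRUE
      genes <- character(k)
      if (any(own)) genes[own] <- sample(pool_own, sum(own), replace = TRUE)
      if (any(!own)) genes[!own] <- sample(pool_other, sum(!own), replace = TRUE)
      tibble(entity = id, gene = unique(genes))
    })
    bind_rows(rows)
  }

  m_pairs <- draw_entity_genes(mirna_ids, m_cluster)
  d_pairs <- draw_entity_genes(disease_ids, d_cluster)

  match_mat <- outer(m_cluster, d_cluster, `==`)
  p_assoc <- ifelse(match_mat, cfg$p_assoc_within, cfg$p_assoc_between)
  A <- matrix(rbinom(length(p_assoc), 1L, as.vector(p_assoc)),
              nrow = cfg$n_mirna, dimnames = list(mirna_ids, disease_ids))
  if (sum(A) == 0L) A[1, 1] <- 1L   # degenerate draw guard at tiny sizes
  assoc_pairs <- tibble(
    mirna = rownames(A)[row(A)[A == 1L]],
    disease = colnames(A)[col(A)[A == 1L]]
  )

  base <- ifelse(outer(d_cluster, d_cluster, `==`), 0.9, 0.1)
  noise <- matrix(rnorm(cfg$n_disease^2, sd = 0.05), cfg$n_disease)
  noise <- (noise + t(noise)) / 2
  semantic <- pmin(pmax(base + noise, 0), 1)
  diag(semantic) <- 1
  dimnames(semantic) <- list(disease_ids, disease_ids)

  list(
    mirna_interactions = interaction_table(m_pairs, "miRNA"),
    disease_interactions = interaction_table(d_pairs, "disease"),
    semantic = semantic,
    assoc = association_table(assoc_pairs),
    truth = bind_rows(
      tibble(id = mirna_ids, kind = "miRNA", cluster = m_cluster),
      tibble(id = disease_ids, kind = "disease", cluster = d_cluster),
      tibble(id = gene_ids, kind = "gene", cluster = gene_cluster)
    ),
    config = cfg
  )
}

#' Write a fixture to TSV files
#'
#' Serializes the four pipeline inputs plus the cluster truth so a run
#' can be reproduced from files alone.
#'
#' @param fixture Output of [generate_fixture()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    associations = file.path(dir, "associations.tsv"),
    mirna_interactions = file.path(dir, "mirna_interactions.tsv"),
    disease_interactions = file.path(dir, "disease_interactions.tsv"),
    semantic = file.path(dir, "semantic_similarity.tsv"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_tsv(fixture$assoc$pairs, paths[["associations"]],
                   col_names = FALSE)
  readr::write_tsv(fixture$mirna_interactions$pairs,
                   paths[["mirna_interactions"]], col_names = FALSE)
  readr::write_tsv(fixture$disease_interactions$pairs,
                   paths[["disease_interactions"]], col_names = FALSE)
  write_similarity_matrix(fixture$semantic, paths[["semantic"]])
  jsonlite::write_json(fixture$truth, paths[["truth"]], dataframe = "columns")
  invisible(paths)
}
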