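#' Build the balanced training set
#'
#' Positives are all known associations in scope; negatives are sampled
#' unknown pairs (`negative_ratio` per positive, uniform without
#' replacement).  Features are assembled with the supplied similarity
#' matrices, PCA models and corpora.
#'
#' @param assoc An `association_table`.
#' @param SM,SD Similarity matrices.
#' @param pca Output of [fit_block_pca()].
#' @param mirna_corpus,disease_corpus Interaction corpora.
#' @param negative_ratio Negatives per positive.
#' @param seed Integer seed for negative sampling.
#' @param top_k,group_size Structural-feature parameters.
#' @return A labeled `feature_table` with the positive/negative pair
#'   lists attached as attributes `positive_pairs` / `negative_pairs`.
#' @export
build_training_set <- function(assoc, SM, SD, pca, mirna_corpus,
                               disease_corpus, negative_ratio = 1,
                               seed = 1, top_k = 200, group_size = 50) {
  positives <- assoc$pairs
  negatives <- sample_negatives(assoc, round(negative_ratio * nrow(positives)),
                                seed = seed)
  train_pairs <- bind_rows(mutate(positives, label = 1L),
                           mutate(negatives, label = 0L))
  ft <- assemble_feature_table(train_pairs[, c("mirna", "disease")],
                               train_pairs$label, SM, SD, pca,
                               mirna_corpus, disease_corpus,
                               top_k = top_k, group_size = group_size)
  attr(ft, "positive_pairs") <- positives
  attr(ft, "negative_pairs") <- negatives
  ft
}

#' Run the full association-prediction pipeline
#'
#' End to end: interaction corpora, entropy/NMI similarity matrices
#' (miRNA functional similarity `SM`; disease similarity `SD`, an
#' alpha-blend of semantic and functional similarity when a semantic
#' matrix is supplied), block PCA, balanced training set, stratified
#' cross-validation, and a final ensemble trained on the full training
#' set.
#'
#' @param assoc An `association_table`.
#' @param mirna_interactions,disease_interactions `interaction_table`s.
#' @param semantic Optional precomputed disease semantic-similarity
#'   matrix; if `NULL`, disease similarity is the functional similarity
#'   alone.
#' @param alpha Semantic-blend weight (see [integrate_similarity()]).
#' @param variance_threshold PCA explained-variance fraction.
#' @param top_k,group_size Structural-feature parameters.
#' @param spec An [ensemble_spec()].
#' @param folds,repeats,threshold Cross-validation settings.
#' @param negative_ratio Negatives per positive.
#' @param seed Integer seed controlling negative sampling, fold
#'   assignment and member fits.
#' @return An `mda_pipeline`: list with `SM`, `SD`, `SD1`, `SD2`, `pca`,
#'   `training` (feature table), `cv` (`cv_report`), `model`
#'   (`trained_ensemble`), corpora and the resolved configuration.
#' @export
run_pipeline <- function(assoc, mirna_interactions, disease_interactions,
                         semantic = NULL, alpha = 0.5,
                         variance_threshold = 0.8, top_k = 200,
                         group_size = 50, spec = ensemble_spec(),
                         folds = 5, repeats = 1, threshold = 0.5,
                         negative_ratio = 1, seed = 1) {
  mirna_corpus <- build_corpus(mirna_interactions)
  disease_corpus <- build_corpus(disease_interactions)
  SM <- functional_similarity(mirna_corpus, assoc$mirnas)
  SD2 <- functional_similarity(disease_corpus, assoc$diseases)
  SD1 <- if (is.null(semantic)) NULL else align_semantic(semantic, assoc$diseases)
  SD <- if (is.null(SD1)) SD2 else integrate_similarity(SD1, SD2, alpha)
  pca <- fit_block_pca(SM, SD, variance_threshold)
  training <- build_training_set(assoc, SM, SD, pca, mirna_corpus,
                                 disease_corpus, negative_ratio, seed,
                                 top_k, group_size)
  cv <- run_cross_validation(training, spec = spec, folds = folds,
                             repeats = repeats, seed = seed,
                             threshold = threshold)
  model <- train_ensemble(training$x, training$pairs$label, spec = spec,
                          seed = seed)
  structure(
    list(assoc = assoc, SM = SM, SD = SD, SD1 = SD1, SD2 = SD2, pca = pca,
         mirna_corpus = mirna_corpus, disease_corpus = disease_corpus,
         training = training, cv = cv, model = model,
         config = list(alpha = alpha, variance_threshold = variance_threshold,
                       top_k = top_k, group_size = group_size, folds = folds,
                       repeats = repeats, threshold = threshold,
                       negative_ratio = negative_ratio, seed = seed,
                       members = spec$members)),
    class = "mda_pipeline"
  )
}

#' @export
print.mda_pipeline <- function(x, ...) {
  cat("<mda_pipeline> ", nrow(x$SM), " miRNAs x ", nrow(x$SD),
      " diseases; ", nrow(x$training$x), " training samples x ",
      ncol(x$training$x), " features\n", sep = "")
  print(x$cv)
  invisible(x)
}

#' @describeIn run_pipeline Per-fold cross-validation metrics.
#' @param x An `mda_pipeline`.
#' @param ... Unused.
#' @export
tidy.mda_pipeline <- function(x, ...) tidy(x$cv)

#' @describeIn run_pipeline One-row pipeline summary: CV means/sds plus
#'   dimensions.
#' @export
glance.mda_pipeline <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$cv),
    tibble(n_mirna = nrow(x$SM), n_disease = nrow(x$SD),
           n_features = ncol(x$training$x),
           n_mirna_components = x$pca$mirna$n_components,
           n_disease_components = x$pca$disease$n_components)
  )
}
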