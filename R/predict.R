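#' Score and rank candidate miRNA-disease pairs
#'
#' Applies a trained ensemble to unknown pairs (`A(i, j) = 0`) and ranks
#' them by the voted probability, globally or restricted to one disease.
#' Known associations are excluded unless `include_known = TRUE`, in
#' which case they are flagged.  Ties are broken lexicographically on
#' (miRNA, disease) so output is deterministic.
#'
#' @param model A `trained_ensemble`.
#' @param assoc An `association_table`.
#' @param SM,SD Similarity matrices.
#' @param pca Output of [fit_block_pca()] used at training time.
#' @param mirna_corpus,disease_corpus Interaction corpora.
#' @param scope `"global"` or a disease identifier.
#' @param top_n Optionally keep only the first `top_n` ranked records.
#' @param include_known Also score and flag known pairs.
#' @param top_k,group_size Structural-feature parameters (must match
#'   training).
#' @return A `ranked_predictions` tibble: `rank`, `mirna`, `disease`,
#'   `score`, `known`, with attributes `scope` and `mode`.
#' @export
score_candidates <- function(model, assoc, SM, SD, pca,
                             mirna_corpus, disease_corpus,
                             scope = "global", top_n = NULL,
                             include_known = FALSE,
                             top_k = 200, group_size = 50) {
  cand <- all_pairs(assoc)
  if (!identical(scope, "global")) {
    if (!scope %in% colnames(assoc$A)) {
      abort(paste0("disease '", scope, "' not present in the association table"))
    }
    cand <- filter(cand, .data$disease == scope)
  }
  if (!include_known) cand <- filter(cand, .data$label == 0L)
  ft <- assemble_feature_table(cand, NULL, SM, SD, pca,
                               mirna_corpus, disease_corpus,
                               top_k = top_k, group_size = group_size)
  out <- tibble(mirna = cand$mirna, disease = cand$disease,
                score = predict(model, ft$x),
                known = cand$label == 1L)
  out <- rank_records(out)
  if (!is.null(top_n)) out <- head(out, top_n)
  structure(out, scope = scope, mode = "standard",
            class = c("ranked_predictions", class(out)))
}

#' Cold-start (isolated disease) prediction
#'
#' Treats one disease as isolated: every known association of that
#' disease is removed from the training positives, and (by default) its
#' whole column is also excluded from the negative-sampling pool, so no
#' information about the disease's associations enters training.  All m
#' miRNA pairs of the disease are then scored and ranked.
#'
#' @param disease Disease identifier to isolate.
#' @param assoc An `association_table`.
#' @param SM,SD Similarity matrices.
#' @param pca Output of [fit_block_pca()].
#' @param mirna_corpus,disease_corpus Interaction corpora.
#' @param spec An [ensemble_spec()].
#' @param seed Integer seed (negative sampling and member fits).
#' @param negative_ratio Negatives per positive in the reduced training
#'   set.
#' @param exclude_disease_negatives If `FALSE`, negatives may be drawn
#'   from the isolated disease's column as well (only positive removal).
#' @param top_k,group_size Structural-feature parameters.
#' @return A `ranked_predictions` tibble over all m pairs of `disease`,
#'   with the training pairs attached as attribute `training_pairs`.
#' @export
isolated_disease_run <- function(disease, assoc, SM, SD, pca,
                                 mirna_corpus, disease_corpus,
                                 spec = ensemble_spec(), seed = 1,
                                 negative_ratio = 1,
                                 exclude_disease_negatives = TRUE,
                                 top_k = 200, group_size = 50) {
  if (!disease %in% colnames(assoc$A)) {
    abort(paste0("disease '", disease, "' not present in the association table"))
  }
  positives <- filter(assoc$pairs, .data$disease != !!disease)
  negatives <- sample_negatives(
    assoc, count = round(negative_ratio * nrow(positives)), seed = seed,
    exclude_disease = if (exclude_disease_negatives) disease else NULL
  )
  train_pairs <- bind_rows(mutate(positives, label = 1L),
                           mutate(negatives, label = 0L))
  ft <- assemble_feature_table(train_pairs[, c("mirna", "disease")],
                               train_pairs$label, SM, SD, pca,
                               mirna_corpus, disease_corpus,
                               top_k = top_k, group_size = group_size)
  model <- train_ensemble(ft$x, train_pairs$label, spec = spec, seed = seed)
  targets <- tibble(mirna = rownames(assoc$A), disease = disease)
  tf <- assemble_feature_table(targets, NULL, SM, SD, pca,
                               mirna_corpus, disease_corpus,
                               top_k = top_k, group_size = group_size)
  known_flag <- unname(assoc$A[, disease] == 1L)
  out <- tibble(mirna = targets$mirna, disease = disease,
                score = predict(model, tf$x),
                known = known_flag)
  out <- rank_records(out)
  structure(out, scope = paste0("disease:", disease), mode = "isolated",
            training_pairs = train_pairs,
            class = c("ranked_predictions", class(out)))
}

#' Annotate rankings with an external validation lookup
#'
#' Marks each ranked pair as validated if it appears in a lookup table of
#' associations from a newer release (e.g. an updated association
#' database used to check case-study predictions).
#'
#' @param rankings A `ranked_predictions` tibble.
#' @param lookup Data frame with columns `mirna` and `disease`
#'   (normalized with [normalize_ids()]).
#' @return The rankings with a logical `validated` column.
#' @export
annotate_validated <- function(rankings, lookup) {
  key <- paste(normalize_ids(lookup$mirna), normalize_ids(lookup$disease),
               sep = "\r")
  rankings$validated <- paste(rankings$mirna, rankings$disease,
                              sep = "\r") %in% key
  rankings
}
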