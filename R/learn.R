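#' Sample negative (unknown) miRNA-disease pairs
#'
#' Draws `count` distinct pairs with `A(i, j) = 0` uniformly without
#' replacement.  The known associations are positives; sampled unknowns
#' stand in as negatives so the training set is (near-)balanced.  Fully
#' reproducible under `seed`.
#'
#' @param assoc An `association_table`.
#' @param count Number of negatives; must not exceed the number of
#'   0-entries in scope.
#' @param seed Integer seed.
#' @param strategy Sampling strategy; only `"uniform"` is implemented
#'   (the slot exists so alternative selectors can plug in).
#' @param exclude_disease Optional disease identifier whose entire column
#'   is removed from the sampling pool (cold-start protocol).
#' @return Tibble with columns `mirna`, `disease`.
#' @export
sample_negatives <- function(assoc, count, seed, strategy = "uniform",
                             exclude_disease = NULL) {
  strategy <- match.arg(strategy)
  zero_idx <- which(assoc$A == 0L)
  if (!is.null(exclude_disease)) {
    col <- assoc$diseases$index[[exclude_disease]]
    zero_idx <- zero_idx[((zero_idx - 1L) %/% nrow(assoc$A)) + 1L != col]
  }
  if (count > length(zero_idx)) {
    abort(sprintf("requested %d negatives but only %d unknown pairs available",
                  count, length(zero_idx)))
  }
  take <- withr::with_seed(seed, sample(zero_idx, size = count))
  tibble(
    mirna = rownames(assoc$A)[((take - 1L) %% nrow(assoc$A)) + 1L],
    disease = colnames(assoc$A)[((take - 1L) %/% nrow(assoc$A)) + 1L]
  )
}

#' Specify the soft-voting ensemble
#'
#' The default ensemble combines four base learners, each exposing a
#' calibrated positive-class probability: an RBF-kernel SVM with
#' probability calibration, plain gradient-boosted decision trees (GBDT:
#' depth-3 trees, learning rate 0.1, no regularization, full subsample),
#' a 100-tree probability random forest, and regularized gradient
#' boosting (XGBoost defaults with learning rate 0.1).  None of the
#' hyperparameters is data-derived; all can be overridden via `params`.
#'
#' @param members Subset of `c("svm", "gbdt", "rf", "xgboost")`.
#' @param params Named list of per-member hyperparameter overrides, e.g.
#'   `list(rf = list(num_trees = 200))`.
#' @return An `ensemble_spec`.
#' @export
ensemble_spec <- function(members = c("svm", "gbdt", "rf", "xgboost"),
                          params = list()) {
  members <- match.arg(members, several.ok = TRUE)
  defaults <- list(
    svm = list(cost = 1, gamma = NULL),     # gamma NULL -> e1071's 1/ncol(x)
    gbdt = list(nrounds = 100, eta = 0.1, max_depth = 3),
    rf = list(num_trees = 100),
    xgboost = list(nrounds = 100, eta = 0.1, max_depth = 6)
  )
  for (m in names(params)) {
    stopifnot(m %in% members)
    defaults[[m]][names(params[[m]])] <- params[[m]]
  }
  structure(list(members = members, params = defaults[members]),
            class = "ensemble_spec")
}

# --- base-learner fit/predict backends --------------------------------------

fit_member <- function(member, x, y, params, seed) {
  switch(
    member,
    svm = withr::with_seed(seed, {
      scale_cols <- apply(x, 2, stats::sd) > 0
      e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial",
                 cost = params$cost,
                 gamma = if (is.null(params$gamma)) 1 / ncol(x) else params$gamma,
                 probability = TRUE, scale = scale_cols)
    }),
    gbdt = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = params$eta,
                    max_depth = params$max_depth, lambda = 0, alpha = 0,
                    subsample = 1, colsample_bytree = 1,
                    nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(x, label = y), nrounds = params$nrounds,
      verbose = 0),
    rf = ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                        probability = TRUE, num.trees = params$num_trees,
                        seed = seed, num.threads = 1),
    xgboost = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = params$eta,
                    max_depth = params$max_depth,
                    nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(x, label = y), nrounds = params$nrounds,
      verbose = 0),
    abort(paste0("unknown ensemble member '", member, "'"))
  )
}

predict_member <- function(member, fit, x) {
  p <- switch(
    member,
    svm = attr(predict(fit, x, probability = TRUE), "probabilities")[, "1"],
    gbdt = predict(fit, xgboost::xgb.DMatrix(x)),
    rf = predict(fit, data = x, num.threads = 1)$predictions[, "1"],
    xgboost = predict(fit, xgboost::xgb.DMatrix(x))
  )
  unname(pmin(pmax(as.numeric(p), 0), 1))
}

#' Train the soft-voting ensemble
#'
#' Fits every member of the spec on the same rows.  Each member receives
#' a seed derived deterministically from `seed` and its position, so a
#' refit with the same inputs reproduces identical predictions.
#'
#' @param x Numeric feature matrix.
#' @param labels Binary vector (0/1) with both classes present.
#' @param spec An [ensemble_spec()].
#' @param seed Integer seed.
#' @return A `trained_ensemble`.
#' @export
train_ensemble <- function(x, labels, spec = ensemble_spec(), seed = 1) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    abort("training set must contain both classes")
  }
  if (length(labels) != nrow(x)) abort("label/feature row mismatch")
  fits <- purrr::imap(
    stats::setNames(spec$members, spec$members),
    function(m, pos) fit_member(m, x, labels,
                                spec$params[[m]],
                                seed + match(m, spec$members) * 1000L)
  )
  structure(list(spec = spec, fits = fits, feature_width = ncol(x),
                 feature_names = colnames(x), seed = seed,
                 n_train = nrow(x)),
            class = "trained_ensemble")
}

#' @export
print.trained_ensemble <- function(x, ...) {
  cat("<trained_ensemble> members:", paste(x$spec$members, collapse = ", "),
      "| trained on", x$n_train, "samples x", x$feature_width, "features\n")
  invisible(x)
}

#' Soft-voting aggregation
#'
#' Unweighted arithmetic mean of the members' positive-class
#' probabilities, per sample.  The vote is bounded by the member minimum
#' and maximum for each sample.
#'
#' @param member_probs Numeric matrix, members x samples, entries in
#'   \[0, 1\].
#' @return Numeric vector of length `ncol(member_probs)`.
#' @export
soft_vote <- function(member_probs) {
  member_probs <- as.matrix(member_probs)
  if (any(member_probs < 0 | member_probs > 1)) {
    abort("member probabilities must lie in [0, 1]")
  }
  colMeans(member_probs)
}

#' Predict ensemble probabilities
#'
#' @param object A `trained_ensemble`.
#' @param newdata Feature matrix with the training width.
#' @param type `"vote"` for the soft-voted probability vector,
#'   `"members"` for the members x samples probability matrix.
#' @param ... Unused.
#' @return Numeric vector (vote) or matrix (members).
#' @export
predict.trained_ensemble <- function(object, newdata,
                                     type = c("vote", "members"), ...) {
  type <- match.arg(type)
  if (ncol(newdata) != object$feature_width) {
    abort("newdata width does not match the training feature width")
  }
  probs <- t(vapply(object$spec$members,
                    function(m) predict_member(m, object$fits[[m]], newdata),
                    numeric(nrow(newdata))))
  rownames(probs) <- object$spec$members
  if (type == "members") probs else soft_vote(probs)
}

#' Stratified cross-validation of the ensemble
#'
#' Randomly and evenly partitions the labeled samples into `folds`
#' subsets, stratified by class (per-fold positive fraction within one
#' sample of the global fraction, overall fold sizes within one of each
#' other).  Each fold is held out once; precision, recall, F1 (at
#' `threshold` on the voted probability), AUC and AUPR are computed on
#' the held-out fold, along with every member's individual AUC/AUPR from
#' its own probabilities.  `repeats` re-partitions with derived seeds
#' `seed, seed + 1, ...` and pools the folds.
#'
#' @param features A `feature_table` (labeled) or numeric matrix.
#' @param labels Binary labels; taken from `features$pairs$label` when
#'   `features` is a `feature_table` and `labels` is `NULL`.
#' @param spec An [ensemble_spec()].
#' @param folds Number of folds (>= 2).
#' @param repeats Number of independent partitions.
#' @param seed Integer seed.
#' @param threshold Probability threshold for precision/recall/F1.
#' @return A `cv_report`: list with `folds` (per-fold metrics tibble),
#'   `members` (per-fold per-member AUC/AUPR), `summary` (mean and sd per
#'   metric), `curves` (ROC/PR points per fold) and the configuration.
#' @export
run_cross_validation <- function(features, labels = NULL,
                                 spec = ensemble_spec(), folds = 5,
                                 repeats = 1, seed = 1, threshold = 0.5) {
  if (inherits(features, "feature_table")) {
    if (is.null(labels)) labels <- features$pairs$label
    x <- features$x
  } else {
    x <- as.matrix(features)
  }
  labels <- as.integer(labels)
  if (folds < 2) abort("`folds` must be at least 2")
  if (min(table(labels)) < folds) {
    abort("each class must have at least `folds` members")
  }
  fold_rows <- list(); member_rows <- list(); curve_rows <- list()
  for (r in seq_len(repeats)) {
    assign_seed <- seed + r - 1L
    fold_of <- withr::with_seed(assign_seed, stratified_folds(labels, folds))
    for (k in seq_len(folds)) {
      test <- which(fold_of == k)
      train <- which(fold_of != k)
      model <- train_ensemble(x[train, , drop = FALSE], labels[train],
                              spec = spec, seed = assign_seed * 100L + k)
      probs <- predict(model, x[test, , drop = FALSE], type = "members")
      vote <- soft_vote(probs)
      cm <- classification_metrics(labels[test], vote, threshold)
      fold_rows[[length(fold_rows) + 1L]] <- tibble(
        repeat_id = r, fold = k, n_test = length(test),
        precision = cm$precision, recall = cm$recall, f1 = cm$f1,
        auc = roc_auc(labels[test], vote),
        aupr = pr_auc(labels[test], vote)
      )
      member_rows[[length(member_rows) + 1L]] <- tibble(
        repeat_id = r, fold = k, member = rownames(probs),
        auc = apply(probs, 1, function(p) roc_auc(labels[test], p)),
        aupr = apply(probs, 1, function(p) pr_auc(labels[test], p))
      )
      curve_rows[[length(curve_rows) + 1L]] <-
        mutate(curve_points(labels[test], vote), repeat_id = r, fold = k)
    }
  }
  fold_tab <- bind_rows(fold_rows)
  metric_cols <- c("precision", "recall", "f1", "auc", "aupr")
  summary_tab <- tidyr::pivot_longer(fold_tab, dplyr::all_of(metric_cols),
                                     names_to = "metric") |>
    group_by(.data$metric) |>
    summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
              .groups = "drop")
  structure(
    list(folds = fold_tab, members = bind_rows(member_rows),
         summary = summary_tab, curves = bind_rows(curve_rows),
         config = list(folds = folds, repeats = repeats, seed = seed,
                       threshold = threshold, members = spec$members)),
    class = "cv_report"
  )
}

# Stratified, balanced fold assignment (uses the current RNG state).
stratified_folds <- function(labels, folds) {
  fold_of <- integer(length(labels))
  sizes <- integer(folds)
  for (cls in sort(unique(labels))) {
    idx <- sample(which(labels == cls))
    # cycle folds smallest-first so overall sizes stay within 1
    ord <- order(sizes, seq_len(folds))
    fold_of[idx] <- rep(ord, length.out = length(idx))
    sizes <- tabulate(fold_of[fold_of > 0], folds)
  }
  fold_of
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", x$config$folds, "-fold x ", x$config$repeats,
      " repeat(s), members: ", paste(x$config$members, collapse = ", "),
      "\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-9s %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' @describeIn run_cross_validation Per-fold metrics, one row per fold.
#' @param x A `cv_report`.
#' @param ... Unused.
#' @export
tidy.cv_report <- function(x, ...) x$folds

#' @describeIn run_cross_validation One-row summary (mean and sd of each
#'   metric, wide).
#' @export
glance.cv_report <- function(x, ...) {
  s <- x$summary
  out <- as.list(c(stats::setNames(s$mean, s$metric),
                   stats::setNames(s$sd, paste0(s$metric, "_sd"))))
  as_tibble(out)[, c(rbind(s$metric, paste0(s$metric, "_sd")))]
}

#' @describeIn run_cross_validation ROC and PR curves per fold.
#' @param object A `cv_report`.
#' @export
autoplot.cv_report <- function(object, ...) {
  dat <- mutate(object$curves,
                panel = ifelse(.data$curve == "roc", "ROC", "Precision-recall"),
                fold_id = interaction(.data$repeat_id, .data$fold))
  ggplot2::ggplot(dat, ggplot2::aes(.data$x, .data$y,
                                    group = .data$fold_id,
                                    colour = factor(.data$fold))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = "FPR / recall", y = "TPR / precision",
                  colour = "fold") +
    ggplot2::theme_minimal()
}
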