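tiny_assoc <- association_table(
  tibble::tibble(mirna = c("m1", "m2"), disease = c("d1", "d2"))
)

test_that("negative sampling is uniform over unknown pairs and reproducible", {
  expect_equal(nrow(sample_negatives(tiny_assoc, 0, seed = 1)), 0)

  # 2x2 with one positive: exhaustive sampling returns the 3 unknown pairs
  one_pos <- association_table(tibble::tibble(mirna = "m1", disease = "d1"),
                               mirna_ids = c("m1", "m2"),
                               disease_ids = c("d1", "d2"))
  neg <- sample_negatives(one_pos, 3, seed = 1)
  expect_setequal(paste(neg$mirna, neg$disease),
                  c("m1 d2", "m2 d1", "m2 d2"))

  big <- association_table(tibble::tibble(
    mirna = paste0("m", 1:30), disease = paste0("d", rep(1:15, 2))))
  a <- sample_negatives(big, 100, seed = 9)
  b <- sample_negatives(big, 100, seed = 9)
  c2 <- sample_negatives(big, 100, seed = 10)
  expect_identical(a, b)
  expect_false(identical(a, c2))
  # sampled pairs are all unknown
  expect_true(all(big$A[cbind(a$mirna, a$disease)] == 0))
  expect_error(sample_negatives(tiny_assoc, 10, seed = 1), "only")
})

test_that("soft voting is the member mean, bounded by member extremes", {
  probs <- rbind(c(.2, 1), c(.4, 1), c(.6, 1), c(.8, 1))
  expect_equal(soft_vote(probs), c(0.5, 1))
  expect_equal(soft_vote(matrix(.7, 4, 3)), rep(.7, 3))
  set.seed(2)
  p <- matrix(runif(40), 4)
  v <- soft_vote(p)
  expect_true(all(v >= apply(p, 2, min) - 1e-12))
  expect_true(all(v <= apply(p, 2, max) + 1e-12))
  expect_error(soft_vote(rbind(c(1.2, 0))), "0, 1")
})

sep_data <- local({
  set.seed(14)
  n <- 60
  x <- cbind(a = c(rnorm(n / 2, -3), rnorm(n / 2, 3)), b = rnorm(n))
  list(x = x, y = rep(c(0L, 1L), each = n / 2))
})

test_that("the ensemble fits all members and separates a separable toy set", {
  model <- train_ensemble(sep_data$x, sep_data$y, seed = 3)
  expect_s3_class(model, "trained_ensemble")
  vote <- predict(model, sep_data$x)
  acc <- mean((vote >= 0.5) == (sep_data$y == 1))
  expect_equal(acc, 1)

  # single-member spec degenerates to that member's probabilities
  solo <- train_ensemble(sep_data$x, sep_data$y,
                         spec = ensemble_spec("rf"), seed = 3)
  members <- predict(solo, sep_data$x, type = "members")
  expect_equal(predict(solo, sep_data$x), unname(members["rf", ]))

  # refits with identical seeds reproduce identical predictions
  again <- train_ensemble(sep_data$x, sep_data$y, seed = 3)
  expect_identical(predict(model, sep_data$x), predict(again, sep_data$x))

  expect_error(train_ensemble(sep_data$x, rep(1L, nrow(sep_data$x))),
               "both classes")
  expect_error(predict(model, sep_data$x[, 1, drop = FALSE]), "width")
})

test_that("cross-validation folds are stratified and balanced", {
  set.seed(10)
  labels <- c(rep(1L, 203), rep(0L, 197))
  fold <- withr::with_seed(4, entromir:::stratified_folds(labels, 5))
  sizes <- table(fold)
  expect_lte(max(sizes) - min(sizes), 1)
  pos_frac <- tapply(labels, fold, mean)
  global <- mean(labels)
  per_fold_pos <- tapply(labels, fold, sum)
  expected <- global * sizes
  expect_true(all(abs(per_fold_pos - expected) <= 1))
})

test_that("cross-validation report on a separable set is perfect", {
  cv <- run_cross_validation(sep_data$x, sep_data$y,
                             spec = ensemble_spec("rf"), folds = 5, seed = 2)
  expect_true(all(cv$folds$auc == 1))
  expect_equal(glance(cv)$auc, 1)
  expect_true(all(cv$summary$mean >= 0) && all(cv$summary$mean <= 1))
  expect_equal(nrow(cv$folds), 5)
  # averages equal the arithmetic mean of fold values
  expect_equal(glance(cv)$aupr, mean(cv$folds$aupr))
  expect_error(run_cross_validation(sep_data$x, sep_data$y, folds = 1),
               "folds")
  expect_error(run_cross_validation(sep_data$x,
                                    c(1L, rep(0L, length(sep_data$y) - 1)),
                                    folds = 5), "class")
})

test_that("label-shuffled features give chance-level AUC", {
  set.seed(19)
  n <- 500
  x <- matrix(rnorm(n * 10), n)
  colnames(x) <- paste0("v", 1:10)
  y <- sample(rep(0:1, n / 2))
  cv <- run_cross_validation(x, y, spec = ensemble_spec("rf"),
                             folds = 5, repeats = 3, seed = 6)
  expect_lt(abs(glance(cv)$auc - 0.5), 0.1)
  expect_equal(nrow(cv$folds), 15)   # repeats pool their folds
})
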