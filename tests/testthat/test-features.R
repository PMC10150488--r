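# hand-built context: 3 miRNAs, 2 diseases, known similarity rows
toy_sm <- matrix(c(1, .6, .2,
                   .6, 1, .4,
                   .2, .4, 1), 3, byrow = TRUE,
                 dimnames = list(c("m1", "m2", "m3"), c("m1", "m2", "m3")))
toy_sd <- matrix(c(1, .3,
                   .3, 1), 2, byrow = TRUE,
                 dimnames = list(c("d1", "d2"), c("d1", "d2")))
toy_mc <- build_corpus(interaction_table(
  tibble::tibble(entity = c("m1", "m1", "m2", "m3"),
                 gene = c("g1", "g2", "g2", "g3")), "miRNA"))
toy_dc <- build_corpus(interaction_table(
  tibble::tibble(entity = c("d1", "d1", "d2"),
                 gene = c("g2", "g4", "g4")), "disease"))

test_that("structural features match hand computation on the 3x3 toy", {
  f <- structural_features(1, 1, toy_sm, toy_sd, toy_mc, toy_dc)
  expect_length(f, 17)
  expect_equal(unname(f[1:2]), c(2, 2 / 3))              # gene count, density
  expect_equal(unname(f[3]), mean(c(.6, .2)))            # row mean, self excluded
  expect_equal(unname(f[4]), mean((c(.6, .2) - .4)^2))   # population variance
  # 2 comparators split into 4 contiguous groups of ceiling(2/4) = 1
  expect_equal(unname(f[5:8]), c(.6, .2, 0, 0))
  expect_equal(unname(f[9:10]), c(2, 1))                 # disease count/density
  expect_equal(unname(f[11:12]), c(.3, 0))
  expect_equal(unname(f[13:16]), c(.3, 0, 0, 0))
  expect_equal(unname(f[17]), 1)                         # shared gene g2
})

test_that("entities without annotations give zero count/density/shared features", {
  sm <- rbind(toy_sm, mx = c(.1, .1, .1))
  sm <- cbind(sm, mx = c(.1, .1, .1, 1))
  f <- structural_features(4, 1, sm, toy_sd, toy_mc, toy_dc)
  expect_equal(unname(f[c(1, 2, 17)]), c(0, 0, 0))
})

test_that("raw sample encoding concatenates the two similarity rows", {
  pairs <- tidyr::expand_grid(mirna = rownames(toy_sm),
                              disease = rownames(toy_sd))
  raw <- encode_raw_samples(pairs, toy_sm, toy_sd)
  expect_equal(dim(raw), c(6L, 5L))                      # (3*2) x (3+2)
  one <- encode_raw_samples(tibble::tibble(mirna = "m1", disease = "d1"),
                            toy_sm, toy_sd)
  expect_equal(unname(drop(one)), unname(c(toy_sm["m1", ], toy_sd["d1", ])))
  expect_error(encode_raw_samples(tibble::tibble(mirna = "nope", disease = "d1"),
                                  toy_sm, toy_sd), "absent")
})

test_that("block PCA keeps the minimal component count for the variance target", {
  # rank-1 matrix: all variance on the first axis
  v <- c(1, 2, 3, 4)
  rank1 <- outer(c(1, 2, 3, 4), v)
  dimnames(rank1) <- list(paste0("r", 1:4), paste0("r", 1:4))
  pca <- fit_block_pca(rank1, rank1, 0.8)
  expect_equal(pca$mirna$n_components, 1L)
  expect_gte(pca$mirna$explained_fraction, 0.8)

  set.seed(5)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    S <- matrix(runif(n * n), n)
    S <- (S + t(S)) / 2
    dimnames(S) <- list(paste0("e", 1:n), paste0("e", 1:n))
    model <- fit_block_pca(S, S, 0.8)$mirna
    # oracle: eigenvalues of the covariance of centered rows
    ev <- sort(eigen(stats::cov(S) * (n - 1) / n, symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
    # prcomp divides by n-1; compare explained fractions, scale-free
    frac_oracle <- cumsum(ev) / sum(ev)
    k_oracle <- which(frac_oracle >= 0.8 - 1e-12)[1]
    expect_equal(model$n_components, k_oracle)
    expect_equal(model$explained_fraction, frac_oracle[k_oracle],
                 tolerance = 1e-9)
  }

  # threshold 1.0 spans the full numerical rank
  full <- fit_block_pca(toy_sm, toy_sd, 1)$mirna
  expect_equal(full$n_components, qr(scale(toy_sm, scale = FALSE))$rank)
  expect_error(fit_block_pca(toy_sm, toy_sd, 0), "variance_threshold")
  expect_error(fit_block_pca(toy_sm, toy_sd, 1.2), "variance_threshold")
})

test_that("feature table width is PCA components plus 17 structural features", {
  pca <- fit_block_pca(toy_sm, toy_sd, 0.8)
  pairs <- tidyr::expand_grid(mirna = rownames(toy_sm),
                              disease = rownames(toy_sd))
  ft <- assemble_feature_table(pairs, rep(0:1, 3), toy_sm, toy_sd, pca,
                               toy_mc, toy_dc)
  expect_equal(ncol(ft$x),
               pca$mirna$n_components + pca$disease$n_components + 17)
  expect_equal(length(ft$block_bounds$structural), 17)
  expect_equal(nrow(tidy(ft)), 6)

  empty <- assemble_feature_table(pairs[0, ], integer(), toy_sm, toy_sd, pca,
                                  toy_mc, toy_dc)
  expect_equal(nrow(empty$x), 0)
  expect_equal(ncol(empty$x), ncol(ft$x))

  expect_error(assemble_feature_table(pairs, c(1, 0), toy_sm, toy_sd, pca,
                                      toy_mc, toy_dc), "length")
  expect_error(assemble_feature_table(pairs[c(1, 1), ], c(1, 0), toy_sm,
                                      toy_sd, pca, toy_mc, toy_dc),
               "duplicate")
})

test_that("feature assembly is deterministic and label-independent", {
  pca <- fit_block_pca(toy_sm, toy_sd, 0.8)
  pairs <- tidyr::expand_grid(mirna = rownames(toy_sm),
                              disease = rownames(toy_sd))
  a <- assemble_feature_table(pairs, rep(1:0, 3), toy_sm, toy_sd, pca,
                              toy_mc, toy_dc)
  b <- assemble_feature_table(pairs, rep(0:1, 3), toy_sm, toy_sd, pca,
                              toy_mc, toy_dc)
  expect_identical(a$x, b$x)            # features ignore the labels entirely
  c2 <- assemble_feature_table(pairs, rep(1:0, 3), toy_sm, toy_sd,
                               fit_block_pca(toy_sm, toy_sd, 0.8),
                               toy_mc, toy_dc)
  expect_identical(a$x, c2$x)           # bit-identical across refits
})
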