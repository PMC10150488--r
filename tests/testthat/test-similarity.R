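toy <- toy_interactions()
toy_corpus <- build_corpus(toy)

test_that("corpus counts interactions once and derives global frequencies", {
  expect_equal(toy_corpus$N, 4)
  expect_equal(toy_corpus$p[["g1"]], 0.25)
  expect_equal(toy_corpus$p[["g2"]], 0.5)
  expect_equal(toy_corpus$p[["g3"]], 0.25)
  expect_equal(sum(toy_corpus$freq), toy_corpus$N)

  # duplicate rows collapse before counting
  dup <- interaction_table(
    tibble::tibble(entity = c("a", "a", "a", "b", "b"),
                   gene = c("g1", "g1", "g2", "g2", "g3")), "disease")
  expect_equal(build_corpus(dup)$N, 4)

  single <- build_corpus(interaction_table(
    tibble::tibble(entity = "a", gene = "g1"), "miRNA"))
  expect_equal(single$N, 1)
  expect_equal(single$p[["g1"]], 1)

  empty <- interaction_table(tibble::tibble(entity = character(),
                                            gene = character()), "miRNA")
  expect_error(build_corpus(empty), "empty interaction corpus")
})

test_that("set entropy matches hand evaluation on the toy corpus", {
  expect_equal(set_entropy(toy_corpus, c("g1", "g2")), 1.0, tolerance = 1e-12)
  expect_equal(set_entropy(toy_corpus, character()), 0)
  # a gene occurring in every interaction has p = 1 and contributes nothing
  single <- build_corpus(interaction_table(
    tibble::tibble(entity = "a", gene = "g1"), "miRNA"))
  expect_equal(set_entropy(single, "g1"), 0)
  expect_warning(h <- set_entropy(toy_corpus, c("g1", "unknown")), "absent")
  expect_equal(h, set_entropy(toy_corpus, "g1"))
})

test_that("NMI similarity matches hand evaluation and boundary cases", {
  expect_equal(nmi_similarity(toy_corpus, c("g1", "g2"), c("g2", "g3")), 0.5,
               tolerance = 1e-12)
  expect_equal(nmi_similarity(toy_corpus, c("g1", "g2"), c("g1", "g2")), 1.0)
  expect_equal(nmi_similarity(toy_corpus, "g1", "g3"), 0)      # disjoint
  expect_equal(nmi_similarity(toy_corpus, character(), character()), 0)
})

test_that("functional similarity matrix matches pairwise NMI and handles empty sets", {
  reg <- entity_registry(c("a", "b"), "disease")
  S <- functional_similarity(toy_corpus, reg)
  expect_equal(S["a", "b"], 0.5, tolerance = 1e-12)
  expect_equal(unname(diag(S)), c(1, 1))

  # registry entity absent from the corpus: whole row/column 0, diagonal too
  reg3 <- entity_registry(c("a", "b", "zz"), "disease")
  S3 <- functional_similarity(toy_corpus, reg3)
  expect_equal(unname(S3["zz", ]), c(0, 0, 0))
  expect_equal(unname(S3[, "zz"]), c(0, 0, 0))

  # identical non-empty sets give off-diagonal 1
  twin <- build_corpus(interaction_table(
    tibble::tibble(entity = c("x", "x", "y", "y", "z"),
                   gene = c("g1", "g2", "g1", "g2", "g3")), "miRNA"))
  St <- functional_similarity(twin, entity_registry(c("x", "y", "z"), "miRNA"))
  expect_equal(St["x", "y"], 1)
})

test_that("similarity matrices match the brute-force oracle on random corpora", {
  set.seed(42)
  for (rep in 1:100) {
    tab <- random_interactions(n_entities = sample(2:5, 1),
                               n_genes = sample(3:6, 1))
    corpus <- build_corpus(tab)
    S <- functional_similarity(corpus, tab$entities)
    oracle <- brute_similarity_matrix(tab$pairs, tab$entities$ids)
    # the oracle puts 1 on every diagonal with H > 0; align the empty-set rule
    for (id in tab$entities$ids) {
      if (set_entropy(corpus, corpus$sets[[id]]) == 0) oracle[id, id] <- 0
    }
    expect_lt(max(abs(S - oracle)), 1e-12)
  }
})

test_that("entropy and NMI satisfy their structural properties", {
  set.seed(7)
  for (rep in 1:200) {
    tab <- random_interactions(n_entities = sample(2:6, 1),
                               n_genes = sample(3:8, 1))
    corpus <- build_corpus(tab)
    genes <- names(corpus$p)
    big <- sample(genes, sample(seq_along(genes), 1))
    small <- big[seq_len(sample(length(big), 1))]
    # subset monotonicity of the entropy
    expect_lte(set_entropy(corpus, small), set_entropy(corpus, big) + 1e-12)
    # intersection entropy bound implies NMI <= 1
    a <- sample(genes, sample(seq_along(genes), 1))
    b <- sample(genes, sample(seq_along(genes), 1))
    expect_lte(set_entropy(corpus, intersect(a, b)),
               min(set_entropy(corpus, a), set_entropy(corpus, b)) + 1e-12)
    s <- nmi_similarity(corpus, a, b)
    expect_gte(s, 0)
    expect_lte(s, 1)
    expect_equal(s, nmi_similarity(corpus, b, a))
  }
})

test_that("produced similarity matrices are symmetric with entries in [0, 1]", {
  set.seed(13)
  for (rep in 1:20) {
    tab <- random_interactions(n_entities = 6, n_genes = 8)
    S <- functional_similarity(build_corpus(tab), tab$entities)
    expect_equal(max(abs(S - t(S))), 0)
    expect_gte(min(S), 0)
    expect_lte(max(S), 1)
  }
})

test_that("semantic/functional blend is a convex combination", {
  ids <- c("d1", "d2")
  sd1 <- matrix(c(1, 0.8, 0.8, 1), 2, dimnames = list(ids, ids))
  sd2 <- matrix(c(1, 0.2, 0.2, 1), 2, dimnames = list(ids, ids))
  expect_equal(integrate_similarity(sd1, sd2, 0.5)["d1", "d2"], 0.5)
  expect_equal(integrate_similarity(sd1, sd2, 1), sd1)
  expect_equal(integrate_similarity(sd1, sd2, 0), sd2)
  expect_error(integrate_similarity(sd1, sd2, 1.5), "alpha")
  sd3 <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_error(integrate_similarity(sd1, sd3, 0.5), "registry")
  # monotone in alpha when sd1 >= sd2 entrywise
  alphas <- seq(0, 1, by = 0.1)
  vals <- vapply(alphas,
                 function(a) integrate_similarity(sd1, sd2, a)["d1", "d2"],
                 numeric(1))
  expect_true(all(diff(vals) >= 0))
})
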