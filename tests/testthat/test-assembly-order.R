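# docking extraction, bit-scores, PNN features, interaction model, ranking

test_that("docking regions follow the length convention", {
  b <- tiny_bgc(2, protein_len = 200L)
  d <- extract_docking(b)
  expect_equal(d$head_seq[1], substr(b$genes[[1]]$protein, 1, 100))
  expect_equal(d$tail_seq[1], substr(b$genes[[1]]$protein, 151, 200))
  expect_warning(d2 <- extract_docking(tiny_bgc(1, protein_len = 40L)),
                 "truncated")
  expect_equal(d2$head_seq[1], d2$tail_seq[1])
})

test_that("pathway anchors exclude terminal docking regions", {
  spec <- fixture_spec(seed = 2, n_genes = 3, order = c(2, 1, 3))
  fx <- make_bgc(spec)
  d <- extract_docking(fx$bgc)
  # first assembly gene (pksA2) lacks a KS in module 1 -> head excluded;
  # last assembly gene (pksA3) carries the TE -> tail excluded
  expect_true(d$head_excluded[d$gene == "pksA2"])
  expect_true(d$tail_excluded[d$gene == "pksA3"])
  expect_false(any(d$head_excluded[d$gene != "pksA2"]))
  expect_false(any(d$tail_excluded[d$gene != "pksA3"]))
})

test_that("bit-scores match a hand-computed alignment and are symmetric", {
  # identical 5-mers align without gaps; the Smith-Waterman score is the
  # sum of BLOSUM62 diagonal entries: M=5 K=5 L=4 V=4 A=4 -> 22
  expected_bits <- (0.267 * 22 - log(0.041)) / log(2)
  expect_equal(bitscore("MKLVA", "MKLVA"), expected_bits, tolerance = 1e-6)
  set.seed(1)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:5) {
    x <- paste(sample(aa, 30, replace = TRUE), collapse = "")
    y <- paste(sample(aa, 30, replace = TRUE), collapse = "")
    expect_equal(bitscore(x, y), bitscore(y, x))
    expect_gte(bitscore(x, x), bitscore(x, y))
  }
  expect_equal(bitscore("", "MKLV"), 0)
})

test_that("pair similarity is the sum of its component scores", {
  p <- docking_pair("MKLVAMKLVA", "ACDEFACDEF", id = "p")
  q <- docking_pair("MKIVAMKIVA", "ACDFFACDFF", id = "q")
  expect_equal(pair_distance(p, q),
               bitscore(p$head_seq, q$head_seq) +
                 bitscore(p$tail_seq, q$tail_seq))
  expect_equal(pair_distance(p, q), pair_distance(q, p))
})

test_that("PNN feature vectors have the documented dimensions", {
  train <- make_docking_training(seed = 1, n_codes = 4, pos_per_code = 3,
                                 n_neg = 12)
  q <- train[[1]]
  f4 <- pnn_features(q, train, n = 3, feature_mode = "per_score")
  expect_length(f4, 12L)  # 2 scores x 2 classes x 3 neighbours
  f2 <- pnn_features(q, train, n = 3, feature_mode = "summed")
  expect_length(f2, 6L)   # 2n features
  # a query identical to a positive pair is its own top neighbour
  sc <- pair_distance(q, q)
  expect_equal(f2[1], sc)
  expect_error(pnn_features(q, train, n = 100), "insufficient")
})

test_that("the interaction model balances classes and separates the planted motifs", {
  train <- make_docking_training(seed = 3, n_codes = 6, pos_per_code = 4,
                                 n_neg = 96)
  m <- train_interaction_model(train, seed = 3)
  expect_equal(m$n_neg, m$n_pos)
  # held-out pairs from the same code pool
  test <- make_docking_training(seed = 99, n_codes = 6, pos_per_code = 2,
                                n_neg = 12)
  p <- predict_interaction(m, test)
  expect_true(all(p > 0 & p < 1))
  labs <- vapply(test, function(x) isTRUE(x$label), TRUE)
  expect_equal(mean((p > 0.5) == labs), 1)
  expect_error(train_interaction_model(train[1:5]), "required")
})

test_that("pathway scoring reproduces hand-evaluated sums and weights", {
  S <- matrix(NA_real_, 3, 3, dimnames = list(c("A", "B", "C"),
                                              c("A", "B", "C")))
  S["A", "B"] <- 0.9; S["B", "C"] <- 0.8; S["B", "A"] <- 0.2
  S["C", "B"] <- 0.1; S["A", "C"] <- 0.3; S["C", "A"] <- 0.4
  ranks <- c(A = 1L, B = 2L, C = 3L)
  expect_equal(score_pathway("A", S, ranks), 0)
  # unit weights collapse to the plain sum
  expect_equal(score_pathway(c("A", "B", "C"), S, ranks), 1.7)
  # w_forward = 2 doubles the forward-adjacent pairs only
  expect_equal(score_pathway(c("A", "B", "C"), S, ranks, w_forward = 2),
               2 * 0.9 + 2 * 0.8)
  # backward pair B->A with w_backward = 3
  expect_equal(score_pathway(c("B", "A", "C"), S, ranks, w_backward = 3),
               3 * 0.2 + 0.3)
  expect_error(score_pathway(c("B", "B", "C"), S, ranks), "missing pair")
})

test_that("unit-weight pathway scores equal plain sums on random instances", {
  set.seed(11)
  for (i in 1:200) {
    g <- sample(2:5, 1)
    ids <- paste0("g", seq_len(g))
    S <- matrix(runif(g * g), g, g, dimnames = list(ids, ids))
    ranks <- stats::setNames(sample(seq_len(g)), ids)
    ord <- sample(ids)
    plain <- sum(S[cbind(ord[-g], ord[-1])])
    expect_equal(score_pathway(ord, S, ranks), plain, tolerance = 1e-12)
  }
})

test_that("exhaustive ranking enumerates g! orders with deterministic ties", {
  for (g in c(1, 3, 6)) {
    r <- rank_pathways(tiny_bgc(g), model = NULL, cap = 10)
    expect_equal(r$n_candidates, factorial(g))
  }
  r1 <- rank_pathways(tiny_bgc(4), model = NULL, cap = 30)
  # constant pair scores: every order ties; ties break lexicographically
  expect_equal(r1$orders$order[1], "g1,g2,g3,g4")
  expect_equal(r1$orders$score[1], r1$orders$score[24])
})

test_that("branch-and-bound agrees with exhaustive enumeration", {
  train <- make_docking_training(seed = 21, n_codes = 4, pos_per_code = 3,
                                 n_neg = 24)
  model <- train_interaction_model(train, seed = 21)
  for (i in 1:3) {
    g <- 3L + i
    b <- tiny_bgc(g, seed = i)  # random proteins: varied pair scores
    ex <- rank_pathways(b, model, cap = factorial(g))
    # force the bounded search by lowering the exhaustive limit
    bb <- rank_pathways(b, model, cap = factorial(g), exhaustive_limit = 1L)
    expect_equal(bb$orders$score, ex$orders$score, tolerance = 1e-9)
    # within each tied score group the same permutations are found
    grp <- function(o) split(o$order, round(o$score, 9))
    expect_equal(lapply(grp(bb$orders), sort), lapply(grp(ex$orders), sort))
  }
})

test_that("a scrambled planted order is recovered at rank 1", {
  train <- make_docking_training(seed = 4)
  model <- train_interaction_model(train, seed = 4)
  spec <- fixture_spec(seed = 8, n_genes = 4, modules_per_gene = 1,
                       order = c(3, 1, 4, 2))
  fx <- make_bgc(spec)
  r <- rank_pathways(fx$bgc, model)
  expect_equal(r$orders$order[1], paste(fx$truth$order, collapse = ","))
})

test_that("scores are invariant under gene relabeling", {
  spec <- fixture_spec(seed = 12, n_genes = 3, modules_per_gene = 1)
  fx <- make_bgc(spec)
  train <- make_docking_training(seed = 12)
  model <- train_interaction_model(train, seed = 12)
  r1 <- rank_pathways(fx$bgc, model)
  relabeled <- fx$bgc
  for (i in seq_along(relabeled$genes))
    relabeled$genes[[i]]$id <- paste0("zz", i)
  r2 <- rank_pathways(relabeled, model)
  expect_equal(r1$orders$score, r2$orders$score, tolerance = 1e-12)
})
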