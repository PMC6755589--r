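test_that("1-NN scores are the max Tanimoto over query compounds", {
  query <- random_bitmatrix(10, 64, p = 0.3, seed = 1)
  lib <- random_bitmatrix(50, 64, p = 0.3, seed = 2)
  scores <- knn_scores(query, lib)
  manual <- vapply(1:50, function(i) {
    max(vapply(1:10, function(q)
      tanimoto_loop(lib$bits[i, ], query$bits[q, ]), numeric(1)))
  }, numeric(1))
  expect_equal(unname(scores), manual)

  # a library compound identical to a query compound scores 1
  lib2 <- bit_matrix(rbind(query$bits[3, ], lib$bits),
                     c("copy", lib$ids), lib$scheme_tag)
  expect_equal(unname(knn_scores(query, lib2)["copy"]), 1)

  # single-compound query reduces to plain Tanimoto
  q1 <- bit_matrix(query$bits[1, , drop = FALSE], "q1", query$scheme_tag)
  s1 <- knn_scores(q1, lib)
  expect_equal(unname(s1),
               vapply(1:50, function(i)
                 tanimoto_loop(lib$bits[i, ], query$bits[1, ]), numeric(1)))
})

test_that("single-fingerprint scores are per-compound Tanimoto values", {
  lib <- random_bitmatrix(30, 32, p = 0.4, seed = 3)
  fp <- build_dfp(count_bits(lib), 0.5)
  scores <- single_fp_scores(fp, lib)
  manual <- vapply(1:30, function(i)
    tanimoto_loop(fp$bits, lib$bits[i, ]), numeric(1))
  expect_equal(unname(scores), manual)

  zero <- database_fingerprint(rep(0L, 32), "SB-DFP", 0.01, 10,
                               lib$scheme_tag)
  expect_equal(unname(single_fp_scores(zero, lib)), rep(0, 30))
})

test_that("recovery rate is exact for separable and inverted rankings", {
  labels <- c(rep(1, 5), rep(0, 20))
  top <- c(runif(5, 0.8, 1), runif(20, 0, 0.5))
  expect_equal(recovery_rate(top, labels), 1)
  bottom <- c(runif(5, 0, 0.2), runif(20, 0.5, 1))
  expect_equal(recovery_rate(bottom, labels), 0)
  expect_error(recovery_rate(top, rep(0, 25)), "no actives")
  expect_error(recovery_rate(top, labels, selection_size = 26),
               "selection_size")
})

test_that("ranking ties are broken by identifier, not input position", {
  scores <- c(a9 = 0.5, a1 = 0.9, a5 = 0.5, a3 = 0.5)
  labels <- c(1, 0, 1, 0)
  # cutoff 2: top is a1 (0.9), then the 0.5-tie resolves to a3 (< a5 < a9)
  expect_equal(recovery_rate(scores, labels, selection_size = 2), 0)
  # cutoff 3 admits a5 (active)
  expect_equal(recovery_rate(scores, labels, selection_size = 3), 0.5)

  # permutation invariance of RR and AUC under the deterministic tie rule
  set.seed(7)
  n <- 40
  sc <- round(runif(n), 1)              # plenty of ties
  lb <- rbinom(n, 1, 0.3); lb[1] <- 1; lb[2] <- 0
  ids <- sprintf("c%02d", 1:n)
  names(sc) <- ids
  perm <- sample(n)
  expect_equal(recovery_rate(sc[perm], lb[perm], 10),
               recovery_rate(sc, lb, 10))
  expect_equal(roc_auc(sc[perm], lb[perm])$auc, roc_auc(sc, lb)$auc)
})

test_that("AUC equals the all-pairs counting oracle, with ties at half", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), c(rep(1, 4), rep(0, 6)))$auc, 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "at least one")

  set.seed(9)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    sc <- round(runif(n), 1)
    lb <- c(1, 0, rbinom(n - 2, 1, 0.4))
    res <- roc_auc(sc, lb)
    act <- sc[lb == 1]; dec <- sc[lb == 0]
    wins <- ties <- 0
    for (a in act) for (d in dec) {
      if (a > d) wins <- wins + 1 else if (a == d) ties <- ties + 1
    }
    oracle <- (wins + 0.5 * ties) / (length(act) * length(dec))
    expect_equal(res$auc, oracle, tolerance = 1e-12)

    # trapezoidal area under the returned curve equals the rank-based AUC
    cv <- res$curve
    trap <- sum(diff(cv$fpr) * (head(cv$tpr, -1) + tail(cv$tpr, -1)) / 2)
    expect_equal(trap, res$auc, tolerance = 1e-10)
  }
})

test_that("rank-based AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  sc <- round(runif(60), 2)
  lb <- c(1, 0, rbinom(58, 1, 0.3))
  ours <- roc_auc(sc, lb)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("benchmark is reproducible and honors its protocol", {
  spec <- generator_spec(n_bits = 64, enriched_bits = 0:9,
                         enriched_probs = rep(0.6, 10))
  fx <- make_screening_fixture(spec, 40, 200, seed = 5)
  b1 <- benchmark(fx$actives, fx$decoys, fx$reference,
                  n_reps = 2, query_size = 10, seed = 7)
  b2 <- benchmark(fx$actives, fx$decoys, fx$reference,
                  n_reps = 2, query_size = 10, seed = 7)
  expect_identical(b1$summary, b2$summary)
  expect_identical(b1$replicates, b2$replicates)

  # replicate 1 is unchanged when more replicates are requested
  b3 <- benchmark(fx$actives, fx$decoys, fx$reference,
                  n_reps = 4, query_size = 10, seed = 7)
  expect_equal(b3$replicates[b3$replicates$replicate %in% 1:2, ],
               b1$replicates)

  # different seeds give different draws
  b4 <- benchmark(fx$actives, fx$decoys, fx$reference,
                  n_reps = 2, query_size = 10, seed = 8)
  expect_false(identical(b1$replicates$rr, b4$replicates$rr))

  expect_error(benchmark(fx$actives, fx$decoys, fx$reference,
                         query_size = 40), "more actives")
  clash <- bit_matrix(fx$decoys$bits[1:5, ], fx$actives$ids[1:5],
                      fx$decoys$scheme_tag)
  expect_error(benchmark(fx$actives, clash, fx$reference,
                         n_reps = 1, query_size = 10), "disjoint")
})

test_that("without signal every strategy hovers at AUC one half", {
  spec <- generator_spec(n_bits = 64)
  fx <- make_screening_fixture(spec, 60, 300, seed = 21)
  b <- benchmark(fx$actives, fx$decoys, fx$reference,
                 n_reps = 10, query_size = 10, seed = 3)
  expect_true(all(abs(b$summary$auc_mean - 0.5) < 0.08))
})

test_that("planted enrichment is exploited best by the SB-DFP query", {
  # enrichment 0.2 -> 0.9 gives the actives an intra-set Tanimoto median
  # near 0.4, in the range real activity classes show
  base <- generator_spec(166)$base_probs
  base[1:20] <- 0.2
  spec <- generator_spec(n_bits = 166, base_probs = base,
                         enriched_bits = 0:19,
                         enriched_probs = rep(0.9, 20))
  fx <- make_screening_fixture(spec, 60, 500, seed = 2)
  b <- benchmark(fx$actives, fx$decoys, fx$reference,
                 n_reps = 10, query_size = 10, seed = 4)
  s <- b$summary
  auc <- setNames(s$auc_mean, s$strategy)
  expect_gt(auc[["SB-DFP"]], 0.9)
  expect_gte(auc[["SB-DFP"]], auc[["1-NN"]])
  expect_gt(auc[["1-NN"]], auc[["DFP"]])

  cmp <- best_strategy(b, "auc")
  expect_true(cmp$best[cmp$strategy == "SB-DFP"])
})

test_that("alpha sweep reports one summary block per level", {
  spec <- generator_spec(n_bits = 64, enriched_bits = 0:4,
                         enriched_probs = rep(0.7, 5))
  fx <- make_screening_fixture(spec, 30, 100, seed = 9)
  tab <- benchmark_alpha_sweep(fx$actives, fx$decoys, fx$reference,
                               alphas = c(0.05, 0.01), n_reps = 2,
                               query_size = 5, seed = 1)
  expect_equal(nrow(tab), 2 * 3)
  expect_setequal(unique(tab$alpha), c(0.05, 0.01))
  # 1-NN and DFP do not depend on alpha
  one_nn <- tab[tab$strategy == "1-NN", ]
  expect_equal(one_nn$auc_mean[1], one_nn$auc_mean[2])
})
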