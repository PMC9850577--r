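# The seven generation metrics, threshold sweep, and embedding analytics.

test_that("generation sets flag validity consistently with canonicalization", {
  gs <- make_generation_set("CCO", c("CCC", "C(C", "OCC", ""))
  expect_equal(gs$valid, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(gs$canonical[3], canonicalize_smiles("CCO"))
  expect_error(make_generation_set("C(C", "CCO"), "invalid source")
})

test_that("hand-enumerable metric cases come out exactly", {
  or <- toy_oracle()
  tab <- toy_oracle_table()
  # source 1: 20 valid copies of one molecule; source 2: 20 invalid strings
  s1 <- make_generation_set("CCO", rep("CCC", 20))
  s2 <- make_generation_set("CCN", rep("C(C", 20))
  met <- compute_metrics(list(s1, s2), train_set = c("CCO", "CCN"),
                         oracle = or, delta = 0, epsilon = 0.3)
  expect_equal(met$validity, 0.5)
  expect_equal(met$novelty, 0.5)
  # only source 1 contributes to the conditional means
  expect_equal(met$property, unname(tab[canonicalize_smiles("CCC")]))
  expect_equal(met$similarity, tanimoto_smiles("CCO", "CCC"))
  expect_equal(met$diversity, 0)       # identical outputs
  expect_equal(met$total, met$validity + met$novelty + met$property +
                 met$improvement + met$similarity + met$diversity)

  # outputs identical to an in-training source: similarity 1, diversity 0,
  # and no success when delta > 0
  s3 <- make_generation_set("CCO", rep("CCO", 20))
  met3 <- compute_metrics(list(s3), train_set = c("CCO"), oracle = or,
                          delta = 0.01, epsilon = 0.3)
  expect_equal(met3$similarity, 1)
  expect_equal(met3$diversity, 0)
  expect_equal(met3$improvement, 0)
  expect_equal(met3$success_rate, 0)
  expect_equal(met3$novelty, 0)

  # two distinct valid outputs among invalid ones: the diversity term is
  # 1 - their pairwise similarity
  a <- "CCC"; b <- "CCCCC"
  s4 <- make_generation_set("CCCC", c(a, b, rep("C(C", 18)))
  met4 <- compute_metrics(list(s4), train_set = "CCCC", oracle = or,
                          delta = 0, epsilon = 0.3)
  expect_equal(met4$diversity, 1 - tanimoto_smiles(a, b))
})

test_that("metrics agree with independent brute-force enumeration", {
  or <- toy_oracle()
  tab <- toy_oracle_table()
  set.seed(77)
  for (trial in 1:20) {
    sets <- random_toy_sets(sample(2:4, 1), k = 8L)
    train <- sample(toy_pool_valid, 6)
    delta <- sample(c(0, 0.05), 1)
    eps <- sample(c(0.2, 0.4), 1)
    ours <- compute_metrics(sets, train, or, delta = delta, epsilon = eps)
    ref <- naive_metrics(sets, train, tab, delta, eps)
    for (nm in names(ref)) {
      expect_equal(ours[[nm]], ref[[nm]], tolerance = 1e-12, label = nm)
    }
  }
})

test_that("success rate is dominated by validity and novelty", {
  or <- toy_oracle()
  set.seed(5)
  for (trial in 1:10) {
    sets <- random_toy_sets(3, k = 6L)
    train <- sample(toy_pool_valid, 8)
    met <- compute_metrics(sets, train, or, delta = 0, epsilon = 0.3)
    expect_lte(met$success_rate, met$validity)
    expect_lte(met$success_rate, met$novelty)
  }
})

test_that("threshold sweep is monotone with the advertised grid", {
  or <- toy_oracle()
  set.seed(21)
  sets <- random_toy_sets(6, k = 10L)
  sweep <- success_rate_sweep(sets, toy_pool_valid[1:5], or, delta = 0)
  expect_equal(nrow(sweep), 7L)
  expect_equal(sweep$threshold, seq(0.40, 0.70, by = 0.05))
  expect_true(all(diff(sweep$success_rate) <= 0))
  expect_equal(attr(sweep, "mean"), mean(sweep$success_rate))
  one <- success_rate_sweep(sets, toy_pool_valid[1:5], or, delta = 0,
                            thresholds = 0.5)
  expect_equal(attr(one, "mean"), one$success_rate)
  expect_error(success_rate_sweep(sets, toy_pool_valid[1:5], or,
                                  thresholds = numeric(0)), "empty")
})

test_that("Kruskal-Wallis H matches the rank closed form", {
  # complete separation of two samples of 5: ranks 1..5 vs 6..10
  x <- c(0.1, 0.2, 0.3, 0.4, 0.5); y <- c(1, 2, 3, 4, 5)
  expect_equal(unname(stats::kruskal.test(list(x, y))$statistic),
               12 / (10 * 11) * (5 * (3 - 5.5)^2 + 5 * (8 - 5.5)^2),
               tolerance = 1e-10)
  expect_equal(naive_kruskal_h(x, y), 12 / 110 * 62.5, tolerance = 1e-10)
  # random data: library statistic equals the independent closed form
  set.seed(14)
  for (i in 1:25) {
    a <- rnorm(sample(5:20, 1)); b <- rnorm(sample(5:20, 1), mean = 0.5)
    expect_equal(unname(stats::kruskal.test(list(a, b))$statistic),
                 naive_kruskal_h(a, b), tolerance = 1e-8)
  }
})

test_that("embedding analysis separates pair populations after training", {
  m <- fit_small()
  syn <- syn_small()
  mols <- unique(c(syn$pairs$source, syn$pairs$target))
  parts <- partition_pairs_by_similarity(mols, threshold = 0.4)
  expect_gt(nrow(parts$similar), 0)
  expect_gt(nrow(parts$dissimilar), 0)
  emb <- embedding_analysis(m, mols, parts$similar, parts$dissimilar)
  expect_equal(dim(emb$embedding), c(length(mols), 2L))
  expect_gte(emb$H, 0)
  expect_equal(emb$H,
               naive_kruskal_h(emb$similar_distances,
                               emb$dissimilar_distances),
               tolerance = 1e-8)
  expect_error(embedding_analysis(m, mols, parts$similar[0, ],
                                  parts$dissimilar), "non-empty")
  # null behaviour: two samples from one distribution are rarely significant
  set.seed(3)
  ps <- replicate(40, stats::kruskal.test(list(rnorm(15), rnorm(15)))$p.value)
  expect_gt(mean(ps > 0.05), 0.8)
})

test_that("generation tables round-trip through TSV", {
  sets <- list(make_generation_set("CCO", c("CCC", "C(C", "CCN")),
               make_generation_set("CCN", c("CCO", "CCCC", "xyz")))
  path <- tempfile(fileext = ".tsv")
  write_generation_table(sets, path)
  back <- read_generation_table(path)
  expect_length(back, 2L)
  expect_equal(back[[1]]$source, "CCO")
  expect_equal(back[[1]]$outputs, sets[[1]]$outputs)
  expect_equal(back[[2]]$valid, sets[[2]]$valid)
})
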