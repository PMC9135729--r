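test_that("Otsuka-Ochiai similarity follows |A.B|/sqrt(|A||B|)", {
  fs <- feature_set(list(
    a__mut_gene = c("r1", "r2", "r3", "r4"),
    b__mut_gene = c("r1", "r2"),
    c__mut_gene = c("r1", "r2", "r3", "r4"),
    d__mut_gene = c("r5", "r6")))
  K <- similarity_matrix(fs)
  expect_equal(K["a__mut_gene", "b__mut_gene"], 2 / sqrt(8))
  expect_equal(K["a__mut_gene", "c__mut_gene"], 1)  # identical sets
  expect_equal(K["a__mut_gene", "d__mut_gene"], 0)  # disjoint sets
  expect_equal(K, t(K))
  expect_equal(unname(diag(K)), rep(1, 4))
  expect_error(similarity_matrix(feature_set()), "empty")
})

test_that("clustering separates zero-similarity blocks deterministically", {
  # two blocks of mutually identical features, zero cross-similarity
  fs <- feature_set(list(
    a1__mut_gene = c("r1", "r2"), a2__mut_gene = c("r1", "r2"),
    a3__mut_gene = c("r1", "r2"),
    b1__mut_gene = c("r3", "r4"), b2__mut_gene = c("r3", "r4"),
    b3__mut_gene = c("r3", "r4")))
  sm <- build_similarity_model(fs, names(fs$members), min_cluster_size = 1)
  cl <- sm$cluster
  expect_length(unique(cl), 2L)
  expect_length(unique(cl[1:3]), 1L)
  expect_length(unique(cl[4:6]), 1L)

  # single feature: one singleton cluster
  one <- build_similarity_model(
    feature_set(list(x__mut_gene = "r1")), "x__mut_gene",
    min_cluster_size = 1)
  expect_length(unique(one$cluster), 1L)

  # identical inputs give identical assignments
  sys <- toy_feature_system(seed = 8)
  c1 <- build_similarity_model(sys$ref, sys$ids, min_cluster_size = 5)$cluster
  c2 <- build_similarity_model(sys$ref, sys$ids, min_cluster_size = 5)$cluster
  expect_identical(c1, c2)

  # fewer features than min_cluster_size: single cluster with warning
  expect_warning(cluster_features(similarity_matrix(fs),
                                  min_cluster_size = 100),
                 "min_cluster_size")
})

test_that("penalty factors sum floored same-cluster similarities", {
  ref <- feature_set(list(
    a__mut_gene = c("r1", "r2", "r3"),
    b__mut_gene = c("r1", "r2", "r3"),
    c__mut_gene = c("r1", "r2", "r3"),
    lone__mut_gene = c("r4", "r5"),
    weak1__mut_gene = sprintf("r%d", 10:29),
    weak2__mut_gene = c("r10", sprintf("r%d", 40:58))))
  sm <- build_similarity_model(ref, names(ref$members), min_cluster_size = 1)

  # feature alone in its cluster
  p1 <- penalty_factors(sm, "lone__mut_gene")
  expect_equal(unname(p1$eps), 1)

  # three identical features in one cluster: eps = 3 each
  p3 <- penalty_factors(sm, c("a__mut_gene", "b__mut_gene", "c__mut_gene"))
  expect_equal(unname(p3$eps), c(3, 3, 3))
  expect_equal(p3$efn, 1)  # n_model defaults to present count: 3/3

  # similarity below the 0.1 floor contributes nothing
  K <- sm$K
  expect_equal(K["weak1__mut_gene", "weak2__mut_gene"], 1 / sqrt(400))
  expect_lt(K["weak1__mut_gene", "weak2__mut_gene"], 0.1)
  # force the weak pair into one cluster to isolate the flooring rule
  sm$cluster[c("weak1__mut_gene", "weak2__mut_gene")] <- "cx"
  pw <- penalty_factors(sm, c("weak1__mut_gene", "weak2__mut_gene"))
  expect_equal(unname(pw$eps), c(1, 1))

  expect_error(penalty_factors(sm, "nope__mut_gene"), "not covered")
  p0 <- penalty_factors(sm, character(0))
  expect_equal(p0$n_present, 0L)
})

test_that("signature scores follow the penalized-sum algebra", {
  ref <- feature_set(list(f__mut_gene = c("r1", "r2")))
  sm <- build_similarity_model(ref, "f__mut_gene", min_cluster_size = 1)
  pen <- penalty_factors(sm, "f__mut_gene", n_model = 1)
  expect_equal(igensig_score(c(f__mut_gene = 2), pen), 2)

  # three exact copies of the same feature, w = 2 each: score still 2
  ref3 <- feature_set(list(f1__mut_gene = c("r1", "r2"),
                           f2__mut_gene = c("r1", "r2"),
                           f3__mut_gene = c("r1", "r2")))
  ids3 <- names(ref3$members)
  sm3 <- build_similarity_model(ref3, ids3, min_cluster_size = 1)
  pen3 <- penalty_factors(sm3, ids3, n_model = 3)
  expect_equal(unname(pen3$eps), c(3, 3, 3))
  expect_equal(pen3$efn, 1)
  expect_equal(igensig_score(setNames(rep(2, 3), ids3), pen3), 2)

  # mutually non-redundant features: score = mean of the weights
  refn <- feature_set(list(x__mut_gene = c("r1", "r2"),
                           y__mut_gene = c("r3", "r4"),
                           z__mut_gene = c("r5", "r6")))
  idsn <- names(refn$members)
  smn <- build_similarity_model(refn, idsn, min_cluster_size = 1)
  penn <- penalty_factors(smn, idsn, n_model = 3)
  w <- setNames(c(1, 2, 6), idsn)
  expect_equal(igensig_score(w, penn), mean(w))
  expect_gte(igensig_score(w, penn), min(w))
  expect_lte(igensig_score(w, penn), max(w))
})

test_that("adding a non-redundant positive-weight feature never lowers the raw sum", {
  # mutually disjoint reference sets: every feature its own cluster, eps = 1,
  # so adding one more feature adds exactly its weight to the sum
  ids <- sprintf("q%02d__mut_gene", 1:12)
  ref <- feature_set(setNames(
    lapply(1:12, function(i) sprintf("r%d", (2 * i):(2 * i + 1))), ids))
  sm <- build_similarity_model(ref, ids, min_cluster_size = 1)
  w <- setNames(seq(0.5, 3, length.out = 12), ids)
  set.seed(14)
  for (rep in 1:10) {
    present <- sample(ids, sample(2:11, 1))
    extra <- sample(setdiff(ids, present), 1)
    ewsum <- function(p) {
      pen <- penalty_factors(sm, p, n_model = 12)
      sum(w[names(pen$eps)] / pen$eps)
    }
    expect_gte(ewsum(c(present, extra)) + 1e-12, ewsum(present))
    expect_equal(ewsum(c(present, extra)) - ewsum(present),
                 unname(w[extra]), tolerance = 1e-12)
  }

  # the score matches a from-scratch recomputation on an entangled system
  sys <- toy_feature_system(seed = 14)
  smc <- build_similarity_model(sys$ref, sys$ids, min_cluster_size = 5)
  wc <- setNames(sys$wt$weight, sys$wt$feature_id)
  idx <- subject_index(sys$cohort)
  for (s in names(idx)[1:10]) {
    present <- idx[[s]]
    pen <- penalty_factors(smc, present, n_model = nrow(sys$wt))
    expect_equal(igensig_score(wc, pen),
                 sum(wc[present] / pen$eps[present]) / pen$efn)
  }
})

test_that("scores of subjects without model features are zero", {
  sys <- toy_feature_system(seed = 19)
  sm <- build_similarity_model(sys$ref, sys$ids, min_cluster_size = 5)
  cohort <- feature_set(c(sys$cohort$members,
                          list(other__mut_gene = c("ZZ1", "ZZ2"))))
  sc <- score_cohort(list(sensitive = sys$wt), cohort, sm,
                     subjects = c("ZZ1", sys$subjects[1]))
  expect_equal(sc$sensitive[sc$subject_id == "ZZ1"], 0)
  expect_gt(sc$sensitive[sc$subject_id == sys$subjects[1]], 0)
  expect_equal(sc$resistant, c(0, 0))
})

test_that("fractionally trimmed mean is replication-invariant", {
  expect_equal(trimmed_mean_frac(c(1, 2, 9), 0.3), 2.5)
  set.seed(2)
  for (i in 1:20) {
    x <- rexp(sample(1:9, 1)) * 3
    for (k in c(2, 3, 5))
      expect_equal(trimmed_mean_frac(rep(x, k), 0.3),
                   trimmed_mean_frac(x, 0.3), tolerance = 1e-12)
  }
  # coincides with the classical trim when trim*n is integral
  x <- rexp(10)
  expect_equal(trimmed_mean_frac(x, 0.3), mean(x, trim = 0.3))
})
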