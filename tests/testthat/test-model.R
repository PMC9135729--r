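# small but fully trainable synthetic setup reused across blocks
small_training_case <- function(seed = 2) {
  cfg <- sim_config(seed = seed, n_subjects = 200, n_genes = 300,
                    n_blocks = 6, block_size = 12, n_causal_blocks = 3,
                    activation_rate = 0.18, n_reference = 100)
  sim <- simulate_cohort(cfg)
  config <- igsig_config(B = 1000L, min_sensitive = 10)
  fs <- featurize_cohort(sim$expression, sim$mutations, config)
  ref <- featurize_cohort(sim$reference$expression,
                          sim$reference$mutations, config)
  list(sim = sim, fs = fs, ref = ref, config = config)
}

test_that("stratified splits are balanced, exhaustive and reproducible", {
  labels <- data.frame(
    subject_id = sprintf("s%03d", 1:100),
    label = factor(rep(c("sensitive", "intermediate", "resistant"),
                       c(10, 70, 20))))
  plan <- make_splits(labels, seed = 4)
  expect_length(plan, 5L)
  for (sp in plan) {
    expect_length(sp$test, 20L)
    expect_length(intersect(sp$train, sp$test), 0L)
    expect_setequal(c(sp$train, sp$test), labels$subject_id)
    # 10% sensitive overall: 2 +/- 1 sensitive in each test set
    n_sens <- sum(sp$test %in% labels$subject_id[labels$label == "sensitive"])
    expect_lte(abs(n_sens - 2), 1)
  }
  expect_identical(make_splits(labels, seed = 4), plan)
  expect_false(identical(make_splits(labels, seed = 5), plan))
  expect_error(make_splits(labels[1:5, ], seed = 1), "at least 10")
})

test_that("evaluation reproduces pair-counting AUROC and Youden cutpoint", {
  sc <- data.frame(subject_id = c("a", "b", "c", "d"),
                   sensitive = c(4, 3, 2, 1))
  lab <- data.frame(subject_id = c("a", "b", "c", "d"),
                    label = factor(c("sensitive", "intermediate",
                                     "sensitive", "resistant"),
                                   levels = c("sensitive", "intermediate",
                                              "resistant")))
  ev <- evaluate_scores(sc, lab)
  expect_equal(ev$auroc, 0.75)

  # perfect and anti-perfect rankings
  lab2 <- lab; lab2$label <- factor(c("sensitive", "sensitive",
                                      "intermediate", "resistant"),
                                    levels = levels(lab$label))
  expect_equal(evaluate_scores(sc, lab2)$auroc, 1)
  sc_rev <- sc; sc_rev$sensitive <- rev(sc$sensitive)
  expect_equal(evaluate_scores(sc_rev, lab2)$auroc, 0)

  # oracle equivalence on random data, including ties
  set.seed(31)
  for (i in 1:20) {
    n <- sample(8:25, 1)
    s <- data.frame(subject_id = paste0("x", 1:n),
                    sensitive = sample(seq(0, 1, 0.1), n, replace = TRUE))
    l <- data.frame(subject_id = paste0("x", 1:n),
                    label = factor(sample(c("sensitive", "intermediate",
                                            "resistant"), n, replace = TRUE,
                                          prob = c(.3, .5, .2)),
                                   levels = levels(lab$label)))
    if (length(unique(l$label == "sensitive")) < 2) next
    ev <- evaluate_scores(s, l)
    expect_equal(ev$auroc, brute_auroc(s$sensitive, l$label == "sensitive"))
    # cutpoint maximizes Youden's J among observed thresholds
    js <- sapply(s$sensitive, function(t) {
      pred <- s$sensitive > t
      pos <- l$label == "sensitive"
      sum(pred & pos) / sum(pos) - sum(pred & !pos) / sum(!pos)
    })
    pred <- s$sensitive > ev$cutpoint
    pos <- l$label == "sensitive"
    j_at <- sum(pred & pos) / sum(pos) - sum(pred & !pos) / sum(!pos)
    expect_gte(j_at + 1e-9, max(js))
  }

  expect_error(evaluate_scores(sc, within(lab, label[] <- "sensitive")),
               "both")
})

test_that("training recovers planted signal and supports target ablation", {
  case <- small_training_case(2)
  model <- suppressWarnings(train_model(case$fs, case$sim$response, case$ref,
                                        config = case$config, seed = 2))
  wt <- model$weights$sensitive
  expect_gt(nrow(wt), 0)
  # planted causal genes dominate the sensitive table
  expect_gt(mean(wt$gene %in% case$sim$truth$causal_genes), 0.8)

  # ablation removes the listed genes' features entirely
  ab <- igsig_config(B = 1000L, min_sensitive = 10,
                     target_genes = case$sim$truth$causal_genes)
  expect_error(
    suppressWarnings(train_model(case$fs, case$sim$response, case$ref,
                                 config = ab, seed = 2)),
    "unusable")

  # ineligible drugs are refused
  flat <- case$sim$response
  set.seed(1)
  flat$act_area <- runif(nrow(flat), 0.4, 0.6)
  flat$auc <- 1 - flat$act_area
  expect_error(suppressWarnings(
    train_model(case$fs, flat, case$ref, config = case$config, seed = 2)),
    "ineligible")
})

test_that("model application, serialization and determinism are exact", {
  case <- small_training_case(6)
  model <- suppressWarnings(train_model(case$fs, case$sim$response, case$ref,
                                        config = case$config, seed = 6))
  sc1 <- apply_model(model, case$fs)
  model_b <- suppressWarnings(train_model(case$fs, case$sim$response,
                                          case$ref, config = case$config,
                                          seed = 6))
  sc2 <- apply_model(model_b, case$fs)
  expect_identical(sc1, sc2)

  # byte-identical serialization under a fixed seed
  p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".json")
  save_model(model, p1); save_model(model_b, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))

  # save/load round trip preserves every score exactly
  back <- load_model(p1)
  sc3 <- apply_model(back, case$fs)
  expect_equal(sc3, sc1, tolerance = 0)
  unlink(c(p1, p2))

  # subjects sharing no model features score zero
  alien <- feature_set(list(zz__mut_gene = c("A1", "A2")))
  sc0 <- apply_model(model, alien)
  expect_true(all(sc0$sensitive == 0 & sc0$resistant == 0))

  # a non-training reference cohort is accepted
  sc_ref <- apply_model(model, case$fs, ref_features = case$fs)
  expect_equal(dim(sc_ref), dim(sc1))
})

test_that("training-set LOO scores do not beat full-weight scores on average", {
  case <- small_training_case(3)
  cfg_loo <- case$config
  cfg_loo$loo <- TRUE
  model <- suppressWarnings(train_model(case$fs, case$sim$response, case$ref,
                                        config = cfg_loo, seed = 3))
  expect_false(is.null(model$train_scores))
  full <- apply_model(model, case$fs,
                      subjects = model$train_scores$subject_id)
  labels <- model$labels
  ev_full <- evaluate_scores(full, labels)
  ev_loo <- evaluate_scores(model$train_scores, labels)
  # overfitting guard: LOO training AUROC should not exceed the full-weight
  # training AUROC by more than noise
  expect_lte(ev_loo$auroc, ev_full$auroc + 0.05)
})

test_that("composite scores combine standardized models sensibly", {
  t1 <- structure(data.frame(subject_id = paste0("s", 1:40),
                             sensitive = rnorm(40), resistant = 0),
                  class = c("score_table", "data.frame"))
  expect_identical(composite_score(list(t1)), t1)

  # two identical tables preserve the ranking
  lab <- data.frame(subject_id = t1$subject_id,
                    label = factor(ifelse(t1$sensitive > 0.5, "sensitive",
                                          "intermediate"),
                                   levels = c("sensitive", "intermediate",
                                              "resistant")))
  comp <- composite_score(list(t1, t1), lab)
  cs <- comp$sensitive[match(t1$subject_id, comp$subject_id)]
  expect_equal(order(cs), order(t1$sensitive))

  comp_m <- composite_score(list(t1, t1), method = "mean")
  cm <- comp_m$sensitive[match(t1$subject_id, comp_m$subject_id)]
  expect_equal(order(cm), order(t1$sensitive))

  t2 <- t1; t2$subject_id <- paste0("z", 1:40)
  expect_error(composite_score(list(t1, t2), lab), "different subject")

  # composite of two noisy complementary models is at least as good on average
  set.seed(40)
  truth <- rep(c(TRUE, FALSE), c(30, 70))
  mk <- function() {
    structure(data.frame(subject_id = sprintf("p%03d", 1:100),
                         sensitive = truth * 1 + rnorm(100, 0, 1.2),
                         resistant = 0),
              class = c("score_table", "data.frame"))
  }
  labs <- data.frame(subject_id = sprintf("p%03d", 1:100),
                     label = factor(ifelse(truth, "sensitive",
                                           "intermediate"),
                                    levels = c("sensitive", "intermediate",
                                               "resistant")))
  gain <- replicate(20, {
    a <- mk(); b <- mk()
    comp <- composite_score(list(a, b), labs)
    evaluate_scores(comp, labs)$auroc -
      max(evaluate_scores(a, labs)$auroc, evaluate_scores(b, labs)$auroc)
  })
  expect_gt(mean(gain), -0.01)
})
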