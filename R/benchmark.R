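#' Restrict a weight table to one expression feature per gene
#'
#' Keeps, for every gene, only the single differential-expression feature
#' with the smallest q-value (ties broken by larger weight, then feature id).
#' Mutation features are untouched. This produces the non-redundant
#' comparison scorer used to quantify how much the deliberately redundant
#' multi-level signature buys under feature dropout.
#'
#' @param wt `weight_table`.
#' @return reduced `weight_table`.
#' @export
restrict_one_level_per_gene <- function(wt) {
  stopifnot(inherits(wt, "weight_table"))
  if (nrow(wt) == 0L) return(wt)
  is_dge <- !is.na(wt$level)
  dge <- wt[is_dge, , drop = FALSE]
  keep_ids <- character(0)
  if (nrow(dge)) {
    ord <- order(dge$gene, dge$q, -dge$weight, dge$feature_id)
    dge <- dge[ord, , drop = FALSE]
    keep_ids <- dge$feature_id[!duplicated(dge$gene)]
  }
  out <- wt[!is_dge | wt$feature_id %in% keep_ids, , drop = FALSE]
  attributes(out)$direction <- attr(wt, "direction")
  attributes(out)$params <- attr(wt, "params")
  class(out) <- class(wt)
  rownames(out) <- NULL
  out
}

#' Planted-signal benchmark on a synthetic cohort
#'
#' End-to-end evaluation harness: simulates a cohort with planted causal
#' expression blocks, featurizes it, labels the drug response by the
#' waterfall method, splits subjects into train/test stratified by label,
#' trains a signature model on the training subjects, and reports the
#' test-set AUROC (sensitive vs rest) — optionally after random membership
#' dropout on the test features, and optionally also for the non-redundant
#' one-feature-per-gene scorer built from the same weights.
#'
#' @param seed integer seed driving the simulation, split, weighting nulls
#'   and dropout.
#' @param cfg `sim_config` (its `seed` is overridden by `seed`).
#' @param config `igsig_config` for the modeling pipeline.
#' @param test_frac test fraction of the stratified split.
#' @param dropout numeric vector of membership-dropout rates to evaluate
#'   (0 = clean).
#' @param baseline also evaluate the one-feature-per-gene scorer.
#' @return list: `auroc` (named by dropout rate), `auroc_baseline` (when
#'   requested), `n_significant`, `n_train`, `n_test`, `model`.
#' @export
planted_benchmark <- function(seed,
                              cfg = sim_config(),
                              config = igsig_config(),
                              test_frac = 0.25,
                              dropout = 0,
                              baseline = FALSE) {
  cfg$seed <- as.integer(seed)
  sim <- simulate_cohort(cfg)
  fs <- featurize_cohort(sim$expression, sim$mutations, config)
  ref_fs <- featurize_cohort(sim$reference$expression,
                             sim$reference$mutations, config)

  act <- stats::setNames(sim$response$act_area, sim$response$subject_id)
  labels <- assign_labels(act, waterfall_cutoffs(act,
                                                 mad_scaled = config$mad_scaled))
  split <- make_splits(labels, seed = seed, n_repeats = 1,
                       test_frac = test_frac)[[1]]

  model <- train_model(fs, sim$response, ref_fs,
                       subjects = split$train, config = config, seed = seed)
  test_fs <- subset_features(fs, split$test)
  test_labels <- labels[labels$subject_id %in% split$test, , drop = FALSE]

  score_one <- function(m, d) {
    tfs <- if (d > 0) corrupt_cohort(test_fs, d, seed = seed + 101L) else test_fs
    sc <- apply_model(m, tfs, subjects = split$test)
    evaluate_scores(sc, test_labels)$auroc
  }
  auroc <- vapply(dropout, function(d) score_one(model, d), numeric(1))
  names(auroc) <- paste0("dropout", dropout)
  out <- list(auroc = auroc,
              n_significant = nrow(model$weights$sensitive) +
                nrow(model$weights$resistant),
              n_train = length(split$train), n_test = length(split$test),
              model = model)
  if (baseline) {
    bmodel <- model
    bmodel$weights <- lapply(model$weights, restrict_one_level_per_gene)
    out$auroc_baseline <- vapply(dropout, function(d) score_one(bmodel, d),
                                 numeric(1))
    names(out$auroc_baseline) <- names(auroc)
  }
  out
}

#' Null false-positive calibration of the feature weighting
#'
#' Simulates a cohort whose drug response is pure noise (`effect_size = 0`),
#' draws a fixed number of its genomic features, runs the permutation
#' weighting in the sensitive direction, and reports the fraction of
#' features reaching `q < q_cut`. Under the null this fraction should be
#' small.
#'
#' @param seed integer seed.
#' @param n_features number of features to test (sampled deterministically).
#' @param B permutations per null distribution.
#' @param q_cut FDR threshold assessed.
#' @param cfg `sim_config` template; its effect size is forced to 0.
#' @return list: `fraction` (of features with `q < q_cut`), `n_tested`.
#' @export
null_calibration <- function(seed, n_features = 200, B = 500, q_cut = 0.1,
                             cfg = sim_config(n_subjects = 150, n_genes = 300,
                                              n_blocks = 6, block_size = 10,
                                              n_causal_blocks = 0,
                                              n_reference = 50)) {
  cfg$effect_size <- 0
  cfg$n_causal_blocks <- 0L
  cfg$seed <- as.integer(seed)
  sim <- simulate_cohort(cfg)
  fs <- featurize_cohort(sim$expression, sim$mutations)
  act <- stats::setNames(sim$response$act_area, sim$response$subject_id)
  ranked <- rank_cohort(act)
  # deterministically sample the tested features among the prevalent ones
  sizes <- vapply(fs$members, function(s)
    sum(s %in% ranked$subject_ids), integer(1))
  elig <- names(fs$members)[sizes >= 5 & sizes < length(ranked$subject_ids)]
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed) + 7L)
  take <- sample(elig, min(n_features, length(elig)))
  sub <- feature_set(fs$members[take])
  st <- feature_stats(ranked, sub, B = B, seed = seed, min_pos = 5)
  q <- qvalues(st$p)
  list(fraction = mean(q < q_cut & st$es > 0), n_tested = nrow(st))
}
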