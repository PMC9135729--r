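#' Modeling configuration
#'
#' Flat list of every tunable default in the pipeline. Values are documented
#' where they are consumed; the headline ones: `B` permutations per null
#' (2000), FDR cutoff `q_cut` (0.1), minimum feature prevalence `min_pos`
#' (5), similarity floor (0.1), penalty trim (0.3), cluster parameters
#' (`min_cluster_size` 40, `cut_depth` 2), eligibility threshold
#' `min_sensitive` (20 sensitive subjects, exclusive).
#'
#' @param ... overrides for any default.
#' @return named list of class `igsig_config`.
#' @export
igsig_config <- function(...) {
  cfg <- list(
    trim_frac = 0.10,        # trimmed-mean trim for fold changes
    var_pctl = 0.20,         # SD-percentile gene filter
    max_level = 6L,
    hotspot_min = 3L,
    gene_min = 2L,
    mad_scaled = FALSE,
    min_sensitive = 20,
    exponent = 1,            # weighted K-S exponent
    B = 2000L,
    min_pos = 5L,
    q_cut = 0.1,
    contra_q = 0.3,
    level1_q = 0.3,
    weight_type = "nes",
    qvalue_method = "storey",
    min_cluster_size = 40L,
    cut_depth = 2L,
    similarity_floor = 0.1,
    trim_penalty = 0.3,
    loo = FALSE,             # leave-one-out scores for training subjects
    target_genes = NULL,     # drug-target ablation: drop these genes' features
    enforce_eligibility = TRUE,
    composite = "logistic")
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config option: ", unknown[1])
  cfg[names(over)] <- over
  structure(cfg, class = "igsig_config")
}

#' Stratified train/test split plan
#'
#' Five (by default) independent random partitions into 80% train / 20% test,
#' stratified by response label so the sensitive fraction is balanced between
#' train and test within one subject per class. Deterministic given `seed`.
#'
#' @param labels `response_labels` (or data.frame with subject_id, label).
#' @param seed integer seed.
#' @param n_repeats number of partitions.
#' @param test_frac test fraction.
#' @return list of class `split_plan`; each element a list with `train` and
#'   `test` subject-id vectors.
#' @export
make_splits <- function(labels, seed, n_repeats = 5, test_frac = 0.2) {
  stopifnot(is.data.frame(labels),
            all(c("subject_id", "label") %in% names(labels)))
  n <- nrow(labels)
  if (n < 10L) stop("need at least 10 labeled subjects")
  if (sum(labels$label == "sensitive") < 2L)
    stop("need at least 2 sensitive subjects to stratify")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  classes <- split(as.character(labels$subject_id), labels$label, drop = TRUE)
  plan <- lapply(seq_len(n_repeats), function(r) {
    test <- unlist(lapply(classes, function(ids) {
      k <- round(length(ids) * test_frac)
      sample(ids, k)
    }), use.names = FALSE)
    list(train = sort(setdiff(labels$subject_id, test)), test = sort(test))
  })
  structure(plan, seed = as.integer(seed), test_frac = test_frac,
            class = "split_plan")
}

#' Train an integral genomic signature model for one drug
#'
#' Runs the full training pipeline on a labeled cohort: drug eligibility
#' (negative AUC skewness, > `min_sensitive` sensitive subjects), waterfall
#' response labelling, weighted K-S feature weighting with permutation FDR in
#' both directions (sensitive: ranked by Act Area; resistant: ranked by AUC),
#' feature selection, and construction of the redundancy model on the
#' unlabeled reference cohort restricted to the significant features.
#' Optionally removes all features of configured drug-target genes before
#' weighting, and computes leave-one-out training-subject scores when
#' `config$loo` is TRUE.
#'
#' @param features `feature_set` for the training cohort.
#' @param response data.frame with subject_id, act_area, auc (see
#'   [complete_response()]); restrict to one drug before calling, or pass
#'   `drug` to filter on a `drug_id` column.
#' @param ref_features `feature_set` for the unlabeled reference cohort.
#' @param drug optional drug id (filters `response$drug_id`).
#' @param subjects optional training subject ids (default: all measured).
#' @param config `igsig_config`.
#' @param seed integer seed for the permutation nulls.
#' @return object of class `igsig_model`.
#' @export
train_model <- function(features, response, ref_features, drug = NULL,
                        subjects = NULL, config = igsig_config(), seed = 1) {
  stopifnot(inherits(features, "feature_set"),
            inherits(ref_features, "feature_set"))
  response <- complete_response(response)
  if (!is.null(drug)) {
    stopifnot("drug_id" %in% names(response))
    response <- response[response$drug_id == drug, , drop = FALSE]
  }
  if (!is.null(subjects))
    response <- response[response$subject_id %in% subjects, , drop = FALSE]
  response <- response[is.finite(response$act_area), , drop = FALSE]
  if (anyDuplicated(response$subject_id))
    stop("multiple measurements per subject for this drug")
  act <- stats::setNames(response$act_area, response$subject_id)
  auc <- stats::setNames(response$auc, response$subject_id)

  elig <- drug_eligibility(act, auc, min_sensitive = config$min_sensitive,
                           mad_scaled = config$mad_scaled)
  if (config$enforce_eligibility && !elig$eligible)
    stop(sprintf(paste0("drug ineligible: skewness(AUC) = %.3f, ",
                        "%d sensitive subjects (need negative skew and > %d)"),
                 elig$skewness, elig$n_sensitive, config$min_sensitive))

  if (!is.null(config$target_genes)) {
    keep <- !(features$meta$gene %in% config$target_genes)
    features <- feature_set(features$members[keep])
  }

  cache <- null_cache(seed)
  directions <- list(sensitive = rank_cohort(act),
                     resistant = rank_cohort(auc))
  weight_tables <- list()
  stats_tables <- list()
  for (dir in names(directions)) {
    st <- feature_stats(directions[[dir]], features, B = config$B,
                        seed = seed, min_pos = config$min_pos,
                        exponent = config$exponent, cache = cache)
    wt <- select_significant(st, q_cut = config$q_cut,
                             min_pos = config$min_pos,
                             contra_q = config$contra_q,
                             level1_q = config$level1_q,
                             weight_type = config$weight_type,
                             qvalue_method = config$qvalue_method,
                             direction = dir)
    weight_tables[[dir]] <- wt
    stats_tables[[dir]] <- st
  }
  if (nrow(weight_tables$sensitive) == 0L && nrow(weight_tables$resistant) == 0L)
    stop("empty weight tables in both directions: model unusable")

  sig_ids <- unique(c(weight_tables$sensitive$feature_id,
                      weight_tables$resistant$feature_id))
  simmodel <- build_similarity_model(
    ref_features, sig_ids,
    min_cluster_size = config$min_cluster_size,
    cut_depth = config$cut_depth,
    similarity_floor = config$similarity_floor)

  model <- structure(
    list(drug = drug %||% "drug",
         weights = weight_tables,
         similarity = simmodel,
         ref_members = ref_features$members[
           intersect(sig_ids, names(ref_features$members))],
         labels = elig$labels,
         cutoffs = elig$cutoffs,
         skewness = elig$skewness,
         config = unclass(config),
         provenance = list(seed = as.integer(seed),
                           n_train = length(act),
                           subjects = sort(names(act)))),
    class = "igsig_model")

  if (isTRUE(config$loo)) {
    model$train_scores <- loo_train_scores(model, features, directions, cache)
  }
  model
}

# Per-training-subject scores with dynamically adjusted (leave-one-out)
# weights: guards against overfitting when scoring subjects that took part
# in the weighting.
loo_train_scores <- function(model, features, directions, cache) {
  cfg <- model$config
  idx <- subject_index(features)
  subjects <- model$provenance$subjects
  out <- data.frame(subject_id = subjects, sensitive = 0, resistant = 0,
                    stringsAsFactors = FALSE)
  for (dir in names(directions)) {
    wt <- model$weights[[dir]]
    if (nrow(wt) == 0L) next
    for (s in seq_along(subjects)) {
      x <- subjects[s]
      wtx <- loo_weight_table(wt, directions[[dir]], features, x,
                              B = cfg$B, cache = cache,
                              exponent = cfg$exponent)
      feats <- intersect(idx[[x]], wtx$feature_id)
      pen <- penalty_factors(model$similarity, feats,
                             n_model = nrow(wtx), trim = cfg$trim_penalty)
      out[[dir]][s] <- igensig_score(
        stats::setNames(wtx$weight, wtx$feature_id), pen)
    }
  }
  class(out) <- c("score_table", "data.frame")
  out
}

#' @export
print.igsig_model <- function(x, ...) {
  cat("igsig_model for", x$drug, "\n",
      " sensitive features:", nrow(x$weights$sensitive), "\n",
      " resistant features:", nrow(x$weights$resistant), "\n",
      " trained on", x$provenance$n_train, "subjects\n")
  invisible(x)
}

#' Apply a trained model to a cohort
#'
#' Scores each subject using only the training weights: subject features are
#' intersected with the model's significant features (features missing from
#' the cohort's feature space simply contribute nothing), penalties are
#' computed against the reference cohort, and sensitive/resistant scores are
#' evaluated separately. Supplying `ref_features` re-estimates redundancy on
#' a different reference cohort (e.g. a tumor-type-restricted one) without
#' touching the weights.
#'
#' @param model `igsig_model`.
#' @param cohort_features `feature_set` of the cohort to score.
#' @param ref_features optional replacement reference `feature_set`.
#' @param subjects optional subject ids to score.
#' @return `score_table` data.frame: subject_id, sensitive, resistant.
#' @export
apply_model <- function(model, cohort_features, ref_features = NULL,
                        subjects = NULL) {
  stopifnot(inherits(model, "igsig_model"))
  simmodel <- model$similarity
  if (!is.null(ref_features)) {
    cfg <- model$config
    simmodel <- build_similarity_model(
      ref_features, simmodel$feature_ids,
      min_cluster_size = cfg$min_cluster_size,
      cut_depth = cfg$cut_depth,
      similarity_floor = cfg$similarity_floor)
  }
  score_cohort(model$weights, cohort_features, simmodel,
               subjects = subjects, trim = model$config$trim_penalty)
}

#' Evaluate scores against response labels
#'
#' Positives are the sensitive subjects; negatives pool intermediate and
#' resistant. AUROC is the rank (Mann-Whitney) area with tie correction; the
#' optimal cutpoint maximizes Youden's J on the empirical ROC curve.
#'
#' @param scores `score_table` (the `sensitive` column is evaluated) or a
#'   data.frame with subject_id and a score column named by `column`.
#' @param labels `response_labels`.
#' @param column score column (default `"sensitive"`).
#' @return list of class `igsig_eval`: `auroc`, `cutpoint`, `confusion`
#'   (counts at the cutpoint), `n_pos`, `n_neg`, `data`.
#' @export
evaluate_scores <- function(scores, labels, column = "sensitive") {
  stopifnot(is.data.frame(scores), is.data.frame(labels),
            column %in% names(scores))
  df <- merge(scores[, c("subject_id", column)],
              labels[, c("subject_id", "label")], by = "subject_id")
  names(df)[2] <- "score"
  df$pos <- df$label == "sensitive"
  if (length(unique(df$pos)) < 2L)
    stop("need both sensitive and non-sensitive subjects with scores")
  roc <- pROC::roc(response = df$pos, predictor = df$score,
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  best <- pROC::coords(roc, "best", best.method = "youden", transpose = FALSE)
  cut <- as.numeric(best$threshold[1])
  pred <- df$score > cut
  confusion <- c(tp = sum(pred & df$pos), fp = sum(pred & !df$pos),
                 fn = sum(!pred & df$pos), tn = sum(!pred & !df$pos))
  structure(list(auroc = as.numeric(pROC::auc(roc)), cutpoint = cut,
                 confusion = confusion, n_pos = sum(df$pos),
                 n_neg = sum(!df$pos), data = df),
            class = "igsig_eval")
}

#' @export
print.igsig_eval <- function(x, ...) {
  cat(sprintf("AUROC %.3f (%d sensitive vs %d other), cutpoint %.4g\n",
              x$auroc, x$n_pos, x$n_neg, x$cutpoint))
  invisible(x)
}

#' Combine score tables into a composite score
#'
#' Standardizes each model's sensitive scores across subjects and combines
#' them either by a logistic fit against the provided labels (default) or by
#' an unweighted mean. A single table is returned unchanged.
#'
#' @param score_tables list of `score_table`s over identical subject sets.
#' @param labels `response_labels` (required for the logistic method).
#' @param method `"logistic"` or `"mean"`.
#' @return `score_table` with the composite in the `sensitive` column.
#' @export
composite_score <- function(score_tables, labels = NULL,
                            method = c("logistic", "mean")) {
  method <- match.arg(method)
  stopifnot(is.list(score_tables), length(score_tables) >= 1L)
  if (length(score_tables) == 1L) return(score_tables[[1]])
  ids <- sort(score_tables[[1]]$subject_id)
  for (t in score_tables)
    if (!identical(sort(t$subject_id), ids))
      stop("score tables cover different subject sets")
  Z <- vapply(score_tables, function(t) {
    s <- t$sensitive[match(ids, t$subject_id)]
    if (stats::sd(s) > 0) (s - mean(s)) / stats::sd(s) else s * 0
  }, numeric(length(ids)))
  comp <- if (method == "mean") {
    rowMeans(Z)
  } else {
    if (is.null(labels)) stop("logistic composite requires labels")
    y <- labels$label[match(ids, labels$subject_id)] == "sensitive"
    if (anyNA(y)) stop("labels missing for some scored subjects")
    dat <- data.frame(y = y, Z)
    fit <- suppressWarnings(stats::glm(y ~ ., data = dat, family = stats::binomial()))
    unname(stats::predict(fit, type = "link"))
  }
  out <- data.frame(subject_id = ids, sensitive = comp, resistant = NA_real_,
                    stringsAsFactors = FALSE)
  class(out) <- c("score_table", "data.frame")
  out
}

#' Serialize a trained model to JSON
#'
#' The file carries the weight tables, cluster assignments, the reference
#' membership lists of the significant features (the similarity matrix is
#' recomputed exactly on load), response cutoffs, the configuration snapshot
#' and provenance. Numbers are written at full precision so a load/save
#' round trip reproduces scores exactly.
#'
#' @param model `igsig_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "igsig_model"))
  payload <- list(
    format = "igsig_model",
    version = 1L,
    drug = model$drug,
    weights = lapply(model$weights, function(wt)
      c(as.list(wt), list(.direction = attr(wt, "direction"),
                          .params = attr(wt, "params")))),
    cluster = as.list(model$similarity$cluster),
    similarity_params = model$similarity$params,
    ref_members = model$ref_members,
    cutoffs = model$cutoffs,
    skewness = model$skewness,
    config = model$config,
    provenance = model$provenance,
    train_scores = model$train_scores)
  # 17 significant digits: IEEE doubles round-trip bit-exactly through text
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = FALSE)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path JSON model file.
#' @return `igsig_model`; the similarity matrix is rebuilt from the stored
#'   reference memberships and is bit-identical to the one saved.
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  if (!identical(p$format, "igsig_model"))
    stop("not an igsig model file: ", path)
  rebuild_wt <- function(w) {
    params <- w$.params
    direction <- w$.direction
    w <- w[!names(w) %in% c(".direction", ".params")]
    df <- as.data.frame(lapply(w, unlist), stringsAsFactors = FALSE)
    if (nrow(df) == 0L)
      df <- data.frame(feature_id = character(), gene = character(),
                       kind = character(), level = integer(),
                       n_pos = integer(), es = numeric(), nes = numeric(),
                       p = numeric(), q = numeric(), weight = numeric())
    structure(df, direction = direction, params = params,
              class = c("weight_table", "data.frame"))
  }
  weights <- lapply(p$weights, rebuild_wt)
  ref_members <- lapply(p$ref_members, unlist)
  sig_ids <- unique(c(weights$sensitive$feature_id,
                      weights$resistant$feature_id))
  sp <- p$similarity_params
  ref_fs <- if (length(ref_members))
    feature_set(ref_members) else feature_set()
  simmodel <- build_similarity_model(ref_fs, sig_ids,
                                     min_cluster_size = sp$min_cluster_size,
                                     cut_depth = sp$cut_depth,
                                     similarity_floor = sp$similarity_floor)
  cfg <- p$config
  if (length(cfg$target_genes) == 0L) cfg$target_genes <- NULL
  model <- list(drug = p$drug, weights = weights, similarity = simmodel,
                ref_members = ref_members, labels = NULL,
                cutoffs = p$cutoffs, skewness = p$skewness,
                config = cfg, provenance = p$provenance)
  if (!is.null(p$train_scores)) {
    ts <- as.data.frame(lapply(p$train_scores, unlist),
                        stringsAsFactors = FALSE)
    class(ts) <- c("score_table", "data.frame")
    model$train_scores <- ts
  }
  class(model) <- "igsig_model"
  model
}
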