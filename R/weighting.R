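#' Rank a cohort by a response metric
#'
#' Sorts subjects in descending metric order (Act Area for the sensitive
#' direction, AUC for the resistant direction); ties are broken by subject id
#' in C-locale order so the ranking is fully deterministic.
#'
#' @param metric named numeric vector (names = subject ids, no duplicates).
#' @return object of class `ranked_cohort`: list with `subject_ids` and
#'   `metric`, both in rank order.
#' @export
rank_cohort <- function(metric) {
  stopifnot(is.numeric(metric), !is.null(names(metric)))
  metric <- metric[is.finite(metric)]
  if (anyDuplicated(names(metric))) stop("duplicate subject ids")
  ord <- order(-metric, names(metric), method = "radix")
  structure(list(subject_ids = names(metric)[ord],
                 metric = unname(metric)[ord]),
            class = "ranked_cohort")
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' GSEA-style running-sum statistic: walking down the ranked cohort, member
#' ("hit") subjects increment the sum by `|metric|^p / sum(|metric_hits|^p)`
#' and non-members decrement it by `1/(N - n_pos)`. The enrichment score is
#' the signed running-sum deviation of maximal absolute value (first such
#' position on ties). When all hit metric weights are zero the hits fall back
#' to equal increments `1/n_pos`.
#'
#' @param ranked `ranked_cohort`.
#' @param members character vector of member subject ids.
#' @param exponent metric weighting exponent p (GSEA "weighted" default 1).
#' @return scalar enrichment score in `[-1, 1]`.
#' @export
es_score <- function(ranked, members, exponent = 1) {
  stopifnot(inherits(ranked, "ranked_cohort"))
  hits <- ranked$subject_ids %in% members
  m <- sum(hits)
  N <- length(hits)
  if (m == 0L) stop("members are disjoint from the ranked cohort")
  if (m == N) stop("members cover the whole cohort")
  run <- ks_running_sum(ranked$metric, hits, exponent)
  run[which.max(abs(run))]
}

ks_running_sum <- function(metric, hits, exponent = 1) {
  N <- length(metric)
  m <- sum(hits)
  w <- abs(metric)^exponent
  nr <- sum(w[hits])
  delta <- rep.int(-1 / (N - m), N)
  delta[hits] <- if (nr > 0) w[hits] / nr else 1 / m
  cumsum(delta)
}

# B random enrichment scores for member sets of size m drawn uniformly
# without replacement; deterministic given `seed`.
ks_null_scores <- function(metric, m, B, seed, exponent = 1) {
  N <- length(metric)
  stopifnot(m >= 1L, m < N, B >= 1L)
  w <- abs(metric)^exponent
  miss <- -1 / (N - m)
  out <- numeric(B)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  for (b in seq_len(B)) {
    idx <- sample.int(N, m)
    nr <- sum(w[idx])
    delta <- rep.int(miss, N)
    delta[idx] <- if (nr > 0) w[idx] / nr else 1 / m
    run <- cumsum(delta)
    out[b] <- run[which.max(abs(run))]
  }
  out
}

#' Permutation null cache
#'
#' Environment caching the null enrichment-score distributions, keyed by
#' (cohort size, member-set size). Entries are seeded deterministically from
#' the base seed and the key, so results do not depend on the order in which
#' features are evaluated (and are identical with caching disabled).
#'
#' @param seed integer base seed.
#' @return environment usable as the `cache` argument of
#'   [permutation_stats()] and friends.
#' @export
null_cache <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$seed <- as.integer(seed)
  e
}

get_null <- function(metric, m, B, cache, exponent = 1, base_seed = NULL) {
  N <- length(metric)
  if (is.null(cache)) {
    return(ks_null_scores(metric, m, B, derive_seed(base_seed, N, m), exponent))
  }
  key <- paste0("N", N, ".m", m, ".B", B)
  if (is.null(cache[[key]]))
    cache[[key]] <- ks_null_scores(metric, m, B,
                                   derive_seed(cache$seed, N, m), exponent)
  cache[[key]]
}

#' Permutation statistics for one feature
#'
#' Compares the observed enrichment score against `B` random member sets of
#' the same size. The normalized enrichment score is
#' `NES = ES / mean(ES_random)` over the same-sign random scores, and the
#' p-value uses the add-one permutation estimator for the enrichment tail:
#' `p = (1 + #[ES_random >= ES_obs]) / (1 + B)` for positive scores (mirrored
#' for negative ones).
#'
#' @param ranked `ranked_cohort`.
#' @param members member subject ids.
#' @param B number of random enrichment scores (>= 100).
#' @param seed base seed (ignored when `cache` carries one).
#' @param cache optional [null_cache()] shared across features.
#' @param exponent K-S weighting exponent.
#' @return one-row data.frame: n_pos, es, nes, p. `nes` is `NA` (with a
#'   warning) when the same-sign null mean is degenerate.
#' @export
permutation_stats <- function(ranked, members, B = 2000, seed = 1,
                              cache = NULL, exponent = 1) {
  stopifnot(B >= 100)
  es <- es_score(ranked, members, exponent)
  m <- sum(ranked$subject_ids %in% members)
  null <- get_null(ranked$metric, m, B, cache, exponent, base_seed = seed)
  stats_from_null(es, null, m)
}

stats_from_null <- function(es, null, m) {
  if (es >= 0) {
    p <- (1 + sum(null >= es)) / (1 + length(null))
    denom <- mean(null[null > 0])
  } else {
    p <- (1 + sum(null <= es)) / (1 + length(null))
    denom <- -mean(null[null < 0])
  }
  nes <- if (!is.finite(denom) || abs(denom) < 1e-12) {
    warning("degenerate permutation null: NES undefined")
    NA_real_
  } else es / denom
  data.frame(n_pos = m, es = es, nes = nes, p = p)
}

#' Enrichment statistics for every feature of a cohort
#'
#' Ranks each feature's member set against the ranked cohort and computes
#' ES/NES/p by permutation. Features overlapping the cohort in fewer than
#' `min_pos` subjects, or covering it entirely, are skipped. Null
#' distributions are shared across features of equal member count via
#' `cache`.
#'
#' @param ranked `ranked_cohort`.
#' @param fs `feature_set`.
#' @param B permutations per null distribution.
#' @param seed base seed for the permutation nulls.
#' @param min_pos minimum member count within the cohort.
#' @param exponent K-S weighting exponent.
#' @param cache optional [null_cache()]; created internally when `NULL`.
#' @return data.frame: feature_id, gene, kind, level, n_pos, es, nes, p.
#' @export
feature_stats <- function(ranked, fs, B = 2000, seed = 1, min_pos = 5,
                          exponent = 1, cache = NULL) {
  stopifnot(inherits(ranked, "ranked_cohort"), inherits(fs, "feature_set"))
  if (is.null(cache)) cache <- null_cache(seed)
  N <- length(ranked$subject_ids)
  ids <- names(fs$members)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    hits <- ranked$subject_ids %in% fs$members[[i]]
    m <- sum(hits)
    if (m < min_pos || m >= N) next
    run <- ks_running_sum(ranked$metric, hits, exponent)
    es <- run[which.max(abs(run))]
    null <- get_null(ranked$metric, m, B, cache, exponent)
    st <- withCallingHandlers(
      stats_from_null(es, null, m),
      warning = function(w) invokeRestart("muffleWarning"))
    rows[[i]] <- cbind(feature_id = ids[i], st)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(cbind(parse_feature_ids(character(0)),
                 data.frame(n_pos = integer(), es = numeric(),
                            nes = numeric(), p = numeric())))
  out <- do.call(rbind, rows)
  meta <- parse_feature_ids(out$feature_id)
  cbind(meta, out[, c("n_pos", "es", "nes", "p")])
}

#' Select significant features and build a weight table
#'
#' Computes FDR q-values over all tested features, retains positively
#' enriched features with `q < q_cut` and at least `min_pos` member subjects,
#' then applies two gene-level plausibility filters to the differential-
#' expression features:
#' * contradictory direction: a gene with an Up feature at `q < q_cut` and any
#'   Down feature at `q < contra_q` (or vice versa) has all its DGE features
#'   removed;
#' * level-1 noise: a gene-side whose only `q < q_cut` features are Level-1,
#'   with no higher-level feature of that side reaching `q < level1_q`, has
#'   that side's features removed.
#'
#' The feature weight is the NES by default (raw ES by config).
#'
#' @param stats data.frame from [feature_stats()].
#' @param q_cut FDR cutoff for significance.
#' @param min_pos minimum member count.
#' @param contra_q relaxed FDR threshold for the contradictory filter.
#' @param level1_q relaxed FDR threshold for the level-1 noise filter.
#' @param weight_type `"nes"` or `"es"`.
#' @param qvalue_method `"storey"` or `"BH"`.
#' @param direction label stored with the table (`"sensitive"`/`"resistant"`).
#' @return `weight_table`: data.frame feature_id, gene, kind, level, n_pos,
#'   es, nes, p, q, weight (only retained features), with `direction` and the
#'   selection parameters as attributes. Empty with a warning when nothing
#'   passes.
#' @export
select_significant <- function(stats, q_cut = 0.1, min_pos = 5,
                               contra_q = 0.3, level1_q = 0.3,
                               weight_type = c("nes", "es"),
                               qvalue_method = c("storey", "BH"),
                               direction = "sensitive") {
  weight_type <- match.arg(weight_type)
  qvalue_method <- match.arg(qvalue_method)
  stats$q <- if (nrow(stats)) qvalues(stats$p, method = qvalue_method)
             else numeric(0)
  keep <- stats$es > 0 & stats$q < q_cut & stats$n_pos >= min_pos &
    is.finite(stats$nes)

  is_dge <- !is.na(stats$level)
  side <- ifelse(is_dge & grepl("^Up_", stats$kind), "Up",
                 ifelse(is_dge & grepl("^Down_", stats$kind), "Down", NA))
  # contradictory-direction filter (per gene, over all tested DGE features)
  if (any(is_dge)) {
    d <- stats[is_dge, ]
    dside <- side[is_dge]
    qup <- tapply(d$q[dside == "Up"], d$gene[dside == "Up"], min)
    qdn <- tapply(d$q[dside == "Down"], d$gene[dside == "Down"], min)
    genes <- union(names(qup), names(qdn))
    gu <- qup[genes]; gd <- qdn[genes]
    contra <- genes[(!is.na(gu) & !is.na(gd)) &
                      ((gu < q_cut & gd < contra_q) |
                         (gd < q_cut & gu < contra_q))]
    keep <- keep & !(is_dge & stats$gene %in% contra)

    # level-1 noise filter (per gene-side)
    gs <- paste(d$gene, dside, sep = "\r")
    sig1 <- tapply(seq_len(nrow(d)), gs, function(ix) {
      sig <- d$q[ix] < q_cut & d$es[ix] > 0
      any(sig) && all(d$level[ix][sig] == 1L) &&
        !any(d$level[ix] >= 2L & d$q[ix] < level1_q)
    })
    noisy <- names(sig1)[unlist(sig1)]
    keep <- keep & !(is_dge & paste(stats$gene, side, sep = "\r") %in% noisy)
  }

  out <- stats[keep, , drop = FALSE]
  out$weight <- if (weight_type == "nes") out$nes else out$es
  out <- out[out$weight > 0, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L)
    warning("no significant features selected: model unusable for direction ",
            direction)
  structure(out, direction = direction,
            params = list(q_cut = q_cut, min_pos = min_pos,
                          contra_q = contra_q, level1_q = level1_q,
                          weight_type = weight_type,
                          qvalue_method = qvalue_method),
            class = c("weight_table", "data.frame"))
}

#' Construct a weight table directly
#'
#' Validates and classes a data.frame of feature weights, for programmatic
#' model assembly (e.g. carrying externally derived weights into the scoring
#' machinery). [select_significant()] is the standard constructor.
#'
#' @param df data.frame with at least `feature_id` and `weight` (> 0)
#'   columns; gene/kind/level metadata are derived from the ids when absent.
#' @param direction `"sensitive"` or `"resistant"`.
#' @param params optional list of selection parameters (defaults recorded).
#' @return `weight_table`.
#' @export
as_weight_table <- function(df, direction = "sensitive", params = NULL) {
  stopifnot(is.data.frame(df), all(c("feature_id", "weight") %in% names(df)))
  if (anyDuplicated(df$feature_id)) stop("duplicate feature_id")
  if (any(df$weight <= 0)) stop("weights must be positive")
  meta <- parse_feature_ids(df$feature_id)
  for (col in c("gene", "kind", "level"))
    if (!col %in% names(df)) df[[col]] <- meta[[col]]
  for (col in c("n_pos", "es", "nes", "p", "q"))
    if (!col %in% names(df)) df[[col]] <- NA_real_
  structure(df, direction = direction,
            params = params %||% list(weight_type = "nes"),
            class = c("weight_table", "data.frame"))
}

#' Leave-one-out weight table for a training subject
#'
#' For every selected feature whose member set contains subject `x`, the
#' ES/NES are recomputed on the ranked cohort with `x` removed (null
#' distributions at size `n_pos - 1` on the `N - 1` cohort, from the shared
#' cache); features not containing `x` keep their full-cohort weights.
#' Feature selection itself (q-values and filters) stays frozen on the
#' full-cohort statistics so the significant set is identical across
#' subjects. Features reduced to fewer than one member are dropped for `x`.
#'
#' @param wt `weight_table` from [select_significant()].
#' @param ranked full-cohort `ranked_cohort`.
#' @param fs `feature_set` supplying member sets.
#' @param x subject id to leave out (must be in the cohort, cohort size > 2).
#' @param B,cache,exponent as in [feature_stats()]; `cache` should be the
#'   same cache used for the full-cohort run.
#' @return `weight_table` view valid for subject `x`.
#' @export
loo_weight_table <- function(wt, ranked, fs, x, B = 2000, cache = NULL,
                             exponent = 1) {
  stopifnot(inherits(wt, "weight_table"), inherits(ranked, "ranked_cohort"))
  N <- length(ranked$subject_ids)
  if (N <= 2L) stop("leave-one-out underdetermined for cohorts of size <= 2")
  if (!x %in% ranked$subject_ids) stop("subject ", x, " not in the cohort")
  if (is.null(cache)) cache <- null_cache(1L)
  keep <- ranked$subject_ids != x
  sub <- structure(list(subject_ids = ranked$subject_ids[keep],
                        metric = ranked$metric[keep]),
                   class = "ranked_cohort")
  # nulls at (N-1, m-1) are generated from the full metric less its last
  # element, so all leave-one-out recomputations share one cache entry
  null_metric <- ranked$metric[-N]
  drop <- logical(nrow(wt))
  for (i in seq_len(nrow(wt))) {
    mem <- fs$members[[wt$feature_id[i]]]
    if (is.null(mem) || !x %in% mem) next
    hits <- sub$subject_ids %in% mem
    m <- sum(hits)
    if (m < 1L) { drop[i] <- TRUE; next }
    run <- ks_running_sum(sub$metric, hits, exponent)
    es <- run[which.max(abs(run))]
    null <- get_null(null_metric, m, B, cache, exponent)
    st <- withCallingHandlers(stats_from_null(es, null, m),
                              warning = function(w)
                                invokeRestart("muffleWarning"))
    wt$es[i] <- st$es
    wt$nes[i] <- st$nes
    wt$n_pos[i] <- m
    wt$weight[i] <- if (attr(wt, "params")$weight_type == "nes")
      st$nes else st$es
  }
  out <- wt[!drop & is.finite(wt$weight) & wt$weight > 0, , drop = FALSE]
  attributes(out)$direction <- attr(wt, "direction")
  attributes(out)$params <- attr(wt, "params")
  class(out) <- class(wt)
  out
}
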