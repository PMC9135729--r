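#' Otsuka-Ochiai similarity matrix of binary features
#'
#' Cosine similarity of the binary membership vectors over a reference
#' cohort: `K_ij = |S_i intersect S_j| / sqrt(|S_i| * |S_j|)`.
#'
#' @param fs `feature_set` restricted to the features of interest; every
#'   feature must be nonempty (guaranteed by construction).
#' @return symmetric numeric matrix with unit diagonal, dimnames = feature
#'   ids.
#' @export
similarity_matrix <- function(fs) {
  stopifnot(inherits(fs, "feature_set"))
  if (length(fs$members) == 0L) stop("empty feature set")
  subjects <- sort(unique(unlist(fs$members, use.names = FALSE)))
  if (length(subjects) == 0L) stop("empty reference cohort")
  ids <- names(fs$members)
  M <- Matrix::sparseMatrix(
    i = match(unlist(fs$members, use.names = FALSE), subjects),
    j = rep(seq_along(ids), lengths(fs$members)),
    x = 1,
    dims = c(length(subjects), length(ids)),
    dimnames = list(subjects, ids))
  n <- Matrix::colSums(M)
  K <- as.matrix(Matrix::crossprod(M)) / sqrt(outer(n, n))
  diag(K) <- 1
  K
}

#' Correlated-feature clusters from a similarity matrix
#'
#' Agglomerative clustering with Ward (D2) linkage on the distance `1 - K`,
#' followed by an adaptive dendrogram cut: the tree is cut at a fraction of
#' its maximal merge height controlled by `cut_depth` (deeper = lower cut =
#' finer clusters), and clusters smaller than `min_cluster_size` are
#' dissolved into singletons. Cluster size counts distinct membership
#' profiles: exact duplicate features are collapsed upstream (see
#' [build_similarity_model()]) so that duplicates always share a label and
#' k-fold feature cloning cannot change any clustering decision.
#'
#' @param K similarity matrix from [similarity_matrix()], one row per
#'   distinct membership profile.
#' @param min_cluster_size minimum retained cluster size (default 40).
#' @param cut_depth integer 0-4 controlling cut height (default 2).
#' @return named character vector: feature id -> cluster label.
#' @export
cluster_features <- function(K, min_cluster_size = 40, cut_depth = 2) {
  ids <- rownames(K)
  stopifnot(!is.null(ids))
  n <- length(ids)
  if (n == 1L) return(stats::setNames("c1", ids))
  if (n < min_cluster_size) {
    warning("fewer features than min_cluster_size: single cluster")
    return(stats::setNames(rep("c1", n), ids))
  }
  hc <- stats::hclust(stats::as.dist(1 - K), method = "ward.D2")
  frac <- c(`0` = 0.99, `1` = 0.95, `2` = 0.90, `3` = 0.80, `4` = 0.70)
  f <- frac[as.character(cut_depth)]
  if (is.na(f)) stop("cut_depth must be an integer in 0..4")
  maxh <- max(hc$height)
  cl <- if (maxh <= 0) rep(1L, n) else stats::cutree(hc, h = f * maxh)
  names(cl) <- ids
  csize <- table(cl)
  small <- as.integer(names(csize)[csize < min_cluster_size])
  lab <- paste0("c", cl)
  lab[cl %in% small] <- paste0("s", seq_len(n))[cl %in% small]
  stats::setNames(lab, ids)
}

#' Build the reference-cohort similarity model
#'
#' Restricts the reference feature set to the model's significant features,
#' computes the Otsuka-Ochiai matrix, collapses exact duplicate features
#' before clustering (so duplicates always co-cluster), and stores the
#' floored similarity matrix used by the penalty computation (`K'_ij = 0`
#' when `K_ij < similarity_floor`, diagonal kept at 1). Features absent from
#' the reference cohort cannot be assessed for co-occurrence and fall back
#' to singleton clusters with penalty 1.
#'
#' @param ref_features `feature_set` over the reference cohort.
#' @param feature_ids character vector of significant feature ids.
#' @param min_cluster_size,cut_depth passed to [cluster_features()].
#' @param similarity_floor co-occurrence floor below which similarities are
#'   zeroed in the penalty sum (default 0.1).
#' @return object of class `similarity_model`: `feature_ids`, `K`, `Kp`
#'   (floored), `cluster` (named labels for all `feature_ids`), `params`.
#' @export
build_similarity_model <- function(ref_features, feature_ids,
                                   min_cluster_size = 40, cut_depth = 2,
                                   similarity_floor = 0.1) {
  stopifnot(inherits(ref_features, "feature_set"))
  feature_ids <- unique(feature_ids)
  mem <- ref_features$members[intersect(feature_ids, names(ref_features$members))]
  mem <- mem[lengths(mem) > 0L]
  present <- names(mem)
  absent <- setdiff(feature_ids, present)

  cluster <- stats::setNames(rep(NA_character_, length(feature_ids)),
                             feature_ids)
  K <- NULL
  if (length(present) > 0L) {
    K <- similarity_matrix(feature_set(mem))
    # collapse exact duplicates (identical reference membership)
    key <- vapply(mem, function(s) paste(sort(s), collapse = "\r"),
                  character(1))
    reps <- present[!duplicated(key)]
    group <- stats::setNames(reps[match(key, key[!duplicated(key)])], present)
    rep_cl <- suppressWarnings(
      cluster_features(K[reps, reps, drop = FALSE],
                       min_cluster_size = min_cluster_size,
                       cut_depth = cut_depth))
    cluster[present] <- rep_cl[group]
  }
  if (length(absent) > 0L)
    cluster[absent] <- paste0("a", seq_along(absent))

  Kp <- NULL
  if (!is.null(K)) {
    Kp <- K
    Kp[Kp < similarity_floor] <- 0
    diag(Kp) <- 1
  }
  structure(list(feature_ids = feature_ids, K = K, Kp = Kp,
                 cluster = cluster,
                 params = list(min_cluster_size = min_cluster_size,
                               cut_depth = cut_depth,
                               similarity_floor = similarity_floor)),
            class = "similarity_model")
}

#' @export
print.similarity_model <- function(x, ...) {
  cat("similarity_model:", length(x$feature_ids), "features,",
      length(unique(x$cluster)), "clusters\n")
  invisible(x)
}

#' Redundancy penalty factors for one subject
#'
#' For each significant feature `i` present in the subject, the penalty is
#' the sum of floored similarities to the subject's other present features of
#' the same cluster (self-similarity 1 always included):
#' `eps_i = sum_j K'_ij`, so `eps_i` runs from 1 (no redundancy among the
#' subject's features) up to the number of present features (all identical).
#' The fractionally trimmed mean of the present-feature penalties
#' (trim = 0.3) yields the subject's effective feature number
#' `EFN = n / eps_bar_T`, where `n` is the total number of significant
#' features in the model (`n_model`, defaulting to the present count when the
#' penalty is used standalone).
#'
#' @param model `similarity_model`.
#' @param present character vector of the subject's significant features
#'   (same direction as the weight table the penalties will divide).
#' @param n_model total significant features of the direction's weight table.
#' @param trim trim fraction for the penalty mean.
#' @return list of class `subject_penalty`: `eps` (named), `n_present`,
#'   `n_model`, `eps_bar`, `efn`. For an empty `present`, `n_present = 0` and
#'   the score contribution is 0.
#' @export
penalty_factors <- function(model, present, n_model = length(unique(present)),
                            trim = 0.3) {
  stopifnot(inherits(model, "similarity_model"))
  present <- unique(present)
  bad <- setdiff(present, model$feature_ids)
  if (length(bad))
    stop("features not covered by the similarity model: ", bad[1])
  n <- length(present)
  stopifnot(n_model >= n)
  if (n == 0L)
    return(structure(list(eps = numeric(0), n_present = 0L,
                          n_model = n_model, eps_bar = NA_real_,
                          efn = NA_real_), class = "subject_penalty"))
  eps <- stats::setNames(rep(1, n), present)
  inK <- present[present %in% rownames(model$Kp %||% matrix(0, 0, 0))]
  cl <- model$cluster[inK]
  for (lab in unique(cl)) {
    ix <- inK[cl == lab]
    if (length(ix) > 1L)
      eps[ix] <- rowSums(model$Kp[ix, ix, drop = FALSE])
  }
  eps_bar <- trimmed_mean_frac(eps, trim)
  structure(list(eps = eps, n_present = n, n_model = n_model,
                 eps_bar = eps_bar, efn = n_model / eps_bar),
            class = "subject_penalty")
}

#' Redundancy-penalized signature score for one subject
#'
#' Each present feature contributes its weight divided by its redundancy
#' penalty (effective weight `EW_i = w_i / eps_i`); the sum over the
#' subject's features is normalized by the model's effective feature number:
#' `score = sum(EW) / EFN = sum(w_i / eps_i) * eps_bar_T / n_model`. The
#' score therefore scales with how much of the signature the subject
#' carries, while exact feature duplication leaves it unchanged. Subjects
#' with no significant features score 0.
#'
#' @param weights named numeric vector of feature weights for the features in
#'   `penalty` (a superset is allowed; matched by name).
#' @param penalty `subject_penalty` from [penalty_factors()].
#' @return scalar score.
#' @export
igensig_score <- function(weights, penalty) {
  stopifnot(inherits(penalty, "subject_penalty"))
  if (penalty$n_present == 0L) return(0)
  w <- weights[names(penalty$eps)]
  if (anyNA(w)) stop("missing weights for some present features")
  sum(w / penalty$eps) / penalty$efn
}

#' Score a cohort against sensitive/resistant weight tables
#'
#' For every subject, intersects the subject's features with each direction's
#' significant features, computes the redundancy penalties against the
#' similarity model, and evaluates the signature score. Model features absent
#' from the cohort's feature space contribute nothing.
#'
#' @param weight_tables named list with elements `sensitive` and/or
#'   `resistant` (each a `weight_table`).
#' @param cohort_features `feature_set` for the subjects to score.
#' @param model `similarity_model` covering all weighted features.
#' @param subjects optional subject ids to score (default: all subjects
#'   appearing in `cohort_features`; subjects without features score 0).
#' @param trim penalty trim fraction.
#' @return data.frame of class `score_table`: subject_id, sensitive,
#'   resistant.
#' @export
score_cohort <- function(weight_tables, cohort_features, model,
                         subjects = NULL, trim = 0.3) {
  stopifnot(inherits(cohort_features, "feature_set"),
            inherits(model, "similarity_model"))
  idx <- subject_index(cohort_features)
  if (is.null(subjects)) subjects <- sort(names(idx))
  out <- data.frame(subject_id = subjects,
                    sensitive = 0, resistant = 0,
                    stringsAsFactors = FALSE)
  for (dir in c("sensitive", "resistant")) {
    wt <- weight_tables[[dir]]
    if (is.null(wt) || nrow(wt) == 0L) {
      out[[dir]] <- 0
      next
    }
    w <- stats::setNames(wt$weight, wt$feature_id)
    n_model <- nrow(wt)
    for (s in seq_along(subjects)) {
      feats <- intersect(idx[[subjects[s]]], wt$feature_id)
      pen <- penalty_factors(model, feats, n_model = n_model, trim = trim)
      out[[dir]][s] <- igensig_score(w, pen)
    }
  }
  class(out) <- c("score_table", "data.frame")
  out
}
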