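# Independent brute-force oracles used to check the vectorized implementations.

# Weighted K-S enrichment score by explicit running-sum tabulation.
brute_es <- function(metric, members, subject_ids, exponent = 1) {
  hits <- subject_ids %in% members
  N <- length(hits)
  m <- sum(hits)
  w <- abs(metric)^exponent
  nr <- sum(w[hits])
  cur <- 0
  best <- -Inf
  es <- NA_real_
  for (i in seq_len(N)) {
    cur <- cur + if (hits[i]) {
      if (nr > 0) w[i] / nr else 1 / m
    } else {
      -1 / (N - m)
    }
    if (abs(cur) > best) {           # strict: leftmost maximal deviation
      best <- abs(cur)
      es <- cur
    }
  }
  es
}

# Waterfall sensitivity cutoff by per-index point-to-chord distance.
brute_waterfall_sensitive <- function(act_area) {
  v <- sort(act_area[is.finite(act_area)])
  n <- length(v)
  dx <- n - 1
  dy <- v[n] - v[1]
  len <- sqrt(dx^2 + dy^2)
  best <- -Inf
  arg <- NA_integer_
  for (i in seq_len(n)) {
    d <- abs(dx * (v[i] - v[1]) - dy * (i - 1)) / len
    if (d > best) {
      best <- d
      arg <- i
    }
  }
  v[arg]
}

# AUROC by exhaustive concordant-pair counting (ties count 1/2).
brute_auroc <- function(score, positive) {
  pos <- score[positive]
  neg <- score[!positive]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Clone every element of a named membership list k times (".cl<j>" suffix).
clone_members <- function(mem, k) {
  out <- vector("list", length(mem) * k)
  nm <- character(length(out))
  j <- 0L
  for (id in names(mem)) for (i in seq_len(k)) {
    j <- j + 1L
    nm[j] <- paste0(id, ".cl", i)
    out[[j]] <- mem[[id]]
  }
  names(out) <- nm
  out
}

# Small deterministic feature system shared by scoring tests: cohort and
# reference memberships plus a positive weight table.
toy_feature_system <- function(seed = 42, n_feat = 120, n_subj = 80,
                               n_ref = 60) {
  set.seed(seed)
  subj <- sprintf("S%03d", seq_len(n_subj))
  refs <- sprintf("R%03d", seq_len(n_ref))
  ids <- sprintf("g%03d__Up_Level%d", rep(seq_len(ceiling(n_feat / 3)),
                                          each = 3)[seq_len(n_feat)],
                 rep(1:3, length.out = n_feat))
  mem <- lapply(seq_along(ids), function(i)
    sample(subj, sample(3:min(30, n_subj - 1), 1)))
  names(mem) <- ids
  refmem <- lapply(seq_along(ids), function(i)
    sample(refs, sample(3:min(30, n_ref - 1), 1)))
  names(refmem) <- ids
  refmem[ids[4:6]] <- refmem[ids[1:3]]  # exact duplicates across genes
  wt <- as_weight_table(data.frame(feature_id = ids,
                                   weight = stats::runif(n_feat, 0.5, 3)))
  list(ids = ids, cohort = feature_set(mem), ref = feature_set(refmem),
       wt = wt, subjects = subj)
}
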