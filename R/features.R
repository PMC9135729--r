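#' Binary genomic feature sets
#'
#' A `feature_set` maps feature identifiers to the set of subjects carrying the
#' feature, together with per-feature metadata (source gene and feature kind).
#' Feature identifiers follow the grammar `"<gene>__<kind>"` with kind one of
#' `Up_Level1..6`, `Down_Level1..6`, `mut_gene`, or `hotspot_<protein_change>`,
#' so the gene is recoverable losslessly (genes must not contain `"__"`).
#'
#' @param members named list; each element a character vector of subject ids.
#' @return object of class `feature_set`.
#' @export
feature_set <- function(members = list()) {
  stopifnot(is.list(members))
  ids <- names(members)
  if (length(members) > 0 && (is.null(ids) || any(ids == "")))
    stop("all features must be named")
  if (anyDuplicated(ids)) stop("duplicate feature_id: ",
                               ids[duplicated(ids)][1])
  if (any(lengths(members) == 0L))
    stop("every feature must have at least one subject")
  members <- lapply(members, function(s) unique(as.character(s)))
  structure(list(members = members, meta = parse_feature_ids(ids)),
            class = "feature_set")
}

parse_feature_ids <- function(ids) {
  if (length(ids) == 0L)
    return(data.frame(feature_id = character(), gene = character(),
                      kind = character(), level = integer(),
                      stringsAsFactors = FALSE))
  pos <- regexpr("__", ids, fixed = TRUE)
  gene <- ifelse(pos > 0, substr(ids, 1L, pos - 1L), NA_character_)
  kind <- ifelse(pos > 0, substr(ids, pos + 2L, nchar(ids)), NA_character_)
  lev <- rep(NA_integer_, length(ids))
  dge <- !is.na(kind) & grepl("^(Up|Down)_Level[1-6]$", kind)
  lev[dge] <- as.integer(sub("^(Up|Down)_Level", "", kind[dge]))
  data.frame(feature_id = ids, gene = gene, kind = kind, level = lev,
             stringsAsFactors = FALSE)
}

#' @export
print.feature_set <- function(x, ...) {
  cat("feature_set:", length(x$members), "features,",
      length(unique(unlist(x$members, use.names = FALSE))), "subjects\n")
  invisible(x)
}

#' @export
length.feature_set <- function(x) length(x$members)

#' Combine feature sets
#'
#' @param ... `feature_set` objects with disjoint feature ids.
#' @return merged `feature_set`.
#' @export
combine_features <- function(...) {
  sets <- list(...)
  stopifnot(all(vapply(sets, inherits, logical(1), "feature_set")))
  feature_set(do.call(c, lapply(sets, `[[`, "members")))
}

#' Restrict a feature set to a subject subset
#'
#' Intersects every feature's member list with `subjects`; features left empty
#' are dropped.
#'
#' @param fs `feature_set`.
#' @param subjects character vector of subject ids to retain.
#' @return restricted `feature_set`.
#' @export
subset_features <- function(fs, subjects) {
  stopifnot(inherits(fs, "feature_set"))
  mem <- lapply(fs$members, function(s) s[s %in% subjects])
  feature_set(mem[lengths(mem) > 0L])
}

#' Subject-to-feature index
#'
#' @param fs `feature_set`.
#' @return named list: subject id -> character vector of feature ids.
#' @export
subject_index <- function(fs) {
  stopifnot(inherits(fs, "feature_set"))
  if (length(fs$members) == 0L) return(list())
  feat <- rep(names(fs$members), lengths(fs$members))
  subj <- unlist(fs$members, use.names = FALSE)
  split(feat, subj)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every subject (column) to share the identical value distribution:
#' each value is replaced by the mean across subjects of the values at its
#' within-column rank; ties receive the mean of their tied-rank targets.
#'
#' @param expr numeric matrix, genes x subjects, non-negative, no missing
#'   values; dimnames required.
#' @return normalized matrix with the same dimnames.
#' @export
quantile_normalize <- function(expr) {
  expr <- as.matrix(expr)
  if (anyNA(expr)) stop("expression matrix contains missing values")
  if (!is.numeric(expr)) stop("expression matrix must be numeric")
  if (any(expr < 0)) stop("expression values must be non-negative")
  if (nrow(expr) < 1L || ncol(expr) < 1L) stop("empty expression matrix")
  check_ids(rownames(expr), "gene")
  check_ids(colnames(expr), "subject")
  if (ncol(expr) == 1L) return(expr)
  out <- limma::normalizeQuantiles(expr, ties = TRUE)
  dimnames(out) <- dimnames(expr)
  out
}

check_ids <- function(ids, what) {
  if (is.null(ids)) stop(what, " ids (dimnames) are required")
  if (anyDuplicated(ids)) stop("duplicate ", what, " ids")
  invisible(ids)
}

#' Per-gene log2 fold changes against the trimmed mean
#'
#' For each gene, adds 1 to the (normalized, linear-scale) expression values,
#' computes the trimmed mean across subjects (dropping the
#' `floor(trim_frac * N)` largest and smallest values), and forms
#' `fc = log2(x + 1) - log2(tm + 1)`. Genes whose cross-subject fold-change
#' standard deviation falls below the `var_pctl` quantile of all gene SDs
#' (inclusive lower quantile, linear interpolation) are removed.
#'
#' @param expr quantile-normalized expression matrix (genes x subjects).
#' @param trim_frac fraction trimmed from each end for the trimmed mean.
#' @param var_pctl quantile of gene SDs below which genes are filtered.
#' @return object of class `fold_change`: list with `fc` (matrix over retained
#'   genes), `mu`, `sd` (per-gene mean/SD of fc across subjects).
#' @export
fold_change_matrix <- function(expr, trim_frac = 0.10, var_pctl = 0.20) {
  expr <- as.matrix(expr)
  stopifnot(trim_frac >= 0, trim_frac < 0.5, var_pctl >= 0, var_pctl <= 1)
  if (anyNA(expr)) stop("expression matrix contains missing values")
  n <- ncol(expr)
  if (n < 3L) stop("need at least 3 subjects for trimmed mean and SD")
  x1 <- expr + 1
  k <- floor(trim_frac * n)
  tm <- apply(x1, 1L, function(v) {
    v <- sort(v)
    mean(v[(k + 1L):(n - k)])
  })
  fc <- log2(x1) - log2(tm)  # tm is already the trimmed mean of (x + 1)
  mu <- rowMeans(fc)
  sdv <- apply(fc, 1L, stats::sd)
  thr <- stats::quantile(sdv, var_pctl, type = 7, names = FALSE)
  keep <- sdv >= thr & sdv > 0
  structure(list(fc = fc[keep, , drop = FALSE], mu = mu[keep], sd = sdv[keep]),
            class = "fold_change")
}

#' Multi-level differential-expression features
#'
#' Assigns subjects to twelve overlapping groups per gene: `Up_Levelk` when the
#' fold change exceeds `mu + k * sd` and `Down_Levelk` when it is below
#' `mu - k * sd`, k = 1..6 (strict inequalities). A subject beyond level k is
#' by construction also a member of levels 1..k-1. Empty features are dropped.
#'
#' @param fcs `fold_change` object from [fold_change_matrix()].
#' @param max_level deepest level to generate (default 6).
#' @return `feature_set` of DGE features.
#' @export
dge_features <- function(fcs, max_level = 6L) {
  stopifnot(inherits(fcs, "fold_change"), max_level >= 1L)
  subj <- colnames(fcs$fc)
  genes <- rownames(fcs$fc)
  if (any(grepl("__", genes, fixed = TRUE)))
    stop("gene ids must not contain '__' (reserved feature_id separator)")
  members <- vector("list", 2L * max_level * length(genes))
  ids <- character(length(members))
  j <- 0L
  for (g in seq_along(genes)) {
    fc <- fcs$fc[g, ]
    mu <- fcs$mu[g]; sdv <- fcs$sd[g]
    if (!is.finite(sdv) || sdv <= 0) next
    for (k in seq_len(max_level)) {
      up <- subj[fc > mu + k * sdv]
      if (length(up)) {
        j <- j + 1L
        ids[j] <- paste0(genes[g], "__Up_Level", k)
        members[[j]] <- up
      }
      dn <- subj[fc < mu - k * sdv]
      if (length(dn)) {
        j <- j + 1L
        ids[j] <- paste0(genes[g], "__Down_Level", k)
        members[[j]] <- dn
      }
    }
  }
  members <- members[seq_len(j)]
  names(members) <- ids[seq_len(j)]
  feature_set(members)
}

#' Somatic mutation features
#'
#' Builds binary features from a mutation catalog. Silent and unrecognized
#' (`other`) variant classes are excluded. A hotspot feature
#' `<gene>__hotspot_<protein_change>` is created for every (gene, protein
#' change) pair observed in at least `hotspot_min` subjects, and a gene-level
#' feature `<gene>__mut_gene` for every gene nonsynonymously mutated in at
#' least `gene_min` subjects.
#'
#' @param muts data.frame with columns `subject_id`, `gene`, and optionally
#'   `protein_change`, `variant_class` (one of missense, nonsense, frameshift,
#'   silent; anything else is mapped to "other").
#' @param hotspot_min minimum recurrence for a hotspot feature.
#' @param gene_min minimum recurrence for a gene-level feature.
#' @return `feature_set` of mutation features (possibly empty).
#' @export
mutation_features <- function(muts, hotspot_min = 3L, gene_min = 2L) {
  stopifnot(is.data.frame(muts), all(c("subject_id", "gene") %in% names(muts)))
  vc <- if ("variant_class" %in% names(muts))
    tolower(as.character(muts$variant_class)) else rep("other", nrow(muts))
  vc[!vc %in% c("missense", "nonsense", "frameshift", "silent")] <- "other"
  keep <- vc %in% c("missense", "nonsense", "frameshift")
  muts <- muts[keep, , drop = FALSE]
  members <- list()
  if (nrow(muts) > 0) {
    if (any(grepl("__", muts$gene, fixed = TRUE)))
      stop("gene ids must not contain '__'")
    # gene-level recurrence counts distinct subjects
    by_gene <- lapply(split(as.character(muts$subject_id), muts$gene), unique)
    by_gene <- by_gene[lengths(by_gene) >= gene_min]
    if (length(by_gene))
      members <- c(members, stats::setNames(
        by_gene, paste0(names(by_gene), "__mut_gene")))
    pc <- if ("protein_change" %in% names(muts))
      as.character(muts$protein_change) else rep(NA_character_, nrow(muts))
    hs <- !is.na(pc) & nzchar(pc)
    if (any(hs)) {
      key <- paste0(muts$gene[hs], "__hotspot_", gsub("\\s+", "", pc[hs]))
      by_hs <- lapply(split(as.character(muts$subject_id[hs]), key), unique)
      by_hs <- by_hs[lengths(by_hs) >= hotspot_min]
      members <- c(members, by_hs)
    }
  }
  feature_set(members)
}

#' Read a GMT feature file
#'
#' One feature per line, tab-separated: feature id, description, then subject
#' ids (at least one). Lines with fewer than three fields or duplicated
#' feature ids are errors.
#'
#' @param path file path.
#' @return `feature_set`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("malformed GMT line ", short[1], ": fewer than 3 fields")
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate feature_id in GMT: ", ids[duplicated(ids)][1])
  members <- lapply(fields, function(f) f[-(1:2)])
  names(members) <- ids
  feature_set(members)
}

#' Write a GMT feature file
#'
#' @param fs `feature_set` (all features nonempty by construction).
#' @param path output file path.
#' @param descriptions optional named character vector of per-feature
#'   descriptions; defaults to the feature kind (or "na").
#' @return `path`, invisibly.
#' @export
write_gmt <- function(fs, path, descriptions = NULL) {
  stopifnot(inherits(fs, "feature_set"))
  ids <- names(fs$members)
  desc <- descriptions[ids] %||% fs$meta$kind
  desc[is.na(desc)] <- "na"
  lines <- vapply(seq_along(ids), function(i) {
    paste(c(ids[i], desc[i], fs$members[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' Expects genes in rows (first column = gene id) and subjects in columns.
#'
#' @param path TSV file path.
#' @return numeric matrix with gene rownames and subject colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("expression matrix contains missing values")
  check_ids(rownames(m), "gene")
  check_ids(colnames(m), "subject")
  m
}

#' Read a mutation catalog from TSV
#'
#' MAF-like columns: `Sample`/`subject_id`, `Gene`/`gene`,
#' `ProteinChange`/`protein_change`, `VariantClass`/`variant_class`.
#'
#' @param path TSV file path.
#' @return data.frame with canonical column names.
#' @export
read_mutations_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  ren <- c(Sample = "subject_id", Gene = "gene",
           ProteinChange = "protein_change", VariantClass = "variant_class")
  for (i in seq_along(ren))
    names(df)[names(df) == names(ren)[i]] <- ren[[i]]
  if (!all(c("subject_id", "gene") %in% names(df)))
    stop("mutation table needs subject_id/Sample and gene/Gene columns")
  df
}
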