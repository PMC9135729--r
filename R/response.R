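#' Read a drug-response table from TSV
#'
#' Columns: `subject_id`, `drug_id`, and at least one of `act_area` (area
#' above the dose-response curve) and `auc` (area under it). Whichever of the
#' two is absent is derived as `1 - value`.
#'
#' @param path TSV file path.
#' @return data.frame with columns subject_id, drug_id, act_area, auc.
#' @export
read_response_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  complete_response(df)
}

#' Complete a response table
#'
#' Derives the missing one of act_area / auc as `1 - value` (per measurement)
#' and checks basic sanity.
#'
#' @param df data.frame with subject_id and act_area and/or auc columns.
#' @return data.frame with both measurements present.
#' @export
complete_response <- function(df) {
  stopifnot(is.data.frame(df), "subject_id" %in% names(df))
  if (!"act_area" %in% names(df) && !"auc" %in% names(df))
    stop("response table needs an act_area or auc column")
  if (!"act_area" %in% names(df)) df$act_area <- 1 - df$auc
  if (!"auc" %in% names(df)) df$auc <- 1 - df$act_area
  miss <- is.na(df$act_area) & !is.na(df$auc)
  df$act_area[miss] <- 1 - df$auc[miss]
  miss <- is.na(df$auc) & !is.na(df$act_area)
  df$auc[miss] <- 1 - df$act_area[miss]
  if (any(df$act_area < 0, na.rm = TRUE))
    stop("act_area must be non-negative")
  df
}

#' Moment skewness of a response distribution
#'
#' Sample moment skewness `g1 = m3 / m2^1.5`. A drug qualifies for modeling
#' when its AUC distribution is negatively skewed (most subjects resistant, a
#' small tail of outstanding responders).
#'
#' @param values numeric vector (AUC scale), at least 3 finite values.
#' @return scalar skewness; `NA` with a warning for a constant vector.
#' @export
response_skewness <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3L) stop("need at least 3 finite values")
  if (stats::sd(values) == 0) {
    warning("constant response vector: skewness undefined")
    return(NA_real_)
  }
  e1071::skewness(values, type = 1)
}

#' Waterfall sensitivity and resistance cutoffs
#'
#' Act Area values are sorted ascending to form the waterfall curve
#' `(i, v_i)`. The sensitivity cutoff is the value at the point of maximal
#' perpendicular distance to the chord through the first and last points
#' (leftmost index on ties); the resistance cutoff is
#' `median(act_area) - MAD(act_area)` with the raw (unscaled) MAD by default.
#'
#' @param act_area numeric vector, length >= 3, not all equal.
#' @param mad_scaled use the 1.4826-scaled MAD instead of the raw median
#'   absolute deviation.
#' @return list with `cutoff_sensitive` and `cutoff_resistant`.
#' @export
waterfall_cutoffs <- function(act_area, mad_scaled = FALSE) {
  v <- act_area[is.finite(act_area)]
  if (length(v) < 3L) stop("need at least 3 finite values")
  if (max(v) == min(v)) stop("degenerate waterfall: all values equal")
  v <- sort(v)
  n <- length(v)
  # perpendicular distance from (i, v_i) to the chord (1, v1)-(n, vn)
  dx <- n - 1
  dy <- v[n] - v[1]
  i <- seq_len(n)
  d <- abs(dx * (v - v[1]) - dy * (i - 1)) / sqrt(dx^2 + dy^2)
  cutoff_sensitive <- v[which.max(d)]
  mad_v <- stats::mad(act_area, constant = if (mad_scaled) 1.4826 else 1)
  list(cutoff_sensitive = cutoff_sensitive,
       cutoff_resistant = stats::median(act_area, na.rm = TRUE) - mad_v)
}

#' Label subjects as sensitive / intermediate / resistant
#'
#' Strict comparisons: Act Area above the sensitivity cutoff is sensitive,
#' below the resistance cutoff is resistant, anything between is intermediate.
#' Subjects with a missing measurement are omitted with a warning.
#'
#' @param act_area named numeric vector of Act Area values (names = subjects).
#' @param cutoffs list from [waterfall_cutoffs()].
#' @return data.frame subject_id, act_area, label (factor), with the cutoffs
#'   attached as attributes; class `response_labels`.
#' @export
assign_labels <- function(act_area, cutoffs) {
  stopifnot(is.numeric(act_area), !is.null(names(act_area)),
            all(c("cutoff_sensitive", "cutoff_resistant") %in% names(cutoffs)))
  cs <- cutoffs$cutoff_sensitive
  cr <- cutoffs$cutoff_resistant
  if (cs < cr) {
    warning("cutoff_sensitive below cutoff_resistant; clamping resistance cutoff")
    cr <- cs
  }
  miss <- !is.finite(act_area)
  if (any(miss)) {
    warning(sum(miss), " subject(s) without measurement omitted")
    act_area <- act_area[!miss]
  }
  lab <- ifelse(act_area > cs, "sensitive",
                ifelse(act_area < cr, "resistant", "intermediate"))
  out <- data.frame(subject_id = names(act_area),
                    act_area = unname(act_area),
                    label = factor(lab, levels = c("sensitive", "intermediate",
                                                   "resistant")),
                    stringsAsFactors = FALSE)
  attr(out, "cutoff_sensitive") <- cs
  attr(out, "cutoff_resistant") <- cr
  class(out) <- c("response_labels", "data.frame")
  out
}

#' Drug eligibility for response modeling
#'
#' A drug is eligible when its AUC distribution has negative skewness and the
#' waterfall labelling yields more than `min_sensitive` sensitive subjects.
#'
#' @param act_area named numeric vector of Act Area values.
#' @param auc optional AUC values (derived as `1 - act_area` when absent).
#' @param min_sensitive minimum count of sensitive subjects (exclusive bound).
#' @param mad_scaled passed to [waterfall_cutoffs()].
#' @return list: `skewness`, `n_sensitive`, `eligible`, `labels`, `cutoffs`.
#' @export
drug_eligibility <- function(act_area, auc = NULL, min_sensitive = 20,
                             mad_scaled = FALSE) {
  if (is.null(auc)) auc <- 1 - act_area
  sk <- response_skewness(auc)
  res <- tryCatch({
    cut <- waterfall_cutoffs(act_area, mad_scaled = mad_scaled)
    labels <- assign_labels(act_area, cut)
    list(labels = labels, cutoffs = cut)
  }, error = function(e) {
    warning("waterfall labelling failed: ", conditionMessage(e))
    NULL
  })
  n_sens <- if (is.null(res)) 0L else sum(res$labels$label == "sensitive")
  list(skewness = sk,
       n_sensitive = n_sens,
       eligible = isTRUE(sk < 0) && n_sens > min_sensitive,
       labels = res$labels,
       cutoffs = res$cutoffs)
}
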