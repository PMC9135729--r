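#' Fractionally trimmed mean
#'
#' Mean after removing `trim * length(x)` observations' worth of mass from each
#' end of the sorted vector, with boundary observations fractionally weighted.
#' Unlike the floor-based trim of [mean()], this convention is exactly invariant
#' under k-fold replication of the input multiset, which the redundancy-penalty
#' normalization relies on (see the methods vignette). When `trim * length(x)`
#' is an integer the two conventions coincide.
#'
#' @param x numeric vector.
#' @param trim fraction in `[0, 0.5)` trimmed from each end.
#' @return scalar mean; `NaN` for empty input.
#' @export
#' @examples
#' trimmed_mean_frac(c(1, 2, 9), trim = 0.3)   # weights (0.1, 1, 0.1)
trimmed_mean_frac <- function(x, trim = 0.3) {
  stopifnot(is.numeric(x), trim >= 0, trim < 0.5)
  n <- length(x)
  if (n == 0L) return(NaN)
  if (trim == 0) return(mean(x))
  s <- sort(x)
  cut <- trim * n
  i <- seq_len(n)
  lo <- pmin(1, pmax(0, cut - (i - 1)))  # mass removed from the bottom
  hi <- pmin(1, pmax(0, cut - (n - i)))  # mass removed from the top
  w <- pmax(0, 1 - lo - hi)
  sum(w * s) / sum(w)
}

#' False discovery rate q-values
#'
#' Storey q-values with the null proportion pi0 estimated at a single lambda
#' (default 0.5), or Benjamini-Hochberg as a conservative fallback
#' (equivalent to Storey with pi0 = 1).
#'
#' @param p vector of p-values in (0, 1].
#' @param method `"storey"` or `"BH"`.
#' @param lambda tuning point for the pi0 estimate (storey only).
#' @return q-values, same length/order as `p`; monotone nondecreasing in `p`.
#' @export
qvalues <- function(p, method = c("storey", "BH"), lambda = 0.5) {
  method <- match.arg(method)
  stopifnot(all(is.finite(p)), all(p > 0), all(p <= 1))
  m <- length(p)
  if (m == 0L) return(numeric(0))
  if (method == "BH") return(stats::p.adjust(p, method = "BH"))
  pi0 <- min(1, (sum(p > lambda) + 1) / ((1 - lambda) * (m + 1)))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * m * p[o] / rank(p, ties.method = "max")[o]
  q <- pmin(1, cummin(q))[ro]
  q
}

# Deterministic sub-seed for a keyed random draw; kept below 2^31.
derive_seed <- function(base, n, m) {
  as.integer((abs(as.numeric(base)) * 10007 + as.numeric(n) * 131 +
                as.numeric(m) * 7919) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
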