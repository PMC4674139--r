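## Per-complex and dataset-level performance of the mining protocol.

#' Per-complex mining precision
#'
#' The fraction of correct (interface) residues among all identified
#' residues of one complex, accumulated over its `N` abstracts:
#' `P = sum(n_int) / sum(n_int + n_non)`.
#'
#' @param n_int,n_non Per-abstract counts of interface and non-interface
#'   identified residues.
#' @return A fraction in `[0, 1]`, or `NA` when no residues were
#'   identified at all (the complex then drops out of distributions).
#' @export
ptm <- function(n_int, n_non) {
  stopifnot(length(n_int) == length(n_non),
            all(n_int >= 0), all(n_non >= 0))
  den <- sum(n_int) + sum(n_non)
  if (den == 0) return(NA_real_)
  sum(n_int) / den
}

.round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Dataset-level coverage, success and accuracy
#'
#' From the number of complexes for which mining found at least one
#' abstract with residues (`l_tot`), the number with at least one
#' correct (interface) residue (`l_int`) and the dataset size:
#' coverage = `l_tot / n_total`, success = `l_int / n_total`, accuracy =
#' `l_int / l_tot`; reported as percentages rounded half-up to one
#' decimal.
#'
#' @param l_tot,l_int,n_total Counts with
#'   `0 <= l_int <= l_tot <= n_total`.
#' @return Named numeric vector `c(coverage, success, accuracy)` in
#'   percent; accuracy is `NA` when `l_tot` is zero.
#' @export
dataset_metrics <- function(l_tot, l_int, n_total) {
  stopifnot(n_total > 0, l_int >= 0, l_tot >= l_int, n_total >= l_tot)
  c(coverage = .round_half_up(100 * l_tot / n_total),
    success = .round_half_up(100 * l_int / n_total),
    accuracy = if (l_tot > 0) .round_half_up(100 * l_int / l_tot)
               else NA_real_)
}

#' Distribution of complexes over mining precision
#'
#' Histogram of per-complex [ptm()] values over `[0, 1]`, normalized by
#' the number of complexes with a defined value, so the bins sum to 1.
#'
#' @param ptm_values Numeric vector (`NA`s dropped).
#' @param bins Number of equal-width bins over `[0, 1]`. The last bin is
#'   closed on both sides.
#' @return Named numeric vector of normalized bin masses.
#' @export
ptm_histogram <- function(ptm_values, bins = 10) {
  v <- ptm_values[!is.na(ptm_values)]
  if (!length(v)) stop("no complexes with a defined precision")
  stopifnot(all(v >= 0), all(v <= 1))
  edges <- seq(0, 1, length.out = bins + 1L)
  idx <- pmin(findInterval(v, edges, rightmost.closed = TRUE), bins)
  counts <- tabulate(idx, nbins = bins)
  labels <- sprintf("[%.2f,%.2f%s", edges[-length(edges)], edges[-1L],
                    c(rep(")", bins - 1L), "]"))
  stats::setNames(counts / length(v), labels)
}

#' Per-complex precision change under relevance filtering
#'
#' Compares mining precision before and after an abstract-relevance
#' filter removed abstracts. Complexes for which the filter removed
#' *all* abstracts are flagged: their precision after filtering is
#' undefined and the change is reported as `NA`.
#'
#' @param before,after Per-complex [ptm()] values (same order; `after`
#'   is `NA` where all abstracts were removed).
#' @return Data frame with columns `delta` and `all_removed`.
#' @export
delta_ptm <- function(before, after) {
  stopifnot(length(before) == length(after))
  all_removed <- is.na(after) & !is.na(before)
  data.frame(delta = after - before, all_removed = all_removed)
}
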