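#' Contingency table between reference classes and predicted clusters
#'
#' @param reference vector of reference (manual-gating) labels.
#' @param predicted vector of predicted population labels, same length.
#' @param exclude reference labels to drop before scoring (e.g. an
#'   "unassigned" code); the number of excluded cells is recorded.
#' @return An object of class `contingency_table`: `counts` (classes x
#'   clusters), `ref_sizes`, `pred_sizes`, `n`, `n_excluded`.
#' @export
contingency_table <- function(reference, predicted, exclude = NULL) {
  if (length(reference) != length(predicted)) {
    stop("`reference` and `predicted` must have equal length")
  }
  keep <- !(reference %in% exclude)
  n_excluded <- sum(!keep)
  reference <- reference[keep]; predicted <- predicted[keep]
  if (length(reference) == 0L) stop("no cells left after exclusion")
  counts <- table(reference, predicted)
  structure(
    list(counts = unclass(counts),
         ref_sizes = rowSums(counts),
         pred_sizes = colSums(counts),
         n = length(reference),
         n_excluded = n_excluded),
    class = "contingency_table"
  )
}

#' Precision, recall and F-score of one class/cluster pair
#'
#' `precision = n_ij / |cluster j|`, `recall = n_ij / |class i|`,
#' `f` their harmonic mean (0 when the pair shares no cells).
#'
#' @param tab a `contingency_table`.
#' @param i reference class (index or name).
#' @param j predicted cluster (index or name).
#' @return Named numeric vector `c(precision, recall, f)`.
#' @export
pairwise_f <- function(tab, i, j) {
  stopifnot(inherits(tab, "contingency_table"))
  nij <- tab$counts[i, j]
  precision <- nij / tab$pred_sizes[[j]]
  recall <- nij / tab$ref_sizes[[i]]
  f <- if (nij == 0) 0 else 2 * precision * recall / (precision + recall)
  c(precision = unname(precision), recall = unname(recall), f = unname(f))
}

#' Weighted F-measure of a clustering against reference labels
#'
#' `F = (1/N) sum_i |class i| * max_j f(class i, cluster j)`: each
#' reference class is matched to its best predicted cluster by harmonic
#' mean of precision and recall, and the per-class scores are averaged
#' weighted by class size. The score lies in (0, 1], equals 1 exactly for
#' a perfect clustering, and is invariant to relabeling of the predicted
#' clusters.
#'
#' @inheritParams contingency_table
#' @return F-measure in (0, 1].
#' @export
#' @examples
#' f_measure(c(1, 1, 2, 2), c(5, 5, 9, 9)) # 1: same partition, new names
f_measure <- function(reference, predicted, exclude = NULL) {
  tab <- contingency_table(reference, predicted, exclude = exclude)
  cnt <- tab$counts
  prec <- sweep(cnt, 2L, tab$pred_sizes, "/")
  rec <- sweep(cnt, 1L, tab$ref_sizes, "/")
  f <- matrix(0, nrow(cnt), ncol(cnt))
  nz <- cnt > 0
  f[nz] <- 2 * prec[nz] * rec[nz] / (prec[nz] + rec[nz])
  best <- apply(f, 1L, max)
  sum(tab$ref_sizes * best) / tab$n
}

#' Count non-empty final populations
#'
#' @param assignment a `population_assignment` from [merge_populations()].
#' @return Number of populations that received at least one cell.
#' @export
count_populations <- function(assignment) {
  stopifnot(inherits(assignment, "population_assignment"))
  sum(tabulate(assignment$final_labels, assignment$n_populations) > 0L)
}
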