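#' Build a similarity graph over cluster centers
#'
#' Gaussian similarity `A_ij = exp(-||mu_i - mu_j||^2 / (2 sigma^2))` with
#' unit self-loops (`A_ii = 1`, the canonical Markov-clustering
#' stabilizer). With `sigma = "auto"` the scale is the median pairwise
#' center distance (1 when there is a single center or all centers
#' coincide).
#'
#' @param centers K x M matrix of cluster centers.
#' @param sigma positive kernel scale, or `"auto"`.
#' @return An object of class `center_graph` with fields `adjacency`
#'   (K x K symmetric, non-negative, positive diagonal) and `sigma`.
#' @export
build_center_graph <- function(centers, sigma = "auto") {
  centers <- as.matrix(centers)
  k <- nrow(centers)
  d <- as.matrix(stats::dist(centers))
  if (identical(sigma, "auto")) {
    off <- d[upper.tri(d)]
    sigma <- if (length(off) == 0L || stats::median(off) == 0) 1 else stats::median(off)
  }
  if (!is.numeric(sigma) || sigma <= 0) stop("`sigma` must be positive or \"auto\"")
  a <- exp(-d^2 / (2 * sigma^2))
  diag(a) <- 1
  dimnames(a) <- NULL
  structure(list(adjacency = a, sigma = sigma), class = "center_graph")
}

normalize_columns <- function(s) {
  cs <- colSums(s)
  dead <- cs == 0
  if (any(dead)) {          # re-seed emptied columns on their own node
    s[cbind(which(dead), which(dead))] <- 1
    cs[dead] <- 1
  }
  sweep(s, 2L, cs, "/")
}

#' Markov clustering of a center graph
#'
#' Column-normalizes the adjacency matrix and alternates expansion (matrix
#' power) and inflation (element-wise power followed by column
#' renormalization), pruning entries below `prune`, until the matrix stops
#' changing. The converged matrix decomposes the graph into segments:
#' attractor nodes (positive diagonal) collect the nodes that flow into
#' them, and attractors sharing any node are unioned.
#'
#' @param graph a `center_graph` (or a plain symmetric non-negative matrix).
#' @param expansion integer matrix-power exponent, >= 2.
#' @param inflation element-wise power, > 1.
#' @param prune entries below this are zeroed each iteration.
#' @param tol convergence threshold on the max absolute change.
#' @param max_iter iteration cap; non-convergence yields the current
#'   segmentation with a warning.
#' @return An object of class `mcl_result`: `segments` (list of disjoint
#'   integer vectors covering `1:K`), `converged_matrix` (column
#'   stochastic), `iterations`, `converged`.
#' @export
mcl <- function(graph, expansion = 2L, inflation = 2, prune = 1e-8,
                tol = 1e-6, max_iter = 100L) {
  a <- if (inherits(graph, "center_graph")) graph$adjacency else as.matrix(graph)
  if (any(a < 0)) stop("adjacency entries must be non-negative")
  if (expansion < 2L) stop("`expansion` must be >= 2")
  if (inflation <= 1) stop("`inflation` must be > 1")
  k <- nrow(a)
  s <- normalize_columns(a)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    s_old <- s
    se <- s
    for (p in seq_len(expansion - 1L)) se <- se %*% s  # S^expansion
    se <- se^inflation
    se[se < prune] <- 0
    s <- normalize_columns(se)
    if (max(abs(s - s_old)) < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("MCL did not converge within max_iter; using current matrix")

  attractors <- which(diag(s) > 1e-6)
  if (length(attractors) == 0L) attractors <- seq_len(k)
  # each node joins the attractor receiving most of its flow
  owner <- vapply(seq_len(k), function(j) {
    attractors[which.max(s[attractors, j])]
  }, integer(1))
  # union attractors that share support: any node with flow into several
  # attractors links them into one segment
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (j in seq_len(k)) {
    supp <- attractors[s[attractors, j] > prune]
    if (length(supp) > 1L) {
      r <- find(supp[1L])
      for (other in supp[-1L]) {
        ro <- find(other)
        if (ro != r) parent[ro] <- r
      }
    }
  }
  root <- vapply(owner, find, integer(1))
  segs <- split(seq_len(k), root)
  segs <- segs[order(vapply(segs, min, integer(1)))]
  names(segs) <- NULL
  structure(
    list(segments = segs, converged_matrix = s, iterations = iter,
         converged = converged),
    class = "mcl_result"
  )
}

#' @export
print.mcl_result <- function(x, ...) {
  cat(sprintf("mcl_result: %d segments after %d iterations%s\n",
              length(x$segments), x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Merge initial clusters into final populations
#'
#' Initial clusters whose centers fall in the same Markov-clustering
#' segment become one final population; every cell's final label is the
#' segment of its initial cluster, so population sizes conserve N.
#'
#' @param model a `cluster_model` from [fcm_fit()].
#' @param labels integer vector of initial hard labels (from
#'   [hard_assign()]).
#' @param result an `mcl_result` whose segments partition the K initial
#'   clusters.
#' @return An object of class `population_assignment`: `merge_map`
#'   (length-K integer vector: initial cluster -> population),
#'   `final_labels`, `n_populations`.
#' @export
merge_populations <- function(model, labels, result) {
  k <- nrow(model$centers)
  segs <- result$segments
  flat <- sort(unlist(segs))
  if (!identical(as.integer(flat), seq_len(k))) {
    stop("MCL segments do not form a partition of the initial clusters")
  }
  merge_map <- integer(k)
  for (i in seq_along(segs)) merge_map[segs[[i]]] <- i
  structure(
    list(merge_map = merge_map,
         final_labels = merge_map[labels],
         n_populations = length(segs)),
    class = "population_assignment"
  )
}

#' @export
print.population_assignment <- function(x, ...) {
  cat(sprintf("population_assignment: %d populations over %d cells\n",
              x$n_populations, length(x$final_labels)))
  invisible(x)
}
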