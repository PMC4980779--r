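#' Two-stage clustering of one flow cytometry sample
#'
#' Runs the full single-sample pipeline: estimate the initial cluster
#' count K from significant density modes along the eigenvector
#' projections ([estimate_initial_k()]), soft-cluster the cells with
#' Mahalanobis fuzzy C-means ([fcm_fit()]), build a Gaussian similarity
#' graph over the K cluster centers, Markov-cluster it ([mcl()]) and merge
#' initial clusters sharing a segment into final populations
#' ([merge_populations()]).
#'
#' @param sample a [flow_sample].
#' @param alpha_modes significance level of the mode-count gradient test.
#' @param m fuzzifier (> 1).
#' @param distance_mode `"mahalanobis"` or `"euclidean"` (see [fcm_fit()]).
#' @param expansion,inflation Markov clustering parameters (see [mcl()]).
#' @param sigma center-graph kernel scale. The default `"spread"` sets
#'   sigma to twice the mean within-cluster RMS spread (root mean
#'   diagonal of the hard-assigned clusters' covariances), so two centers
#'   are strongly connected exactly when they sit within a few
#'   cluster-widths of each other — the regime in which they describe one
#'   split population — while centers a population-separation apart stay
#'   disconnected. `"auto"` (median pairwise center distance) or a number
#'   are passed to [build_center_graph()].
#' @param seed integer seed controlling the fuzzy C-means initialization.
#' @param K optional fixed initial cluster count, bypassing
#'   [estimate_initial_k()].
#' @return An object of class `cytoclust_result`: `k_initial`,
#'   `mode_result`, `model` (the `cluster_model`), `mcl` (the
#'   `mcl_result`), `assignment` (the `population_assignment`),
#'   `n_populations` and `population_sizes`.
#' @export
#' @examples
#' sim <- gen_mixture_sample(seven_population_spec(50), seed = 7)
#' res <- cluster_sample(sim$sample, seed = 7)
#' res$n_populations
cluster_sample <- function(sample, alpha_modes = 0.05, m = 2,
                           distance_mode = "mahalanobis",
                           expansion = 2L, inflation = 2, sigma = "spread",
                           seed = 1L, K = NULL) {
  stopifnot(inherits(sample, "flow_sample"))
  mode_result <- NULL
  if (is.null(K)) {
    mode_result <- estimate_initial_k(sample, alpha = alpha_modes)
    K <- min(mode_result$K, n_cells(sample))
  }
  model <- fcm_fit(sample, K = K, m = m, distance_mode = distance_mode,
                   seed = seed)
  labels <- hard_assign(model)
  if (identical(sigma, "spread")) {
    sigma <- spread_sigma(sample$values, labels, K)
  }
  graph <- build_center_graph(model$centers, sigma = sigma)
  mcl_res <- mcl(graph, expansion = expansion, inflation = inflation)
  assignment <- merge_populations(model, labels, mcl_res)
  structure(
    list(k_initial = K, mode_result = mode_result, model = model,
         mcl = mcl_res, assignment = assignment,
         n_populations = assignment$n_populations,
         population_sizes = tabulate(assignment$final_labels,
                                     assignment$n_populations)),
    class = "cytoclust_result"
  )
}

# Three times the mean within-cluster RMS spread of the hard partition;
# the center-graph kernel scale at which split fragments of one
# population stay connected and distinct populations do not. Fragments of
# a split Gaussian population sit within about 1.5-2.5 cluster widths of
# each other (the exact figure grows with dimension), while populations a
# biologist would call distinct sit many widths apart, so a kernel scale
# of a few widths separates the two regimes. Falls back to the median
# pairwise center distance when no cluster has two cells.
spread_sigma <- function(x, labels, k, multiplier = 3) {
  spreads <- vapply(seq_len(k), function(j) {
    xj <- x[labels == j, , drop = FALSE]
    if (nrow(xj) < 2L) return(NA_real_)
    sqrt(mean(diag(stats::cov(xj))))
  }, numeric(1))
  s <- mean(spreads, na.rm = TRUE)
  if (!is.finite(s) || s <= 0) return("auto")
  multiplier * s
}

#' @export
print.cytoclust_result <- function(x, ...) {
  cat(sprintf("cytoclust_result: K initial = %d -> %d final populations\n",
              x$k_initial, x$n_populations))
  cat("population sizes:", paste(x$population_sizes, collapse = ", "), "\n")
  invisible(x)
}

# JSON-ready summary of a clustering run.
cluster_report <- function(result, sample) {
  list(
    sample_id = sample$sample_id,
    n_cells = n_cells(sample),
    markers = sample$marker_names,
    k_initial = result$k_initial,
    per_eigenvector_modes =
      if (is.null(result$mode_result)) NULL
      else result$mode_result$per_eigenvector_modes,
    n_populations = result$n_populations,
    population_sizes = result$population_sizes,
    merge_map = result$assignment$merge_map,
    fcm_iterations = result$model$iterations,
    fcm_converged = result$model$converged,
    mcl_iterations = result$mcl$iterations
  )
}
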