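#' Mahalanobis distance between a point and a cluster center
#'
#' `sqrt((x - mu) S^-1 (x - mu)^T)`. With `S` the identity this is the
#' Euclidean distance; in general it discounts displacement along
#' directions in which the cluster is spread out.
#'
#' @param x numeric vector (one cell).
#' @param mu numeric vector (cluster center), same length.
#' @param S symmetric positive-definite covariance matrix.
#' @return Non-negative distance.
#' @export
#' @examples
#' mahalanobis_distance(c(3, 4), c(0, 0), diag(2)) # 5
mahalanobis_distance <- function(x, mu, S) {
  if (!isSymmetric(unname(S), tol = 1e-8)) stop("`S` must be symmetric")
  sqrt(stats::mahalanobis(matrix(x, nrow = 1L), mu, S))
}

#' Regularize a cluster covariance matrix
#'
#' Returns `S + eps * I` with `eps = 1e-6 * trace(S)/M` (or `1e-6` when the
#' trace is zero). When the cluster holds no more points than dimensions —
#' the regime in which the sample covariance is singular and the
#' Mahalanobis distance otherwise undefined — the off-diagonal entries are
#' dropped first (diagonal covariance), so small or rare populations remain
#' clusterable.
#'
#' @param S symmetric matrix.
#' @param n_points number of points supporting the estimate of `S`.
#' @return A symmetric positive-definite matrix.
#' @export
regularize_covariance <- function(S, n_points = Inf) {
  if (!isSymmetric(unname(S), tol = 1e-8)) stop("`S` must be symmetric")
  m <- nrow(S)
  tr <- sum(diag(S))
  eps <- if (tr / m < 1e-12) 1e-6 else 1e-6 * tr / m
  if (n_points <= m) S <- diag(diag(S), nrow = m)
  S + diag(eps, m)
}

# k-means++ seeding: first center uniform, then each next center drawn with
# probability proportional to squared distance to the nearest chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  if (k > 1L) {
    d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
    for (j in 2:k) {
      tot <- sum(d2)
      idx <- if (tot <= 0) sample.int(n, 1L) else {
        sample.int(n, 1L, prob = d2 / tot)
      }
      centers[j, ] <- x[idx, ]
      d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
    }
  }
  centers
}

# Initialization: several k-means++ seedings, each refined by a short
# k-means run, keeping the centers with the lowest within-cluster sum of
# squares. The refinement makes the start robust against the occasional
# k-means++ draw that double-seeds one population.
best_kmeans_init <- function(x, k, n_starts = 5L) {
  best <- NULL
  best_ss <- Inf
  for (s in seq_len(n_starts)) {
    centers <- kmeanspp_centers(x, k)
    km <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = centers, iter.max = 10L)),
      error = function(e) NULL)
    if (is.null(km)) {
      d2 <- cluster_sq_distances(x, centers)
      ss <- sum(d2[cbind(seq_len(nrow(x)), max.col(-d2))])
      cand <- centers
    } else {
      ss <- km$tot.withinss
      cand <- km$centers
    }
    if (ss < best_ss) { best_ss <- ss; best <- cand }
  }
  unname(as.matrix(best))
}

# Squared distances from every row of x to every center, per distance mode.
# covs: list of K regularized covariance matrices (mahalanobis mode).
cluster_sq_distances <- function(x, centers, covs = NULL) {
  k <- nrow(centers)
  d2 <- matrix(0, nrow(x), k)
  for (j in seq_len(k)) {
    if (is.null(covs)) {
      xc <- sweep(x, 2L, centers[j, ])
      d2[, j] <- rowSums(xc * xc)
    } else {
      S <- covs[[j]]
      # escalate the ridge if the regularized matrix is still numerically
      # singular (e.g. a nearly collapsed cluster)
      repeat {
        md <- tryCatch(stats::mahalanobis(x, centers[j, ], S),
                       error = function(e) NULL)
        if (!is.null(md)) break
        S <- S + diag(max(sum(diag(S)) / nrow(S), 1e-6), nrow(S))
      }
      d2[, j] <- md
    }
  }
  pmax(d2, 0)
}

# Membership update from squared distances: u_ij proportional to
# D_ij^(-2/(m-1)). Cells at zero distance from one or more centers get
# membership split equally among those centers (classical FCM convention).
fcm_memberships <- function(d2, m) {
  p <- -1 / (m - 1)          # (D^2)^p = D^(-2/(m-1))
  w <- d2
  zero <- d2 < .Machine$double.eps
  any_zero <- rowSums(zero) > 0L
  w[!any_zero, ] <- d2[!any_zero, , drop = FALSE]^p
  u <- w / rowSums(w)
  if (any(any_zero)) {
    zr <- which(any_zero)
    u[zr, ] <- zero[zr, , drop = FALSE] / rowSums(zero[zr, , drop = FALSE])
  }
  u
}

#' Fuzzy C-means clustering with Mahalanobis or Euclidean distance
#'
#' Alternates the center update
#' `mu_j = sum_i u_ij^m x_i / sum_i u_ij^m` and the membership update
#' `u_ij = 1 / sum_k (D(x_i, mu_j) / D(x_i, mu_k))^(2/(m-1))`, minimizing
#' the fuzzy objective `J_m = sum_ij u_ij^m D(x_i, mu_j)^2` subject to each
#' cell's memberships summing to one. In `"mahalanobis"` mode each
#' cluster's covariance is re-estimated every iteration from the current
#' memberships (weights `u_ij^m`) and regularized with
#' [regularize_covariance()], so elongated or rare populations are measured
#' in their own metric; `"euclidean"` mode is the classical algorithm.
#'
#' @param sample a [flow_sample].
#' @param K number of clusters (1 <= K <= N), e.g. from
#'   [estimate_initial_k()].
#' @param m fuzzifier, > 1; 2 is the standard choice used throughout.
#' @param distance_mode `"mahalanobis"` (default) or `"euclidean"`.
#' @param seed integer seed for the k-means++ center initialization.
#' @param tol convergence threshold on `max |u' - u|`.
#' @param max_iter iteration cap.
#' @param n_starts number of seeded k-means++ starts evaluated during
#'   initialization (each refined by a short k-means run; the best by
#'   within-cluster sum of squares seeds the fuzzy iteration).
#' @param init_centers optional K x M matrix of starting centers; overrides
#'   the seeded k-means++ initialization (used for oracle comparisons).
#' @return An object of class `cluster_model` with fields `centers` (K x M),
#'   `memberships` (N x K), `covariances` (list of K matrices, identity in
#'   euclidean mode), `m`, `distance_mode`, `objective_trace`, `iterations`
#'   and `converged`.
#' @export
fcm_fit <- function(sample, K, m = 2, distance_mode = c("mahalanobis", "euclidean"),
                    seed = 1L, tol = 1e-5, max_iter = 100L, n_starts = 5L,
                    init_centers = NULL) {
  stopifnot(inherits(sample, "flow_sample"))
  distance_mode <- match.arg(distance_mode)
  x <- sample$values
  n <- nrow(x); mm <- ncol(x)
  if (K < 1L) stop("K must be >= 1")
  if (K > n) stop(sprintf("K = %d exceeds the number of cells N = %d", K, n))
  if (m <= 1) stop("fuzzifier `m` must be > 1")

  centers <- if (is.null(init_centers)) {
    with_seed(seed, best_kmeans_init(x, K, n_starts = n_starts))
  } else {
    stopifnot(nrow(init_centers) == K, ncol(init_centers) == mm)
    as.matrix(init_centers)
  }

  maha <- distance_mode == "mahalanobis"
  covs <- NULL  # first membership step is Euclidean (no partition yet)
  u <- fcm_memberships(cluster_sq_distances(x, centers, covs), m)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    w <- u^m
    centers <- t(w) %*% x / colSums(w)
    if (maha) {
      hard <- max.col(u, ties.method = "first")
      covs <- lapply(seq_len(K), function(j) {
        xc <- sweep(x, 2L, centers[j, ])
        S <- crossprod(xc * w[, j], xc) / sum(w[, j])
        regularize_covariance((S + t(S)) / 2, n_points = sum(hard == j))
      })
    }
    d2 <- cluster_sq_distances(x, centers, covs)
    u_new <- fcm_memberships(d2, m)
    trace <- c(trace, sum(u_new^m * d2))
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (is.null(covs)) covs <- rep(list(diag(mm)), K)
  dimnames(centers) <- list(NULL, sample$marker_names)
  structure(
    list(centers = centers, memberships = u, covariances = covs,
         m = m, distance_mode = distance_mode, objective_trace = trace,
         iterations = iter, converged = converged),
    class = "cluster_model"
  )
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: %d clusters, %d cells, %s distance, %d iterations%s\n",
              nrow(x$centers), nrow(x$memberships), x$distance_mode,
              x$iterations, if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Hard cluster assignment from fuzzy memberships
#'
#' Assigns each cell to its maximum-membership cluster; ties go to the
#' lowest cluster index.
#'
#' @param model a `cluster_model` from [fcm_fit()].
#' @return Integer label vector (values in `1:K`).
#' @export
hard_assign <- function(model) {
  stopifnot(inherits(model, "cluster_model"))
  max.col(model$memberships, ties.method = "first")
}
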