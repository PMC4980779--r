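# Independent reference implementations used as oracles in the tests.
# These deliberately use the most direct (slow) formulation of each
# quantity and share no code with the package internals.

# Classical fuzzy C-means, Euclidean distance, textbook update formulas.
naive_fcm <- function(x, centers, m = 2, tol = 1e-5, max_iter = 100L) {
  k <- nrow(centers)
  n <- nrow(x)
  u <- matrix(0, n, k)
  for (it in seq_len(max_iter)) {
    d <- matrix(0, n, k)
    for (j in seq_len(k)) {
      for (i in seq_len(n)) d[i, j] <- sqrt(sum((x[i, ] - centers[j, ])^2))
    }
    u_new <- matrix(0, n, k)
    for (i in seq_len(n)) {
      if (any(d[i, ] == 0)) {
        u_new[i, d[i, ] == 0] <- 1 / sum(d[i, ] == 0)
      } else {
        for (j in seq_len(k)) {
          u_new[i, j] <- 1 / sum((d[i, j] / d[i, ])^(2 / (m - 1)))
        }
      }
    }
    delta <- max(abs(u_new - u))
    u <- u_new
    for (j in seq_len(k)) {
      w <- u[, j]^m
      centers[j, ] <- colSums(w * x) / sum(w)
    }
    if (delta < tol) break
  }
  list(centers = centers, u = u)
}

# Weighted F-measure by explicit double loop over all class/cluster pairs.
brute_f_measure <- function(reference, predicted) {
  n <- length(reference)
  classes <- unique(reference)
  clusters <- unique(predicted)
  total <- 0
  for (cl in classes) {
    size <- sum(reference == cl)
    best <- 0
    for (cu in clusters) {
      nij <- sum(reference == cl & predicted == cu)
      if (nij > 0) {
        p <- nij / sum(predicted == cu)
        r <- nij / size
        best <- max(best, 2 * p * r / (p + r))
      }
    }
    total <- total + size * best
  }
  total / n
}

# Mode count as the number of interior local maxima of the density on the
# same grid the package uses (no significance testing). Maxima below 1 %
# of the peak density are sampling micro-bumps in the far tail, not modes.
count_density_maxima <- function(e, grid_size = 512L) {
  h <- scott_bandwidth(e)
  grid <- seq(min(e) - 3 * h, max(e) + 3 * h, length.out = grid_size)
  f <- kde_and_gradient(e, grid, h)$density
  mx <- which(diff(sign(diff(f))) == -2) + 1L
  sum(f[mx] > 0.01 * max(f))
}

# Classical density-peak delta: distance to the nearest point of strictly
# higher density; global maximum gets the largest distance to any point.
classical_delta <- function(x, rho) {
  d <- as.matrix(dist(x))
  vapply(seq_along(rho), function(i) {
    higher <- which(rho > rho[i])
    if (length(higher) == 0L) max(d[i, ]) else min(d[i, higher])
  }, numeric(1))
}

# Small deterministic two-blob sample for clustering tests.
two_blob_sample <- function(n_per = 200L, seed = 1L) {
  sim <- gen_mixture_sample(
    mixture_spec(rbind(c(0, 0), c(20, 20)), n_cells = 2L * n_per),
    seed = seed)
  sim
}
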