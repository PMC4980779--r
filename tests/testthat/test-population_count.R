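test_that("eigen projections are centered and aligned with the covariance axes", {
  # 1-D: single projection equals the centered values up to global sign
  v <- c(1, 4, 2, 8, 5)
  fs1 <- flow_sample(matrix(v, ncol = 1))
  p1 <- eigen_projections(fs1)[[1]]
  expect_equal(abs(p1), abs(v - mean(v)))

  # 2-D data with diagonal covariance: first axis is the high-variance
  # coordinate (up to sign)
  x <- rep(c(-2, -2, 2, 2), 25) * sqrt(3)
  y <- rep(c(-1, 1, -1, 1), 25)
  fs2 <- flow_sample(cbind(x, y))
  proj <- eigen_projections(fs2)
  expect_equal(abs(proj[[1]]), abs(x), tolerance = 1e-9)
  expect_equal(abs(proj[[2]]), abs(y), tolerance = 1e-9)

  # projections have zero mean
  sim <- two_blob_sample(100)
  for (p in eigen_projections(sim$sample)) {
    expect_lt(abs(mean(p)), 1e-9)
  }
  expect_error(eigen_projections(flow_sample(matrix(1, 1, 2))), "at least 2")
})

test_that("mode-counting bandwidth follows the printed rule", {
  e <- rnorm(1000)
  e <- (e - mean(e)) / sd(e)        # sigma* exactly 1
  expect_equal(scott_bandwidth(e), 0.35)
  expect_equal(scott_bandwidth(2 * e), 0.70)
  # doubling N multiplies h by 2^(-1/3)
  e2 <- c(e, e)
  expect_equal(scott_bandwidth(e2) / scott_bandwidth(e),
               2^(-1 / 3) * sd(e2) / sd(e))
  expect_error(scott_bandwidth(rep(3, 10)), "constant")
  expect_error(scott_bandwidth(1), "at least 2")
})

test_that("kernel density and gradient match closed forms and finite differences", {
  # single point: f(0) = 1/(h sqrt(2 pi)), gradient 0 by symmetry
  h <- 0.7
  kg <- kde_and_gradient(0, grid = c(-1, 0, 1), h = h)
  expect_equal(kg$density[2], 1 / (h * sqrt(2 * pi)))
  expect_equal(kg$gradient[2], 0)

  # symmetric sample: gradient 0 at the center
  kg2 <- kde_and_gradient(c(-2, 2), grid = c(-1, 0, 1), h = 1)
  expect_equal(kg2$gradient[2], 0)

  # analytic gradient agrees with centered finite differences of f
  set.seed(11)
  e <- rnorm(400)
  h <- scott_bandwidth(e)
  grid <- seq(-3, 3, length.out = 3001)
  kg3 <- kde_and_gradient(e, grid, h)
  g <- length(grid)
  fd <- (kg3$density[-(1:2)] - kg3$density[seq_len(g - 2)]) /
    (grid[-(1:2)] - grid[seq_len(g - 2)])
  mid <- kg3$gradient[2:(g - 1)]
  interior <- abs(mid) > 1e-3
  expect_lt(max(abs(mid[interior] - fd[interior]) / abs(mid[interior])),
            1e-4)

  expect_error(kde_and_gradient(e, grid = c(1, 0), h = 1), "increasing")
  expect_error(kde_and_gradient(e, grid = c(0, 1), h = -1), "> 0")
})

test_that("density is non-negative and integrates to ~1 on the counting grid", {
  set.seed(5)
  for (e in list(rnorm(500), c(rnorm(300), rnorm(300, 15)))) {
    h <- scott_bandwidth(e)
    grid <- seq(min(e) - 4 * h, max(e) + 4 * h, length.out = 512)
    f <- kde_and_gradient(e, grid, h)$density
    expect_true(all(f >= 0))
    integral <- sum((f[-1] + f[-length(f)]) / 2 * diff(grid))
    expect_lt(abs(integral - 1), 0.02)
  }
})

test_that("significant-gradient mode counts match the density-maxima oracle", {
  # unimodal and well-separated bimodal samples, against the direct count
  # of local maxima of the same density estimate
  for (s in 1:5) {
    set.seed(100 + s)
    uni <- rnorm(5000)
    expect_equal(count_modes(uni), count_density_maxima(uni))
    expect_equal(count_modes(uni), 1L)
    bi <- c(rnorm(2500), rnorm(2500, 20))
    expect_equal(count_modes(bi), count_density_maxima(bi))
    expect_equal(count_modes(bi), 2L)
  }
})

test_that("mode counts are invariant to shift and positive scaling", {
  set.seed(21)
  e <- c(rnorm(800), rnorm(800, 12))
  base <- count_modes(e)
  expect_equal(count_modes(e + 100), base)
  expect_equal(count_modes(e * 3.7), base)
  expect_equal(count_modes(-e), base)
})

test_that("unimodal mode count is stable across seeds", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    hits <- hits + (count_modes(rnorm(5000)) == 1L)
  }
  expect_gte(hits, 19L)
})

test_that("initial K sums per-eigenvector modes and floors at 1", {
  # 3 collinear unit-variance clusters: modes (3, 1), K = 4
  sim <- gen_mixture_sample(
    mixture_spec(rbind(c(0, 0), c(10, 0), c(20, 0)), n_cells = 900L),
    seed = 2)
  mr <- estimate_initial_k(sim$sample)
  expect_equal(mr$per_eigenvector_modes, c(3L, 1L))
  expect_equal(mr$K, 4L)
  expect_true(all(mr$bandwidths > 0))

  # single tight blob in 3-D: at most one mode per eigenvector
  sim3 <- gen_mixture_sample(
    mixture_spec(matrix(0, 1, 3), n_cells = 800L), seed = 3)
  mr3 <- estimate_initial_k(sim3$sample)
  expect_gte(mr3$K, 1L)
  expect_lte(mr3$K, 3L)

  # K never drops below 1 even when no mode is significant
  tiny <- flow_sample(matrix(runif(20, 0, 1e-3), ncol = 2))
  expect_gte(estimate_initial_k(tiny)$K, 1L)
})
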