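#' Specify a Gaussian-mixture flow sample
#'
#' @param means K x M matrix of population means.
#' @param covariances list of K covariance matrices; default identity.
#' @param weights positive population weights summing to 1; default equal.
#' @param n_cells total number of cells to draw.
#' @param marker_names optional length-M character vector.
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(means, covariances = NULL, weights = NULL,
                         n_cells = 1000L, marker_names = NULL) {
  means <- as.matrix(means)
  k <- nrow(means); m <- ncol(means)
  if (is.null(covariances)) covariances <- rep(list(diag(m)), k)
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (length(covariances) != k) stop("need one covariance per population")
  if (length(weights) != k) stop("need one weight per population")
  if (any(weights <= 0)) stop("weights must be positive")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  if (is.null(marker_names)) marker_names <- paste0("M", seq_len(m))
  structure(
    list(means = means, covariances = covariances, weights = weights,
         n_cells = as.integer(n_cells), marker_names = marker_names),
    class = "mixture_spec"
  )
}

#' Draw a seeded Gaussian-mixture sample with ground-truth labels
#'
#' Cells are assigned to populations multinomially by the mixture weights
#' and drawn from the corresponding Gaussian. Fully deterministic given
#' `(spec, seed)`.
#'
#' @param spec a [mixture_spec].
#' @param seed integer seed.
#' @param sample_id,subject_id identifiers passed to [flow_sample()].
#' @return A list with elements `sample` (a [flow_sample]) and `labels`
#'   (integer vector of generating populations).
#' @export
gen_mixture_sample <- function(spec, seed = 1L, sample_id = "synthetic",
                               subject_id = NULL) {
  stopifnot(inherits(spec, "mixture_spec"))
  with_seed(seed, {
    k <- nrow(spec$means)
    n <- spec$n_cells
    labels <- sample.int(k, n, replace = TRUE, prob = spec$weights)
    x <- matrix(NA_real_, n, ncol(spec$means))
    for (j in seq_len(k)) {
      idx <- which(labels == j)
      if (length(idx) > 0L) {
        x[idx, ] <- MASS::mvrnorm(length(idx), spec$means[j, ],
                                  spec$covariances[[j]])
      }
    }
    list(sample = flow_sample(x, marker_names = spec$marker_names,
                              sample_id = sample_id, subject_id = subject_id),
         labels = labels)
  })
}

#' Default two-marker, seven-population demonstration mixture
#'
#' Seven unit-covariance populations with pairwise center separation of at
#' least 9 standard deviations, 300 cells each: a well-separated benchmark
#' for which ground truth is unambiguous. The centers are laid out so that
#' each principal axis of the data sees four well-spaced projection groups
#' of comparable mass (and the two axis variances differ enough to pin the
#' eigenvectors), which keeps the density-mode count per axis stable and
#' the summed initial cluster estimate at or above the true population
#' count — the over-estimation regime the merge stage is designed for.
#'
#' @param cells_per_population cells per population.
#' @return A [mixture_spec] with 7 populations in 2 dimensions.
#' @export
seven_population_spec <- function(cells_per_population = 300L) {
  means <- rbind(
    c(0, 0), c(20, 0), c(10, 9), c(30, 9),
    c(20, 18), c(30, 18), c(0, 27)
  )
  mixture_spec(means, n_cells = 7L * cells_per_population,
               marker_names = c("FL1", "FL2"))
}

#' Specify a multi-subject synthetic cohort
#'
#' Every subject is drawn from a shared mixture template whose population
#' means are jittered per subject (between-subject biological variation).
#' Anomalous subjects additionally have selected markers of selected
#' populations shifted by `anomaly_shift` pooled standard deviations
#' (the pooled SD is the analytic marker SD of the template mixture)
#' and, optionally, their first anomalous population's weight changed by
#' `anomaly_fraction_change` (renormalized).
#'
#' @param template a [mixture_spec] shared by all subjects.
#' @param n_subjects number of subjects P.
#' @param jitter_sd SD of the per-subject jitter added to every mean entry.
#' @param n_anomalous number of anomalous subjects (< P).
#' @param anomaly_shift marker shift in pooled-SD units, >= 0.
#' @param anomaly_markers marker indices shifted in anomalous subjects.
#' @param anomaly_populations population indices receiving the shift.
#' @param anomaly_fraction_change additive change to the weight of the
#'   first anomalous population (0 = none).
#' @param cells_per_subject cells drawn per subject.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(template = aml_template_spec(),
                        n_subjects = 150L, jitter_sd = 0.3,
                        n_anomalous = 2L, anomaly_shift = 4,
                        anomaly_markers = c(4L, 5L),
                        anomaly_populations = 1L,
                        anomaly_fraction_change = 0,
                        cells_per_subject = 200L) {
  stopifnot(inherits(template, "mixture_spec"))
  if (n_anomalous >= n_subjects) stop("`n_anomalous` must be < `n_subjects`")
  if (anomaly_shift < 0) stop("`anomaly_shift` must be >= 0")
  structure(
    list(template = template, n_subjects = as.integer(n_subjects),
         jitter_sd = jitter_sd, n_anomalous = as.integer(n_anomalous),
         anomaly_shift = anomaly_shift,
         anomaly_markers = as.integer(anomaly_markers),
         anomaly_populations = as.integer(anomaly_populations),
         anomaly_fraction_change = anomaly_fraction_change,
         cells_per_subject = as.integer(cells_per_subject)),
    class = "cohort_spec"
  )
}

#' Default cohort template: three populations over five markers
#'
#' Three unit-covariance populations separated on the lineage markers
#' (CD45, CD3, CD19) and identical on the progenitor/blast markers (CD34,
#' CD117), so that an induced CD34/CD117 shift in anomalous subjects mimics
#' an emerging leukemic phenotype rather than a new lineage.
#'
#' @return A [mixture_spec] with 3 populations in 5 dimensions.
#' @export
aml_template_spec <- function() {
  means <- rbind(
    c(0, 0, 0, 0, 0),
    c(10, 0, 0, 0, 0),
    c(0, 10, 0, 0, 0)
  )
  mixture_spec(means, n_cells = 1L,
               marker_names = c("CD45", "CD3", "CD19", "CD34", "CD117"))
}

# Analytic per-marker SD of a Gaussian mixture:
# var = sum_k w_k (S_kk + mu_k^2) - (sum_k w_k mu_k)^2.
mixture_pooled_sd <- function(spec) {
  w <- spec$weights
  mu <- spec$means
  dvar <- t(vapply(spec$covariances, diag, numeric(ncol(mu))))
  if (ncol(mu) == 1L) dvar <- matrix(dvar, ncol = 1L)
  ex <- colSums(w * mu)
  ex2 <- colSums(w * (dvar + mu^2))
  sqrt(pmax(ex2 - ex^2, 0))
}

#' Generate a seeded synthetic cohort with known anomalies
#'
#' @param spec a [cohort_spec].
#' @param seed integer seed; the whole cohort (anomaly placement, jitter,
#'   cell draws) is deterministic given `(spec, seed)`.
#' @return A list with `samples` (list of [flow_sample]s, subject ids
#'   `"S001"...`), `anomalous` (sorted indices of the injected anomalous
#'   subjects) and `pooled_sd` (analytic template marker SDs).
#' @export
gen_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  tpl <- spec$template
  pooled_sd <- mixture_pooled_sd(tpl)
  with_seed(seed, {
    p <- spec$n_subjects
    anomalous <- sort(sample.int(p, spec$n_anomalous))
    samples <- vector("list", p)
    for (i in seq_len(p)) {
      means_i <- tpl$means +
        matrix(stats::rnorm(length(tpl$means), sd = spec$jitter_sd),
               nrow(tpl$means), ncol(tpl$means))
      weights_i <- tpl$weights
      if (i %in% anomalous) {
        means_i[spec$anomaly_populations, spec$anomaly_markers] <-
          means_i[spec$anomaly_populations, spec$anomaly_markers] +
          spec$anomaly_shift * rep(pooled_sd[spec$anomaly_markers],
                                   each = length(spec$anomaly_populations))
        if (spec$anomaly_fraction_change != 0) {
          j <- spec$anomaly_populations[1L]
          weights_i[j] <- max(1e-3, weights_i[j] + spec$anomaly_fraction_change)
          weights_i <- weights_i / sum(weights_i)
        }
      }
      spec_i <- mixture_spec(means_i, covariances = tpl$covariances,
                             weights = weights_i,
                             n_cells = spec$cells_per_subject,
                             marker_names = tpl$marker_names)
      sid <- sprintf("S%03d", i)
      # inner draw uses the ambient (seeded) stream
      k <- nrow(spec_i$means)
      labels <- sample.int(k, spec_i$n_cells, replace = TRUE,
                           prob = spec_i$weights)
      x <- matrix(NA_real_, spec_i$n_cells, ncol(spec_i$means))
      for (jj in seq_len(k)) {
        idx <- which(labels == jj)
        if (length(idx) > 0L) {
          x[idx, ] <- MASS::mvrnorm(length(idx), spec_i$means[jj, ],
                                    spec_i$covariances[[jj]])
        }
      }
      samples[[i]] <- flow_sample(x, marker_names = spec_i$marker_names,
                                  sample_id = sid, subject_id = sid)
    }
    list(samples = samples, anomalous = anomalous, pooled_sd = pooled_sd)
  })
}
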