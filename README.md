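# cytoclust

Automated gating and cohort anomaly detection for flow cytometry data.

Flow cytometry measures a handful of fluorescence markers on each of
thousands of cells; identifying the cell populations in such a sample
("gating") is traditionally done by hand on biaxial plots, which is slow
and subjective. `cytoclust` automates it with a two-stage clustering
procedure and extends the same machinery to a cohort-level question:
given one sample per subject, which subjects have anomalous cellular
profiles?

## Method

**Stage 0 — how many clusters?** For a sample `X` (N cells × M markers),
the cells are projected onto each eigenvector of the sample covariance
matrix. On each projection a Gaussian-kernel density estimate is formed
with the oversmoothing bandwidth `h = (7/2) σ* N^(−1/3)` (`σ*` the
projection SD), and grid points where the density gradient is
significantly non-zero (plug-in standard error, two-sided Bonferroni
`α/(2G)` over the G grid points) are marked. Each significant
positive-to-negative gradient transition is one mode; the initial cluster
count `K` is the sum of mode counts over all eigenvectors (at least 1).
Summing over axes deliberately over-estimates the number of populations —
the merge stage removes the redundancy.

**Stage 1 — fuzzy C-means with Mahalanobis distance.** Cells are soft
assigned to `K` clusters by minimizing

    J_m = Σ_i Σ_j u_ij^m D(x_i, μ_j)²,   Σ_j u_ij = 1,

with fuzzifier `m = 2` and `D` the Mahalanobis distance
`√((x−μ_j) S_j⁻¹ (x−μ_j)ᵀ)` under each cluster's own covariance `S_j`
(re-estimated from the memberships every iteration and ridge-regularized,
so small or rare populations with singular covariances remain usable).

**Stage 2 — Markov-clustering merge.** A Gaussian similarity graph is
built over the `K` cluster centers and clustered with MCL (alternating
matrix expansion and element-wise inflation of the column-stochastic
flow matrix until it converges). Centers that land in the same MCL
segment are merged into one final population.

**Cohort anomaly detection.** All subjects are pooled and clustered once
with the two-stage procedure. Each subject is then summarized by, per
population, the median fluorescence intensity (MFI) of each marker over
the subject's cells in that population plus the percentage of the
subject's cells there. In the standardized feature space every subject
gets a local density `ρ_i = ω / Σ_{j∈ωNN} ‖s_i − s_j‖²` (with
`ω = round(0.15 P)`) and a distance `δ_i` to its nearest higher-density
subjects; anomalous subjects combine low `ρ` with high `δ`, so extreme
values of `δ_i/ρ_i` are flagged by an iterative outlier test on the log
ratios (distribution-free critical value by default; see
`?detect_anomalies`). The clustering F-measure of the original method
(class-size-weighted best-pair harmonic mean of precision and recall) is
included for evaluation against reference gates.

## Worked example

```r
library(cytoclust)

sim <- gen_mixture_sample(seven_population_spec(300), seed = 7)
sim$sample
#> flow_sample 'synthetic': 2100 cells x 2 markers (FL1, FL2)

res <- cluster_sample(sim$sample, seed = 7)
res$mode_result
#> mode_count_result: K = 7 (per-eigenvector modes: 4, 3)
res
#> cytoclust_result: K initial = 7 -> 7 final populations
#> population sizes: 290, 300, 318, 300, 317, 320, 255
f_measure(sim$labels, res$assignment$final_labels)
#> [1] 1
```

The mode counter found 4 + 3 significant density modes on the two
principal axes, fuzzy C-means produced seven clusters, and MCL kept them
separate: all seven simulated populations are recovered exactly
(F-measure 1 against the generating labels).

```r
coh <- gen_cohort(cohort_spec(), seed = 7)   # 150 subjects, 2 anomalous
rep <- run_anomaly_pipeline(coh$samples, seed = 7)
rep
#> anomaly_report: 150 subjects, 3 pooled populations (K initial = 8)
#> omega = 22, gamma = 1; flagged: S042, S103
coh$anomalous
#> [1]  42 103
```

The two subjects whose CD34/CD117 expression was shifted by 4 pooled SDs
in one population are exactly the two flagged; their `δ/ρ` ratios (970
and 607 here) dwarf the rest of the cohort (≤ 182).

A command-line interface wraps the same functions
(`inst/exec/cytoclust`): `simulate`, `cluster`, `evaluate` and `anomaly`
subcommands emit CSV labels, JSON reports and optional biaxial /
decision plots.

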