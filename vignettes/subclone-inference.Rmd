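---
title: "Inferring tumor subclonal architecture from variant allele frequencies"
author: "vbclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring tumor subclonal architecture from variant allele frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A bulk tumor sample is a mixture of cell populations: a founding clone
carrying the mutations of the tumor-initiating cell, and subclones that
acquired further mutations during expansion. For a heterozygous somatic SNV
in a copy-number-neutral region, the variant allele frequency (VAF) —
variant reads divided by total reads — is half the fraction of cells
carrying the mutation. Mutations private to one cell population therefore
aggregate at a common VAF, and the clonal architecture of the tumor can be
read off as clusters in VAF space, across one sample or jointly across
several (tumor/relapse pairs, multi-region biopsies).

`vbclone` clusters these VAFs with variational Bayesian mixture models,
infers how many populations the data support, assigns each variant to a
population probabilistically, and provides the surrounding arithmetic
(purity, expected VAFs under copy-number states, pseudo-VAFs for
copy-number events) and simulation harnesses for assessing resolution.

## The model

Each variant contributes a D-vector x of VAFs (one per sample), assumed
independent across samples *within* a cluster. Component k of the mixture
is a product of beta densities with shape parameters u_kd, v_kd; mixing
proportions carry a Dirichlet prior and each shape parameter a broad gamma
prior (shape 1 — an exponential — and rate 0.001, so the prior variance is
very large and the data determine the posterior). The beta likelihood has
no usable conjugate prior, so the variational posterior over the shape
parameters is kept in gamma form through a second-order Taylor lower bound
on the expected log beta normalizer; minimizing the Kullback–Leibler
divergence then yields closed-form updates:

* E step: responsibilities r_nk proportional to
  exp(E[log pi_k] + sum_d E[log Beta(x_nd; u_kd, v_kd)]), computed in log
  space with log-sum-exp; the Dirichlet expectation is digamma-based and
  the beta normalizer uses the Taylor bound.
* M step: Dirichlet concentrations c_k = c_0 + sum_n r_nk; gamma rates
  accumulate -sum_n r_nk log x_nd (and the mirror for v); gamma shapes are
  updated through the same bound, with the increment clamped at zero so
  parameters remain positive on any input.

Two conjugate alternatives plug into the same engine: a binomial mixture on
the read counts themselves (beta posterior per component; deeper sites
weigh more, which is the model's defining property) and a Gaussian mixture
on VAFs (Normal–Gamma per dimension, diagonal covariance — the same
within-cluster independence the beta model assumes; we do not provide a
full-covariance variant because every analysis in the package operates
under that factorization).

## Fitting procedure

1. k-means (`stats::kmeans`, 10 restarts, seeded) with a deliberately
   overestimated number of clusters (`init_k = 10`).
2. Prior initialization: each component's expected mean E[u]/(E[u]+E[v])
   is set to its k-means center. The total concentration E[u]+E[v] is set
   by method of moments from the member variance, **capped at the median
   read depth**: a beta over VAFs cannot be more concentrated than
   binomial counting noise, and k-means partitions of a single cluster
   underestimate its variance. Without the cap, duplicated components
   freeze side by side inside one cluster; with a fixed broad start
   instead, genuinely distinct clusters blur together before the shape
   updates tighten. One E step (expectations only) and one M step driven
   by the hard k-means labels complete initialization.
3. E/M iteration until the largest absolute change in any responsibility
   falls below `conv_eps = 1e-5` (safeguard `max_iter = 10000`; hitting it
   warns and marks the fit unconverged rather than failing).
4. Small-cluster pruning: components with fewer than max(3, 0.5% of N)
   hard-assigned variants are removed (a beta needs at least two points to
   fix its two degrees of freedom); the fit is warm-started from the
   surviving posterior and run to convergence again, iterating until
   stable. Warm starting rather than re-initializing keeps the surviving
   structure and is markedly faster.
5. Overlap pruning: cluster crispness is measured by the self-overlap
   S_k = sum_n r_nk^2 / sum_n r_nk (1 for crisp clusters, 0.5 for a
   component sharing all its variants 50/50). Components with
   S_k < kappa_1 / D are redundant; the single lowest-S offender is
   removed per pass, followed by a warm refit, until all survive. Removing
   one per pass avoids deleting both halves of one doubly-covered cluster.
6. Outlier detection (optional, on by default in `vaf_cluster()`): for
   each variant, a density-ordering p-value under its assigned cluster's
   posterior predictive — the probability that a predictive draw has lower
   density than the variant. Closed form for the 1-D Gaussian model
   (two-sided Student-t tail), Monte-Carlo elsewhere (10,000 seeded
   draws). Variants with p < 0.01 (uncorrected) are flagged and excluded
   from cluster sizes. A pre-filter restricts the integral to variants
   lying, in **every** sample, outside the narrowest interval holding
   99.9% of the posterior fluctuation of the cluster mean.

Components are reported sorted by descending mean VAF in sample 1.

## Choosing the overlap threshold

The calibration that fixes `kappa1` is shipped as `kappa_calibration()`:
random architectures (2–5 clusters, 1–3 dimensions, beta noise), one fit
per dataset, every candidate threshold evaluated by re-running the overlap
pruning and scoring label concordance (exact assignment matching). In our
sweep the one-dimensional mean concordance peaks on a plateau around
`kappa1` 0.80–0.85, while two- and three-dimensional results are
insensitive to the threshold over the whole candidate range (clusters
overlap less as dimensions are added). The default is `kappa1 = 0.85`,
applied as 0.85/D; it is exposed as `--overlap-threshold`.

## Boundary VAFs

Beta densities are undefined at 0 and 1, so boundary VAFs must be shifted
inward (`clamp_vafs()`, by machine precision). When read counts are
available the pipeline instead clamps to a half-read floor 0.5/(depth+1):
a VAF of 0 at depth n is only evidence that the true VAF is below ~1/n,
and representing it as 2.2e-16 places an atom some 30 log-units below the
continuous mass of a near-zero cluster. A beta component then specializes
on that atom — absorbing zero-count sites from *different* clusters — and
the true clusters merge. The half-read floor keeps zero-count sites
attached to their cluster's continuous mass. Pure-VAF input (no counts)
retains the machine-precision shift.

## The synthetic-data generator

`clonal_architecture()` + `generate()` draw component membership from the
mixing proportions and then either binomial variant counts at the
component mean (the realistic sequencing model; used by both presets and
the sweeps) or beta-distributed VAFs with concentration 200 (sd ≈ 0.035
at mean 0.5, approximating depth ≈ 190 counting spread). Two presets
encode the package's reference conditions:

* `MM-mimic` — one sample, 2018 variants, depth 188, three components at
  mean VAFs 0.461 / 0.320 / 0.119, proportions 0.60 / 0.25 / 0.15: a
  founding clone just below 0.5 (purity ≈ 0.92) plus two subclones.
* `AML-mimic` — tumor/relapse pair, 800 variants, depth 753, five
  components at (0.449, 0.413), (0.431, 0.116), (0.427, 0.003),
  (0.003, 0.328), (0.190, 0.003), proportions 0.30 / 0.22 / 0.18 / 0.15 /
  0.15: three populations indistinguishable in the tumor that separate at
  relapse, one relapse-specific population, one eradicated subclone.

Cluster proportions and the near-zero means are modeling choices (only the
cluster means, depths, sample counts and variant totals are anchored);
the generator draws exact binomial counts with no overdispersion, no
sequencing error, no mapping bias, and no correlation between sites. Real
capture data is noticeably overdispersed relative to binomial at these
depths, so resolution measured on these presets is a *best case*: passing
recovery tests here demonstrates the inference machinery, not performance
on any particular patient. The downsampling harness illustrates this
concretely — with pure binomial noise at depth 753 the five AML-mimic
clusters remain recoverable down to very small variant counts, whereas
overdispersed real data loses structure far earlier.

## Evaluation harnesses

* `concordance()` — maximal fraction of identically-assigned items over
  label relabelings; exact via dynamic programming on the assignment
  problem (cross-checked against exhaustive permutation in tests).
* `consensus_matrix()` — pairwise co-clustering frequency across runs
  (models x initial cluster counts).
* `downsample_sweep()` — surviving component count as a function of
  subsample size.
* `separation_sweep()` — two-cluster resolution, accuracy, and overlap
  (fraction of data within one SD of both clusters) as the inter-cluster
  distance varies.
* `simulation_suite()` / `kappa_calibration()` — random-architecture
  accuracy floor and threshold calibration.

Sweeps run with outlier detection disabled: outlier flags do not change
the surviving component count, and the Monte-Carlo predictive is the only
expensive step. The test suite runs the suite and sweeps at reduced
replication (3–5 replicates, subsets of the size/separation grids, n =
500 per dataset) to keep a full check fast; `scripts/acceptance.R` uses
the full grids with 10 replicates.

## Numerical choices and degenerate inputs

* All densities and responsibilities in log space; log-sum-exp
  normalization; row maxima via `max.col`.
* Gamma-shape update increments clamped at zero; shapes/rates floored at
  1e-10.
* k-means k is reduced to the number of distinct points when necessary
  (with a warning); empty k-means clusters are dropped before VB starts.
* Ties in hard assignment go to the lowest cluster index.
* A fit in which every component would be pruned raises an error
  (degenerate input); if every cluster fails the overlap threshold, the
  largest is kept with a warning.
* All stochastic steps (k-means restarts, Monte-Carlo predictive, the
  generator, sweeps) are seeded; a fixed seed reproduces assignments
  bit-for-bit.

## Limitations

* Sites in copy-number-altered or LOH regions are excluded, not modeled;
  phasing-based VAF adjustment is out of scope.
* Populations at similar frequencies in every sample cannot be separated
  by any marginal-VAF method; additional samples are the remedy.
* The binomial model is exactly depth-aware but assumes no
  overdispersion; on very deep data it tends to split boundary variants
  into extra components (the beta model is the default for this reason).
* Variant identity is (chromosome, position); multi-allelic sites are not
  handled specially.
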