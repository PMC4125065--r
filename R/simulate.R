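## Synthetic clonal-architecture generator and evaluation harnesses:
## concordance, consensus matrices, downsampling and separation sweeps,
## plus named presets mimicking a deeply sequenced multiple-myeloma genome
## (1 sample, 3 clusters) and an AML tumor/relapse pair (2 samples,
## 5 clusters).

#' Define a ground-truth clonal architecture
#'
#' @param means K x D matrix of component mean VAFs in (0,1).
#' @param proportions K-vector of mixing proportions (summing to 1).
#' @param depth Constant integer read depth, or a function(n) returning
#'   per-site depths.
#' @param noise `"binomial"` (variant counts drawn at the component mean;
#'   the realistic sequencing model) or `"beta"` (VAFs drawn from a beta at
#'   the component mean with concentration `beta_conc`).
#' @param beta_conc Beta-noise concentration (default 200, sd about 0.035
#'   at mean 0.5, approximating depth ~190 binomial spread).
#' @return Object of class `clonal_architecture`.
#' @export
clonal_architecture <- function(means, proportions,
                                depth = 100, noise = c("binomial", "beta"),
                                beta_conc = 200) {
  means <- as.matrix(means)
  noise <- match.arg(noise)
  stopifnot(nrow(means) == length(proportions),
            abs(sum(proportions) - 1) < 1e-8,
            all(means > 0 & means < 1), all(proportions > 0))
  structure(list(K = nrow(means), D = ncol(means), means = means,
                 proportions = proportions, depth = depth, noise = noise,
                 beta_conc = beta_conc),
            class = "clonal_architecture")
}

#' Named simulation presets
#'
#' `"MM-mimic"`: one sample, 2018 variants at constant depth 188 with three
#' components at mean VAFs 0.461 / 0.320 / 0.119 (founding clone plus two
#' subclones of a hyperdiploid multiple-myeloma genome, restricted to its
#' copy-number-neutral regions). `"AML-mimic"`: tumor/relapse pair, 800
#' variants at constant depth 753 with five components whose (tumor,
#' relapse) means are (0.449, 0.413), (0.431, 0.116), (0.427, 0.003),
#' (0.003, 0.328), (0.190, 0.003): three populations overlapping near VAF
#' 0.43 in the tumor that separate at relapse, one relapse-specific
#' cluster, and one chemotherapy-eradicated subclone.
#'
#' @param name `"MM-mimic"` or `"AML-mimic"`.
#' @return List with the `clonal_architecture` (`arch`) and the preset's
#'   variant count `n`.
#' @export
preset <- function(name) {
  switch(name,
    "MM-mimic" = list(
      arch = clonal_architecture(
        means = matrix(c(0.461, 0.320, 0.119), ncol = 1),
        proportions = c(0.60, 0.25, 0.15),
        depth = 188, noise = "binomial"),
      n = 2018),
    "AML-mimic" = list(
      arch = clonal_architecture(
        means = matrix(c(0.449, 0.413,
                         0.431, 0.116,
                         0.427, 0.003,
                         0.003, 0.328,
                         0.190, 0.003), ncol = 2, byrow = TRUE),
        proportions = c(0.30, 0.22, 0.18, 0.15, 0.15),
        depth = 753, noise = "binomial"),
      n = 800),
    stop("unknown preset '", name, "'; available: MM-mimic, AML-mimic")
  )
}

#' Generate a synthetic VAF dataset
#'
#' Component membership is drawn from the architecture's proportions; under
#' binomial noise each site/sample receives a depth and variant counts
#' binomial at the component mean; under beta noise VAFs are drawn from a
#' beta parameterized by mean and concentration. Deterministic given seed.
#'
#' @param arch A [clonal_architecture()].
#' @param n Total number of variants.
#' @param seed Integer seed.
#' @return List of class `simulated_dataset`: `vafs` (n x D), `var_counts`
#'   and `ref_counts` (binomial noise only), `labels`, `arch`, `seed`.
#' @export
generate <- function(arch, n, seed = 1) {
  stopifnot(inherits(arch, "clonal_architecture"), n >= arch$K)
  set.seed(seed)
  z <- sample.int(arch$K, n, replace = TRUE, prob = arch$proportions)
  d <- arch$D
  mu <- arch$means[z, , drop = FALSE]
  if (arch$noise == "binomial") {
    depth <- if (is.function(arch$depth))
      matrix(arch$depth(n * d), n, d) else matrix(arch$depth, n, d)
    v <- matrix(stats::rbinom(n * d, size = depth, prob = mu), n, d)
    vafs <- v / depth
    ds <- list(vafs = vafs, var_counts = v, ref_counts = depth - v,
               labels = z, arch = arch, seed = seed)
  } else {
    conc <- arch$beta_conc
    vafs <- matrix(stats::rbeta(n * d, shape1 = mu * conc,
                                shape2 = (1 - mu) * conc), n, d)
    ds <- list(vafs = vafs, var_counts = NULL, ref_counts = NULL,
               labels = z, arch = arch, seed = seed)
  }
  structure(ds, class = "simulated_dataset")
}

## ---- concordance -------------------------------------------------------

## Exact maximum-weight injective assignment of the smaller label set into
## the larger, by dynamic programming over column subsets. M is the
## contingency matrix with nrow(M) <= ncol(M); returns the maximum total.
assignment_max <- function(m) {
  a <- nrow(m); b <- ncol(m)
  stopifnot(a <= b, b <= 20)
  dp <- rep(-Inf, bitwShiftL(1L, b))
  dp[1] <- 0
  pop <- integer(length(dp))
  for (s in seq_len(length(dp) - 1))
    pop[s + 1] <- pop[bitwShiftR(s, 1) + 1] + bitwAnd(s, 1L)
  for (s in 0:(length(dp) - 2)) {
    i <- pop[s + 1]
    if (i >= a || !is.finite(dp[s + 1])) next
    for (j in 0:(b - 1)) {
      bit <- bitwShiftL(1L, j)
      if (bitwAnd(s, bit) == 0) {
        t <- bitwOr(s, bit)
        val <- dp[s + 1] + m[i + 1, j + 1]
        if (val > dp[t + 1]) dp[t + 1] <- val
      }
    }
  }
  max(dp[pop == a])
}

#' Label concordance between two clusterings
#'
#' The maximal fraction of items assigned to the same cluster, over all
#' injective relabelings of one clustering onto the other; exact (dynamic
#' programming over the assignment problem). Equals 1 iff the predicted
#' labeling is a relabeling of the truth.
#'
#' @param true_labels,predicted_labels Equal-length integer vectors.
#' @return Fraction in \[0,1\].
#' @export
concordance <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors must have equal length")
  tab <- table(true_labels, predicted_labels)
  m <- matrix(as.numeric(tab), nrow(tab), ncol(tab))
  if (nrow(m) > ncol(m)) m <- t(m)
  assignment_max(m) / length(true_labels)
}

## ---- harnesses ---------------------------------------------------------

#' Consensus co-clustering matrix across runs
#'
#' Entry (i, j) is the fraction of runs in which variants i and j received
#' the same hard cluster; symmetric with unit diagonal.
#'
#' @param dataset A `simulated_dataset` (or any list with `vafs` and,
#'   for binomial configs, `var_counts`/`ref_counts`).
#' @param configs List of `list(model =, init_k =)` specifications (>= 2).
#' @param seed Seed shared by all runs' initializations.
#' @param kappa1 Overlap-pruning threshold passed to the pipeline.
#' @return N x N numeric matrix.
#' @export
consensus_matrix <- function(dataset, configs, seed = 1, kappa1 = 0.85) {
  stopifnot(length(configs) >= 2)
  n <- nrow(dataset$vafs)
  acc <- matrix(0, n, n)
  for (cf in configs) {
    fit <- vaf_cluster(vafs = dataset$vafs,
                       var_counts = dataset$var_counts,
                       ref_counts = dataset$ref_counts,
                       config = engine_config(init_k = cf$init_k,
                                              model = cf$model, seed = seed),
                       kappa1 = kappa1, outlier_detection = FALSE)
    same <- outer(fit$assignments, fit$assignments, `==`)
    acc <- acc + same
  }
  acc / length(configs)
}

#' Downsampling sweep: inferred cluster count versus variant count
#'
#' Randomly subsamples the dataset without replacement at each size, fits
#' the beta model through the full pipeline, and records the surviving
#' component count.
#'
#' @param dataset A `simulated_dataset`.
#' @param sizes Subsample sizes (sizes below 2 are skipped with a warning).
#' @param replicates Replicates per size.
#' @param seed Base seed; replicate r of size index s uses
#'   `seed + 97 * s + r`.
#' @param init_k Initial component count for each fit.
#' @return List with `table` (size, replicate, K) and `summary`
#'   (size, mean_K, sd_K, modal_K).
#' @export
downsample_sweep <- function(dataset, sizes, replicates = 10, seed = 1,
                             init_k = 10) {
  n <- nrow(dataset$vafs)
  bad <- sizes < 2
  if (any(bad)) {
    warning("skipping sizes below 2: ", paste(sizes[bad], collapse = ", "))
    sizes <- sizes[!bad]
  }
  sizes <- pmin(sizes, n)
  rows <- list()
  for (s in seq_along(sizes)) {
    for (r in seq_len(replicates)) {
      rs <- seed + 97L * s + r
      set.seed(rs)
      idx <- sample.int(n, sizes[s])
      sub <- function(m) if (is.null(m)) NULL else m[idx, , drop = FALSE]
      fit <- vaf_cluster(vafs = dataset$vafs[idx, , drop = FALSE],
                         var_counts = sub(dataset$var_counts),
                         ref_counts = sub(dataset$ref_counts),
                         config = engine_config(init_k = init_k, seed = rs),
                         outlier_detection = FALSE)
      rows[[length(rows) + 1]] <-
        data.frame(size = sizes[s], replicate = r, K = fit$K)
    }
  }
  tab <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(tab, tab$size), function(g)
    data.frame(size = g$size[1], mean_K = mean(g$K), sd_K = stats::sd(g$K),
               modal_K = modal_value(g$K))))
  rownames(summ) <- NULL
  list(table = tab, summary = summ[order(summ$size), ])
}

#' Random-architecture accuracy suite
#'
#' Generates datasets from random clonal architectures (beta noise) in one
#' to three dimensions with two to five clusters, fits the beta model, and
#' records the label concordance. Component mean vectors are rejection
#' sampled in \[0.1, 0.9\] so every pair of components differs by at least
#' `min_sep` in some dimension (distinct subclones at or beyond the
#' method's resolvability limit); proportions are drawn from a symmetric
#' Dirichlet(5).
#'
#' @param dims Dimensionalities to test.
#' @param ks Cluster counts to test.
#' @param reps Datasets per (dimension, K) pair.
#' @param n Variants per dataset.
#' @param beta_conc Beta-noise concentration.
#' @param min_sep Minimum per-pair mean separation (some dimension).
#' @param seed Base seed.
#' @return List with `table` (dimension, K, replicate, true K, inferred K,
#'   concordance) and `summary` (mean concordance per dimension).
#' @export
simulation_suite <- function(dims = 1:3, ks = 2:5, reps = 10, n = 500,
                             beta_conc = 200, min_sep = 0.08, seed = 1) {
  rows <- list()
  for (d in dims) for (k in ks) for (r in seq_len(reps)) {
    rs <- seed + 7919L * d + 613L * k + r
    set.seed(rs)
    means <- random_separated_means(k, d, min_sep)
    props <- stats::rgamma(k, 5); props <- props / sum(props)
    arch <- clonal_architecture(means, props, noise = "beta",
                                beta_conc = beta_conc)
    ds <- generate(arch, n, seed = rs)
    fit <- vaf_cluster(vafs = ds$vafs,
                       config = engine_config(seed = rs),
                       outlier_detection = FALSE)
    rows[[length(rows) + 1]] <-
      data.frame(dimension = d, K = k, replicate = r, inferred_K = fit$K,
                 concordance = concordance(ds$labels, fit$assignments))
  }
  tab <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(tab, tab$dimension), function(g)
    data.frame(dimension = g$dimension[1],
               mean_concordance = mean(g$concordance),
               mean_K_error = mean(g$inferred_K - g$K))))
  rownames(summ) <- NULL
  list(table = tab, summary = summ)
}

#' Calibrate the self-overlap pruning threshold by simulation
#'
#' Reproduces the calibration of the overlap threshold kappa: random
#' architectures are generated as in [simulation_suite()], each dataset is
#' fit once, and every candidate one-dimensional threshold `kappa1`
#' (applied as kappa1 / d) is evaluated by re-running the overlap pruning
#' from the converged fit and scoring label concordance.
#'
#' @inheritParams simulation_suite
#' @param kappas Candidate `kappa1` values.
#' @return List with `table` (dimension, K, replicate, kappa1, inferred K,
#'   concordance) and `summary` (mean concordance per dimension x kappa1).
#' @export
kappa_calibration <- function(kappas = seq(0.5, 0.95, by = 0.05),
                              dims = 1:3, ks = 2:5, reps = 5, n = 500,
                              beta_conc = 200, min_sep = 0.08, seed = 1) {
  rows <- list()
  for (d in dims) for (k in ks) for (r in seq_len(reps)) {
    rs <- seed + 7919L * d + 613L * k + r
    set.seed(rs)
    means <- random_separated_means(k, d, min_sep)
    props <- stats::rgamma(k, 5); props <- props / sum(props)
    arch <- clonal_architecture(means, props, noise = "beta",
                                beta_conc = beta_conc)
    ds <- generate(arch, n, seed = rs)
    base <- suppressWarnings(vb_fit(ds$vafs, engine_config(seed = rs)))
    for (kp in kappas) {
      fit <- suppressWarnings(prune_overlapping(base, kappa1 = kp))
      rows[[length(rows) + 1]] <-
        data.frame(dimension = d, K = k, replicate = r, kappa1 = kp,
                   inferred_K = fit$K,
                   concordance = concordance(ds$labels, fit$assignments))
    }
  }
  tab <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(
    split(tab, list(tab$dimension, tab$kappa1)), function(g)
      data.frame(dimension = g$dimension[1], kappa1 = g$kappa1[1],
                 mean_concordance = mean(g$concordance))))
  rownames(summ) <- NULL
  list(table = tab, summary = summ[order(summ$dimension, summ$kappa1), ])
}

## Rejection-sample K mean vectors in [0.1, 0.9]^d with every pair at least
## min_sep apart in some dimension.
random_separated_means <- function(k, d, min_sep) {
  repeat {
    m <- matrix(stats::runif(k * d, 0.1, 0.9), k, d)
    ok <- TRUE
    if (k > 1) for (i in 1:(k - 1)) for (j in (i + 1):k)
      if (max(abs(m[i, ] - m[j, ])) < min_sep) ok <- FALSE
    if (ok) return(m)
  }
}

#' Separation sweep: resolvability of two clusters versus their distance
#'
#' Generates two-component one-dimensional datasets (equal proportions,
#' binomial noise at `depth`) with means `base_mean` and
#' `base_mean + separation`, fits the beta model, and records whether two
#' clusters survive, the assignment accuracy (concordance), and the overlap
#' (fraction of the data within one standard deviation of both clusters).
#'
#' @param base_mean Lower cluster mean VAF.
#' @param separations Positive separations to test
#'   (`base_mean + max(separations)` must stay below 1).
#' @param n_per_cluster Variants per cluster.
#' @param depth Constant read depth.
#' @param replicates Replicates per separation.
#' @param seed Base seed; replicate r of separation index s uses
#'   `seed + 131 * s + r`.
#' @param init_k Initial component count for each fit.
#' @return List with `table` (separation, replicate, resolved, accuracy,
#'   overlap) and `summary` (per-separation means and the fraction of
#'   replicates resolved with accuracy >= 0.95).
#' @export
separation_sweep <- function(base_mean, separations, n_per_cluster = 150,
                             depth = 753, replicates = 10, seed = 1,
                             init_k = 10) {
  stopifnot(all(separations > 0), base_mean + max(separations) < 1)
  rows <- list()
  for (s in seq_along(separations)) {
    sep <- separations[s]
    arch <- clonal_architecture(
      means = matrix(c(base_mean, base_mean + sep), ncol = 1),
      proportions = c(0.5, 0.5), depth = depth, noise = "binomial")
    for (r in seq_len(replicates)) {
      rs <- seed + 131L * s + r
      ds <- generate(arch, 2L * n_per_cluster, seed = rs)
      fit <- vaf_cluster(vafs = ds$vafs,
                         var_counts = ds$var_counts, ref_counts = ds$ref_counts,
                         config = engine_config(init_k = init_k, seed = rs),
                         outlier_detection = FALSE)
      acc <- concordance(ds$labels, fit$assignments)
      ## overlap: within one empirical SD of both true clusters
      sd1 <- stats::sd(ds$vafs[ds$labels == 1, 1])
      sd2 <- stats::sd(ds$vafs[ds$labels == 2, 1])
      in1 <- abs(ds$vafs[, 1] - base_mean) <= sd1
      in2 <- abs(ds$vafs[, 1] - (base_mean + sep)) <= sd2
      rows[[length(rows) + 1]] <-
        data.frame(separation = sep, replicate = r, K = fit$K,
                   resolved = fit$K == 2, accuracy = acc,
                   overlap = mean(in1 & in2))
    }
  }
  tab <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(tab, tab$separation), function(g)
    data.frame(separation = g$separation[1], mean_K = mean(g$K),
               mean_accuracy = mean(g$accuracy),
               mean_overlap = mean(g$overlap),
               frac_resolved = mean(g$resolved & g$accuracy >= 0.95))))
  rownames(summ) <- NULL
  list(table = tab, summary = summ[order(summ$separation), ])
}
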