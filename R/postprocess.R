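## Convert a converged fit into biological output: hard/probabilistic
## assignments, self-overlap cluster removal, posterior-predictive
## densities, outlier p-values, and cluster summaries.

#' Hard cluster assignments from responsibilities
#'
#' `label_n = argmax_k r_nk`; ties are broken toward the lowest component
#' index.
#'
#' @param responsibilities N x K matrix with rows summing to 1.
#' @return Integer vector of labels in 1..K.
#' @export
hard_assign <- function(responsibilities) {
  max.col(responsibilities, ties.method = "first")
}

#' Cluster self-overlap
#'
#' S_k = sum_n r_nk^2 / sum_n r_nk: the responsibility-weighted overlap of a
#' cluster with itself, relative to its "size" sum_n r_nk. Crisp clusters
#' (all r_nk in \{0,1\}) score 1; a cluster that shares all its variants
#' 50/50 with another scores 0.5. A zero-mass cluster returns 0 (prunable).
#'
#' @param responsibilities N x K responsibility matrix.
#' @param k Component index (omit for all components).
#' @return Self-overlap value(s) in \[0,1\].
#' @export
self_overlap <- function(responsibilities, k = NULL) {
  num <- colSums(responsibilities^2)
  den <- colSums(responsibilities)
  s <- ifelse(den > 0, num / den, 0)
  if (is.null(k)) s else s[k]
}

#' Remove overlapping (redundant) clusters
#'
#' Clusters must be well separated to be called distinct subclones. Any
#' cluster whose self-overlap S_k falls below the dimensionality-dependent
#' threshold kappa_d = kappa_1 / d is redundant with its neighbours; the
#' single lowest-S offender is removed, the model is refit (warm start) and
#' the check repeats until all survivors pass. Removing one cluster per pass
#' (rather than all offenders at once) prevents deleting both halves of one
#' doubly-covered blob, which would lose a genuine cluster.
#'
#' @param fit A `vaf_fit`.
#' @param kappa1 One-dimensional threshold; the applied threshold scales
#'   inversely with the number of samples. The default 0.85 sits in the
#'   concordance-optimal range found by the [kappa_calibration()]
#'   simulation sweep (one-dimensional accuracy peaks for kappa1 near
#'   0.80-0.85 and higher dimensions are insensitive).
#' @return The updated `vaf_fit` (with `overlap_pruned` history attached).
#' @export
prune_overlapping <- function(fit, kappa1 = 0.85) {
  d <- ncol(fit$means)
  kappa <- kappa1 / d
  cfg <- fit$config
  mf <- model_funs(cfg$model)
  hyper <- if (is.null(cfg$hyper)) mf$default_hyper() else cfg$hyper
  removed <- list()
  repeat {
    s <- self_overlap(fit$r)
    low <- which(s < kappa)
    if (length(low) == 0) break
    if (length(low) == fit$K) {
      warning("every cluster falls below the overlap threshold; keeping the largest")
      keep <- which.max(tabulate(fit$assignments, fit$K))
      fit <- subset_fit(fit, keep)
      break
    }
    worst <- low[which.min(s[low])]
    removed <- c(removed, list(c(cluster = worst, S = s[worst])))
    fit <- subset_fit(fit, setdiff(seq_len(fit$K), worst))
    res <- vb_iterate(fit$data, fit$posterior, hyper, cfg, r_start = fit$r)
    fit <- build_fit(res, fit$data, cfg, mf,
                     fit$n_iter + res$iter, fit$pruning_history)
    pr <- prune_small_clusters(fit, fit$data$n)
    fit <- pr$fit
  }
  fit$overlap_pruned <- removed
  finalize_fit(fit)
}

## ---- posterior predictive ----------------------------------------------

## Monte-Carlo parameter draws for the beta predictive, cached per cluster.
beta_param_draws <- function(fit, k, n_param_draws = 1000, seed = NULL) {
  sample_beta_posterior(fit$posterior, k, n_param_draws, seed)
}

## Density of points under the cluster-k posterior predictive.
## x: matrix (rows = points, cols = dimensions); for the binomial model x
## holds variant counts and `depth` the total counts.
predictive_density_k <- function(fit, k, x, depth = NULL,
                                 n_param_draws = 1000, seed = NULL,
                                 param_draws = NULL) {
  x <- as.matrix(x)
  post <- fit$posterior
  d <- ncol(fit$means)
  switch(fit$config$model,
    beta = {
      pd <- if (is.null(param_draws))
        beta_param_draws(fit, k, n_param_draws, seed) else param_draws
      m <- nrow(pd$u)
      dens <- numeric(nrow(x))
      lx <- log(clamp_unit(x)); l1mx <- log1p(-clamp_unit(x))
      ## average over parameter draws in density space, computed in log space
      ## per draw: log f_s(x_i) = sum_d dbeta components
      lf <- matrix(0, nrow(x), m)
      for (j in seq_len(d)) {
        lf <- lf + outer(lx[, j], pd$u[, j] - 1) +
          outer(l1mx[, j], pd$v[, j] - 1) +
          matrix(lgamma(pd$u[, j] + pd$v[, j]) - lgamma(pd$u[, j]) -
                   lgamma(pd$v[, j]), nrow(x), m, byrow = TRUE)
      }
      mx <- row_max(lf)
      dens <- exp(mx) * rowMeans(exp(lf - mx))
      dens
    },
    gaussian = {
      ## product over dimensions of Student-t predictives
      dens <- rep(1, nrow(x))
      for (j in seq_len(d)) {
        st <- gauss_predictive_t(post, k, j)
        dens <- dens * stats::dt((x[, j] - st$loc) / st$scale, df = st$df) / st$scale
      }
      dens
    },
    binomial = {
      stopifnot(!is.null(depth))
      depth <- as.matrix(depth)
      dens <- rep(1, nrow(x))
      for (j in seq_len(d))
        dens <- dens * dbetabinom(x[, j], depth[, j], post$a[k, j], post$b[k, j])
      dens
    })
}

## Student-t parameters of the Gaussian Normal-Gamma predictive for
## component k, dimension j: location m, scale sqrt(b(beta+1)/(a beta)),
## df 2a.
gauss_predictive_t <- function(post, k, j) {
  a <- post$a[k, j]; b <- post$b[k, j]; beta <- post$beta[k]
  list(loc = post$m[k, j], scale = sqrt(b * (beta + 1) / (a * beta)), df = 2 * a)
}

## Beta-binomial pmf (posterior predictive of the binomial component).
dbetabinom <- function(v, n, a, b, log = FALSE) {
  lp <- lchoose(n, v) + lbeta(a + v, b + n - v) - lbeta(a, b)
  if (log) lp else exp(lp)
}

## Draw observations from the cluster-k posterior predictive.
sample_predictive_k <- function(fit, k, n_draws, seed = NULL, depth = NULL) {
  if (!is.null(seed)) set.seed(seed)
  post <- fit$posterior
  d <- ncol(fit$means)
  switch(fit$config$model,
    beta = {
      pd <- sample_beta_posterior(fit$posterior, k, n_draws)
      matrix(stats::rbeta(n_draws * d, pd$u, pd$v), n_draws, d)
    },
    gaussian = {
      y <- matrix(0, n_draws, d)
      for (j in seq_len(d)) {
        st <- gauss_predictive_t(post, k, j)
        y[, j] <- st$loc + st$scale * stats::rt(n_draws, df = st$df)
      }
      y
    },
    binomial = {
      stopifnot(!is.null(depth))
      y <- matrix(0, n_draws, d)
      for (j in seq_len(d)) {
        p <- stats::rbeta(n_draws, post$a[k, j], post$b[k, j])
        y[, j] <- stats::rbinom(n_draws, size = depth[j], prob = p)
      }
      y
    })
}

#' Posterior predictive density
#'
#' Density of new observations under the converged model: per cluster and
#' weighted by the mixing expectations E\[pi_k\]. Closed form for the
#' Gaussian (Student-t) and binomial (beta-binomial) models; Monte-Carlo
#' integration over the gamma parameter posteriors for the beta model.
#'
#' @param fit A `vaf_fit`.
#' @param x Points at which to evaluate: vector (1-D) or matrix with one
#'   column per sample. For the binomial model, variant counts.
#' @param depth Total read counts per point/dimension (binomial model only).
#' @param n_param_draws Monte-Carlo parameter draws (beta model).
#' @param seed Seed for the Monte-Carlo draws.
#' @return List with `per_cluster` (N x K density matrix) and `total`
#'   (E\[pi\]-weighted sum).
#' @export
posterior_predictive <- function(fit, x, depth = NULL,
                                 n_param_draws = 1000, seed = 1) {
  x <- if (is.null(dim(x))) matrix(x, ncol = ncol(fit$means)) else as.matrix(x)
  per <- sapply(seq_len(fit$K), function(k)
    predictive_density_k(fit, k, x, depth = depth,
                         n_param_draws = n_param_draws,
                         seed = if (is.null(seed)) NULL else seed + k))
  per <- matrix(per, nrow = nrow(x))
  list(per_cluster = per, total = as.numeric(per %*% fit$pi))
}

## ---- outlier detection -------------------------------------------------

## Shortest interval containing `mass` of the posterior fluctuation of the
## cluster-k mean, per dimension. Monte-Carlo for beta; analytic (symmetric,
## hence equal-tailed) for the Gaussian; exact beta quantile search for the
## binomial.
posterior_mean_interval <- function(fit, k, mass = 0.999, n_draws = 4000,
                                    seed = 1) {
  post <- fit$posterior
  d <- ncol(fit$means)
  out <- matrix(0, d, 2, dimnames = list(NULL, c("lo", "hi")))
  model <- fit$config$model
  if (model == "gaussian") {
    for (j in seq_len(d)) {
      a <- post$a[k, j]; b <- post$b[k, j]
      scale <- sqrt(b / (a * post$beta[k]))
      q <- stats::qt(1 - (1 - mass) / 2, df = 2 * a)
      out[j, ] <- post$m[k, j] + c(-1, 1) * q * scale
    }
    return(out)
  }
  if (!is.null(seed)) set.seed(seed + k)
  draws <- switch(model,
    beta = {
      pd <- sample_beta_posterior(fit$posterior, k, n_draws)
      pd$u / (pd$u + pd$v)
    },
    binomial = {
      matrix(stats::rbeta(n_draws * d, rep(post$a[k, ], each = n_draws),
                          rep(post$b[k, ], each = n_draws)), n_draws, d)
    })
  for (j in seq_len(d)) out[j, ] <- shortest_interval(draws[, j], mass)
  out
}

## Shortest window covering `mass` of a sample.
shortest_interval <- function(x, mass) {
  x <- sort(x)
  n <- length(x)
  w <- max(2, ceiling(mass * n))
  if (w >= n) return(c(x[1], x[n]))
  i <- which.min(x[(w):n] - x[1:(n - w + 1)])
  c(x[i], x[i + w - 1])
}

#' Outlier candidate pre-filter
#'
#' A variant is an outlier candidate only when, in EVERY sample dimension,
#' its VAF lies outside the narrowest interval containing `mass` of the
#' posterior fluctuation of its assigned cluster's mean. Only candidates
#' receive the (expensive) predictive p-value.
#'
#' @param fit A `vaf_fit`.
#' @param x VAF vector of one variant (length D).
#' @param k Assigned cluster.
#' @param mass Interval mass (default 0.999).
#' @param seed Seed for the Monte-Carlo interval.
#' @return Logical: is the variant a candidate?
#' @export
outlier_prefilter <- function(fit, x, k, mass = 0.999, seed = 1) {
  ci <- posterior_mean_interval(fit, k, mass = mass, seed = seed)
  all(x < ci[, "lo"] | x > ci[, "hi"])
}

#' Posterior-predictive outlier p-value
#'
#' Density-ordering tail probability of a variant under its assigned
#' cluster's posterior predictive: the probability that a draw y from the
#' predictive has density no larger than the density at x (the Heaviside
#' construction). Closed form for the one-dimensional Gaussian model
#' (two-sided Student-t tail); Monte-Carlo otherwise.
#'
#' @param fit A `vaf_fit`.
#' @param x VAF vector of the variant (length D); variant counts for the
#'   binomial model.
#' @param k Assigned cluster.
#' @param n_draws Predictive draws (>= 100).
#' @param seed Seed.
#' @param depth Read depths of the variant (binomial model).
#' @return p-value in \[0,1\].
#' @export
outlier_pvalue <- function(fit, x, k, n_draws = 10000, seed = 1, depth = NULL) {
  if (n_draws < 100) stop("n_draws must be at least 100 for a stable estimate")
  model <- fit$config$model
  if (model == "gaussian" && ncol(fit$means) == 1) {
    st <- gauss_predictive_t(fit$posterior, k, 1)
    return(2 * stats::pt(-abs(x[1] - st$loc) / st$scale, df = st$df))
  }
  pd <- if (model == "beta")
    beta_param_draws(fit, k, n_param_draws = 1000,
                     seed = if (is.null(seed)) NULL else seed + 7L) else NULL
  y <- sample_predictive_k(fit, k, n_draws, seed = seed, depth = depth)
  ydepth <- if (model == "binomial")
    matrix(depth, n_draws, length(depth), byrow = TRUE) else NULL
  fy <- predictive_density_k(fit, k, y, depth = ydepth, param_draws = pd,
                             seed = seed)
  fx <- predictive_density_k(fit, k, matrix(x, nrow = 1),
                             depth = if (is.null(depth)) NULL
                                     else matrix(depth, nrow = 1),
                             param_draws = pd, seed = seed)
  mean(fy <= fx)
}

#' Flag outlier variants in a converged fit
#'
#' Applies the pre-filter and then the predictive p-value to every variant;
#' variants with p below `alpha` (not corrected for multiple testing) are
#' flagged and removed from cluster membership counts.
#'
#' @param fit A `vaf_fit`.
#' @param alpha Significance threshold (default 0.01).
#' @param mass Pre-filter interval mass.
#' @param n_draws Predictive draws per assigned cluster.
#' @param seed Seed.
#' @return The fit with `outliers` (logical vector) and `outlier_pvalues`
#'   (NA for non-candidates) attached.
#' @export
detect_outliers <- function(fit, alpha = 0.01, mass = 0.999,
                            n_draws = 10000, seed = 1) {
  n <- nrow(fit$r)
  d <- ncol(fit$means)
  model <- fit$config$model
  pvals <- rep(NA_real_, n)
  intervals <- lapply(seq_len(fit$K), posterior_mean_interval, fit = fit,
                      mass = mass, seed = seed)
  ## precompute predictive machinery per cluster, score candidates in bulk
  for (k in seq_len(fit$K)) {
    idx <- which(fit$assignments == k)
    if (length(idx) == 0) next
    xk <- fit$data$x[idx, , drop = FALSE]
    ci <- intervals[[k]]
    cand <- idx[rowSums(sweep(xk, 2, ci[, "lo"], `<`) |
                        sweep(xk, 2, ci[, "hi"], `>`)) == d]
    if (length(cand) == 0) next
    if (model == "binomial") {
      for (i in cand)
        pvals[i] <- outlier_pvalue(fit, fit$data$var_counts[i, ], k,
                                   n_draws = n_draws, seed = seed + k,
                                   depth = fit$data$var_counts[i, ] +
                                     fit$data$ref_counts[i, ])
    } else {
      pd <- if (model == "beta")
        beta_param_draws(fit, k, 1000, seed = seed + 7L + k) else NULL
      y <- sample_predictive_k(fit, k, n_draws, seed = seed + k)
      fy <- predictive_density_k(fit, k, y, param_draws = pd, seed = seed + k)
      fx <- predictive_density_k(fit, k, fit$data$x[cand, , drop = FALSE],
                                 param_draws = pd, seed = seed + k)
      pvals[cand] <- sapply(fx, function(f) mean(fy <= f))
    }
  }
  fit$outlier_pvalues <- pvals
  fit$outliers <- !is.na(pvals) & pvals < alpha
  fit
}

## ---- summaries ---------------------------------------------------------

#' Per-cluster summary table
#'
#' @param fit A `vaf_fit` (optionally after [detect_outliers()]).
#' @return Data frame: cluster, size (hard-assigned, excluding outliers),
#'   per-sample mean and SD of member VAFs, mixing expectation, and
#'   self-overlap.
#' @export
cluster_summary <- function(fit) {
  d <- ncol(fit$means)
  out <- is_outlier(fit)
  s <- self_overlap(fit$r)
  rows <- lapply(seq_len(fit$K), function(k) {
    member <- fit$assignments == k & !out
    x <- fit$data$x[member, , drop = FALSE]
    df <- data.frame(cluster = k, size = sum(member))
    for (j in seq_len(d)) {
      df[[paste0("mean_vaf_s", j)]] <- if (nrow(x)) mean(x[, j]) else NA_real_
      df[[paste0("sd_vaf_s", j)]] <- if (nrow(x) > 1) stats::sd(x[, j]) else NA_real_
    }
    df$pi <- fit$pi[k]
    df$self_overlap <- s[k]
    df
  })
  do.call(rbind, rows)
}

is_outlier <- function(fit) {
  if (is.null(fit$outliers)) rep(FALSE, nrow(fit$r)) else fit$outliers
}

#' Per-variant assignment table
#'
#' @param fit A `vaf_fit`.
#' @param variants Optional data frame of variant metadata (chrom, pos, ...)
#'   with one row per clustered variant, prepended to the output.
#' @return Data frame: metadata, per-sample VAFs, hard cluster (NA for
#'   outliers), per-cluster posterior probabilities, outlier p-value.
#' @export
assignment_table <- function(fit, variants = NULL) {
  d <- ncol(fit$means)
  out <- is_outlier(fit)
  df <- data.frame(row.names = seq_len(nrow(fit$r)))
  if (!is.null(variants)) df <- cbind(df, variants)
  for (j in seq_len(d)) df[[paste0("vaf_s", j)]] <- fit$data$x[, j]
  df$cluster <- ifelse(out, NA_integer_, fit$assignments)
  for (k in seq_len(fit$K)) df[[paste0("prob_c", k)]] <- fit$r[, k]
  df$outlier_pvalue <- if (is.null(fit$outlier_pvalues)) NA_real_
                       else fit$outlier_pvalues
  df
}
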