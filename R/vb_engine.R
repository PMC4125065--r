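## Model-agnostic variational loop: k-means initialization, E/M iteration to
## convergence on responsibilities, small-cluster pruning with warm-started
## refit.

#' Engine configuration
#'
#' @param init_k Initial (over-estimated) number of components.
#' @param model One of `"beta"`, `"binomial"`, `"gaussian"`.
#' @param conv_eps Convergence threshold: maximum absolute change of any
#'   responsibility between consecutive iterations.
#' @param max_iter Iteration safeguard.
#' @param min_cluster_abs,min_cluster_frac A surviving component must have
#'   at least `max(min_cluster_abs, ceiling(min_cluster_frac * N))` hard
#'   assignments (at least two points are needed to fix the two degrees of
#'   freedom of a beta component; three adds margin).
#' @param seed Integer seed for k-means initialization.
#' @param hyper Optional model hyperparameter object; model defaults used
#'   when `NULL`.
#' @return An object of class `engine_config`.
#' @export
engine_config <- function(init_k = 10, model = c("beta", "binomial", "gaussian"),
                          conv_eps = 1e-5, max_iter = 10000,
                          min_cluster_abs = 3, min_cluster_frac = 0.005,
                          seed = 1, hyper = NULL) {
  model <- match.arg(model)
  stopifnot(init_k >= 1, conv_eps > 0, conv_eps < 1, max_iter >= 1,
            min_cluster_abs >= 2, min_cluster_frac >= 0)
  structure(list(init_k = init_k, model = model, conv_eps = conv_eps,
                 max_iter = max_iter, min_cluster_abs = min_cluster_abs,
                 min_cluster_frac = min_cluster_frac, seed = seed,
                 hyper = hyper),
            class = "engine_config")
}

#' Seeded k-means initialization
#'
#' Wraps `stats::kmeans` (10 restarts, 100 iterations) with deterministic
#' seeding and degenerate-input handling: k is reduced to the number of
#' distinct rows (with a warning when that is fewer than requested).
#'
#' @param vafs N x D matrix of clamped VAFs.
#' @param k Requested number of clusters.
#' @param seed Integer seed.
#' @return List with `labels` (1..k') and `centers` (k' x D).
#' @export
kmeans_init <- function(vafs, k, seed = 1) {
  vafs <- as.matrix(vafs)
  n_distinct <- nrow(unique(vafs))
  if (k > n_distinct) {
    warning("k reduced from ", k, " to ", n_distinct, " distinct points")
    k <- n_distinct
  }
  if (k == 1) {
    return(list(labels = rep(1L, nrow(vafs)),
                centers = matrix(colMeans(vafs), 1)))
  }
  set.seed(seed)
  km <- stats::kmeans(vafs, centers = k, nstart = 10, iter.max = 100)
  list(labels = km$cluster, centers = km$centers)
}

#' Responsibility convergence check
#'
#' @param r_prev,r_curr Same-shape responsibility matrices.
#' @param conv_eps Threshold.
#' @return TRUE iff `max(abs(r_curr - r_prev)) < conv_eps`.
#' @export
check_convergence <- function(r_prev, r_curr, conv_eps) {
  if (!all(dim(r_prev) == dim(r_curr))) stop("responsibility shape mismatch")
  max(abs(r_curr - r_prev)) < conv_eps
}

#' Remove under-populated components
#'
#' Drops every component whose hard-assigned count is below
#' `max(min_cluster_abs, ceiling(min_cluster_frac * n_total))` and
#' renormalizes the retained mixing expectations.
#'
#' @param fit A `vaf_fit`.
#' @param n_total Total number of variants N.
#' @return List with the updated `fit` and `removed` (sizes of dropped
#'   components).
#' @export
prune_small_clusters <- function(fit, n_total = nrow(fit$r)) {
  cfg <- fit$config
  thr <- max(cfg$min_cluster_abs, ceiling(cfg$min_cluster_frac * n_total))
  sizes <- tabulate(fit$assignments, nbins = fit$K)
  keep <- sizes >= thr
  if (all(keep)) return(list(fit = fit, removed = integer(0)))
  if (!any(keep)) stop("all components fall below the minimum cluster size")
  list(fit = subset_fit(fit, which(keep)), removed = sizes[!keep])
}

## Restrict a fit to a subset of components; responsibilities are dropped
## column-wise and renormalized, assignments recomputed.
subset_fit <- function(fit, keep) {
  mf <- model_funs(fit$config$model)
  fit$posterior <- mf$subset(fit$posterior, keep)
  r <- fit$r[, keep, drop = FALSE]
  fit$r <- r / rowSums(r)
  fit$K <- length(keep)
  fit$pi <- fit$posterior$conc / sum(fit$posterior$conc)
  fit$means <- mf$means(fit$posterior)
  fit$assignments <- hard_assign(fit$r)
  fit
}

## Core E/M loop from a given posterior until the responsibilities are
## stationary. Returns r, posterior, iterations used, converged flag.
vb_iterate <- function(data, posterior, hyper, cfg, r_start = NULL) {
  mf <- model_funs(cfg$model)
  r_prev <- if (is.null(r_start)) mf$estep(data, posterior) else r_start
  posterior <- mf$mstep(data, r_prev, hyper, posterior)
  converged <- FALSE
  iter <- 0L
  while (iter < cfg$max_iter) {
    iter <- iter + 1L
    r <- mf$estep(data, posterior)
    if (check_convergence(r_prev, r, cfg$conv_eps)) {
      converged <- TRUE
      r_prev <- r
      break
    }
    posterior <- mf$mstep(data, r, hyper, posterior)
    r_prev <- r
  }
  list(r = r_prev, posterior = posterior, iter = iter, converged = converged)
}

#' Fit a variational Bayesian mixture to VAFs or read counts
#'
#' Runs k-means initialization, the model-specific prior initialization (one
#' E step without a responsibility update, then one M step driven by the
#' hard k-means labels), then E/M iteration until the maximum absolute
#' responsibility change falls below `conv_eps`. Converged fits are pruned
#' of under-populated components; if any component is removed the loop is
#' warm-started from the surviving posterior and run again until no further
#' removal occurs. Components are reported sorted by descending mean VAF in
#' sample 1 (ties broken by later samples).
#'
#' @param vafs N x D matrix of VAFs (beta/gaussian models); may be `NULL`
#'   for the binomial model.
#' @param config An [engine_config()].
#' @param var_counts,ref_counts N x D integer count matrices (required for
#'   the binomial model; optional otherwise).
#' @return An object of class `vaf_fit`: responsibilities `r`, `posterior`,
#'   mixing expectations `pi`, component `means`, hard `assignments`,
#'   iteration count, `converged` flag, and `pruning_history`.
#' @export
vb_fit <- function(vafs = NULL, config = engine_config(),
                   var_counts = NULL, ref_counts = NULL) {
  if (config$model == "binomial" && (is.null(var_counts) || is.null(ref_counts)))
    stop("binomial model requires var_counts and ref_counts")
  data <- prepare_vaf_data(x = vafs, var_counts = var_counts,
                           ref_counts = ref_counts)
  if (data$n < 2) stop("need at least two variants to cluster")
  mf <- model_funs(config$model)
  hyper <- if (is.null(config$hyper)) mf$default_hyper() else config$hyper
  km <- kmeans_init(data$x, config$init_k, config$seed)
  ## drop empty k-means clusters before VB starts
  used <- sort(unique(km$labels))
  labels <- match(km$labels, used)
  centers <- km$centers[used, , drop = FALSE]
  posterior <- mf$init(centers, hyper, data, labels)

  pruning_history <- list()
  res <- vb_iterate(data, posterior, hyper, cfg = config)
  total_iter <- res$iter
  repeat {
    fit <- build_fit(res, data, config, mf, total_iter, pruning_history)
    pr <- prune_small_clusters(fit, data$n)
    if (length(pr$removed) == 0) return(finalize_fit(pr$fit))
    pruning_history <- c(pruning_history,
                         list(list(iteration = total_iter, removed = pr$removed)))
    fit <- pr$fit
    res <- vb_iterate(data, fit$posterior, hyper, cfg = config, r_start = fit$r)
    total_iter <- total_iter + res$iter
  }
}

build_fit <- function(res, data, config, mf, total_iter, pruning_history) {
  if (!res$converged)
    warning("VB iteration did not converge within max_iter = ", config$max_iter)
  r <- res$r
  structure(list(r = r, posterior = res$posterior,
                 pi = res$posterior$conc / sum(res$posterior$conc),
                 means = mf$means(res$posterior),
                 assignments = hard_assign(r),
                 K = ncol(r), n_iter = total_iter, converged = res$converged,
                 pruning_history = pruning_history,
                 config = config, data = data, outliers = NULL),
            class = "vaf_fit")
}

## Sort components by descending mean in sample 1, ties by later samples.
finalize_fit <- function(fit) {
  ord <- do.call(order, c(lapply(seq_len(ncol(fit$means)),
                                 function(d) -fit$means[, d])))
  if (!identical(ord, seq_len(fit$K))) fit <- subset_fit(fit, ord)
  fit
}

#' @export
print.vaf_fit <- function(x, ...) {
  cat("Variational Bayesian", x$config$model, "mixture fit\n")
  cat(sprintf("  %d variants x %d sample(s); %d surviving component(s); %s after %d iterations\n",
              nrow(x$r), ncol(x$means), x$K,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  m <- round(x$means, 4)
  for (k in seq_len(x$K))
    cat(sprintf("  cluster %d: n = %d, pi = %.3f, mean VAF = %s\n",
                k, sum(x$assignments == k), x$pi[k],
                paste(m[k, ], collapse = ", ")))
  invisible(x)
}

#' Fit the binomial mixture model to read counts
#'
#' Convenience wrapper around [vb_fit()] with `model = "binomial"`.
#'
#' @param var_counts,ref_counts N x D integer count matrices.
#' @param config An [engine_config()]; its `model` field is overridden.
#' @return A `vaf_fit`.
#' @export
fit_binomial <- function(var_counts, ref_counts, config = engine_config()) {
  config$model <- "binomial"
  vb_fit(config = config, var_counts = var_counts, ref_counts = ref_counts)
}

#' Fit the Gaussian mixture model to VAFs
#'
#' Convenience wrapper around [vb_fit()] with `model = "gaussian"`.
#'
#' @param vafs N x D matrix of VAFs.
#' @param config An [engine_config()]; its `model` field is overridden.
#' @return A `vaf_fit`.
#' @export
fit_gaussian <- function(vafs, config = engine_config()) {
  config$model <- "gaussian"
  vb_fit(vafs = vafs, config = config)
}
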