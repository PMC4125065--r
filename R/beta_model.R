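## Variational Bayesian mixture of D-dimensional factorized beta components.
##
## Each component k has shape parameters u_kd, v_kd per sample dimension d.
## The (non-conjugate) prior over each shape parameter is a gamma
## distribution; the variational posterior retains gamma form through a
## second-order Taylor lower bound on E[log Beta normalizer].

#' Beta-model hyperparameters
#'
#' Prior specification for the variational beta mixture: a symmetric
#' Dirichlet over mixing proportions and independent gamma priors over every
#' beta shape parameter. With shape 1 the gamma priors collapse to
#' exponential distributions; the small default rate makes them broad, so the
#' number of clusters and their locations are determined by the data.
#'
#' @param dirichlet_conc Dirichlet concentration per component (c0).
#' @param gamma_shape_u,gamma_rate_u Gamma prior shape/rate for u.
#' @param gamma_shape_v,gamma_rate_v Gamma prior shape/rate for v.
#' @return An object of class `beta_hyperparams`.
#' @export
beta_hyperparams <- function(dirichlet_conc = 1,
                             gamma_shape_u = 1, gamma_rate_u = 0.001,
                             gamma_shape_v = 1, gamma_rate_v = 0.001) {
  stopifnot(dirichlet_conc > 0, gamma_shape_u > 0, gamma_rate_u > 0,
            gamma_shape_v > 0, gamma_rate_v > 0)
  structure(list(dirichlet_conc = dirichlet_conc,
                 gamma_shape_u = gamma_shape_u, gamma_rate_u = gamma_rate_u,
                 gamma_shape_v = gamma_shape_v, gamma_rate_v = gamma_rate_v),
            class = "beta_hyperparams")
}

## Construct a beta posterior object from K x D gamma parameter matrices and
## a length-K Dirichlet concentration vector.
new_beta_posterior <- function(u_shape, u_rate, v_shape, v_rate, conc, hyper) {
  stopifnot(all(u_shape > 0), all(u_rate > 0), all(v_shape > 0),
            all(v_rate > 0), all(conc > 0))
  structure(list(u_shape = u_shape, u_rate = u_rate,
                 v_shape = v_shape, v_rate = v_rate,
                 conc = conc, hyper = hyper),
            class = "beta_posterior")
}

## Expectations under the gamma variational posteriors.
## E[(log u - log E[u])^2] = trigamma(a) + (digamma(a) - log a)^2: the rate
## cancels, only the shape enters.
beta_post_expectations <- function(post) {
  a_u <- post$u_shape; a_v <- post$v_shape
  list(
    ubar   = post$u_shape / post$u_rate,
    vbar   = post$v_shape / post$v_rate,
    Elnu   = digamma(a_u) - log(post$u_rate),
    Elnv   = digamma(a_v) - log(post$v_rate),
    dlnu   = digamma(a_u) - log(a_u),             # E[log u] - log E[u]
    dlnv   = digamma(a_v) - log(a_v),
    d2lnu  = trigamma(a_u) + (digamma(a_u) - log(a_u))^2,
    d2lnv  = trigamma(a_v) + (digamma(a_v) - log(a_v))^2
  )
}

#' Expected component means of a beta posterior
#'
#' @param post A `beta_posterior`.
#' @return K x D matrix of E\[u\]/(E\[u\]+E\[v\]).
#' @export
beta_component_means <- function(post) {
  ub <- post$u_shape / post$u_rate
  vb <- post$v_shape / post$v_rate
  ub / (ub + vb)
}

#' Log density of one factorized beta component
#'
#' Sum over dimensions of `dbeta(x_d; u_d, v_d, log = TRUE)`; the
#' within-cluster independence assumption across samples.
#'
#' @param x VAF vector of length D, strictly inside (0,1).
#' @param u,v Positive shape-parameter vectors of length D.
#' @return Scalar log density.
#' @export
beta_component_logdensity <- function(x, u, v) {
  stopifnot(length(x) == length(u), length(u) == length(v),
            all(u > 0), all(v > 0))
  if (any(x <= 0 | x >= 1))
    stop("x must lie strictly inside (0, 1); clamp VAFs first")
  sum(stats::dbeta(x, u, v, log = TRUE))
}

## Second-order Taylor lower bound on E_q[log(Gamma(u+v)/(Gamma(u)Gamma(v)))]
## per component/dimension, evaluated at the posterior means. Returns a
## K x D matrix.
beta_logC_bound <- function(ex) {
  ub <- ex$ubar; vb <- ex$vbar
  s <- ub + vb
  lgamma(s) - lgamma(ub) - lgamma(vb) +
    ub * (digamma(s) - digamma(ub)) * ex$dlnu +
    vb * (digamma(s) - digamma(vb)) * ex$dlnv +
    0.5 * ub^2 * (trigamma(s) - trigamma(ub)) * ex$d2lnu +
    0.5 * vb^2 * (trigamma(s) - trigamma(vb)) * ex$d2lnv +
    ub * vb * trigamma(s) * ex$dlnu * ex$dlnv
}

#' Variational E step for the beta mixture
#'
#' Computes responsibilities r_nk proportional to
#' exp(E\[log pi_k\] + sum_d E\[log Beta(x_nd; u_kd, v_kd)\]), using the
#' digamma expectation for the Dirichlet term and the Taylor bound for the
#' beta normalizer; rows are normalized in log space (log-sum-exp).
#'
#' @param data List with elements `lx` (log VAFs, N x D) and `l1mx`
#'   (log(1 - VAF)); see [prepare_vaf_data()].
#' @param post A `beta_posterior`.
#' @return N x K responsibility matrix, rows summing to 1.
#' @export
e_step_beta <- function(data, post) {
  ex <- beta_post_expectations(post)
  lnC <- beta_logC_bound(ex)                       # K x D
  eln_pi <- digamma(post$conc) - digamma(sum(post$conc))
  ## N x K: constant_k + lx %*% t(ubar-1) + l1mx %*% t(vbar-1)
  lr <- sweep(data$lx %*% t(ex$ubar - 1) + data$l1mx %*% t(ex$vbar - 1),
              2, eln_pi + rowSums(lnC), `+`)
  normalize_log_rows(lr)
}

#' Variational M step for the beta mixture
#'
#' Updates the Dirichlet concentrations (prior plus responsibility mass) and
#' the gamma variational parameters of every shape parameter. The shape
#' updates use the current posterior expectations through the same Taylor
#' bound as the E step; the rate updates accumulate -sum_n r_nk log x_nd
#' (and the mirror for v). Shape increments are clamped at zero so the
#' parameters remain positive on any clamped input.
#'
#' @inheritParams e_step_beta
#' @param r N x K responsibility matrix (rows normalized).
#' @param hyper A `beta_hyperparams`.
#' @param post Current `beta_posterior` (supplies the expansion point).
#' @return Updated `beta_posterior`.
#' @export
m_step_beta <- function(data, r, hyper, post) {
  ex <- beta_post_expectations(post)
  ub <- ex$ubar; vb <- ex$vbar
  s <- ub + vb
  n_k <- colSums(r)
  conc <- hyper$dirichlet_conc + n_k
  ## data-independent bracket terms, K x D
  br_u <- digamma(s) - digamma(ub) + vb * trigamma(s) * ex$dlnv
  br_v <- digamma(s) - digamma(vb) + ub * trigamma(s) * ex$dlnu
  u_shape <- hyper$gamma_shape_u + n_k * ub * pmax(br_u, 0)
  v_shape <- hyper$gamma_shape_v + n_k * vb * pmax(br_v, 0)
  u_rate <- hyper$gamma_rate_u - t(r) %*% data$lx    # lx <= 0
  v_rate <- hyper$gamma_rate_v - t(r) %*% data$l1mx
  new_beta_posterior(pmax(u_shape, 1e-10), pmax(u_rate, 1e-10),
                     pmax(v_shape, 1e-10), pmax(v_rate, 1e-10),
                     conc, hyper)
}

#' Initialize the beta posterior from k-means centers
#'
#' Sets the gamma variational parameters so every component's expected mean
#' E\[u\]/(E\[u\]+E\[v\]) equals its k-means center, with the total
#' concentration E\[u\] + E\[v\] taken from a method-of-moments beta fit to
#' the component's hard-assigned members (so the initial components match
#' both the location and the spread of their k-means clusters; a too-broad
#' start lets adjacent clusters blur together before the shape updates
#' tighten). Dirichlet concentrations start at the prior. Then one E step is
#' performed without updating responsibilities (the posterior expectations
#' enter the update brackets) followed by one M step driven by the hard
#' k-means assignments.
#'
#' @inheritParams e_step_beta
#' @param centers K x D matrix of initial means in (0,1).
#' @param hyper A `beta_hyperparams`.
#' @param labels Integer vector of hard initial assignments (1..K).
#' @return A `beta_posterior`.
#' @export
init_beta_posterior <- function(centers, hyper, data, labels) {
  centers <- clamp_unit(centers)
  k <- nrow(centers)
  d <- ncol(centers)
  ## method-of-moments concentration per component/dimension,
  ## s = m(1-m)/var - 1, capped at the sampling-noise limit: a beta over
  ## VAFs cannot be more concentrated than binomial counting noise at the
  ## observed depth, and k-means partitions of a single blob underestimate
  ## its variance (which would freeze duplicated components side by side)
  cap <- if (!is.null(data$var_counts))
    stats::median(data$var_counts + data$ref_counts) else 1000
  s0 <- matrix(pmin(100, cap), k, d)
  for (j in seq_len(k)) {
    x <- data$x[labels == j, , drop = FALSE]
    if (nrow(x) >= 2) {
      v <- apply(x, 2, stats::var)
      m <- centers[j, ]
      s0[j, ] <- ifelse(v > 0, pmin(pmax(m * (1 - m) / v - 1, 2), cap), cap)
    }
  }
  post <- new_beta_posterior(
    u_shape = s0 * centers, u_rate = matrix(1, k, d),
    v_shape = s0 * (1 - centers), v_rate = matrix(1, k, d),
    conc = rep(hyper$dirichlet_conc, k), hyper = hyper)
  r <- one_hot(labels, k)
  m_step_beta(data, r, hyper, post)
}

#' Sample shape parameters from the approximate posterior
#'
#' Independent gamma draws of (u_kd, v_kd) for one component; used by the
#' Monte-Carlo posterior predictive.
#'
#' @param post A `beta_posterior`.
#' @param k Component index.
#' @param n_draws Number of draws.
#' @param seed Integer seed (optional).
#' @return List with `u` and `v`, each n_draws x D.
#' @export
sample_beta_posterior <- function(post, k, n_draws, seed = NULL) {
  stopifnot(n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  d <- ncol(post$u_shape)
  u <- matrix(stats::rgamma(n_draws * d, shape = rep(post$u_shape[k, ], each = n_draws),
                            rate = rep(post$u_rate[k, ], each = n_draws)),
              n_draws, d)
  v <- matrix(stats::rgamma(n_draws * d, shape = rep(post$v_shape[k, ], each = n_draws),
                            rate = rep(post$v_rate[k, ], each = n_draws)),
              n_draws, d)
  list(u = u, v = v)
}

## Drop components (columns/rows) from a beta posterior.
subset_beta_posterior <- function(post, keep) {
  new_beta_posterior(post$u_shape[keep, , drop = FALSE],
                     post$u_rate[keep, , drop = FALSE],
                     post$v_shape[keep, , drop = FALSE],
                     post$v_rate[keep, , drop = FALSE],
                     post$conc[keep], post$hyper)
}
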