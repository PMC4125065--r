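## Alternative variational mixture families: binomial (on read counts) and
## Gaussian (on VAFs). Both are fully conjugate, so the variational updates
## are closed form; they plug into the same engine loop as the beta model.

## ---- binomial ----------------------------------------------------------

## Posterior: per component/dimension a beta distribution (a, b) over the
## binomial success probability, plus Dirichlet concentrations.
new_binom_posterior <- function(a, b, conc, hyper) {
  stopifnot(all(a > 0), all(b > 0), all(conc > 0))
  structure(list(a = a, b = b, conc = conc, hyper = hyper),
            class = "binom_posterior")
}

#' Binomial-model hyperparameters
#'
#' @param dirichlet_conc Dirichlet concentration per component.
#' @param a0,b0 Beta prior over the per-dimension success probability
#'   (default uniform).
#' @return An object of class `binom_hyperparams`.
#' @export
binom_hyperparams <- function(dirichlet_conc = 1, a0 = 1, b0 = 1) {
  stopifnot(dirichlet_conc > 0, a0 > 0, b0 > 0)
  structure(list(dirichlet_conc = dirichlet_conc, a0 = a0, b0 = b0),
            class = "binom_hyperparams")
}

binom_component_means <- function(post) post$a / (post$a + post$b)

## E step: log r_nk = E[log pi_k]
##   + sum_d v_nd E[log p_kd] + r_nd E[log(1-p_kd)]  (+ const in k).
## Sites enter weighted by their own read depth: deeper sites constrain more.
e_step_binom <- function(data, post) {
  eln_p  <- digamma(post$a) - digamma(post$a + post$b)   # K x D
  eln_1p <- digamma(post$b) - digamma(post$a + post$b)
  eln_pi <- digamma(post$conc) - digamma(sum(post$conc))
  lr <- sweep(data$var_counts %*% t(eln_p) + data$ref_counts %*% t(eln_1p),
              2, eln_pi, `+`)
  normalize_log_rows(lr)
}

m_step_binom <- function(data, r, hyper, post = NULL) {
  conc <- hyper$dirichlet_conc + colSums(r)
  a <- hyper$a0 + t(r) %*% data$var_counts
  b <- hyper$b0 + t(r) %*% data$ref_counts
  new_binom_posterior(a, b, conc, hyper)
}

init_binom_posterior <- function(centers, hyper, data, labels) {
  m_step_binom(data, one_hot(labels, nrow(centers)), hyper)
}

subset_binom_posterior <- function(post, keep) {
  new_binom_posterior(post$a[keep, , drop = FALSE],
                      post$b[keep, , drop = FALSE],
                      post$conc[keep], post$hyper)
}

## ---- Gaussian ----------------------------------------------------------

## Posterior: per component/dimension a Normal-Gamma (m, beta, a, b) over
## mean and precision (diagonal covariance: the same within-cluster
## across-sample independence assumed by the beta model), plus Dirichlet
## concentrations. beta is shared across dimensions of a component.
new_gauss_posterior <- function(m, beta, a, b, conc, hyper) {
  stopifnot(all(beta > 0), all(a > 0), all(b > 0), all(conc > 0))
  structure(list(m = m, beta = beta, a = a, b = b, conc = conc, hyper = hyper),
            class = "gauss_posterior")
}

#' Gaussian-model hyperparameters
#'
#' Broad Normal-Gamma prior per dimension: mean location `m0` with scale
#' count `beta0`, gamma prior (`a0`, `b0`) over the precision.
#'
#' @param dirichlet_conc Dirichlet concentration per component.
#' @param m0 Prior mean location (VAF scale).
#' @param beta0 Prior pseudo-count on the mean.
#' @param a0,b0 Gamma prior shape/rate over the precision.
#' @return An object of class `gauss_hyperparams`.
#' @export
gauss_hyperparams <- function(dirichlet_conc = 1, m0 = 0.5, beta0 = 1e-3,
                              a0 = 1e-3, b0 = 1e-3) {
  stopifnot(dirichlet_conc > 0, beta0 > 0, a0 > 0, b0 > 0)
  structure(list(dirichlet_conc = dirichlet_conc, m0 = m0, beta0 = beta0,
                 a0 = a0, b0 = b0),
            class = "gauss_hyperparams")
}

gauss_component_means <- function(post) post$m

e_step_gauss <- function(data, post) {
  n <- data$n; k <- length(post$conc); d <- data$d
  eln_pi <- digamma(post$conc) - digamma(sum(post$conc))
  eln_lam <- digamma(post$a) - log(post$b)               # K x D
  lr <- matrix(0, n, k)
  for (j in seq_len(k)) {
    quad <- sweep(data$x, 2, post$m[j, ], `-`)^2
    equad <- sweep(quad, 2, post$a[j, ] / post$b[j, ], `*`) + 1 / post$beta[j]
    lr[, j] <- eln_pi[j] + 0.5 * sum(eln_lam[j, ]) -
      0.5 * d * log(2 * pi) - 0.5 * rowSums(equad)
  }
  normalize_log_rows(lr)
}

m_step_gauss <- function(data, r, hyper, post = NULL) {
  n_k <- pmax(colSums(r), 1e-12)
  k <- ncol(r); d <- data$d
  xbar <- t(r) %*% data$x / n_k                          # K x D
  beta <- hyper$beta0 + n_k
  m <- sweep(sweep(xbar, 1, n_k, `*`) + hyper$beta0 * hyper$m0, 1, beta, `/`)
  a <- matrix(hyper$a0 + n_k / 2, k, d)
  s <- matrix(0, k, d)                                   # N_k * within-cluster var
  for (j in seq_len(k))
    s[j, ] <- colSums(r[, j] * sweep(data$x, 2, xbar[j, ], `-`)^2)
  b <- hyper$b0 + 0.5 * (s + sweep((xbar - hyper$m0)^2, 1,
                                   hyper$beta0 * n_k / beta, `*`))
  new_gauss_posterior(m, beta, a, b, hyper$dirichlet_conc + colSums(r), hyper)
}

init_gauss_posterior <- function(centers, hyper, data, labels) {
  m_step_gauss(data, one_hot(labels, nrow(centers)), hyper)
}

subset_gauss_posterior <- function(post, keep) {
  new_gauss_posterior(post$m[keep, , drop = FALSE], post$beta[keep],
                      post$a[keep, , drop = FALSE], post$b[keep, , drop = FALSE],
                      post$conc[keep], post$hyper)
}

## ---- generic dispatch used by the engine -------------------------------

model_funs <- function(model) {
  switch(model,
    beta = list(init = init_beta_posterior, estep = e_step_beta,
                mstep = m_step_beta, means = beta_component_means,
                subset = subset_beta_posterior,
                default_hyper = beta_hyperparams),
    binomial = list(init = init_binom_posterior, estep = e_step_binom,
                    mstep = m_step_binom, means = binom_component_means,
                    subset = subset_binom_posterior,
                    default_hyper = binom_hyperparams),
    gaussian = list(init = init_gauss_posterior, estep = e_step_gauss,
                    mstep = m_step_gauss, means = gauss_component_means,
                    subset = subset_gauss_posterior,
                    default_hyper = gauss_hyperparams),
    stop("unknown model: ", model)
  )
}
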