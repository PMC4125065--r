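test_that("beta component log density matches closed forms and factorizes", {
  # uniform component: density 1 everywhere
  expect_equal(beta_component_logdensity(0.37, 1, 1), 0)
  # Beta(2,2) at 1/2: 6 * 0.5 * 0.5 = 1.5
  expect_equal(beta_component_logdensity(0.5, 2, 2), log(1.5))
  # independence across dimensions: joint = product
  x <- c(0.3, 0.7); u <- c(2, 5); v <- c(3, 4)
  expect_equal(beta_component_logdensity(x, u, v),
               beta_component_logdensity(x[1], u[1], v[1]) +
                 beta_component_logdensity(x[2], u[2], v[2]))
  expect_error(beta_component_logdensity(0, 2, 2), "clamp")
})

make_posterior <- function(u_mean, v_mean, shape = 400, conc = NULL) {
  # gamma posteriors concentrated at the requested means
  k <- length(u_mean)
  vbclone:::new_beta_posterior(
    u_shape = matrix(shape, k, 1), u_rate = matrix(shape / u_mean, k, 1),
    v_shape = matrix(shape, k, 1), v_rate = matrix(shape / v_mean, k, 1),
    conc = if (is.null(conc)) rep(1, k) else conc,
    hyper = beta_hyperparams())
}

test_that("E-step responsibilities normalize and respect symmetry", {
  dat <- vbclone:::prepare_vaf_data(matrix(c(0.2, 0.5, 0.8), ncol = 1))
  # K = 1: every responsibility is 1
  p1 <- make_posterior(20, 30)
  expect_equal(as.vector(e_step_beta(dat, p1)), rep(1, 3))
  # symmetric components, equidistant point -> 0.5 / 0.5
  p2 <- make_posterior(c(20, 30), c(30, 20), conc = c(5, 5))
  r <- e_step_beta(dat, p2)
  expect_equal(rowSums(r), rep(1, 3), tolerance = 1e-9)
  expect_equal(as.vector(r[2, ]), c(0.5, 0.5), tolerance = 1e-6)
})

test_that("well-separated components give near-crisp responsibilities that
          agree with the direct density ratio", {
  p <- make_posterior(c(40, 10), c(60, 90), shape = 5000, conc = c(5, 5))
  x <- 0.4  # component 1 mean
  dat <- vbclone:::prepare_vaf_data(matrix(x, 1, 1))
  r <- e_step_beta(dat, p)
  expect_gt(r[1, 1], 0.99)
  # oracle: likelihood ratio at the posterior-expected shapes
  l1 <- dbeta(x, 40, 60); l2 <- dbeta(x, 10, 90)
  expect_equal(r[1, 1] / r[1, 2], l1 / l2, tolerance = 0.15)
})

test_that("M step: zero-mass components revert to the prior and
          concentrations are conserved", {
  hyper <- beta_hyperparams()
  set.seed(4)
  n <- 120
  x <- matrix(rbeta(n, 0.47 * 600, 0.53 * 600), ncol = 1)
  dat <- vbclone:::prepare_vaf_data(x)
  post0 <- make_posterior(c(47, 10), c(53, 90), conc = c(1, 1))
  r <- cbind(rep(1, n), rep(0, n))  # all mass in component 1
  post <- m_step_beta(dat, r, hyper, post0)
  # dead component keeps its prior parameterization
  expect_equal(post$u_shape[2, 1], hyper$gamma_shape_u)
  expect_equal(post$u_rate[2, 1], hyper$gamma_rate_u)
  expect_equal(post$conc[2], hyper$dirichlet_conc)
  # Dirichlet conservation: sum = K * c0 + N
  expect_equal(sum(post$conc), 2 * hyper$dirichlet_conc + n, tolerance = 1e-9)
})

test_that("iterated M steps recover a maximum-likelihood beta fit", {
  skip_if_not_installed("fitdistrplus")
  hyper <- beta_hyperparams()
  set.seed(5)
  n <- 400
  x <- matrix(rbeta(n, 0.47 * 300, 0.53 * 300), ncol = 1)
  dat <- vbclone:::prepare_vaf_data(x)
  post <- init_beta_posterior(matrix(mean(x), 1, 1), hyper, dat, rep(1L, n))
  r <- matrix(1, n, 1)
  for (i in 1:200) post <- m_step_beta(dat, r, hyper, post)
  ml <- fitdistrplus::fitdist(as.vector(x), "beta")$estimate
  vb_mean <- beta_component_means(post)[1, 1]
  expect_equal(vb_mean, unname(ml[1] / (ml[1] + ml[2])), tolerance = 0.02)
  expect_equal(vb_mean, 0.47, tolerance = 0.02)
})

test_that("initialization matches k-means centers in expectation", {
  hyper <- beta_hyperparams()
  set.seed(6)
  x <- matrix(c(rbeta(60, 0.5 * 400, 0.5 * 400),
                rbeta(60, 0.25 * 400, 0.75 * 400)), ncol = 1)
  dat <- vbclone:::prepare_vaf_data(x)
  labels <- rep(1:2, each = 60)
  centers <- matrix(c(0.5, 0.25), 2, 1)
  post <- init_beta_posterior(centers, hyper, dat, labels)
  # post-init component means stay at the centers (init is one E + one M
  # step on the hard assignments, which preserves the cluster locations)
  m <- beta_component_means(post)
  expect_equal(m[1, 1], 0.5, tolerance = 0.02)
  expect_equal(m[2, 1], 0.25, tolerance = 0.02)
  # mean identity of the parameterization: at mean 1/2 the expected shapes
  # are equal; at mean 1/4, E[v] = 3 E[u]
  ub <- post$u_shape / post$u_rate
  vb <- post$v_shape / post$v_rate
  expect_equal(vb[1, 1] / ub[1, 1], (1 - m[1, 1]) / m[1, 1], tolerance = 1e-9)
  expect_equal(vb[2, 1] / ub[2, 1], (1 - m[2, 1]) / m[2, 1], tolerance = 1e-9)
})

test_that("posterior sampling is seeded, positive, and unbiased", {
  p <- make_posterior(20, 30, shape = 50)
  d1 <- sample_beta_posterior(p, 1, 10000, seed = 9)
  d2 <- sample_beta_posterior(p, 1, 10000, seed = 9)
  expect_identical(d1, d2)
  expect_true(all(d1$u > 0) && all(d1$v > 0))
  # gamma(50, 50/20): mean 20, sd 20/sqrt(50); 3 SE band
  se <- 20 / sqrt(50) / sqrt(10000)
  expect_lt(abs(mean(d1$u) - 20), 3 * se)
})

test_that("E/M iteration keeps variational parameters positive on
          boundary-heavy input", {
  hyper <- beta_hyperparams()
  for (s in 1:5) {
    set.seed(s)
    raw <- matrix(c(rep(0, 20), runif(60), rep(1, 20)), ncol = 1)
    dat <- vbclone:::prepare_vaf_data(clamp_vafs(raw))
    km <- kmeans_init(dat$x, 3, seed = s)
    post <- init_beta_posterior(km$centers, hyper, dat, km$labels)
    for (i in 1:10) {
      r <- e_step_beta(dat, post)
      expect_equal(rowSums(r), rep(1, nrow(r)), tolerance = 1e-9)
      post <- m_step_beta(dat, r, hyper, post)
      expect_true(all(post$u_shape > 0, post$u_rate > 0,
                      post$v_shape > 0, post$v_rate > 0))
    }
  }
})

test_that("a single simulated beta cluster is recovered within 0.02 at
          N = 500", {
  arch <- clonal_architecture(matrix(0.35, 1, 1), 1, noise = "beta",
                              beta_conc = 150)
  ds <- generate(arch, 500, seed = 21)
  fit <- suppressWarnings(
    vaf_cluster(ds$vafs, config = engine_config(seed = 21),
                outlier_detection = FALSE))
  expect_equal(fit$K, 1L)
  expect_equal(unname(fit$means[1, 1]), 0.35, tolerance = 0.02)
})
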