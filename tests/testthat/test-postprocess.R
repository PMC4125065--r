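test_that("hard assignment is argmax with ties to the lowest cluster", {
  r <- rbind(c(0.93, 0.07), c(0.42, 0.58), c(0.5, 0.5))
  expect_equal(hard_assign(r), c(1L, 2L, 1L))
  r3 <- rbind(c(0.421, 0.578, 0.001))
  expect_equal(hard_assign(r3), 2L)
})

test_that("self-overlap matches its definition", {
  # crisp clusters score exactly 1
  r <- vbclone:::one_hot(c(1, 1, 2, 2), 2)
  expect_equal(self_overlap(r), c(1, 1))
  # maximally shared clusters score 0.5
  r2 <- matrix(0.5, 4, 2)
  expect_equal(self_overlap(r2), c(0.5, 0.5))
  # hand computation: column (0.9, 0.8, 0.5)
  r3 <- cbind(c(0.9, 0.8, 0.5), c(0.1, 0.2, 0.5))
  expect_equal(self_overlap(r3, 1), (0.81 + 0.64 + 0.25) / 2.2)
  expect_equal(self_overlap(r3, 1), 0.772727, tolerance = 1e-6)
  # zero-mass cluster reports 0
  r4 <- cbind(c(1, 1), c(0, 0))
  expect_equal(self_overlap(r4, 2), 0)
})

test_that("overlap pruning removes redundant clusters and keeps crisp ones", {
  base <- one_blob_fit()
  # a crisp fit is untouched at any threshold <= 1
  crisp <- prune_overlapping(base, kappa1 = 0.99)
  expect_equal(crisp$K, base$K)
  # two duplicated components sharing one blob (r = 0.5 everywhere):
  # S = 0.5 < 0.6 in one dimension -> one removed, refit to a single cluster
  dup <- duplicated_fit(base, copies = 2)
  pruned <- suppressWarnings(prune_overlapping(dup, kappa1 = 0.6))
  expect_equal(pruned$K, 1L)
  # the threshold scales as kappa1 / d: the same S = 0.5 survives when the
  # effective dimensionality makes kappa_d = 0.3
  dup2 <- duplicated_fit(base, copies = 2)
  dup2$means <- cbind(dup2$means, dup2$means)  # pretend d = 2
  dup2$posterior$u_shape <- cbind(dup2$posterior$u_shape,
                                  dup2$posterior$u_shape)
  dup2$posterior$u_rate <- cbind(dup2$posterior$u_rate,
                                 dup2$posterior$u_rate)
  dup2$posterior$v_shape <- cbind(dup2$posterior$v_shape,
                                  dup2$posterior$v_shape)
  dup2$posterior$v_rate <- cbind(dup2$posterior$v_rate,
                                 dup2$posterior$v_rate)
  s <- self_overlap(dup2$r)
  expect_true(all(s >= 0.6 / 2))  # would survive the d = 2 threshold
})

test_that("posterior predictive integrates to one and is largest near the
          cluster", {
  fit <- one_blob_fit()
  grid <- seq(0.0005, 0.9995, length.out = 2000)
  pp <- posterior_predictive(fit, grid, seed = 2)
  integral <- mean(pp$total) * (max(grid) - min(grid)) / 0.999
  expect_equal(integral, 1, tolerance = 0.01)
  m <- fit$means[1, 1]
  sd_blob <- sd(fit$data$x[, 1])
  at_mean <- posterior_predictive(fit, m, seed = 2)$total
  far <- posterior_predictive(fit, m + 5 * sd_blob, seed = 2)$total
  expect_gt(at_mean, far)
})

test_that("gaussian K = 1 predictive matches the Student-t closed form", {
  set.seed(41)
  x <- matrix(rnorm(300, 0.4, 0.05), ncol = 1)
  fit <- vaf_cluster(x, config = engine_config(init_k = 3, seed = 41,
                                               model = "gaussian"),
                     outlier_detection = FALSE)
  expect_equal(fit$K, 1L)
  st <- vbclone:::gauss_predictive_t(fit$posterior, 1, 1)
  grid <- c(0.3, 0.4, 0.5)
  got <- vbclone:::predictive_density_k(fit, 1, matrix(grid, ncol = 1))
  want <- dt((grid - st$loc) / st$scale, df = st$df) / st$scale
  expect_equal(got, want, tolerance = 1e-12)
  # with 300 observations the predictive is close to N(mean, sd)
  expect_equal(st$loc, 0.4, tolerance = 0.01)
  expect_equal(st$scale, 0.05, tolerance = 0.05)
})

test_that("outlier p-value at 1.96 sigma of a Gaussian predictive is 0.05", {
  set.seed(42)
  x <- matrix(rnorm(2000, 0.4, 0.05), ncol = 1)
  fit <- fit_gaussian(x, engine_config(init_k = 3, seed = 42))
  st <- vbclone:::gauss_predictive_t(fit$posterior, 1, 1)
  p <- outlier_pvalue(fit, st$loc + 1.96 * st$scale, 1)
  # density ordering on a symmetric unimodal density = two-sided tail
  expect_equal(p, 0.05, tolerance = 0.003)
  # at the mode the p-value is ~1
  expect_gt(outlier_pvalue(fit, st$loc, 1), 0.99)
})

test_that("beta-model outlier p-values behave at the mode and in the far
          tail", {
  fit <- one_blob_fit(n = 200)
  m <- fit$means[1, 1]
  expect_gt(outlier_pvalue(fit, m, 1, n_draws = 4000, seed = 5), 0.8)
  p_far <- outlier_pvalue(fit, 0.95, 1, n_draws = 4000, seed = 5)
  expect_lt(p_far, 1e-3)
  expect_error(outlier_pvalue(fit, m, 1, n_draws = 50), "at least 100")
})

test_that("the outlier pre-filter requires exceedance in every sample", {
  p <- preset("AML-mimic")
  ds <- generate(p$arch, 400, seed = 43)
  fit <- vb_fit(ds$vafs, engine_config(seed = 43),
                var_counts = ds$var_counts, ref_counts = ds$ref_counts)
  k <- fit$assignments[1]
  x <- fit$data$x[1, ]
  ci <- vbclone:::posterior_mean_interval(fit, k)
  center <- rowMeans(ci)
  expect_false(outlier_prefilter(fit, center, k))
  expect_true(outlier_prefilter(fit, pmin(center + 0.4, 0.99), k))
  # outside in sample 1 only -> not a candidate
  half_out <- center; half_out[1] <- min(half_out[1] + 0.4, 0.99)
  expect_false(outlier_prefilter(fit, half_out, k))
})

test_that("outlier flagging is monotone in alpha", {
  set.seed(44)
  x <- matrix(c(rbeta(150, 0.4 * 400, 0.6 * 400), 0.75, 0.9), ncol = 1)
  fit <- vb_fit(x, engine_config(init_k = 3, seed = 44))
  f1 <- detect_outliers(fit, alpha = 0.001, n_draws = 2000, seed = 1)
  f2 <- detect_outliers(fit, alpha = 0.05, n_draws = 2000, seed = 1)
  expect_true(all(which(f1$outliers) %in% which(f2$outliers)))
  expect_true(any(f2$outliers))  # the planted far points are caught
})

test_that("assignment and summary tables are consistent with the fit", {
  fit <- detect_outliers(one_blob_fit(), n_draws = 500, seed = 3)
  at <- assignment_table(fit)
  expect_equal(nrow(at), nrow(fit$r))
  probs <- as.matrix(at[, grep("^prob_c", names(at)), drop = FALSE])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(at)), tolerance = 1e-9)
  cs <- cluster_summary(fit)
  expect_equal(sum(cs$size) + sum(is.na(at$cluster)), nrow(at))
  expect_true(all(cs$self_overlap >= 0 & cs$self_overlap <= 1))
})
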