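## Top-level clustering pipeline: VB fit, small-cluster pruning (inside the
## engine), overlapping-cluster removal, optional posterior-predictive
## outlier detection.

#' Cluster VAFs into subclones
#'
#' Runs the full inference chain on a prepared VAF (or count) matrix:
#' [vb_fit()] (k-means initialization, variational E/M iteration,
#' small-cluster pruning), then [prune_overlapping()] with the
#' dimensionality-scaled self-overlap threshold, then optionally
#' [detect_outliers()].
#'
#' @param vafs N x D matrix of VAFs (beta/gaussian models).
#' @param var_counts,ref_counts N x D count matrices (binomial model).
#' @param config An [engine_config()].
#' @param kappa1 One-dimensional self-overlap threshold; see
#'   [prune_overlapping()] for the simulation-calibrated default.
#' @param outlier_detection Run posterior-predictive outlier flagging
#'   (default TRUE; sweeps disable it since outliers do not change the
#'   surviving component count).
#' @param alpha Outlier p-value threshold (default 0.01, uncorrected).
#' @param n_draws Predictive draws for the outlier integral.
#' @return A `vaf_fit`.
#' @export
vaf_cluster <- function(vafs = NULL, var_counts = NULL, ref_counts = NULL,
                        config = engine_config(), kappa1 = 0.85,
                        outlier_detection = TRUE, alpha = 0.01,
                        n_draws = 10000) {
  fit <- vb_fit(vafs = vafs, config = config,
                var_counts = var_counts, ref_counts = ref_counts)
  fit <- prune_overlapping(fit, kappa1 = kappa1)
  if (outlier_detection)
    fit <- detect_outliers(fit, alpha = alpha, n_draws = n_draws,
                           seed = config$seed)
  fit
}
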