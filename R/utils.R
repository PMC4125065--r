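## Shared numerical helpers.

## Row-wise softmax of a matrix of log weights, via log-sum-exp.
## (max.col is C-level; apply(lw, 1, max) would dominate the E-step cost)
row_max <- function(m) m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]

normalize_log_rows <- function(lw) {
  w <- exp(lw - row_max(lw))
  w / rowSums(w)
}

## N x K one-hot matrix from integer labels in 1..k.
one_hot <- function(labels, k) {
  r <- matrix(0, length(labels), k)
  r[cbind(seq_along(labels), labels)] <- 1
  r
}

## Clamp values into the open unit interval by machine precision.
clamp_unit <- function(x, eps = .Machine$double.eps) {
  x[x <= 0] <- eps
  x[x >= 1] <- 1 - eps
  x
}

#' Shift boundary VAFs into the open unit interval
#'
#' VAFs exactly 0 or 1 are undefined under a beta density; they are shifted
#' to `eps` and `1 - eps` respectively (machine precision by default).
#' Interior values are unchanged.
#'
#' @param x Numeric vector/matrix of VAFs in \[0,1\].
#' @param eps Shift amount; defaults to machine precision.
#' @return Same shape as `x`, all values in (0,1).
#' @export
clamp_vafs <- function(x, eps = .Machine$double.eps) {
  stopifnot(eps > 0, eps < 0.5)
  clamp_unit(x, eps)
}

## Precompute the per-model data representation used by the E/M steps.
## x: N x D VAF matrix; var_counts/ref_counts: N x D integer matrices.
## Boundary VAFs are shifted into (0,1): by machine precision for pure VAF
## input, and to a half-read floor 0.5/(depth+1) when read counts are
## available — a VAF of 0 at depth n is only evidence that the true VAF is
## below ~1/n, and clamping it to machine precision instead would place an
## atom ~30 log-units below the cluster's continuous mass, which a beta
## component then latches onto.
prepare_vaf_data <- function(x = NULL, var_counts = NULL, ref_counts = NULL) {
  have_counts <- !is.null(var_counts) && !is.null(ref_counts)
  if (have_counts) {
    var_counts <- as.matrix(var_counts)
    ref_counts <- as.matrix(ref_counts)
    depth <- var_counts + ref_counts
    if (any(depth <= 0)) stop("zero-depth entry; filter sites upstream")
  }
  if (is.null(x)) {
    stopifnot(have_counts)
    x <- var_counts / depth
  }
  x <- as.matrix(x)
  if (have_counts && all(dim(depth) == dim(x))) {
    floor_ <- 0.5 / (depth + 1)
    xc <- pmin(pmax(x, floor_), 1 - floor_)
  } else {
    xc <- clamp_unit(x)
  }
  list(x = xc, lx = log(xc), l1mx = log1p(-xc),
       var_counts = var_counts, ref_counts = ref_counts,
       n = nrow(x), d = ncol(x))
}

## Modal value of an integer vector (smallest mode on ties).
modal_value <- function(x) {
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}
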