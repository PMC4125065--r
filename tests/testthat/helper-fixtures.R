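# Shared fixture builders. All data is generated in code at test time.

write_tsv_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# A variant file with given positions/counts (chrom "1" throughout).
make_variant_file <- function(pos, ref, var, header = FALSE) {
  lines <- paste("1", pos, ref, var, sep = "\t")
  if (header) lines <- c("chrom\tpos\tref_counts\tvar_counts", lines)
  write_tsv_lines(lines)
}

# Ten-site, one-sample fixture: 3 sites below depth 50, 2 sites in LOH,
# 5 clean sites (depths all >= 50 elsewhere). Hand-checked in tests.
ten_site_fixture <- function() {
  pos <- c(100, 200, 300, 400, 500, 600, 700, 800, 900, 1000)
  ref <- c(60, 20, 55, 10, 80, 70, 65, 15, 90, 75)
  var <- c(40, 10, 45, 20, 60, 50, 55, 10, 70, 65)
  # depths: 100,30,100,30,140,120,120,25,160,140 -> pos 200,400,800 low
  loh <- write_tsv_lines(c("1\t550\t650", "1\t950\t1050"))  # pos 600, 1000
  list(variants = make_variant_file(pos, ref, var), loh = loh,
       pos = pos, ref = ref, var = var)
}

# Deterministic one-blob 1-D beta fit used by postprocess tests.
one_blob_fit <- function(n = 150, mean = 0.4, depth = 300, seed = 11) {
  arch <- clonal_architecture(matrix(mean, 1, 1), 1, depth = depth)
  ds <- generate(arch, n, seed = seed)
  vb_fit(ds$vafs, engine_config(init_k = 4, seed = seed),
         var_counts = ds$var_counts, ref_counts = ds$ref_counts)
}

# Build a vaf_fit whose posterior duplicates one converged component k
# times, with uniform responsibilities (maximally overlapping clusters).
duplicated_fit <- function(base, copies = 2) {
  stopifnot(base$K == 1)
  keep <- rep(1L, copies)
  post <- vbclone:::subset_beta_posterior(base$posterior, keep)
  n <- nrow(base$r)
  r <- matrix(1 / copies, n, copies)
  fit <- base
  fit$posterior <- post
  fit$r <- r
  fit$K <- copies
  fit$pi <- rep(1 / copies, copies)
  fit$means <- vbclone:::beta_component_means(post)
  fit$assignments <- hard_assign(r)
  fit
}

# Brute-force concordance by exhaustive permutation of predicted labels
# (independent oracle for the assignment-matching implementation).
concordance_bruteforce <- function(true, pred) {
  pl <- sort(unique(pred))
  tl <- sort(unique(true))
  all_labels <- union(tl, pl)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- 0
  for (p in perms(all_labels)) {
    mapped <- p[match(pred, all_labels)]
    best <- max(best, mean(mapped == true))
  }
  best
}

make_sized_fit <- function(sizes, n) {
  # minimal vaf_fit with hard responsibilities and matching posterior
  k <- length(sizes)
  labels <- rep(seq_len(k), times = sizes)
  r <- vbclone:::one_hot(labels, k)
  post <- vbclone:::new_beta_posterior(
    u_shape = matrix(10, k, 1), u_rate = matrix(20, k, 1),
    v_shape = matrix(10, k, 1), v_rate = matrix(10, k, 1),
    conc = rep(1, k) + sizes, hyper = beta_hyperparams())
  structure(list(r = r, posterior = post, pi = sizes / sum(sizes),
                 means = vbclone:::beta_component_means(post),
                 assignments = labels, K = k, n_iter = 0L, converged = TRUE,
                 pruning_history = list(), config = engine_config(),
                 data = vbclone:::prepare_vaf_data(
                   matrix(runif(sum(sizes), 0.2, 0.8), ncol = 1)),
                 outliers = NULL),
            class = "vaf_fit")
}
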