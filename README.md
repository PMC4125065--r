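# vbclone

Infer the clonal architecture of a tumor from somatic variant allele
frequencies (VAFs). `vbclone` clusters the VAFs of copy-number-neutral,
LOH-free, adequately covered SNVs across one or many samples (tumor/relapse
pairs, multi-region biopsies) with variational Bayesian mixture models,
determines how many cell populations the data support, and assigns every
variant to a population with a posterior probability. It is aimed at cancer
genomics analysts working from deep-sequencing read counts produced by
standard somatic pipelines.

## Model

For variant n, the VAF vector x_n across D samples is modeled as a mixture
of K components, each a product of beta densities (independence across
samples within a cluster):

    p(x_n | Z, U, V) = prod_k [ pi_k * prod_d Beta(x_nd; u_kd, v_kd) ]^z_nk

with a Dirichlet prior on the mixing proportions pi and broad gamma priors
on every beta shape parameter. Because the beta likelihood has no usable
conjugate prior, the variational posterior over (u, v) is kept in gamma
form via a second-order Taylor bound on the expected log beta normalizer;
E/M updates iterate to convergence of the responsibilities r_nk.
Under-populated components (fewer than max(3, 0.5% N) variants) and
redundant components (self-overlap S_k = sum r^2 / sum r below a
dimension-scaled threshold) are pruned, so an initial overestimate of K
(ten by default) collapses to the number of populations the data support.
Binomial (on read counts, exactly depth-aware) and Gaussian (on VAFs)
mixtures are available as alternatives, and posterior-predictive p-values
flag outlier variants. Helper functions cover tumor purity (rho = twice
the founding-clone mean VAF), expected VAFs under copy-number states
(m·rho / (2(1−rho) + t·rho)), and conversion of copy-number-event cellular
prevalences to pseudo-VAFs (p/2) for joint clustering.

See the methods vignette (`vignettes/subclone-inference.Rmd`) for the full
model, fitting procedure, and design rationale.

## Worked example

A small synthetic single-sample dataset ships with the package: 90 variant
calls, a copy-number segmentation containing one trisomic segment, and an
LOH track.

```r
library(vbclone)

vf   <- system.file("extdata", "synthetic_tumor.tsv", package = "vbclone")
cnf  <- system.file("extdata", "synthetic_cn.tsv",    package = "vbclone")
lohf <- system.file("extdata", "synthetic_loh.tsv",   package = "vbclone")

tumor <- read_variant_table(vf, "tumor")
flt <- merge_and_filter(list(tumor),
                        cn      = list(read_cn_segments(cnf)),
                        exclude = list(read_region_file(lohf)),
                        min_depth = 50)
table(flt$excluded$exclude_reason)
#> cn-altered        loh  low-depth
#>          3          3          4

counts <- count_matrices(flt$retained)
fit <- vaf_cluster(vafs       = vaf_matrix(flt$retained),
                   var_counts = counts$var_counts,
                   ref_counts = counts$ref_counts,
                   config     = engine_config(seed = 1))
fit
#> Variational Bayesian beta mixture fit
#>   80 variants x 1 sample(s); 3 surviving component(s); converged after 2781 iterations
#>   cluster 1: n = 45, pi = 0.554, mean VAF = 0.4652
#>   cluster 2: n = 21, pi = 0.266, mean VAF = 0.3312
#>   cluster 3: n = 14, pi = 0.181, mean VAF = 0.1113

estimate_purity(cluster_summary(fit)$mean_vaf_s1[1])$rho
#> [1] 0.9320444
```

Ten sites fail the filters (4 under-covered, 3 in the trisomic segment, 3
in LOH); the remaining 80 VAFs resolve into a founding clone near 0.47 —
implying a tumor purity of about 0.93 — and two subclones near 0.33 and
0.11. `assignment_table(fit)` gives each variant's per-cluster posterior
probabilities and outlier p-value; `plot_vaf_density(fit)` draws the
histogram with per-cluster posterior predictive curves.

The same pipeline is scriptable from a shell via the thin CLI in `exec/`:

```sh
vbclone simulate --preset AML-mimic --out-prefix aml
vbclone fit --variants aml.sample1.tsv,aml.sample2.tsv --samples tumor,relapse \
            --seed 1 --out-prefix aml_run
vbclone sweep --type separation --out-prefix sep
```

`fit` writes `<prefix>.assignments.tsv`, `<prefix>.clusters.tsv`, a run
log, and plots; flags mirror `engine_config()` and can come from a YAML
config file (`--config`).

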