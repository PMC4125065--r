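Package: vbclone
Title: Variational Bayesian Mixture Modeling of Variant Allele
    Frequencies for Tumor Subclone Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers the number and composition of tumor subclones by
    clustering somatic variant allele frequencies (VAFs) across one or
    many samples with variational Bayesian mixture models (beta on VAFs,
    binomial on read counts, Gaussian on VAFs). Sites are restricted to
    copy-number-neutral, LOH-free, adequately covered regions. Includes
    principled small-cluster and overlapping-cluster pruning, posterior
    predictive outlier detection, probabilistic variant-to-clone
    assignment, tumor purity and copy-number VAF arithmetic, conversion
    of copy-number-event cellular prevalences to pseudo-VAFs, and a
    synthetic clonal-architecture simulator with downsampling,
    separation, and consensus-clustering evaluation harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    fitdistrplus,
    withr
Config/testthat/edition: 3
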