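## Copy-number arithmetic: tumor purity from the founding clone, expected
## VAFs under arbitrary copy states, and conversion of copy-number-event
## cellular prevalences to pseudo-VAFs for joint clustering.

#' Estimate tumor purity from the founding clone
#'
#' Heterozygous founding-clone mutations in copy-number-neutral regions sit
#' at VAF rho/2, so purity is estimated as twice the founding cluster's mean
#' VAF (the highest-mean surviving cluster), clamped at 1.
#'
#' @param founding_mean_vaf Mean VAF of the founding cluster, in (0, ~0.5].
#' @param cluster Optional source cluster id (metadata).
#' @return List of class `purity_estimate`: `rho`, `founding_mean_vaf`,
#'   `cluster`.
#' @export
estimate_purity <- function(founding_mean_vaf, cluster = NA_integer_) {
  if (!is.numeric(founding_mean_vaf) || founding_mean_vaf <= 0)
    stop("founding_mean_vaf must be positive")
  if (founding_mean_vaf > 0.5 + 0.05)
    stop("founding_mean_vaf ", founding_mean_vaf,
         " is far above 0.5; check copy-number filtering")
  if (founding_mean_vaf > 0.5)
    warning("founding_mean_vaf slightly above 0.5; purity clamped to 1")
  structure(list(rho = min(1, 2 * founding_mean_vaf),
                 founding_mean_vaf = founding_mean_vaf,
                 cluster = cluster),
            class = "purity_estimate")
}

#' Expected VAF under an arbitrary copy-number state
#'
#' For tumor purity `rho`, total copy number `t` in tumor cells and `m`
#' mutant copies, normal cells contribute two reference copies, giving
#' expected VAF m * rho / (2 * (1 - rho) + t * rho). The heterozygous
#' neutral case (t = 2, m = 1) reduces to rho / 2; single-copy loss of the
#' reference allele (t = m = 1) at full purity doubles the VAF to 1.
#'
#' @param rho Tumor purity in (0, 1].
#' @param t Total copy number in tumor cells (positive integer).
#' @param m Mutant copies (0 <= m <= t).
#' @return Expected VAF in \[0,1\].
#' @export
expected_vaf <- function(rho, t, m) {
  stopifnot(rho > 0, rho <= 1)
  if (t < 1) stop("total copy number t must be at least 1")
  if (m < 0 || m > t) stop("mutant copies m must satisfy 0 <= m <= t")
  m * rho / (2 * (1 - rho) + t * rho)
}

#' Convert a copy-number event's cellular prevalence to a pseudo-VAF
#'
#' An event present in a fraction `p` of cells would, as a fully linked
#' heterozygous marker, appear at VAF p/2; the pseudo-VAF lets copy-number
#' events be clustered jointly with SNVs. The same mapping is applied to all
#' copy states.
#'
#' @param p Cellular prevalence in \[0,1\].
#' @return Pseudo-VAF in \[0, 0.5\].
#' @export
prevalence_to_pseudovaf <- function(p) {
  if (any(p < 0 | p > 1)) stop("cellular prevalence must lie in [0,1]")
  p / 2
}

#' Read a copy-number event (cellular prevalence) table
#'
#' Tab-separated chrom, start, stop, cellular_prevalence.
#'
#' @param path File path.
#' @return Data frame with a computed `pseudo_vaf` column.
#' @export
read_cna_events <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "stop",
                                        "cellular_prevalence"))
  df$pseudo_vaf <- prevalence_to_pseudovaf(df$cellular_prevalence)
  df
}

#' Overlay copy-number events on a merged variant table
#'
#' Appends each event as a pseudo-variant row at its pseudo-VAF, flagged as
#' CNA-derived. For count-based models the event receives a synthetic depth
#' equal to the median depth of the retained SNVs (so events carry
#' comparable evidential weight), with variant counts
#' round(pseudo_vaf * depth). The same pseudo-VAF is used in every sample.
#'
#' @param events Data frame from [read_cna_events()] (needs `chrom`,
#'   `start`, `pseudo_vaf`).
#' @param variants Retained variant data frame from [merge_and_filter()].
#' @return The augmented variant data frame with a logical `cna_derived`
#'   column.
#' @export
overlay_cna_events <- function(events, variants) {
  variants$cna_derived <- FALSE
  if (is.null(events) || nrow(events) == 0) return(variants)
  vaf_cols <- grep("^vaf_s[0-9]+$", names(variants), value = TRUE)
  vc_cols <- grep("^var_counts_s[0-9]+$", names(variants), value = TRUE)
  rc_cols <- grep("^ref_counts_s[0-9]+$", names(variants), value = TRUE)
  depths <- as.matrix(variants[, vc_cols, drop = FALSE]) +
    as.matrix(variants[, rc_cols, drop = FALSE])
  med_depth <- round(stats::median(depths, na.rm = TRUE))
  rows <- lapply(seq_len(nrow(events)), function(i) {
    row <- variants[1, , drop = FALSE]
    row[1, ] <- NA
    row$chrom <- as.character(events$chrom[i])
    row$pos <- as.integer(events$start[i])
    row$annotation <- "CNA-event"
    for (j in seq_along(vaf_cols)) {
      pv <- events$pseudo_vaf[i]
      row[[vaf_cols[j]]] <- pv
      row[[vc_cols[j]]] <- as.integer(round(pv * med_depth))
      row[[rc_cols[j]]] <- as.integer(med_depth - round(pv * med_depth))
    }
    row$cna_derived <- TRUE
    row
  })
  out <- rbind(variants, do.call(rbind, rows))
  rownames(out) <- NULL
  out
}
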