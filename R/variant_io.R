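## Read variant, copy-number, and exclusion-region tables; merge samples;
## filter to copy-number-neutral, LOH-free, adequately covered sites.
##
## File conventions (all tab-separated, 1-based inclusive coordinates):
##   variant file:   chrom  pos  ref_counts  var_counts  [vaf  annotation]
##   CN file:        chrom  start  stop  copy_number
##   exclusion file: chrom  start  stop

#' Read a single-sample variant table
#'
#' Tab-separated with at least four columns (chrom, pos, ref_counts,
#' var_counts); an optional fifth VAF column is ignored and recomputed from
#' the counts, an optional sixth column is kept as annotation. A header line
#' is detected by a non-numeric `pos` field. Input order is preserved.
#'
#' @param path File path.
#' @param sample_name Sample label attached to the result.
#' @return Data frame: chrom, pos, ref_counts, var_counts, vaf, annotation,
#'   sample.
#' @export
read_variant_table <- function(path, sample_name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty variant file: ", path)
  first <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  start <- if (length(first) >= 2 && is.na(suppressWarnings(as.numeric(first[2]))))
    2L else 1L
  rows <- lapply(seq(start, length(lines)), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4)
      stop("line ", i, ": expected at least 4 tab-separated columns")
    pos <- suppressWarnings(as.numeric(f[2]))
    rc <- suppressWarnings(as.numeric(f[3]))
    vc <- suppressWarnings(as.numeric(f[4]))
    if (is.na(pos) || pos <= 0 || pos != round(pos))
      stop("line ", i, ": malformed position '", f[2], "'")
    if (is.na(rc) || is.na(vc) || rc < 0 || vc < 0 ||
        rc != round(rc) || vc != round(vc))
      stop("line ", i, ": malformed read counts '", f[3], "', '", f[4], "'")
    data.frame(chrom = f[1], pos = as.integer(pos),
               ref_counts = as.integer(rc), var_counts = as.integer(vc),
               annotation = if (length(f) >= 6) f[6] else NA_character_)
  })
  df <- do.call(rbind, rows)
  depth <- df$ref_counts + df$var_counts
  df$vaf <- ifelse(depth > 0, df$var_counts / depth, NA_real_)
  df$sample <- sample_name
  df[, c("chrom", "pos", "ref_counts", "var_counts", "vaf",
         "annotation", "sample")]
}

#' Read a copy-number segment table
#'
#' Tab-separated chrom, start, stop, copy_number; 1-based inclusive.
#'
#' @param path File path.
#' @return Data frame of segments.
#' @export
read_cn_segments <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "stop", "copy_number"),
                          colClasses = c("character", "numeric", "numeric",
                                         "character"))
  cn <- suppressWarnings(as.numeric(df$copy_number))
  if (any(is.na(cn))) stop("non-numeric copy_number in ", path)
  df$copy_number <- cn
  if (any(df$start > df$stop))
    stop("segment with start > stop in ", path)
  if (any(df$copy_number < 0)) stop("negative copy_number in ", path)
  df
}

#' Read an exclusion-region table
#'
#' Tab-separated chrom, start, stop; 1-based inclusive.
#'
#' @param path File path.
#' @param label Region label (e.g. "LOH").
#' @return Data frame of intervals with a `label` column.
#' @export
read_region_file <- function(path, label = "LOH") {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "stop"),
                          colClasses = c("character", "numeric", "numeric"))
  if (any(df$start > df$stop)) stop("region with start > stop in ", path)
  df$label <- label
  df
}

## Interval lookup: value of the first covering segment, NA when uncovered.
lookup_segments <- function(chrom, pos, segments, value_col = "copy_number") {
  if (is.null(segments) || nrow(segments) == 0)
    return(rep(NA_real_, length(chrom)))
  vapply(seq_along(chrom), function(i) {
    hit <- which(segments$chrom == chrom[i] & segments$start <= pos[i] &
                   segments$stop >= pos[i])
    if (length(hit) == 0) NA_real_ else segments[[value_col]][hit[1]]
  }, numeric(1))
}

in_regions <- function(chrom, pos, regions) {
  if (is.null(regions) || nrow(regions) == 0)
    return(rep(FALSE, length(chrom)))
  vapply(seq_along(chrom), function(i) {
    any(regions$chrom == chrom[i] & regions$start <= pos[i] &
          regions$stop >= pos[i])
  }, logical(1))
}

#' Merge per-sample variant tables and filter to clusterable sites
#'
#' Variant identity is (chrom, pos). A site is retained only if, in every
#' sample, its total depth is at least `min_depth`, its copy number is
#' within `cn_tolerance` of 2, and it lies in no exclusion region. Sites
#' absent from a sample's table are excluded (reason `low-depth`). A site
#' not covered by any CN segment is treated as neutral unless `strict_cn`
#' is set. Exclusion reasons follow the fixed precedence low-depth,
#' cn-altered, loh, user.
#'
#' @param samples List of per-sample data frames from [read_variant_table()].
#' @param cn Optional list (per sample) of CN segment tables.
#' @param exclude Optional list (per sample) of exclusion-region tables.
#' @param min_depth Minimum depth in every sample (default 100; WES
#'   analyses typically relax this to 50).
#' @param cn_tolerance Allowed deviation of a segment mean from 2 to call a
#'   site copy-number neutral (default 0.25).
#' @param strict_cn Exclude sites not covered by any CN segment instead of
#'   assuming neutrality.
#' @return List with data frames `retained` and `excluded` (the latter with
#'   an `exclude_reason` column); both carry per-sample count/VAF/CN columns
#'   `ref_counts_s<j>`, `var_counts_s<j>`, `vaf_s<j>`, `cn_s<j>`.
#' @export
merge_and_filter <- function(samples, cn = NULL, exclude = NULL,
                             min_depth = 100, cn_tolerance = 0.25,
                             strict_cn = FALSE) {
  stopifnot(length(samples) >= 1)
  d <- length(samples)
  key <- unique(do.call(rbind, lapply(samples, function(s)
    s[, c("chrom", "pos")])))
  key <- key[order(key$chrom, key$pos), , drop = FALSE]
  rownames(key) <- NULL
  n <- nrow(key)
  df <- key
  df$annotation <- NA_character_
  reason <- rep(NA_character_, n)
  set_reason <- function(reason, bad, code)
    ifelse(is.na(reason) & bad, code, reason)

  depth_ok <- cn_ok <- loh_ok <- matrix(TRUE, n, d)
  for (j in seq_len(d)) {
    s <- samples[[j]]
    idx <- match(paste(key$chrom, key$pos), paste(s$chrom, s$pos))
    rc <- s$ref_counts[idx]; vc <- s$var_counts[idx]
    present <- !is.na(idx)
    rc[!present] <- NA_integer_; vc[!present] <- NA_integer_
    depth <- rc + vc
    df[[paste0("ref_counts_s", j)]] <- rc
    df[[paste0("var_counts_s", j)]] <- vc
    df[[paste0("vaf_s", j)]] <- ifelse(!is.na(depth) & depth > 0,
                                       vc / depth, NA_real_)
    ann <- s$annotation[idx]
    df$annotation <- ifelse(is.na(df$annotation), ann, df$annotation)
    depth_ok[, j] <- present & !is.na(depth) & depth >= min_depth
    cnv <- lookup_segments(key$chrom, key$pos,
                           if (is.null(cn)) NULL else cn[[j]])
    uncovered <- is.na(cnv)
    if (any(uncovered) && !is.null(cn) && !strict_cn)
      message(sum(uncovered), " site(s) uncovered by CN segments in sample ",
              j, "; treated as copy-number neutral")
    df[[paste0("cn_s", j)]] <- ifelse(uncovered, if (strict_cn) NA_real_ else 2,
                                      cnv)
    cn_ok[, j] <- if (strict_cn) !uncovered & abs(cnv - 2) <= cn_tolerance
                  else uncovered | abs(cnv - 2) <= cn_tolerance
    loh_ok[, j] <- !in_regions(key$chrom, key$pos,
                               if (is.null(exclude)) NULL else exclude[[j]])
  }
  reason <- set_reason(reason, !apply(depth_ok, 1, all), "low-depth")
  reason <- set_reason(reason, !apply(cn_ok, 1, all), "cn-altered")
  reason <- set_reason(reason, !apply(loh_ok, 1, all), "loh")
  keep <- is.na(reason)
  if (!any(keep))
    stop("zero variants retained; consider lowering min_depth (currently ",
         min_depth, ")")
  excluded <- df[!keep, , drop = FALSE]
  excluded$exclude_reason <- reason[!keep]
  rownames(excluded) <- NULL
  retained <- df[keep, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, excluded = excluded)
}

#' Extract the VAF matrix from a merged variant table
#'
#' @param variants Data frame from [merge_and_filter()] (`retained`).
#' @return N x D numeric matrix of VAFs.
#' @export
vaf_matrix <- function(variants) {
  cols <- grep("^vaf_s[0-9]+$", names(variants), value = TRUE)
  as.matrix(variants[, cols, drop = FALSE])
}

#' Extract count matrices from a merged variant table
#'
#' @param variants Data frame from [merge_and_filter()] (`retained`).
#' @return List with N x D matrices `var_counts` and `ref_counts`.
#' @export
count_matrices <- function(variants) {
  vc <- grep("^var_counts_s[0-9]+$", names(variants), value = TRUE)
  rc <- grep("^ref_counts_s[0-9]+$", names(variants), value = TRUE)
  list(var_counts = as.matrix(variants[, vc, drop = FALSE]),
       ref_counts = as.matrix(variants[, rc, drop = FALSE]))
}
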