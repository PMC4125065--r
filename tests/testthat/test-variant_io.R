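test_that("variant tables parse, recompute VAFs, and preserve order", {
  f <- make_variant_file(c(100, 500), c(53, 80), c(47, 0))
  v <- read_variant_table(f, "s1")
  expect_equal(v$vaf, c(0.47, 0))
  expect_equal(v$pos, c(100L, 500L))
  expect_equal(v$sample, rep("s1", 2))

  fh <- make_variant_file(c(100, 500), c(53, 80), c(47, 0), header = TRUE)
  expect_equal(read_variant_table(fh, "s1")$vaf, c(0.47, 0))
})

test_that("malformed variant rows are rejected with their line number", {
  f <- write_tsv_lines(c("1\t100\t53\t47", "1\tabc\t10\t10", "1\t300\t5\t5"))
  expect_error(read_variant_table(f), "line 2")
  f2 <- write_tsv_lines(c("1\t100\t5.5\t47"))
  expect_error(read_variant_table(f2), "line 1")
  f3 <- write_tsv_lines(character(0))
  expect_error(read_variant_table(f3), "empty")
})

test_that("copy-number segments parse and invalid intervals error", {
  f <- write_tsv_lines(c("1\t1\t1000\t2.0", "3\t1\t198022430\t3.1"))
  seg <- read_cn_segments(f)
  expect_equal(seg$copy_number, c(2.0, 3.1))
  expect_error(read_cn_segments(write_tsv_lines("1\t500\t100\t2.0")),
               "start > stop")
  expect_error(read_cn_segments(write_tsv_lines("1\t1\t100\tx")),
               "non-numeric")
})

test_that("merge_and_filter applies depth, CN, and LOH filters in order", {
  fx <- ten_site_fixture()
  s <- read_variant_table(fx$variants, "tumor")
  res <- merge_and_filter(list(s), exclude = list(read_region_file(fx$loh)),
                          min_depth = 50)
  expect_equal(nrow(res$retained), 5L)
  expect_setequal(res$excluded$exclude_reason,
                  c("low-depth", "loh"))
  expect_equal(sum(res$excluded$exclude_reason == "low-depth"), 3L)
  expect_equal(sum(res$excluded$exclude_reason == "loh"), 2L)
  # retained + excluded partition the input sites
  expect_equal(sort(c(res$retained$pos, res$excluded$pos)), sort(fx$pos))
  # VAFs equal v/(v+r) exactly
  i <- match(res$retained$pos, fx$pos)
  expect_identical(res$retained$vaf_s1,
                   fx$var[i] / (fx$var[i] + fx$ref[i]))
})

test_that("copy-number altered sites are excluded with reason cn-altered", {
  s <- read_variant_table(make_variant_file(c(100, 5000), c(100, 100),
                                            c(88, 90)), "t")
  cn <- read_cn_segments(write_tsv_lines(c("1\t1\t1000\t2.0",
                                           "1\t4000\t6000\t3.0")))
  res <- merge_and_filter(list(s), cn = list(cn), min_depth = 50)
  expect_equal(res$retained$pos, 100L)
  expect_equal(res$excluded$exclude_reason, "cn-altered")
  # strict mode excludes uncovered sites too
  cn2 <- read_cn_segments(write_tsv_lines("1\t4000\t6000\t3.0"))
  res2 <- tryCatch(merge_and_filter(list(s), cn = list(cn2), min_depth = 50,
                                    strict_cn = TRUE),
                   error = function(e) e)
  expect_s3_class(res2, "error")  # zero retained
})

test_that("sites absent from one sample are excluded as low-depth", {
  s1 <- read_variant_table(make_variant_file(c(100, 200), c(100, 100),
                                             c(90, 95)), "a")
  s2 <- read_variant_table(make_variant_file(100, 110, 80), "b")
  res <- merge_and_filter(list(s1, s2), min_depth = 50)
  expect_equal(res$retained$pos, 100L)
  expect_equal(res$excluded$pos, 200L)
  expect_equal(res$excluded$exclude_reason, "low-depth")
})

test_that("filtering is idempotent on its own retained output", {
  fx <- ten_site_fixture()
  s <- read_variant_table(fx$variants, "t")
  excl <- list(read_region_file(fx$loh))
  r1 <- merge_and_filter(list(s), exclude = excl, min_depth = 50)
  s_again <- r1$retained
  s_again <- data.frame(chrom = s_again$chrom, pos = s_again$pos,
                        ref_counts = s_again$ref_counts_s1,
                        var_counts = s_again$var_counts_s1,
                        vaf = s_again$vaf_s1, annotation = NA, sample = "t")
  r2 <- merge_and_filter(list(s_again), exclude = excl, min_depth = 50)
  expect_equal(r2$retained$pos, r1$retained$pos)
  expect_equal(nrow(r2$excluded), 0L)
})

test_that("zero retained variants gives an actionable error", {
  s <- read_variant_table(make_variant_file(100, 10, 10), "t")
  expect_error(merge_and_filter(list(s), min_depth = 100), "min_depth")
})

test_that("boundary VAFs are shifted into the open unit interval", {
  eps <- .Machine$double.eps
  expect_gt(clamp_vafs(0), 0)
  expect_equal(clamp_vafs(0), eps)
  expect_equal(clamp_vafs(1), 1 - eps)
  expect_identical(clamp_vafs(0.47), 0.47)
  expect_equal(clamp_vafs(c(0, 0.25, 1)), c(eps, 0.25, 1 - eps))
})
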