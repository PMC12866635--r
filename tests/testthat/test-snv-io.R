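test_that("SNV identifiers parse, format and round-trip in both dialects", {
  k <- parse_snv_id("17:48895725:C>T")
  expect_equal(k$chrom, "17")
  expect_equal(k$pos, 48895725L)
  expect_equal(k$ref, "C")
  expect_equal(k$alt, "T")
  expect_equal(format_snv_id(k), "17:48895725:C>T")
  # underscore dialect normalizes to the same key
  expect_equal(parse_snv_id("Y:2865219_C>T")$snv_id, "Y:2865219:C>T")
  # parse-then-format is the identity on canonical strings
  ids <- c("1:1:A>G", "chrX:123:G>C", "17:48895725:C>T")
  expect_equal(format_snv_id(parse_snv_id(ids)), ids)
  expect_error(parse_snv_id("Y:2865219:C>C"), "differ")
  expect_error(parse_snv_id("17:48895725"), "unparseable")
  expect_error(make_snv_key("1", 0, "A", "C"), "positive")
})

test_that("SCReadCounts tables load with zero-coverage rows dropped", {
  path <- write_tsv_lines(c(
    "CHROM\tPOS\tREF\tALT\tReadGroup\tSNVCount\tRefCount\tExtra",
    "17\t48895725\tC\tT\tAAAC-1\t2\t3\tx",
    "17\t48895725\tC\tT\tAAAG-1\t0\t5\tx",
    "1\t100\tA\tG\tAAAC-1\t0\t0\tx",
    "Y\t2865219\tC\tT\tTTGA-1\t1\t9\tx"))
  expect_message(tab <- read_screadcounts(path), "1 row")
  expect_s3_class(tab, "snv_table")
  expect_equal(nrow(tab), 3L)
  expect_equal(attr(tab, "n_dropped_zero"), 1L)
  r <- tab[tab$barcode == "AAAC-1" & tab$chrom == "17", ]
  expect_equal(r$n_var, 2L)
  expect_equal(r$n_ref, 3L)
  # conservation: dropped + retained = data rows
  expect_equal(attr(tab, "n_dropped_zero") + nrow(tab), 4L)
})

test_that("header-only and malformed SCReadCounts files behave per contract", {
  empty <- write_tsv_lines("CHROM\tPOS\tREF\tALT\tReadGroup\tSNVCount\tRefCount")
  tab <- read_screadcounts(empty)
  expect_equal(nrow(tab), 0L)

  missing <- write_tsv_lines(c("CHROM\tPOS\tREF\tALT\tReadGroup\tSNVCount",
                               "17\t1\tC\tT\tA-1\t2"))
  expect_error(read_screadcounts(missing), "n_ref")

  badcount <- write_tsv_lines(c(
    "CHROM\tPOS\tREF\tALT\tReadGroup\tSNVCount\tRefCount",
    "17\t10\tC\tT\tA-1\t2\t3",
    "17\t11\tC\tT\tA-1\ttwo\t3"))
  expect_error(read_screadcounts(badcount), "line 3")

  badpos <- write_tsv_lines(c(
    "CHROM\tPOS\tREF\tALT\tReadGroup\tSNVCount\tRefCount",
    "17\t-4\tC\tT\tA-1\t2\t3"))
  expect_error(read_screadcounts(badpos), "position")
})

test_that("duplicate (snv, barcode) rows error by default and sum on request", {
  path <- write_tsv_lines(c(
    "CHROM\tPOS\tREF\tALT\tReadGroup\tSNVCount\tRefCount",
    "17\t10\tC\tT\tA-1\t2\t3",
    "17\t10\tC\tT\tA-1\t1\t1"))
  expect_error(read_screadcounts(path), "duplicate")
  tab <- read_screadcounts(path, dedup_policy = "sum")
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$n_var, 3L)
  expect_equal(tab$n_ref, 4L)
})

test_that("the simplified dialect parses and VAF follows", {
  path <- write_tsv_lines(c("SNV_ID\tBarcode\tN_VAR\tN_REF",
                            "Y:2865219:C>T\tTTGA-1\t1\t9",
                            "Y:2865219_C>G\tTTGA-1\t2\t2"))
  tab <- read_simple_table(path)
  expect_equal(nrow(tab), 2L)
  expect_equal(vaf(tab$n_var[1], tab$n_ref[1]), 0.1)
  expect_equal(tab$snv_id[2], "Y:2865219:C>G")

  bad <- write_tsv_lines(c("SNV_ID\tBarcode\tN_VAR\tN_REF",
                           "Y:2865219:C>C\tTTGA-1\t1\t9"))
  expect_error(read_simple_table(bad), "differ")
})

test_that("simplified-dialect write/read restores records exactly and is order-insensitive", {
  m <- random_cell_snv_matrix(12, 6, seed = 7)
  set.seed(8)
  obs <- Matrix::which(observed_matrix(m), arr.ind = TRUE)
  rec <- cbind(m$snvs[obs[, 2], , drop = FALSE],
               data.frame(barcode = m$cells[obs[, 1]],
                          n_var = as.integer(m$var_counts[obs]),
                          n_ref = as.integer(m$ref_counts[obs])))
  tab <- cellsnv:::new_snv_table(rec, "t", list(path = NA, dialect = "t"))
  f <- tempfile(fileext = ".tsv")
  write_snv_table(tab, f)
  back <- read_simple_table(f)
  key <- function(t) {
    d <- as.data.frame(t)[, c("snv_id", "barcode", "n_var", "n_ref")]
    d[order(d$snv_id, d$barcode), ]
  }
  expect_equal(key(back), key(tab), ignore_attr = TRUE)

  # permuting input rows yields an equal record set
  lines <- readLines(f)
  perm <- c(lines[1], sample(lines[-1]))
  f2 <- write_tsv_lines(perm)
  expect_equal(key(read_simple_table(f2)), key(back), ignore_attr = TRUE)
})

test_that("MatrixMarket triplet directories load with sums preserved", {
  dir <- tempfile()
  dir.create(dir)
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 4", "1 1 5", "2 1 1", "3 2 2", "1 2 7"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("g1", "g2", "g3"), file.path(dir, "features.tsv"))
  writeLines(c("AAAC-1", "TTGA-1"), file.path(dir, "barcodes.tsv"))
  m <- read_expression_matrix(dir)
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(length(m@x), 4L)
  expect_equal(unname(Matrix::rowSums(m)), c(12, 1, 2))
  expect_equal(unname(Matrix::colSums(m)), c(6, 9))
  expect_equal(colnames(m), c("AAAC-1", "TTGA-1"))

  # sidecar mismatch
  writeLines(c("AAAC-1", "TTGA-1", "CCCT-1"), file.path(dir, "barcodes.tsv"))
  expect_error(read_expression_matrix(dir), "3 x 2.*3 barcodes")
})

test_that("dense TSV expression input and the all-zero case load", {
  f <- write_tsv_lines(c("gene\tAAAC-1\tTTGA-1", "g1\t0\t0", "g2\t0\t0"))
  expect_message(m <- read_expression_matrix(f, format = "dense_tsv"),
                 "all zero")
  expect_equal(dim(m), c(2L, 2L))
  f2 <- write_tsv_lines(c("gene\tA-1", "g1\t2.5"))
  expect_error(read_expression_matrix(f2, format = "dense_tsv"), "integer")
})

test_that("barcode harmonization applies the suffix policy", {
  h <- harmonize_barcodes(c("AAAC", "TTGA"), c("AAAC-1", "TTGA-1", "CCCT-1"))
  expect_setequal(h$matched, c("AAAC", "TTGA"))
  expect_equal(h$n_unmatched_expr, 1L)
  expect_equal(h$n_unmatched_snv, 0L)

  ident <- harmonize_barcodes(c("A-1", "B-1"), c("A-1", "B-1"))
  expect_equal(ident$policy_applied, "keep")
  expect_equal(ident$n_unmatched_snv + ident$n_unmatched_expr, 0L)

  expect_error(harmonize_barcodes(c("AAAA"), c("CCCC"), "keep"), "no barcodes")
  expect_warning(harmonize_barcodes(c("A-1", "B-1", "C-1", "D-1"), c("A-1")),
                 "50%")
})

test_that("per-cell metric TSVs round-trip exactly, NA as empty field", {
  met <- data.frame(barcode = c("A-1", "B-1"), n_snvs = c(2L, 0L),
                    total_nvar = c(5L, 0L), total_nref = c(9L, 0L),
                    total_vaf = c(5 / 14, NA), mean_vaf = c(0.475, NA),
                    median_vaf = c(0.475, NA), stringsAsFactors = FALSE)
  class(met) <- c("cell_metrics", "data.frame")
  f <- tempfile(fileext = ".tsv")
  write_metrics_table(met, f)
  txt <- readLines(f)
  expect_false(any(grepl("NA|NaN", txt)))
  expect_match(txt[3], "\t\t")  # undefined ratios serialize as empty fields
  back <- read_metrics_table(f)
  expect_identical(back$total_vaf, met$total_vaf)
  expect_identical(back$mean_vaf, met$mean_vaf)
  expect_identical(back$n_snvs, met$n_snvs)
  expect_identical(back$barcode, met$barcode)
})
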