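make_two_locus_cell <- function() {
  keys <- parse_snv_id(c("1:100:A>G", "2:200:C>T", "3:300:G>A"))
  rec <- cbind(keys[c(1, 2, 1), ],
               data.frame(barcode = c("A-1", "A-1", "B-1"),
                          n_var = c(2L, 3L, 0L), n_ref = c(8L, 1L, 6L)))
  tab <- cellsnv:::new_snv_table(rec, "t", list(path = NA, dialect = "t"))
  suppressMessages(build_snv_matrix(tab, c("A-1", "B-1", "C-1")))
}

test_that("per-cell metrics follow the set-level formulas", {
  m <- make_two_locus_cell()
  met <- compute_cell_metrics(m)
  a <- met[met$barcode == "A-1", ]
  # cell covering (2,8) and (3,1): totals and the three VAF summaries
  expect_equal(a$n_snvs, 2L)
  expect_equal(a$total_nvar, 5L)
  expect_equal(a$total_nref, 9L)
  expect_equal(a$total_vaf, 5 / 14)
  expect_equal(a$mean_vaf, (0.2 + 0.75) / 2)
  expect_equal(a$median_vaf, 0.475)
  # cell covering one reference-only locus: zero, defined
  b <- met[met$barcode == "B-1", ]
  expect_equal(b$n_snvs, 0L)
  expect_equal(b$total_vaf, 0)
  expect_equal(b$mean_vaf, 0)
  expect_equal(b$median_vaf, 0)
  # cell covering nothing: totals defined zero, ratios undefined
  c_ <- met[met$barcode == "C-1", ]
  expect_equal(c_$n_snvs, 0L)
  expect_equal(c_$total_nvar, 0L)
  expect_true(is.na(c_$total_vaf) && is.na(c_$mean_vaf) && is.na(c_$median_vaf))

  expect_error(compute_cell_metrics(m, character()), "empty")
  expect_error(compute_cell_metrics(m, "9:9:A>C"), "absent")
})

test_that("total VAF is bounded by the per-locus extremes and selection collapses", {
  for (seed in 1:5) {
    m <- random_cell_snv_matrix(25, 8, seed = seed + 200)
    met <- compute_cell_metrics(m)
    vafs <- vaf_matrix(m)
    for (ci in seq_along(m$cells)) {
      row <- vafs[ci, ]
      if (all(is.na(row))) next
      expect_gte(met$total_vaf[ci], min(row, na.rm = TRUE) - 1e-12)
      expect_lte(met$total_vaf[ci], max(row, na.rm = TRUE) + 1e-12)
    }
    # restricting to one SNV makes all three summaries that SNV's VAF
    one <- m$snvs$snv_id[1]
    m1 <- compute_cell_metrics(m, selection = one)
    covered <- !is.na(vafs[, 1])
    expect_equal(m1$total_vaf[covered], unname(vafs[covered, 1]))
    expect_equal(m1$mean_vaf[covered], unname(vafs[covered, 1]))
    expect_equal(m1$median_vaf[covered], unname(vafs[covered, 1]))
  }
})

test_that("vectorized metrics equal the brute-force loop oracle", {
  for (seed in 1:6) {
    m <- random_cell_snv_matrix(sample(5:40, 1), sample(3:15, 1),
                                seed = seed + 300)
    sel <- sample(m$snvs$snv_id, max(2, nrow(m$snvs) %/% 2))
    got <- compute_cell_metrics(m, sel)
    want <- oracle_cell_metrics(m, sel)
    expect_equal(as.data.frame(got), want, tolerance = 1e-12)
  }
})

test_that("histogram binning is left-closed with a right-closed final bin", {
  h <- histogram_data(c(0, 0.5, 1), bins = 2)
  expect_equal(h$counts, c(1L, 2L))
  expect_equal(h$edges, c(0, 0.5, 1))
  expect_equal(histogram_data(numeric(), 4)$counts, rep(0L, 4))
  expect_equal(sum(histogram_data(rep(0.37, 9), 50)$counts), 9L)
  expect_error(histogram_data(1:3, 0), "bins")
  # count metrics get integer-aligned edges
  hc <- histogram_data(c(0, 3, 7), bins = 4, integer_align = TRUE)
  expect_true(all(hc$edges == floor(hc$edges)))
  expect_equal(sum(hc$counts), 3L)
  # NAs are not counted
  expect_equal(sum(histogram_data(c(0.1, NA, 0.9), 10)$counts), 2L)
})

test_that("group summaries partition cells and respect undefined metrics", {
  met <- data.frame(barcode = sprintf("B%d-1", 1:5),
                    n_snvs = c(1L, 2L, 0L, 1L, 3L),
                    total_nvar = c(1L, 4L, 0L, 2L, 5L),
                    total_nref = c(3L, 2L, 0L, 1L, 0L),
                    total_vaf = c(0.25, 2 / 3, NA, 2 / 3, 1),
                    mean_vaf = c(0.2, 0.4, NA, 0.6, 1),
                    median_vaf = c(0.2, 0.4, NA, 0.6, 1))
  class(met) <- c("cell_metrics", "data.frame")
  s <- summarize_by_group(met, c("g1", "g1", "g1", "g2", "g2"))
  expect_equal(sort(unique(s$summary$group)), c("g1", "g2"))
  n_per_group <- unique(s$summary[, c("group", "n_cells")])
  expect_equal(n_per_group$n_cells[order(n_per_group$group)], c(3L, 2L))
  # mean/median over a simple group
  row <- s$summary[s$summary$group == "g2" & s$summary$metric == "mean_vaf", ]
  expect_equal(row$mean, 0.8)
  expect_equal(row$median, 0.8)
  # undefined values are excluded from histograms but n recorded
  g1_mean <- s$summary[s$summary$group == "g1" & s$summary$metric == "mean_vaf", ]
  expect_equal(g1_mean$n_cells, 3L)
  expect_equal(g1_mean$n_defined, 2L)
  expect_equal(sum(s$histograms$g1$mean_vaf$counts), 2L)

  # unlabeled cells are excluded and counted; all-unlabeled errors
  s2 <- summarize_by_group(met, c("g1", NA, NA, "g2", "g2"))
  expect_equal(s2$n_unlabeled, 2L)
  expect_error(summarize_by_group(met, rep(NA, 5)), "unlabeled")
  expect_error(summarize_by_group(met, c("a", "b")), "align")

  # hand check of simple summary values
  s3 <- summarize_by_group(
    transform(met, mean_vaf = c(0.2, 0.4, 0.6, NA, NA)), rep("g", 5))
  row3 <- s3$summary[s3$summary$metric == "mean_vaf", ]
  expect_equal(row3$mean, 0.4)
  expect_equal(row3$median, 0.4)
})
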