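test_that("build_snv_matrix lays out cells x SNVs with the observed mask", {
  keys <- parse_snv_id(c("17:48895725:C>T", "Y:2865219:C>T"))
  rec <- cbind(keys[c(1, 1, 2), ],
               data.frame(barcode = c("A-1", "B-1", "A-1"),
                          n_var = c(2L, 0L, 1L), n_ref = c(3L, 5L, 9L)))
  tab <- cellsnv:::new_snv_table(rec, "t", list(path = NA, dialect = "t"))
  m <- build_snv_matrix(tab, c("A-1", "B-1", "C-1", "D-1"))
  expect_equal(dim(m), c(4L, 2L))
  expect_equal(sum(observed_matrix(m)), 3)
  expect_equal(m$var_counts["A-1", "17:48895725:C>T"], 2)
  # unobserved entries are structural zeros
  expect_equal(m$var_counts["C-1", 1], 0)

  # records outside the universe are dropped with a message
  expect_message(m2 <- build_snv_matrix(tab, c("A-1", "C-1")), "1 record")
  expect_equal(m2$n_dropped_outside, 1L)
  expect_error(suppressMessages(build_snv_matrix(tab, c("Z-1"))), "no SNV records")
})

test_that("vaf distinguishes zero from undefined and rejects negatives", {
  expect_equal(vaf(5, 5), 0.5)
  expect_equal(vaf(0, 7), 0)
  expect_true(is.na(vaf(0, 0)))
  expect_equal(vaf(c(5, 0, 0), c(5, 7, 0)), c(0.5, 0, NA))
  expect_error(vaf(-1, 2), "nonnegative")
})

test_that("allelic states are a pure function of the two counts", {
  expect_equal(as.character(classify_allelic_state(0, 0)), "no_coverage")
  expect_equal(as.character(classify_allelic_state(0, 4)), "ref_only")
  expect_equal(as.character(classify_allelic_state(3, 0)), "var_only")
  expect_equal(as.character(classify_allelic_state(2, 8)), "biallelic")
})

test_that("vaf and allelic state obey their joint law on random counts", {
  set.seed(42)
  nv <- stats::rpois(500, 1)
  nr <- stats::rpois(500, 1)
  v <- vaf(nv, nr)
  s <- classify_allelic_state(nv, nr)
  expect_equal(is.na(v), s == "no_coverage")
  expect_equal(!is.na(v) & v == 1 & nv >= 1, s == "var_only")
  expect_equal(!is.na(v) & v == 0 & nr >= 1, s == "ref_only")
})

test_that("cell-support filter keeps SNVs observed in at least the threshold", {
  m <- matrix_with_supports(c(25, 19, 3, 40, 20))
  f <- apply_filters(m, filter_spec(min_cells_per_snv = 20))
  # "fewer than 20 cells" excluded: supports 25, 40 and 20 survive
  expect_equal(f$report$snvs_kept, 3L)
  expect_equal(f$report$snvs_removed_min_cells, 2L)
  kept_support <- Matrix::colSums(observed_matrix(f$matrix))
  expect_setequal(unname(kept_support), c(25, 40, 20))
})

test_that("depth filter marks shallow entries unobserved", {
  m <- matrix_with_supports(c(5, 5), n_var = 1L, n_ref = 1L)  # depth 2 entries
  f <- apply_filters(m, filter_spec(min_depth = 3))
  expect_equal(sum(observed_matrix(f$matrix)), 0)
  expect_equal(f$report$entries_removed_min_depth, 10)
})

test_that("filters are the identity at (0,0), idempotent and monotone", {
  for (seed in 1:5) {
    m <- random_cell_snv_matrix(30, 12, seed = seed)
    id <- apply_filters(m, filter_spec(0, 0))
    expect_equal(id$matrix$var_counts, m$var_counts)
    expect_equal(id$matrix$ref_counts, m$ref_counts)

    spec <- filter_spec(min_cells_per_snv = 5, min_depth = 3)
    f1 <- apply_filters(m, spec)
    f2 <- apply_filters(f1$matrix, spec)
    expect_equal(f2$matrix$var_counts, f1$matrix$var_counts)
    expect_equal(f2$report$entries_removed_min_depth, 0)
    expect_equal(f2$report$snvs_removed_min_cells, 0L)

    # monotone: observed set shrinks, never grows
    obs_in <- Matrix::which(observed_matrix(m), arr.ind = TRUE)
    obs_out <- Matrix::which(observed_matrix(f1$matrix), arr.ind = TRUE)
    in_keys <- paste(m$cells[obs_in[, 1]], m$snvs$snv_id[obs_in[, 2]])
    out_keys <- paste(f1$matrix$cells[obs_out[, 1]],
                      f1$matrix$snvs$snv_id[obs_out[, 2]])
    expect_true(all(out_keys %in% in_keys))
  }
})

test_that("filtering equals the brute-force per-entry oracle", {
  for (seed in 1:5) {
    m <- random_cell_snv_matrix(25, 10, seed = seed + 50)
    spec <- filter_spec(min_cells_per_snv = 4, min_depth = 3)
    f <- suppressWarnings(apply_filters(m, spec))
    o <- oracle_apply_filters(m, spec)
    expect_equal(f$matrix$snvs$snv_id, o$kept)
    expect_equal(unname(as.matrix(f$matrix$var_counts)), unname(o$var))
    expect_equal(unname(as.matrix(f$matrix$ref_counts)), unname(o$ref))
  }
})

test_that("per-SNV profiles tally a column by hand", {
  keys <- cellsnv:::.random_keys(1)
  rec <- cbind(keys[rep(1, 3), ],
               data.frame(barcode = c("A-1", "B-1", "C-1"),
                          n_var = c(0L, 3L, 1L), n_ref = c(2L, 0L, 1L)))
  tab <- cellsnv:::new_snv_table(rec, "t", list(path = NA, dialect = "t"))
  m <- build_snv_matrix(tab, sprintf("%s-1", LETTERS[1:5]))
  p <- per_snv_profile(m, keys$snv_id)
  expect_equal(p$n_cells_covered, 3)
  expect_equal(p$n_ref_only, 1)
  expect_equal(p$n_var_only, 1)
  expect_equal(p$n_biallelic, 1)
  expect_setequal(p$vaf_values, c(0, 1, 0.5))
  expect_equal(p$median_vaf_covered, 0.5)
  expect_error(per_snv_profile(m, "1:1:A>C"), "unknown SNV")
})

test_that("a single variant-only entry yields a pure profile", {
  p <- profile_from_counts(list(c(4L, 0L)))
  expect_equal(p$n_var_only, 1)
  expect_equal(p$median_vaf_covered, 1.0)
  expect_equal(p$n_cells_covered, 1)
})

test_that("profiles match the brute-force oracle and tallies partition coverage", {
  for (seed in 1:5) {
    m <- random_cell_snv_matrix(30, 10, seed = seed + 100)
    total_obs <- 0
    for (id in m$snvs$snv_id) {
      p <- per_snv_profile(m, id)
      o <- oracle_snv_profile(m, id)
      expect_equal(p[names(o)], o, ignore_attr = TRUE)
      expect_equal(p$n_cells_covered, p$n_ref_only + p$n_var_only + p$n_biallelic)
      expect_equal(length(p$vaf_values), p$n_cells_covered)
      total_obs <- total_obs + p$n_cells_covered
    }
    expect_equal(total_obs, sum(observed_matrix(m)))
  }
})
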