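# Builders for small in-code fixtures shared across the suite.

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# A random cells x SNVs matrix built through the package's own loaders.
random_cell_snv_matrix <- function(n_cells, n_snvs, seed, density = 0.4) {
  set.seed(seed)
  cells <- sprintf("BC%04d-1", seq_len(n_cells))
  keys <- cellsnv:::.random_keys(n_snvs)
  obs <- which(matrix(stats::runif(n_cells * n_snvs) < density,
                      n_cells, n_snvs), arr.ind = TRUE)
  if (nrow(obs) == 0) obs <- cbind(1L, 1L)
  n_var <- stats::rpois(nrow(obs), 1.2)
  n_ref <- stats::rpois(nrow(obs), 2.0)
  zero <- n_var + n_ref == 0
  n_ref[zero] <- 1L
  rec <- cbind(keys[obs[, 2], , drop = FALSE],
               data.frame(barcode = cells[obs[, 1]],
                          n_var = as.integer(n_var),
                          n_ref = as.integer(n_ref),
                          stringsAsFactors = FALSE))
  table <- cellsnv:::new_snv_table(rec, "test", list(path = NA, dialect = "test"))
  suppressMessages(build_snv_matrix(table, cells))
}

# Build a matrix where SNV j is observed in exactly supports[j] cells.
matrix_with_supports <- function(supports, n_cells = max(supports),
                                 n_var = 1L, n_ref = 1L) {
  cells <- sprintf("BC%04d-1", seq_len(n_cells))
  keys <- cellsnv:::.random_keys(length(supports))
  rec <- do.call(rbind, lapply(seq_along(supports), function(j) {
    cbind(keys[rep(j, supports[j]), , drop = FALSE],
          data.frame(barcode = cells[seq_len(supports[j])],
                     n_var = n_var, n_ref = n_ref,
                     stringsAsFactors = FALSE))
  }))
  table <- cellsnv:::new_snv_table(rec, "test", list(path = NA, dialect = "test"))
  suppressMessages(build_snv_matrix(table, cells))
}

# A hand-specified profile for the origin rules: counts is a list of
# c(n_var, n_ref) per covered cell padded to n_cells total cells.
profile_from_counts <- function(counts, n_cells = length(counts) + 5) {
  cells <- sprintf("BC%04d-1", seq_len(n_cells))
  keys <- cellsnv:::.random_keys(2)  # a second SNV keeps the matrix nonempty rows
  rec <- do.call(rbind, lapply(seq_along(counts), function(i) {
    cbind(keys[1, , drop = FALSE],
          data.frame(barcode = cells[i], n_var = counts[[i]][1],
                     n_ref = counts[[i]][2], stringsAsFactors = FALSE))
  }))
  rec <- rbind(rec, cbind(keys[2, , drop = FALSE],
                          data.frame(barcode = cells[1], n_var = 1L, n_ref = 1L,
                                     stringsAsFactors = FALSE)))
  table <- cellsnv:::new_snv_table(rec, "test", list(path = NA, dialect = "test"))
  m <- suppressMessages(build_snv_matrix(table, cells))
  per_snv_profile(m, keys$snv_id[1])
}
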