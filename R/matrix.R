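#' Expressed variant allele fraction (VAF_RNA)
#'
#' `VAF_RNA = N_VAR / (N_VAR + N_REF)`, computed from RNA reads at a locus.
#' When no reads cover the locus the fraction is undefined (`NA`), which is
#' deliberately distinct from 0: a covered locus with no variant reads is a
#' negative signal (the reference allele is expressed), while an uncovered
#' locus carries no signal at all.
#'
#' @param n_var,n_ref nonnegative integer vectors of variant and reference
#'   read counts (recycled to a common length).
#' @return numeric vector in `[0, 1]`, `NA` where `n_var + n_ref == 0`.
#' @examples
#' vaf(c(5, 0, 0), c(5, 7, 0))  # 0.5, 0, NA
#' @export
vaf <- function(n_var, n_ref) {
  if (any(n_var < 0, na.rm = TRUE) || any(n_ref < 0, na.rm = TRUE)) {
    stop("read counts must be nonnegative")
  }
  depth <- n_var + n_ref
  ifelse(depth >= 1, n_var / depth, NA_real_)
}

#' Per-(cell, SNV) allelic state
#'
#' A pure function of the two read counts: `no_coverage` (0, 0),
#' `ref_only` (0, >0), `var_only` (>0, 0), `biallelic` (>0, >0).
#'
#' @inheritParams vaf
#' @return factor with levels `no_coverage`, `ref_only`, `var_only`,
#'   `biallelic`.
#' @export
classify_allelic_state <- function(n_var, n_ref) {
  if (any(n_var < 0, na.rm = TRUE) || any(n_ref < 0, na.rm = TRUE)) {
    stop("read counts must be nonnegative")
  }
  lv <- c("no_coverage", "ref_only", "var_only", "biallelic")
  idx <- 1L + (n_ref > 0) + 2L * (n_var > 0)
  factor(lv[idx], levels = lv)
}

new_cell_snv_matrix <- function(var_counts, ref_counts, cells, snvs,
                                n_dropped_outside = 0L) {
  stopifnot(identical(dim(var_counts), dim(ref_counts)))
  structure(list(var_counts = var_counts, ref_counts = ref_counts,
                 cells = cells, snvs = snvs,
                 n_dropped_outside = as.integer(n_dropped_outside)),
            class = "cell_snv_matrix")
}

#' @exportS3Method print cell_snv_matrix
print.cell_snv_matrix <- function(x, ...) {
  obs <- observed_matrix(x)
  cat("<cell_snv_matrix> ", length(x$cells), " cells x ", nrow(x$snvs),
      " SNVs, ", sum(obs), " observed entries\n", sep = "")
  invisible(x)
}

#' @export
dim.cell_snv_matrix <- function(x) c(length(x$cells), nrow(x$snvs))

#' Build the layered cells-by-SNVs matrix
#'
#' Rows are the full cell universe (typically the expression-matrix
#' barcodes, after [harmonize_barcodes()]), columns the distinct SNV keys
#' of the table. Three aligned layers are maintained: variant counts,
#' reference counts, and the observed mask (`TRUE` exactly where a loaded
#' record existed, i.e. where `n_var + n_ref >= 1`). Unobserved entries
#' hold structural zeros in both count layers, never a sentinel, so the
#' three-way no-signal / negative-signal / variant-signal distinction is
#' preserved throughout.
#'
#' @param table an `snv_table`.
#' @param cell_universe character vector of barcodes defining the rows.
#'   Records whose barcode is outside the universe are dropped with a
#'   message and counted.
#' @return A `cell_snv_matrix`: list with sparse `var_counts` and
#'   `ref_counts` (cells x SNVs, `dgCMatrix`), `cells`, `snvs` (key
#'   data.frame) and `n_dropped_outside`.
#' @export
build_snv_matrix <- function(table, cell_universe) {
  cell_universe <- as.character(cell_universe)
  stopifnot(!anyDuplicated(cell_universe))
  inside <- table$barcode %in% cell_universe
  n_out <- sum(!inside)
  if (n_out > 0) {
    message(n_out, " record(s) with barcodes outside the cell universe dropped")
    table <- table[inside, , drop = FALSE]
  }
  if (nrow(table) == 0) stop("no SNV records left after restricting to the cell universe")
  snvs <- unique(as.data.frame(table)[, c("chrom", "pos", "ref", "alt", "snv_id")])
  snvs <- snvs[order(snvs$chrom, snvs$pos, snvs$alt), , drop = FALSE]
  rownames(snvs) <- NULL
  i <- match(table$barcode, cell_universe)
  j <- match(table$snv_id, snvs$snv_id)
  dims <- c(length(cell_universe), nrow(snvs))
  dn <- list(cell_universe, snvs$snv_id)
  var_counts <- Matrix::sparseMatrix(i = i, j = j, x = as.numeric(table$n_var),
                                     dims = dims, dimnames = dn)
  ref_counts <- Matrix::sparseMatrix(i = i, j = j, x = as.numeric(table$n_ref),
                                     dims = dims, dimnames = dn)
  new_cell_snv_matrix(var_counts, ref_counts, cell_universe, snvs, n_out)
}

#' Observed mask of a cell-SNV matrix
#'
#' @param m a `cell_snv_matrix`.
#' @return sparse logical matrix, `TRUE` where `n_var + n_ref >= 1`.
#' @export
observed_matrix <- function(m) {
  (m$var_counts + m$ref_counts) > 0
}

#' Dense VAF matrix of a cell-SNV matrix
#'
#' @param m a `cell_snv_matrix`.
#' @param unobserved value to place at unobserved entries (`NA` by
#'   default; the transposed-matrix clustering uses 0 plus an explicit
#'   observed-indicator block instead).
#' @return dense numeric matrix, cells x SNVs.
#' @export
vaf_matrix <- function(m, unobserved = NA_real_) {
  v <- as.matrix(m$var_counts)
  d <- v + as.matrix(m$ref_counts)
  out <- v / d
  out[d == 0] <- unobserved
  out
}

#' SNV-level filter thresholds
#'
#' Two user-facing filters remove low-confidence SNVs: a per-entry read
#' coverage (sequencing depth) floor and a minimum number of cells an SNV
#' must be observed in. Depth is applied first — an entry failing the depth
#' floor is set to unobserved and therefore does not count toward the
#' SNV's cell support. Typical settings exclude SNVs detected in fewer
#' than 20 cells and entries with depth below 3 reads.
#'
#' @param min_cells_per_snv keep an SNV iff observed in at least this many
#'   cells (after the depth filter).
#' @param min_depth keep an entry iff `n_var + n_ref >=` this.
#' @return a `filter_spec` list.
#' @export
filter_spec <- function(min_cells_per_snv = 0L, min_depth = 0L) {
  stopifnot(min_cells_per_snv >= 0, min_depth >= 0)
  structure(list(min_cells_per_snv = as.integer(min_cells_per_snv),
                 min_depth = as.integer(min_depth)),
            class = "filter_spec")
}

#' Apply SNV-level filters
#'
#' Entries with depth below `min_depth` become unobserved (both counts
#' zeroed); SNVs then observed in fewer than `min_cells_per_snv` cells are
#' dropped as columns. Cells are never dropped — cell QC belongs to the
#' expression pipeline. The operation is monotone (the output observed set
#' is a subset of the input's) and idempotent.
#'
#' @param m a `cell_snv_matrix`.
#' @param spec a [filter_spec()].
#' @return list with `matrix` (the filtered `cell_snv_matrix`) and
#'   `report` (entries and SNVs removed per rule).
#' @export
apply_filters <- function(m, spec) {
  v <- m$var_counts
  r <- m$ref_counts
  depth <- v + r
  low <- depth > 0 & depth < spec$min_depth
  n_entries_removed <- sum(low)
  if (n_entries_removed > 0) {
    v[low] <- 0
    r[low] <- 0
    v <- Matrix::drop0(v)
    r <- Matrix::drop0(r)
  }
  support <- Matrix::colSums((v + r) > 0)
  keep <- support >= spec$min_cells_per_snv
  n_snvs_removed <- sum(!keep)
  out <- new_cell_snv_matrix(v[, keep, drop = FALSE], r[, keep, drop = FALSE],
                             m$cells, m$snvs[keep, , drop = FALSE],
                             m$n_dropped_outside)
  if (nrow(out$snvs) == 0) warning("filters removed every SNV")
  list(matrix = out,
       report = list(entries_removed_min_depth = n_entries_removed,
                     snvs_removed_min_cells = as.integer(n_snvs_removed),
                     snvs_kept = as.integer(sum(keep))))
}

#' Cross-cell expression profile of one SNV
#'
#' Tallies the allelic states of a single SNV across the cell universe and
#' collects the per-covered-cell VAF distribution; these are the
#' quantities the origin rules consume.
#'
#' @param m a `cell_snv_matrix`.
#' @param snv_id canonical SNV identifier present in `m`.
#' @return An `snv_profile` list: `snv_id`, `n_cells`, `n_cells_covered`,
#'   `n_ref_only`, `n_var_only`, `n_biallelic`, `vaf_values` (one per
#'   covered cell), `median_vaf_covered`, `mean_vaf_covered`,
#'   `median_nvar_expressing` (median `n_var` over cells carrying the
#'   variant allele, i.e. state var_only or biallelic; `NA` if none).
#' @export
per_snv_profile <- function(m, snv_id) {
  j <- match(snv_id, m$snvs$snv_id)
  if (is.na(j)) stop("unknown SNV: ", snv_id)
  nv <- as.numeric(m$var_counts[, j])
  nr <- as.numeric(m$ref_counts[, j])
  covered <- nv + nr >= 1
  vafs <- nv[covered] / (nv[covered] + nr[covered])
  expressing <- nv >= 1
  structure(list(
    snv_id = snv_id,
    n_cells = length(m$cells),
    n_cells_covered = sum(covered),
    n_ref_only = sum(covered & nv == 0),
    n_var_only = sum(covered & nr == 0),
    n_biallelic = sum(nv > 0 & nr > 0),
    vaf_values = vafs,
    median_vaf_covered = if (length(vafs)) stats::median(vafs) else NA_real_,
    mean_vaf_covered = if (length(vafs)) mean(vafs) else NA_real_,
    median_vaf_expressing = if (any(expressing))
      stats::median(vafs[nv[covered] >= 1]) else NA_real_,
    median_nvar_expressing = if (any(expressing))
      stats::median(nv[expressing]) else NA_real_
  ), class = "snv_profile")
}

#' Profile every SNV of a matrix
#'
#' @param m a `cell_snv_matrix`.
#' @return data.frame, one row per SNV, with the scalar fields of
#'   [per_snv_profile()] (the per-cell VAF vectors are available through
#'   `per_snv_profile()` itself).
#' @export
snv_profiles <- function(m) {
  if (nrow(m$snvs) == 0) {
    return(data.frame(snv_id = character(), n_cells_covered = integer(),
                      n_ref_only = integer(), n_var_only = integer(),
                      n_biallelic = integer(), median_vaf_covered = numeric(),
                      mean_vaf_covered = numeric(),
                      median_vaf_expressing = numeric(),
                      median_nvar_expressing = numeric(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(m$snvs$snv_id, function(id) {
    p <- per_snv_profile(m, id)
    data.frame(snv_id = p$snv_id, n_cells_covered = p$n_cells_covered,
               n_ref_only = p$n_ref_only, n_var_only = p$n_var_only,
               n_biallelic = p$n_biallelic,
               median_vaf_covered = p$median_vaf_covered,
               mean_vaf_covered = p$mean_vaf_covered,
               median_vaf_expressing = p$median_vaf_expressing,
               median_nvar_expressing = p$median_nvar_expressing,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
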