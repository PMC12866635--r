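# Brute-force per-entry reimplementations used as independent oracles.
# These loop over every (cell, SNV) entry explicitly and never call the
# vectorized paths they check.

oracle_cell_metrics <- function(m, selection = m$snvs$snv_id) {
  j <- match(selection, m$snvs$snv_id)
  out <- data.frame(barcode = m$cells, n_snvs = 0L, total_nvar = 0L,
                    total_nref = 0L, total_vaf = NA_real_,
                    mean_vaf = NA_real_, median_vaf = NA_real_,
                    stringsAsFactors = FALSE)
  for (ci in seq_along(m$cells)) {
    vafs <- c()
    nv_sum <- 0L; nr_sum <- 0L; n_expr <- 0L
    for (jj in j) {
      nv <- m$var_counts[ci, jj]
      nr <- m$ref_counts[ci, jj]
      if (nv + nr >= 1) {
        vafs <- c(vafs, nv / (nv + nr))
        nv_sum <- nv_sum + nv
        nr_sum <- nr_sum + nr
        if (nv >= 1) n_expr <- n_expr + 1L
      }
    }
    out$n_snvs[ci] <- n_expr
    out$total_nvar[ci] <- as.integer(nv_sum)
    out$total_nref[ci] <- as.integer(nr_sum)
    if (length(vafs) > 0) {
      out$total_vaf[ci] <- nv_sum / (nv_sum + nr_sum)
      out$mean_vaf[ci] <- mean(vafs)
      out$median_vaf[ci] <- stats::median(vafs)
    }
  }
  out
}

oracle_snv_profile <- function(m, snv_id) {
  jj <- match(snv_id, m$snvs$snv_id)
  vafs <- c(); n_ref_only <- 0L; n_var_only <- 0L; n_biallelic <- 0L
  nvars_expressing <- c(); vafs_expressing <- c()
  for (ci in seq_along(m$cells)) {
    nv <- m$var_counts[ci, jj]
    nr <- m$ref_counts[ci, jj]
    if (nv + nr >= 1) {
      vafs <- c(vafs, nv / (nv + nr))
      if (nv == 0) n_ref_only <- n_ref_only + 1L
      if (nr == 0) n_var_only <- n_var_only + 1L
      if (nv > 0 && nr > 0) n_biallelic <- n_biallelic + 1L
      if (nv >= 1) {
        nvars_expressing <- c(nvars_expressing, nv)
        vafs_expressing <- c(vafs_expressing, nv / (nv + nr))
      }
    }
  }
  list(n_cells_covered = length(vafs), n_ref_only = n_ref_only,
       n_var_only = n_var_only, n_biallelic = n_biallelic,
       vaf_values = vafs,
       median_vaf_covered = if (length(vafs)) stats::median(vafs) else NA_real_,
       mean_vaf_covered = if (length(vafs)) mean(vafs) else NA_real_,
       median_vaf_expressing = if (length(vafs_expressing))
         stats::median(vafs_expressing) else NA_real_,
       median_nvar_expressing = if (length(nvars_expressing))
         stats::median(nvars_expressing) else NA_real_)
}

oracle_apply_filters <- function(m, spec) {
  v <- as.matrix(m$var_counts)
  r <- as.matrix(m$ref_counts)
  for (ci in seq_len(nrow(v))) {
    for (jj in seq_len(ncol(v))) {
      d <- v[ci, jj] + r[ci, jj]
      if (d > 0 && d < spec$min_depth) {
        v[ci, jj] <- 0
        r[ci, jj] <- 0
      }
    }
  }
  keep <- colSums(v + r > 0) >= spec$min_cells_per_snv
  list(var = v[, keep, drop = FALSE], ref = r[, keep, drop = FALSE],
       kept = m$snvs$snv_id[keep])
}

# Chance-corrected partition agreement (Hubert & Arabie form), written
# out directly so no clustering package stands behind the check.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- si * sj / n
  (sij - expected) / ((si + sj) / 2 - expected)
}
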