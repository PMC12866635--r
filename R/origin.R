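#' Thresholds for SNV origin inference
#'
#' Heterozygous germline variants show balanced allelic expression with
#' VAF_RNA centered near 0.5 and many biallelic cells; homozygous germline
#' variants show monoallelic variant expression in essentially every
#' expressing cell; somatic variants are expressed from one allele in a
#' subset of cells with transcription-consistent VAF; RNA-level variants
#' (editing, transcriptional infidelity) show low variant read counts and
#' low VAF across cells. These qualitative patterns are made operational
#' by the numeric thresholds below — all of them package choices, every
#' one settable here and from the command line.
#'
#' @param min_cells_covered minimum covered cells for any call (profiles
#'   below it are `unclassified`).
#' @param hom_varonly_frac,hom_mean_vaf homozygous rule: fraction of
#'   covered cells that are variant-only, and mean VAF over covered cells.
#' @param het_biallelic_frac,het_median_vaf_lo,het_median_vaf_hi
#'   heterozygous rule: biallelic fraction floor and the admissible band
#'   for the median VAF over covered cells.
#' @param somatic_cellfrac_lo,somatic_cellfrac_hi,somatic_median_vaf
#'   somatic rule: band for the fraction of covered cells carrying the
#'   variant allele (state var_only or biallelic), and the floor on the
#'   median VAF among those carrier cells.
#' @param rna_median_vaf,rna_median_nvar RNA-origin rule: ceiling on the
#'   median VAF over covered cells (strict) and on the median `n_var`
#'   among carrier cells.
#' @param mono_ratio_lo,mono_ratio_hi,mono_biallelic_max_frac random
#'   monoallelic expression: admissible var-only/ref-only cell-count
#'   ratio band and biallelic-fraction ceiling.
#' @return an `origin_thresholds` list.
#' @export
origin_thresholds <- function(min_cells_covered = 10L,
                              hom_varonly_frac = 0.95,
                              hom_mean_vaf = 0.95,
                              het_biallelic_frac = 0.2,
                              het_median_vaf_lo = 0.35,
                              het_median_vaf_hi = 0.65,
                              somatic_cellfrac_lo = 0.05,
                              somatic_cellfrac_hi = 0.5,
                              somatic_median_vaf = 0.2,
                              rna_median_vaf = 0.2,
                              rna_median_nvar = 2,
                              mono_ratio_lo = 1 / 3,
                              mono_ratio_hi = 3,
                              mono_biallelic_max_frac = 0.1) {
  th <- list(min_cells_covered = as.integer(min_cells_covered),
             hom_varonly_frac = hom_varonly_frac,
             hom_mean_vaf = hom_mean_vaf,
             het_biallelic_frac = het_biallelic_frac,
             het_median_vaf_lo = het_median_vaf_lo,
             het_median_vaf_hi = het_median_vaf_hi,
             somatic_cellfrac_lo = somatic_cellfrac_lo,
             somatic_cellfrac_hi = somatic_cellfrac_hi,
             somatic_median_vaf = somatic_median_vaf,
             rna_median_vaf = rna_median_vaf,
             rna_median_nvar = rna_median_nvar,
             mono_ratio_lo = mono_ratio_lo,
             mono_ratio_hi = mono_ratio_hi,
             mono_biallelic_max_frac = mono_biallelic_max_frac)
  fr <- c("hom_varonly_frac", "hom_mean_vaf", "het_biallelic_frac",
          "het_median_vaf_lo", "het_median_vaf_hi", "somatic_cellfrac_lo",
          "somatic_cellfrac_hi", "somatic_median_vaf", "rna_median_vaf",
          "mono_biallelic_max_frac")
  stopifnot(all(unlist(th[fr]) >= 0), all(unlist(th[fr]) <= 1),
            th$het_median_vaf_lo < th$het_median_vaf_hi,
            th$somatic_cellfrac_lo < th$somatic_cellfrac_hi,
            th$mono_ratio_lo < th$mono_ratio_hi)
  structure(th, class = "origin_thresholds")
}

.origin_labels <- c("germline_hom", "germline_het", "somatic_like",
                    "rna_origin_like", "unclassified")

.profile_evidence <- function(profile) {
  cov <- profile$n_cells_covered
  carriers <- profile$n_var_only + profile$n_biallelic
  list(
    n_cells_covered = cov,
    varonly_frac = if (cov) profile$n_var_only / cov else NA_real_,
    biallelic_frac = if (cov) profile$n_biallelic / cov else NA_real_,
    carrier_frac = if (cov) carriers / cov else NA_real_,
    mean_vaf_covered = profile$mean_vaf_covered,
    median_vaf_covered = profile$median_vaf_covered,
    median_vaf_carriers = profile$median_vaf_expressing,
    median_nvar_carriers = profile$median_nvar_expressing,
    n_var_only = profile$n_var_only,
    n_ref_only = profile$n_ref_only,
    n_biallelic = profile$n_biallelic
  )
}

#' Infer the probable origin class of one SNV
#'
#' Rules are applied in a fixed, documented order from the most to the
#' least constrained pattern — homozygous, heterozygous, somatic-like,
#' RNA-origin-like — and the first match wins; profiles matching none
#' (or covered in too few cells) are `unclassified`. The returned
#' evidence values reproduce the decision deterministically.
#'
#' @param profile an `snv_profile` from [per_snv_profile()].
#' @param thresholds an [origin_thresholds()] list.
#' @return An `origin_call` list: `snv_id`, `label`, `evidence`.
#' @export
classify_origin <- function(profile, thresholds = origin_thresholds()) {
  ev <- .profile_evidence(profile)
  label <- "unclassified"
  if (ev$n_cells_covered >= thresholds$min_cells_covered) {
    if (ev$varonly_frac >= thresholds$hom_varonly_frac &&
        ev$mean_vaf_covered >= thresholds$hom_mean_vaf) {
      label <- "germline_hom"
    } else if (ev$biallelic_frac >= thresholds$het_biallelic_frac &&
               ev$median_vaf_covered >= thresholds$het_median_vaf_lo &&
               ev$median_vaf_covered <= thresholds$het_median_vaf_hi) {
      label <- "germline_het"
    } else if (ev$carrier_frac >= thresholds$somatic_cellfrac_lo &&
               ev$carrier_frac <= thresholds$somatic_cellfrac_hi &&
               !is.na(ev$median_vaf_carriers) &&
               ev$median_vaf_carriers >= thresholds$somatic_median_vaf) {
      label <- "somatic_like"
    } else if (ev$median_vaf_covered < thresholds$rna_median_vaf &&
               !is.na(ev$median_nvar_carriers) &&
               ev$median_nvar_carriers <= thresholds$rna_median_nvar) {
      label <- "rna_origin_like"
    }
  }
  structure(list(snv_id = profile$snv_id,
                 label = factor(label, levels = .origin_labels),
                 evidence = ev),
            class = "origin_call")
}

#' Flag random monoallelic expression
#'
#' At a heterozygous locus subject to X-inactivation or transcriptional
#' bursting, each cell expresses one allele essentially exclusively, so
#' across cells the variant-only and reference-only tallies are of
#' comparable size while biallelic cells are rare. The flag is `TRUE` iff
#' the biallelic fraction is at most `mono_biallelic_max_frac`, both
#' monoallelic tallies are nonzero, and their ratio lies inside the
#' `mono_ratio` band. It is orthogonal to the origin label — such loci
#' are typically germline heterozygous *and* monoallelically expressed.
#' Profiles below the coverage floor return `NA` (undetermined, not
#' `FALSE`).
#'
#' @inheritParams classify_origin
#' @return list with `flag` (`TRUE`/`FALSE`/`NA`) and `evidence`.
#' @export
detect_random_monoallelic <- function(profile, thresholds = origin_thresholds()) {
  ev <- .profile_evidence(profile)
  if (ev$n_cells_covered < thresholds$min_cells_covered) {
    return(list(flag = NA, evidence = ev))
  }
  ratio <- if (ev$n_ref_only >= 1) ev$n_var_only / ev$n_ref_only else NA_real_
  flag <- ev$biallelic_frac <= thresholds$mono_biallelic_max_frac &&
    ev$n_var_only >= 1 && ev$n_ref_only >= 1 &&
    ratio >= thresholds$mono_ratio_lo && ratio <= thresholds$mono_ratio_hi
  list(flag = flag, evidence = ev)
}

#' Classify every SNV of a matrix
#'
#' @param m a `cell_snv_matrix`.
#' @param thresholds an [origin_thresholds()] list.
#' @return data.frame, one row per SNV: `snv_id`, `origin` (factor),
#'   `monoallelic_random` (logical, `NA` below the coverage floor) and
#'   every evidence column the rules consumed.
#' @export
classify_all <- function(m, thresholds = origin_thresholds()) {
  if (nrow(m$snvs) == 0) {
    return(data.frame(snv_id = character(),
                      origin = factor(character(), levels = .origin_labels),
                      monoallelic_random = logical()))
  }
  rows <- lapply(m$snvs$snv_id, function(id) {
    p <- per_snv_profile(m, id)
    call <- classify_origin(p, thresholds)
    mono <- detect_random_monoallelic(p, thresholds)
    cbind(data.frame(snv_id = id, origin = call$label,
                     monoallelic_random = mono$flag,
                     stringsAsFactors = FALSE),
          as.data.frame(call$evidence, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write origin calls to TSV
#'
#' @param calls the data.frame from [classify_all()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_origin_table <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}
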