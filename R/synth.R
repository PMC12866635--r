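#' Configuration for the synthetic dataset generator
#'
#' The generator emulates a droplet scRNA-seq sample together with a
#' per-cell SNV read-count table in which every origin pattern the
#' classifier must recover is planted:
#' \describe{
#'   \item{het}{germline heterozygous — each read at the locus carries the
#'     variant allele with probability 0.5.}
#'   \item{hom}{germline homozygous — every read carries the variant.}
#'   \item{somatic}{heterozygous within a single subclone of cell
#'     fraction `somatic_f`; zero variant reads elsewhere.}
#'   \item{rna}{RNA-level — every read converts to the variant with a
#'     small probability `rna_e` in all cells.}
#'   \item{bursting}{random monoallelic expression — each cell picks one
#'     allele (Bernoulli 0.5) and all its reads come from it.}
#' }
#' Locus depth per cell is `Poisson(coverage_rate * s_c)` where `s_c` is
#' the cell's relative library size, drawn log-normal with `sdlog =
#' lib_sdlog` and unit mean; cell-SNV pairs with zero depth are omitted
#' from the table, creating true no-read-count loci. Gene counts are
#' negative binomial with Gamma-distributed base means, per-cell size
#' factors `s_c`, and, per expression group, a fraction `de_frac` of
#' genes shifted by `2^de_lfc`.
#'
#' @param n_cells,n_genes dataset dimensions.
#' @param n_groups number of planted expression groups.
#' @param de_frac fraction of genes differentially expressed per group.
#' @param de_lfc log2 fold change of those genes.
#' @param lib_sdlog sdlog of the log-normal per-cell size factors
#'   (meanlog is set to `-lib_sdlog^2 / 2` so the mean factor is 1).
#' @param gene_mean_shape,gene_mean_rate Gamma parameters of gene base
#'   means.
#' @param nb_size negative-binomial size (inverse dispersion) of gene
#'   counts.
#' @param coverage_rate Poisson mean locus depth for a cell of unit size
#'   factor.
#' @param n_per_class named integer vector of planted SNV counts per
#'   class.
#' @param somatic_f subclone cell fraction for somatic loci.
#' @param rna_e per-read variant conversion rate for RNA-origin loci
#'   (must be < 0.5).
#' @param seed integer seed; the whole dataset is a pure function of the
#'   configuration.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_cells = 300L, n_genes = 500L, n_groups = 3L,
                       de_frac = 0.1, de_lfc = 2,
                       lib_sdlog = 0.5,
                       gene_mean_shape = 0.5, gene_mean_rate = 0.1,
                       nb_size = 2,
                       coverage_rate = 5,
                       n_per_class = c(het = 50L, hom = 50L, somatic = 50L,
                                       rna = 50L, bursting = 50L),
                       somatic_f = 0.2, rna_e = 0.02,
                       seed = 1L) {
  stopifnot(n_cells >= 1, n_genes >= 1, n_groups >= 1,
            de_frac >= 0, de_frac <= 1,
            somatic_f > 0, somatic_f < 1,
            rna_e >= 0, rna_e < 0.5,
            coverage_rate > 0, all(n_per_class >= 0),
            sum(n_per_class) >= 1)
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 n_groups = as.integer(n_groups), de_frac = de_frac,
                 de_lfc = de_lfc, lib_sdlog = lib_sdlog,
                 gene_mean_shape = gene_mean_shape,
                 gene_mean_rate = gene_mean_rate, nb_size = nb_size,
                 coverage_rate = coverage_rate,
                 n_per_class = n_per_class, somatic_f = somatic_f,
                 rna_e = rna_e, seed = as.integer(seed)),
            class = "sim_config")
}

.random_barcodes <- function(n) {
  bc <- replicate(n, paste0(paste(sample(c("A", "C", "G", "T"), 16,
                                         replace = TRUE), collapse = ""), "-1"))
  while (anyDuplicated(bc)) {
    dup <- which(duplicated(bc))
    bc[dup] <- replicate(length(dup),
                         paste0(paste(sample(c("A", "C", "G", "T"), 16,
                                             replace = TRUE), collapse = ""), "-1"))
  }
  bc
}

.random_keys <- function(n) {
  bases <- c("A", "C", "G", "T")
  draw <- function(k) {
    chrom <- sample(c(as.character(1:22), "X"), k, replace = TRUE)
    pos <- sample.int(2e8, k)
    ref <- sample(bases, k, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "",
                  USE.NAMES = FALSE)
    make_snv_key(chrom, pos, ref, alt)
  }
  keys <- draw(n)
  while (anyDuplicated(keys$snv_id)) {
    dup <- which(duplicated(keys$snv_id))
    keys[dup, ] <- draw(length(dup))
  }
  keys
}

#' Simulate a single-cell dataset with planted SNV classes
#'
#' @param config a [sim_config()].
#' @return list with `expr` (sparse genes x cells count matrix),
#'   `table` (an `snv_table` in memory), and `truth` (list: `snv_truth`
#'   data.frame of planted classes, `cell_groups` integer vector,
#'   `subclone` logical vector, `size_factors`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_cells
  barcodes <- .random_barcodes(n)
  size_factors <- stats::rlnorm(n, meanlog = -config$lib_sdlog^2 / 2,
                                sdlog = config$lib_sdlog)
  cell_groups <- sort(rep_len(seq_len(config$n_groups), n))

  # genes x cells NB counts with per-group mean shifts
  base_mean <- stats::rgamma(config$n_genes, shape = config$gene_mean_shape,
                             rate = config$gene_mean_rate)
  n_de <- round(config$de_frac * config$n_genes)
  de_sets <- lapply(seq_len(config$n_groups), function(g) {
    sample.int(config$n_genes, n_de)
  })
  mu <- matrix(base_mean, nrow = config$n_genes, ncol = n)
  for (g in seq_len(config$n_groups)) {
    cells_g <- which(cell_groups == g)
    mu[de_sets[[g]], cells_g] <- mu[de_sets[[g]], cells_g] * 2^config$de_lfc
  }
  mu <- sweep(mu, 2, size_factors, `*`)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = config$nb_size),
                   nrow = config$n_genes)
  dimnames(counts) <- list(sprintf("gene%04d", seq_len(config$n_genes)), barcodes)
  expr <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")

  # planted SNVs
  classes <- rep(names(config$n_per_class), times = config$n_per_class)
  n_snvs <- length(classes)
  keys <- .random_keys(n_snvs)
  subclone <- seq_len(n) %in% sample.int(n, round(config$somatic_f * n))

  recs <- vector("list", n_snvs)
  for (s in seq_len(n_snvs)) {
    depth <- stats::rpois(n, config$coverage_rate * size_factors)
    nv <- integer(n)
    has <- depth > 0
    d <- depth[has]
    nv[has] <- switch(classes[s],
      het = stats::rbinom(sum(has), d, 0.5),
      hom = d,
      somatic = ifelse(subclone[has], stats::rbinom(sum(has), d, 0.5), 0L),
      rna = stats::rbinom(sum(has), d, config$rna_e),
      bursting = d * stats::rbinom(sum(has), 1, 0.5)
    )
    recs[[s]] <- data.frame(idx = s, cell = which(has),
                            n_var = as.integer(nv[has]),
                            n_ref = as.integer(depth[has] - nv[has]),
                            stringsAsFactors = FALSE)
  }
  recs <- do.call(rbind, recs)
  records <- cbind(keys[recs$idx, , drop = FALSE],
                   data.frame(barcode = barcodes[recs$cell],
                              n_var = recs$n_var, n_ref = recs$n_ref,
                              stringsAsFactors = FALSE))
  table <- new_snv_table(records, sample_id = "synthetic",
                         provenance = list(path = NA_character_,
                                           dialect = "simulated"),
                         n_dropped_zero = 0L)
  truth <- list(
    snv_truth = data.frame(snv_id = keys$snv_id, class = classes,
                           stringsAsFactors = FALSE),
    cell_groups = stats::setNames(cell_groups, barcodes),
    subclone = stats::setNames(subclone, barcodes),
    size_factors = stats::setNames(size_factors, barcodes)
  )
  list(expr = expr, table = table, truth = truth, config = config)
}

#' Write a simulated dataset as on-disk fixtures
#'
#' Emits the exact input formats the readers consume: a MatrixMarket
#' triplet directory (`matrix.mtx`, `features.tsv`, `barcodes.tsv`), the
#' SNV table in the simplified dialect (`snv_table.tsv`), and the planted
#' ground truth (`snv_truth.tsv`, `cell_groups.tsv`).
#'
#' @param dataset result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(dataset$expr, file.path(dir, "matrix.mtx"))
  writeLines(rownames(dataset$expr), file.path(dir, "features.tsv"))
  writeLines(colnames(dataset$expr), file.path(dir, "barcodes.tsv"))
  write_snv_table(dataset$table, file.path(dir, "snv_table.tsv"))
  utils::write.table(dataset$truth$snv_truth, file.path(dir, "snv_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  utils::write.table(
    data.frame(Barcode = names(dataset$truth$cell_groups),
               Group = unname(dataset$truth$cell_groups),
               Subclone = unname(dataset$truth$subclone)),
    file.path(dir, "cell_groups.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(dir)
}
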