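#' Per-cell metrics over a set of SNVs
#'
#' For a selected SNV set, each cell is summarized by:
#' \describe{
#'   \item{n_snvs}{number of expressed SNVs, i.e. selected loci with
#'     `n_var >= 1` in the cell. Reference-only coverage is a negative
#'     signal and does not count as an expressed SNV.}
#'   \item{total_nvar, total_nref}{read-count sums over the selected loci.}
#'   \item{total_vaf}{`sum(n_var) / sum(n_var + n_ref)` over the covered
#'     selected loci — the depth-weighted overall variant expression
#'     magnitude of the cell.}
#'   \item{mean_vaf, median_vaf}{mean/median of the per-locus VAFs over
#'     covered loci (VAF = 0 loci included: excluding the negative signal
#'     would bias every summary toward 1).}
#' }
#' Cells covering no selected locus keep defined zero totals but undefined
#' (`NA`) ratios.
#'
#' @param m a `cell_snv_matrix`.
#' @param selection character vector of SNV ids to aggregate over
#'   (default: all SNVs of `m`). Must be a nonempty subset of the matrix
#'   columns.
#' @return A `cell_metrics` data.frame, one row per cell of `m`, columns
#'   `barcode`, `n_snvs`, `total_nvar`, `total_nref`, `total_vaf`,
#'   `mean_vaf`, `median_vaf`.
#' @export
compute_cell_metrics <- function(m, selection = NULL) {
  if (is.null(selection)) selection <- m$snvs$snv_id
  if (length(selection) == 0) stop("SNV selection is empty")
  missing <- setdiff(selection, m$snvs$snv_id)
  if (length(missing)) {
    stop("selection contains SNVs absent from the matrix: ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  j <- match(selection, m$snvs$snv_id)
  v <- m$var_counts[, j, drop = FALSE]
  r <- m$ref_counts[, j, drop = FALSE]
  depth <- v + r
  covered <- depth > 0
  total_nvar <- Matrix::rowSums(v)
  total_nref <- Matrix::rowSums(r)
  total_depth <- total_nvar + total_nref
  n_cov <- Matrix::rowSums(covered)
  vafm <- as.matrix(v) / as.matrix(depth)  # NaN where depth 0
  vafm[as.matrix(depth) == 0] <- NA_real_
  mean_vaf <- rowMeans(vafm, na.rm = TRUE)
  median_vaf <- apply(vafm, 1, stats::median, na.rm = TRUE)
  mean_vaf[n_cov == 0] <- NA_real_
  median_vaf[n_cov == 0] <- NA_real_
  out <- data.frame(
    barcode = m$cells,
    n_snvs = as.integer(Matrix::rowSums(v >= 1)),
    total_nvar = as.integer(total_nvar),
    total_nref = as.integer(total_nref),
    total_vaf = ifelse(total_depth >= 1, total_nvar / total_depth, NA_real_),
    mean_vaf = mean_vaf,
    median_vaf = median_vaf,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("cell_metrics", "data.frame")
  out
}

#' Histogram bin edges and counts
#'
#' Fixed-rule binning backing the metric histograms: `bins` equal-width
#' intervals over `limits`, left-closed with the final bin right-closed,
#' so every defined value in the range lands in exactly one bin. VAF-type
#' metrics use `limits = c(0, 1)`; count metrics use integer-aligned
#' limits from 0 to the observed maximum.
#'
#' @param values numeric vector (`NA`s are dropped and not counted).
#' @param bins number of bins, >= 1.
#' @param limits length-2 numeric range; default `c(0, 1)`. For
#'   `integer_align = TRUE` the upper limit is raised to a multiple of
#'   `bins` so edges sit on integers.
#' @param integer_align align edges to integers (count metrics).
#' @return list with `edges` (length `bins + 1`) and `counts` (length
#'   `bins`, summing to the number of defined in-range values).
#' @export
histogram_data <- function(values, bins, limits = c(0, 1),
                           integer_align = FALSE) {
  if (bins < 1) stop("bins must be >= 1")
  bins <- as.integer(bins)
  values <- values[!is.na(values)]
  if (integer_align) {
    hi <- max(c(values, 1))
    limits <- c(0, bins * ceiling(hi / bins))
  }
  edges <- seq(limits[1], limits[2], length.out = bins + 1L)
  if (length(values) == 0) {
    return(list(edges = edges, counts = integer(bins)))
  }
  idx <- findInterval(values, edges, rightmost.closed = TRUE, left.open = FALSE)
  idx <- idx[idx >= 1 & idx <= bins]
  counts <- tabulate(idx, nbins = bins)
  list(edges = edges, counts = counts)
}

.metric_cols <- c("n_snvs", "total_nvar", "total_nref",
                  "total_vaf", "mean_vaf", "median_vaf")
.vaf_metrics <- c("total_vaf", "mean_vaf", "median_vaf")

#' Per-group summaries and histograms of cell metrics
#'
#' Groups are typically expression-derived cell clusters. Each metric is
#' summarized (n defined, mean, median, quartiles) and binned over the
#' cells where it is defined; cells without a group label are excluded
#' and counted.
#'
#' @param metrics a `cell_metrics` data.frame.
#' @param labels per-cell group labels aligned to `metrics` rows (`NA` =
#'   unlabeled).
#' @param bins histogram bin count (default 50 for VAF metrics on
#'   `[0, 1]`).
#' @return A `cluster_metrics_summary` list: `summary` data.frame (one
#'   row per group x metric), `histograms` (nested list
#'   `[[group]][[metric]]` of [histogram_data()] results) and
#'   `n_unlabeled`.
#' @export
summarize_by_group <- function(metrics, labels, bins = 50L) {
  if (length(labels) != nrow(metrics)) {
    stop("labels must align 1:1 with metric rows")
  }
  keep <- !is.na(labels)
  n_unlabeled <- sum(!keep)
  if (!any(keep)) stop("every cell is unlabeled")
  metrics <- metrics[keep, , drop = FALSE]
  labels <- as.character(labels[keep])
  groups <- sort(unique(labels))
  rows <- list()
  hists <- list()
  for (g in groups) {
    sub <- metrics[labels == g, , drop = FALSE]
    hists[[g]] <- list()
    for (mcol in .metric_cols) {
      x <- sub[[mcol]]
      defined <- x[!is.na(x)]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, metric = mcol, n_cells = nrow(sub),
        n_defined = length(defined),
        mean = if (length(defined)) mean(defined) else NA_real_,
        median = if (length(defined)) stats::median(defined) else NA_real_,
        q25 = if (length(defined)) unname(stats::quantile(defined, 0.25)) else NA_real_,
        q75 = if (length(defined)) unname(stats::quantile(defined, 0.75)) else NA_real_,
        stringsAsFactors = FALSE)
      hists[[g]][[mcol]] <- if (mcol %in% .vaf_metrics) {
        histogram_data(x, bins, limits = c(0, 1))
      } else {
        histogram_data(x, bins, integer_align = TRUE)
      }
    }
  }
  structure(list(summary = do.call(rbind, rows), histograms = hists,
                 n_unlabeled = n_unlabeled, bins = bins),
            class = "cluster_metrics_summary")
}
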