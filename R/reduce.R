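#' Parameters of the expression-processing pipeline
#'
#' The embedding pipeline is deliberately minimal and fully specified, so
#' a run is reproducible from `(input, params, seed)` alone:
#' library-size normalization to `target_sum` counts per cell, `log1p`,
#' top-`n_hvgs` variable genes by dispersion (variance/mean of the
#' normalized data), per-gene standardization (clipped at ±10), PCA to
#' `n_pcs`, a shared-nearest-neighbor graph over `n_neighbors`
#' neighbors, Louvain community detection at `resolution`, then UMAP
#' and/or t-SNE coordinates in 2 or 3 dimensions.
#'
#' @param target_sum per-cell count total after normalization.
#' @param n_hvgs number of highly variable genes retained.
#' @param n_pcs number of principal components.
#' @param n_neighbors k for the kNN/SNN graph and for UMAP.
#' @param resolution Louvain resolution.
#' @param min_dist UMAP `min_dist`.
#' @param tsne_perplexity t-SNE perplexity (reduced automatically when
#'   the cell count requires it).
#' @return a `reduce_params` list.
#' @export
reduce_params <- function(target_sum = 1e4, n_hvgs = 2000L, n_pcs = 30L,
                          n_neighbors = 15L, resolution = 1.0,
                          min_dist = 0.3, tsne_perplexity = 30) {
  structure(list(target_sum = target_sum, n_hvgs = as.integer(n_hvgs),
                 n_pcs = as.integer(n_pcs),
                 n_neighbors = as.integer(n_neighbors),
                 resolution = resolution, min_dist = min_dist,
                 tsne_perplexity = tsne_perplexity),
            class = "reduce_params")
}

.normalize_log1p <- function(expr, target_sum) {
  lib <- Matrix::colSums(expr)
  lib[lib == 0] <- 1
  log1p(Matrix::t(Matrix::t(expr) * (target_sum / lib)))
}

.select_hvgs <- function(norm, n_hvgs) {
  mu <- Matrix::rowMeans(norm)
  v <- Matrix::rowMeans(norm^2) - mu^2
  disp <- ifelse(mu > 0, v / mu, 0)
  head(order(disp, decreasing = TRUE), n_hvgs)
}

.scale_genes <- function(mat, clip = 10) {
  mat <- as.matrix(mat)
  mu <- rowMeans(mat)
  sd <- apply(mat, 1, stats::sd)
  sd[sd == 0] <- 1
  z <- (mat - mu) / sd
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  z
}

.pca_scores <- function(cells_by_features, n_pcs) {
  n_pcs <- min(n_pcs, ncol(cells_by_features), nrow(cells_by_features) - 1L)
  p <- stats::prcomp(cells_by_features, center = TRUE, scale. = FALSE,
                     rank. = n_pcs)
  scores <- p$x
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  scores
}

# SNN graph: k nearest neighbors by Euclidean distance in PC space,
# edges weighted by the Jaccard overlap of neighbor sets (self included),
# pruned below 1/15 — then Louvain at the requested resolution.
.snn_cluster <- function(scores, k, resolution) {
  n <- nrow(scores)
  k <- min(k, n - 1L)
  d <- as.matrix(stats::dist(scores))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k)]))
  a <- Matrix::sparseMatrix(i = rep(seq_len(n), k + 1L),
                            j = c(as.integer(nn), seq_len(n)),
                            x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(a)
  jac <- shared / (2 * (k + 1) - shared)
  jac <- as.matrix(jac)
  jac[jac < 1 / 15] <- 0
  diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  as.integer(igraph::membership(cl))
}

.run_umap <- function(scores, params, dims) {
  uwot::umap(scores, n_neighbors = min(params$n_neighbors, nrow(scores) - 1L),
             n_components = dims, min_dist = params$min_dist,
             n_threads = 1, n_sgd_threads = 0)
}

.run_tsne <- function(scores, params, dims) {
  perp <- min(params$tsne_perplexity, floor((nrow(scores) - 1) / 3))
  Rtsne::Rtsne(scores, dims = dims, perplexity = perp, pca = FALSE,
               check_duplicates = FALSE, num_threads = 1)$Y
}

new_cell_embedding <- function(barcodes, coords, clusters, meta,
                               params = NULL, seed = NA_integer_) {
  for (co in coords) stopifnot(nrow(co) == length(barcodes))
  structure(list(barcodes = barcodes, coords = coords, clusters = clusters,
                 meta = meta, params = params, seed = seed),
            class = "cell_embedding")
}

#' @exportS3Method print cell_embedding
print.cell_embedding <- function(x, ...) {
  cat("<cell_embedding> ", length(x$barcodes), " cells; methods: ",
      paste(names(x$coords), collapse = ", "), "; ",
      length(unique(x$clusters)), " clusters\n", sep = "")
  invisible(x)
}

#' Embed cells from a raw count matrix
#'
#' Runs the fixed pipeline documented in [reduce_params()]. Every
#' stochastic step (Louvain, UMAP, t-SNE) is driven by `seed`, so
#' repeated runs with the same inputs and seed give bit-identical
#' coordinates.
#'
#' @param expr genes x cells raw count matrix (dimnames required).
#' @param params a [reduce_params()].
#' @param seed integer seed.
#' @param methods coordinate methods to compute, subset of
#'   `c("umap", "tsne", "pca")`.
#' @param dims 2 or 3 output dimensions.
#' @return A `cell_embedding`: `barcodes`, `coords` (named list of
#'   cells x dims matrices), `clusters` (integer Louvain labels), `meta`
#'   data.frame.
#' @export
embed_cells <- function(expr, params = reduce_params(), seed = 1L,
                        methods = "umap", dims = 2L) {
  methods <- match.arg(methods, c("umap", "tsne", "pca"), several.ok = TRUE)
  stopifnot(dims %in% c(2L, 3L))
  n <- ncol(expr)
  if (n < 50) warning("fewer than 50 cells; embeddings will be unstable")
  if (n <= params$n_pcs) {
    stop("more principal components (", params$n_pcs, ") than cells permit (",
         n, " cells); reduce n_pcs")
  }
  set.seed(seed)
  norm <- .normalize_log1p(expr, params$target_sum)
  hv <- .select_hvgs(norm, params$n_hvgs)
  z <- .scale_genes(norm[hv, , drop = FALSE])
  scores <- .pca_scores(t(z), params$n_pcs)
  clusters <- .snn_cluster(scores, params$n_neighbors, params$resolution)
  coords <- list()
  for (meth in methods) {
    coords[[meth]] <- switch(meth,
      pca = scores[, seq_len(dims), drop = FALSE],
      umap = .run_umap(scores, params, dims),
      tsne = .run_tsne(scores, params, dims))
    rownames(coords[[meth]]) <- colnames(expr)
    colnames(coords[[meth]]) <- paste0(toupper(meth), "_", seq_len(dims))
  }
  meta <- data.frame(barcode = colnames(expr), cluster = clusters,
                     stringsAsFactors = FALSE)
  new_cell_embedding(colnames(expr), coords, clusters, meta, params, seed)
}

#' Wrap a precomputed embedding table
#'
#' Accepts coordinates produced by any external processing (e.g. a
#' custom-processed single-cell framework object exported to a table)
#' and bypasses [embed_cells()] entirely.
#'
#' @param coords_table data.frame with a barcode column (named `barcode`,
#'   or the first column) and at least 2 numeric coordinate columns;
#'   an optional `cluster` column is carried through.
#' @param cells optional cell universe; barcodes are matched via
#'   [harmonize_barcodes()] and the table restricted to matches.
#' @return a `cell_embedding` with method `"precomputed"`.
#' @export
attach_embedding <- function(coords_table, cells = NULL) {
  df <- as.data.frame(coords_table)
  bc_col <- if ("barcode" %in% names(df)) "barcode" else names(df)[1]
  barcodes <- as.character(df[[bc_col]])
  cl <- if ("cluster" %in% names(df)) as.integer(df$cluster) else NULL
  coord_cols <- setdiff(names(df), c(bc_col, "cluster"))
  coord_cols <- coord_cols[vapply(df[coord_cols], is.numeric, TRUE)]
  if (length(coord_cols) < 2) stop("need at least 2 numeric coordinate columns")
  if (length(coord_cols) > 3) coord_cols <- coord_cols[1:3]
  if (!is.null(cells)) {
    h <- harmonize_barcodes(barcodes, cells)
    keep <- match(h$snv_barcodes, barcodes)
    df <- df[keep, , drop = FALSE]
    barcodes <- h$snv_barcodes
    if (!is.null(cl)) cl <- cl[keep]
  }
  co <- as.matrix(df[, coord_cols, drop = FALSE])
  rownames(co) <- barcodes
  clusters <- if (is.null(cl)) rep(1L, length(barcodes)) else cl
  meta <- data.frame(barcode = barcodes, cluster = clusters,
                     stringsAsFactors = FALSE)
  new_cell_embedding(barcodes, list(precomputed = co), clusters, meta)
}

#' Cluster SNVs by their cross-cell expression profiles
#'
#' The cells x SNVs matrix is transposed so cells act as features. Each
#' SNV's feature vector concatenates its per-cell VAF (unobserved
#' entries encoded as 0) with an explicit per-cell observed indicator,
#' so absence of variant expression and absence of coverage remain
#' distinguishable to the clustering. PCA, an SNN graph and Louvain
#' follow, plus 2D UMAP coordinates (PCA coordinates when the SNV count
#' is very small). Separates, e.g., homozygous from heterozygous
#' germline variants.
#'
#' @param m a (filtered) `cell_snv_matrix` with at least 2 SNVs.
#' @param params a [reduce_params()].
#' @param seed integer seed.
#' @return An `snv_cluster_result`: `snvs` (key data.frame), `clusters`
#'   (integer per SNV), `coords` (SNVs x 2), `features` (the matrix the
#'   clustering consumed).
#' @export
cluster_snvs <- function(m, params = reduce_params(), seed = 1L) {
  n_snvs <- nrow(m$snvs)
  if (n_snvs < 2) stop("need at least 2 SNVs to cluster")
  set.seed(seed)
  vafs <- vaf_matrix(m, unobserved = 0)
  obs <- as.matrix(observed_matrix(m)) * 1
  features <- cbind(t(vafs), t(obs))
  colnames(features) <- c(paste0("vaf_", m$cells), paste0("obs_", m$cells))
  rownames(features) <- m$snvs$snv_id
  scores <- .pca_scores(features, min(params$n_pcs, n_snvs - 1L))
  clusters <- .snn_cluster(scores, min(params$n_neighbors, n_snvs - 1L),
                           params$resolution)
  coords <- if (n_snvs > 15) {
    .run_umap(scores, params, 2L)
  } else {
    cbind(scores[, 1], if (ncol(scores) > 1) scores[, 2] else 0)
  }
  rownames(coords) <- m$snvs$snv_id
  colnames(coords) <- c("DIM_1", "DIM_2")
  structure(list(snvs = m$snvs, clusters = clusters, coords = coords,
                 features = features, seed = seed),
            class = "snv_cluster_result")
}

#' Integrate multiple samples into a shared embedding
#'
#' Genes are intersected across samples and counts concatenated with
#' barcodes prefixed `"<sampleid>_"` for global uniqueness. In place of
#' anchor-based batch correction, each gene is standardized within each
#' sample before the joint PCA — a simple, fully reproducible scheme
#' that removes per-sample location/scale differences (it does not model
#' nonlinear batch effects; see the vignette). Downstream steps are
#' identical to [embed_cells()], and the result carries a per-cell
#' sample id for plots where cells are grouped by sample.
#'
#' @param exprs named list (>= 2) of genes x cells raw count matrices.
#' @param params a [reduce_params()].
#' @param seed integer seed.
#' @param include optional character vector of sample names to keep.
#' @param tables optional named list of `snv_table`s, merged with the
#'   same barcode prefixes and returned as attribute `"table"`.
#' @param methods,dims as in [embed_cells()].
#' @return a `cell_embedding` whose `meta` has a `sample` column.
#' @export
integrate_samples <- function(exprs, params = reduce_params(), seed = 1L,
                              include = NULL, tables = NULL,
                              methods = "umap", dims = 2L) {
  if (is.null(names(exprs)) || any(names(exprs) == "")) {
    stop("exprs must be a named list of sample matrices")
  }
  if (!is.null(include)) exprs <- exprs[include]
  if (length(exprs) < 2) stop("need at least 2 samples to integrate")
  genes <- Reduce(intersect, lapply(exprs, rownames))
  if (length(genes) == 0) stop("no genes are shared across the samples")
  set.seed(seed)
  norm_list <- lapply(exprs, function(e) {
    .normalize_log1p(e[genes, , drop = FALSE], params$target_sum)
  })
  joint_norm <- do.call(cbind, norm_list)
  hv <- .select_hvgs(joint_norm, params$n_hvgs)
  scaled <- lapply(norm_list, function(nm) .scale_genes(nm[hv, , drop = FALSE]))
  z <- do.call(cbind, scaled)
  sample_id <- rep(names(exprs), times = vapply(exprs, ncol, 1L))
  barcodes <- paste0(sample_id, "_", unlist(lapply(exprs, colnames)))
  colnames(z) <- barcodes
  scores <- .pca_scores(t(z), params$n_pcs)
  clusters <- .snn_cluster(scores, params$n_neighbors, params$resolution)
  coords <- list()
  for (meth in methods) {
    coords[[meth]] <- switch(meth,
      pca = scores[, seq_len(dims), drop = FALSE],
      umap = .run_umap(scores, params, dims),
      tsne = .run_tsne(scores, params, dims))
    rownames(coords[[meth]]) <- barcodes
    colnames(coords[[meth]]) <- paste0(toupper(meth), "_", seq_len(dims))
  }
  meta <- data.frame(barcode = barcodes, cluster = clusters,
                     sample = sample_id, stringsAsFactors = FALSE)
  emb <- new_cell_embedding(barcodes, coords, clusters, meta, params, seed)
  if (!is.null(tables)) {
    merged <- do.call(rbind, lapply(names(tables), function(s) {
      t <- as.data.frame(tables[[s]])
      t$barcode <- paste0(s, "_", t$barcode)
      t
    }))
    attr(emb, "table") <- new_snv_table(merged, "integrated",
                                        list(path = NA, dialect = "merged"), 0L)
  }
  emb
}
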