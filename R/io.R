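#' @importFrom utils read.delim write.table
NULL

# Column synonyms for the read-count table dialects. Matching is
# case-insensitive after stripping a leading "#" and any non-alphanumeric
# characters, so "CHROM", "#CHROM" and "Chrom" all match.
.col_synonyms <- list(
  chrom   = c("chrom", "chr", "chromosome", "seqnames"),
  pos     = c("pos", "position", "start"),
  ref     = c("ref", "reference", "refallele"),
  alt     = c("alt", "altallele", "variant", "var"),
  barcode = c("readgroup", "barcode", "barcodes", "cb", "cellbarcode", "cell"),
  n_var   = c("snvcount", "nvar", "varcount", "varreads"),
  n_ref   = c("refcount", "nref", "refreads")
)

.norm_header <- function(x) gsub("[^a-z0-9]", "", tolower(sub("^#", "", x)))

.match_columns <- function(header, wanted) {
  nh <- .norm_header(header)
  out <- integer(0)
  for (w in wanted) {
    hit <- which(nh %in% .col_synonyms[[w]])
    if (length(hit) == 0) {
      stop("input is missing a required column: '", w,
           "' (accepted header names: ",
           paste(.col_synonyms[[w]], collapse = ", "), ")")
    }
    out[w] <- hit[1]
  }
  out
}

.check_counts <- function(x, col, lines) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) | v < 0 | v != floor(v)
  if (any(bad)) {
    stop("non-integer or negative ", col, " value '", x[which(bad)[1]],
         "' at line ", lines[which(bad)[1]])
  }
  as.integer(v)
}

new_snv_table <- function(records, sample_id, provenance, n_dropped_zero = 0L) {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "snv_id",
                  "barcode", "n_var", "n_ref") %in% names(records)))
  rownames(records) <- NULL
  structure(records,
            sample_id = sample_id,
            provenance = provenance,
            n_dropped_zero = as.integer(n_dropped_zero),
            class = c("snv_table", "data.frame"))
}

#' @exportS3Method print snv_table
print.snv_table <- function(x, ...) {
  cat("<snv_table> sample '", attr(x, "sample_id"), "': ",
      nrow(x), " records, ", length(unique(x$snv_id)), " SNVs, ",
      length(unique(x$barcode)), " cells (",
      attr(x, "n_dropped_zero"), " zero-coverage rows dropped on load)\n",
      sep = "")
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

# Shared post-parse contract: drop zero-coverage rows, enforce barcode
# non-emptiness and (snv, barcode) uniqueness.
.finalize_records <- function(rec, lines, dedup_policy, sample_id, provenance) {
  if (any(rec$barcode == "" | is.na(rec$barcode))) {
    stop("empty cell barcode at line ",
         lines[which(rec$barcode == "" | is.na(rec$barcode))[1]])
  }
  zero <- rec$n_var + rec$n_ref == 0L
  n_dropped <- sum(zero)
  if (n_dropped > 0) {
    message(n_dropped, " row(s) with no read counts (N_VAR + N_REF = 0) dropped")
    rec <- rec[!zero, , drop = FALSE]
  }
  key <- paste(rec$snv_id, rec$barcode, sep = "\r")
  if (anyDuplicated(key)) {
    if (dedup_policy == "error") {
      d <- key[duplicated(key)][1]
      i <- which(key == d)[1]
      stop("duplicate (SNV, barcode) pair: ", rec$snv_id[i], " / ",
           rec$barcode[i], " (use dedup_policy = \"sum\" to aggregate)")
    }
    agg_var <- rowsum(rec$n_var, key)
    agg_ref <- rowsum(rec$n_ref, key)
    keep <- !duplicated(key)
    rec <- rec[keep, , drop = FALSE]
    ord <- match(key[keep], rownames(agg_var))
    rec$n_var <- as.integer(agg_var[ord, 1L])
    rec$n_ref <- as.integer(agg_ref[ord, 1L])
  }
  new_snv_table(rec, sample_id, provenance, n_dropped)
}

#' Read an SCReadCounts-style per-cell SNV read-count table
#'
#' Expects a tab-delimited file with a header naming (at least) chromosome,
#' position, reference allele, alternate allele, cell barcode (often
#' `ReadGroup`), variant read count (`SNVCount`) and reference read count
#' (`RefCount`); extra columns are ignored. Header matching is
#' case-insensitive against a synonym list (see the package vignette).
#' Rows whose variant and reference counts are both zero carry no
#' information beyond "locus not covered in this cell" and are dropped with
#' a message; positions are 1-based throughout.
#'
#' @param path path to the tab-delimited file.
#' @param dedup_policy what to do with duplicated (SNV, barcode) rows:
#'   `"error"` (default; duplicates indicate an upstream fault) or `"sum"`.
#' @param sample_id label stored on the returned table; defaults to the
#'   file name.
#' @return An `snv_table`: a data.frame of records with columns `chrom`,
#'   `pos`, `ref`, `alt`, `snv_id`, `barcode`, `n_var`, `n_ref`, plus
#'   attributes `sample_id`, `provenance` and `n_dropped_zero`.
#' @seealso [read_simple_table()] for the compact identifier dialect.
#' @export
read_screadcounts <- function(path, dedup_policy = c("error", "sum"),
                              sample_id = basename(path)) {
  dedup_policy <- match.arg(dedup_policy)
  raw <- read.delim(path, header = TRUE, colClasses = "character",
                    check.names = FALSE, stringsAsFactors = FALSE)
  idx <- .match_columns(names(raw),
                        c("chrom", "pos", "ref", "alt", "barcode", "n_var", "n_ref"))
  if (nrow(raw) == 0) {
    rec <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), snv_id = character(),
                      barcode = character(), n_var = integer(),
                      n_ref = integer(), stringsAsFactors = FALSE)
    return(new_snv_table(rec, sample_id,
                         list(path = path, dialect = "screadcounts"), 0L))
  }
  lines <- seq_len(nrow(raw)) + 1L  # header is line 1
  pos <- suppressWarnings(as.numeric(raw[[idx["pos"]]]))
  badp <- is.na(pos) | pos < 1 | pos != floor(pos)
  if (any(badp)) {
    stop("non-positive or non-integer position '",
         raw[[idx["pos"]]][which(badp)[1]], "' at line ", lines[which(badp)[1]])
  }
  keys <- make_snv_key(raw[[idx["chrom"]]], as.integer(pos),
                       toupper(raw[[idx["ref"]]]), toupper(raw[[idx["alt"]]]))
  rec <- cbind(keys,
               data.frame(barcode = raw[[idx["barcode"]]],
                          n_var = .check_counts(raw[[idx["n_var"]]], "variant count", lines),
                          n_ref = .check_counts(raw[[idx["n_ref"]]], "reference count", lines),
                          stringsAsFactors = FALSE))
  .finalize_records(rec, lines, dedup_policy, sample_id,
                    list(path = path, dialect = "screadcounts"))
}

.simple_synonyms <- c("snvid", "snv", "id", "variantid")

#' Read the simplified SNV-identifier read-count dialect
#'
#' A four-column tab-delimited table: SNV identifier
#' (`"chrom:pos:ref>alt"` or the `"chrom:pos_ref>alt"` dialect), cell
#' barcode, variant read count and reference read count. Same retention,
#' deduplication and zero-coverage rules as [read_screadcounts()].
#'
#' @inheritParams read_screadcounts
#' @return An `snv_table`.
#' @export
read_simple_table <- function(path, dedup_policy = c("error", "sum"),
                              sample_id = basename(path)) {
  dedup_policy <- match.arg(dedup_policy)
  raw <- read.delim(path, header = TRUE, colClasses = "character",
                    check.names = FALSE, stringsAsFactors = FALSE)
  nh <- .norm_header(names(raw))
  id_col <- which(nh %in% .simple_synonyms)
  if (length(id_col) == 0) {
    stop("input is missing a required column: 'snv_id' (accepted header names: ",
         paste(.simple_synonyms, collapse = ", "), ")")
  }
  idx <- .match_columns(names(raw), c("barcode", "n_var", "n_ref"))
  if (nrow(raw) == 0) {
    rec <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), snv_id = character(),
                      barcode = character(), n_var = integer(),
                      n_ref = integer(), stringsAsFactors = FALSE)
    return(new_snv_table(rec, sample_id,
                         list(path = path, dialect = "simple"), 0L))
  }
  lines <- seq_len(nrow(raw)) + 1L
  keys <- parse_snv_id(raw[[id_col[1]]])
  rec <- cbind(keys,
               data.frame(barcode = raw[[idx["barcode"]]],
                          n_var = .check_counts(raw[[idx["n_var"]]], "variant count", lines),
                          n_ref = .check_counts(raw[[idx["n_ref"]]], "reference count", lines),
                          stringsAsFactors = FALSE))
  .finalize_records(rec, lines, dedup_policy, sample_id,
                    list(path = path, dialect = "simple"))
}

#' Write an SNV table in the simplified dialect
#'
#' Emits `SNV_ID`, `Barcode`, `N_VAR`, `N_REF` tab-delimited with Unix line
#' endings; [read_simple_table()] on the result restores every record
#' exactly.
#'
#' @param table an `snv_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snv_table <- function(table, path) {
  out <- data.frame(SNV_ID = table$snv_id, Barcode = table$barcode,
                    N_VAR = table$n_var, N_REF = table$n_ref)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}

#' Read a genes-by-cells expression matrix
#'
#' Supports the MatrixMarket triplet layout written by Cell Ranger and
#' STARsolo (a `matrix.mtx` coordinate file with `features.tsv` — or
#' `genes.tsv` — and `barcodes.tsv` sidecars in the same directory) and a
#' dense TSV with genes in rows and cell barcodes in the header. Values
#' must be nonnegative integer raw counts; normalization is deliberately
#' left to downstream steps so there is a single place of truth for
#' preprocessing.
#'
#' @param path directory containing the triplet files, the path of the
#'   `.mtx` file itself, or the path of a dense TSV.
#' @param format `"auto"` (default; by extension/contents), `"mtx_triplet"`
#'   or `"dense_tsv"`.
#' @return A [Matrix::sparseMatrix()] (class `dgCMatrix`), genes x cells,
#'   with feature ids as rownames and barcodes as colnames in source order.
#' @export
read_expression_matrix <- function(path,
                                   format = c("auto", "mtx_triplet", "dense_tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path) || grepl("\\.mtx$", path)) "mtx_triplet" else "dense_tsv"
  }
  if (format == "mtx_triplet") {
    if (dir.exists(path)) {
      dir <- path
      mtx <- file.path(dir, "matrix.mtx")
    } else {
      dir <- dirname(path)
      mtx <- path
    }
    if (!file.exists(mtx)) stop("no matrix.mtx found under ", dir)
    feat_path <- Filter(file.exists,
                        file.path(dir, c("features.tsv", "genes.tsv")))
    bc_path <- file.path(dir, "barcodes.tsv")
    if (length(feat_path) == 0 || !file.exists(bc_path)) {
      stop("missing features.tsv/genes.tsv or barcodes.tsv sidecar under ", dir)
    }
    m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
    features <- read.delim(feat_path[1], header = FALSE,
                           stringsAsFactors = FALSE)[[1]]
    barcodes <- read.delim(bc_path, header = FALSE,
                           stringsAsFactors = FALSE)[[1]]
    if (nrow(m) != length(features) || ncol(m) != length(barcodes)) {
      stop("dimension mismatch: matrix is ", nrow(m), " x ", ncol(m),
           " but sidecars list ", length(features), " features and ",
           length(barcodes), " barcodes")
    }
    dimnames(m) <- list(features, barcodes)
  } else {
    df <- read.delim(path, header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
    genes <- df[[1]]
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- genes
    m <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  }
  if (any(m@x < 0) || any(m@x != floor(m@x))) {
    stop("expression values must be nonnegative integer raw counts")
  }
  if (length(m@x) == 0 || all(m@x == 0)) {
    message("expression matrix is all zero")
  }
  m
}

#' Reconcile SNV-table barcodes with expression-matrix barcodes
#'
#' Droplet pipelines frequently disagree on the trailing GEM-well suffix
#' (`"-1"`): one input carries `AAAC...-1`, the other bare `AAAC...`. The
#' `"auto"` policy first intersects barcodes verbatim and, if that is
#' empty, retries after stripping a trailing `-<digits>` from whichever
#' side carries one.
#'
#' @param snv_table an `snv_table`, or a character vector of SNV-side
#'   barcodes.
#' @param expr_barcodes character vector of expression-side barcodes.
#' @param suffix_policy `"auto"` (default), `"keep"` (verbatim match only)
#'   or `"strip"` (strip the suffix from both sides first).
#' @return A list: `matched` (barcodes in the matched key space),
#'   `snv_barcodes` / `expr_barcodes` (the original spellings aligned to
#'   `matched`), `n_unmatched_snv`, `n_unmatched_expr`, and the
#'   `policy_applied`. Warns when the overlap is below half of either
#'   side; errors when no barcode matches under the requested policy.
#' @export
harmonize_barcodes <- function(snv_table, expr_barcodes,
                               suffix_policy = c("auto", "keep", "strip")) {
  suffix_policy <- match.arg(suffix_policy)
  snv_bc <- unique(if (is.data.frame(snv_table)) snv_table$barcode else snv_table)
  expr_bc <- unique(as.character(expr_barcodes))
  if (length(snv_bc) == 0 || length(expr_bc) == 0) {
    stop("both barcode sets must be nonempty")
  }
  strip <- function(x) sub("-[0-9]+$", "", x)
  candidates <- switch(suffix_policy,
    keep  = list(list(snv = snv_bc, expr = expr_bc, applied = "keep")),
    strip = list(list(snv = strip(snv_bc), expr = strip(expr_bc), applied = "strip")),
    auto  = list(
      list(snv = snv_bc, expr = expr_bc, applied = "keep"),
      list(snv = snv_bc, expr = strip(expr_bc), applied = "strip expression suffix"),
      list(snv = strip(snv_bc), expr = expr_bc, applied = "strip SNV suffix"),
      list(snv = strip(snv_bc), expr = strip(expr_bc), applied = "strip both")
    ))
  for (cand in candidates) {
    common <- intersect(cand$snv, cand$expr)
    if (length(common) > 0) {
      res <- list(
        matched = common,
        snv_barcodes = snv_bc[match(common, cand$snv)],
        expr_barcodes = expr_bc[match(common, cand$expr)],
        n_unmatched_snv = length(snv_bc) - length(common),
        n_unmatched_expr = length(expr_bc) - length(common),
        policy_applied = cand$applied
      )
      if (length(common) < 0.5 * length(snv_bc) ||
          length(common) < 0.5 * length(expr_bc)) {
        warning("barcode overlap below 50% of one input (",
                length(common), " matched; ", res$n_unmatched_snv,
                " SNV-side and ", res$n_unmatched_expr,
                " expression-side barcodes unmatched)")
      }
      return(res)
    }
  }
  stop("no barcodes in common under suffix policy '", suffix_policy,
       "'; inspect the two inputs and set the policy manually")
}

# Numeric columns are serialized with %.17g so a read-back reproduces the
# double exactly; undefined values are empty fields, never "NA"/"NaN" text.
.fmt_full <- function(x) {
  out <- vapply(x, function(v) if (is.na(v)) "" else sprintf("%.17g", v), "")
  out
}

#' Write per-cell metric tables to TSV
#'
#' One row per cell; counts as integers, ratios at full double precision,
#' undefined ratios as empty fields. [read_metrics_table()] restores the
#' values exactly.
#'
#' @param metrics a `cell_metrics` data.frame from [compute_cell_metrics()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(metrics, path) {
  out <- data.frame(Barcode = metrics$barcode,
                    N_SNVs = metrics$n_snvs,
                    Total_N_VAR = metrics$total_nvar,
                    Total_N_REF = metrics$total_nref,
                    Total_VAF = .fmt_full(metrics$total_vaf),
                    Mean_VAF = .fmt_full(metrics$mean_vaf),
                    Median_VAF = .fmt_full(metrics$median_vaf),
                    stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   colClasses = c("character", "integer", "integer", "integer",
                                  "character", "character", "character"))
  num <- function(x) ifelse(x == "" | is.na(x), NA_real_, as.numeric(x))
  out <- data.frame(barcode = df$Barcode,
                    n_snvs = df$N_SNVs,
                    total_nvar = df$Total_N_VAR,
                    total_nref = df$Total_N_REF,
                    total_vaf = num(df$Total_VAF),
                    mean_vaf = num(df$Mean_VAF),
                    median_vaf = num(df$Median_VAF),
                    stringsAsFactors = FALSE)
  class(out) <- c("cell_metrics", "data.frame")
  out
}
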