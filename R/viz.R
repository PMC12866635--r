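#' Plot specification
#'
#' Controls how a metric is mapped onto an embedding: the gradient
#' family, point geometry, chrome toggles and dimensionality. VAF
#' metrics are always scaled over `[0, 1]`; count metrics over
#' `[0, max]` (optionally log1p-compressed). Cells whose metric is
#' undefined — no signal at the selected loci — are drawn in a reserved
#' color that never occurs inside the gradient, preserving the
#' no-signal / negative-signal distinction in every plot.
#'
#' @param metric column to color by: one of the per-cell set metrics
#'   (`n_snvs`, `total_nvar`, `total_nref`, `total_vaf`, `mean_vaf`,
#'   `median_vaf`), a per-SNV quantity (`n_var`, `n_ref`, `vaf`), or a
#'   categorical column (`cluster`, `sample`, `cell_type`).
#' @param gradient `"bichromatic"` (blue-white-red, midpoint 0.5 for
#'   VAF) or `"monochromatic"` (white-blue).
#' @param point_size point radius in pixels (interactive) / mm (static).
#' @param border draw a point border.
#' @param show_axes,show_legend,show_labels chrome toggles.
#' @param dims 2 or 3.
#' @param log_scale log1p-compress count gradients.
#' @param no_signal_color reserved color for undefined metrics.
#' @return a `plot_spec` list.
#' @export
plot_spec <- function(metric = "total_vaf",
                      gradient = c("bichromatic", "monochromatic"),
                      point_size = 4, border = FALSE, show_axes = TRUE,
                      show_legend = TRUE, show_labels = TRUE, dims = 2L,
                      log_scale = FALSE, no_signal_color = "#B3B3B3") {
  gradient <- match.arg(gradient)
  stopifnot(dims %in% c(2L, 3L))
  structure(list(metric = metric, gradient = gradient,
                 point_size = point_size, border = border,
                 show_axes = show_axes, show_legend = show_legend,
                 show_labels = show_labels, dims = as.integer(dims),
                 log_scale = log_scale, no_signal_color = no_signal_color),
            class = "plot_spec")
}

.vaf_like <- c("total_vaf", "mean_vaf", "median_vaf", "vaf")
.count_like <- c("n_snvs", "total_nvar", "total_nref", "n_var", "n_ref")
.categorical <- c("cluster", "sample", "cell_type")

.gradient_fun <- function(gradient) {
  cols <- if (gradient == "monochromatic") c("#FFFFFF", "#08306B")
          else c("#2166AC", "#F7F7F7", "#B2182B")
  grDevices::colorRamp(cols)
}

.map_colors <- function(values, spec) {
  metric <- spec$metric
  if (metric %in% .categorical || !is.numeric(values)) {
    lev <- sort(unique(values[!is.na(values)]))
    pal <- grDevices::hcl.colors(max(length(lev), 2L), palette = "Dark 3")
    col <- pal[match(values, lev)]
    col[is.na(col)] <- spec$no_signal_color
    return(list(colors = col, scale = list(type = "categorical",
                                           levels = as.character(lev),
                                           palette = pal[seq_along(lev)])))
  }
  if (metric %in% .vaf_like) {
    lo <- 0; hi <- 1
    t <- values
  } else {
    lo <- 0
    v <- if (spec$log_scale) log1p(values) else values
    hi <- max(c(v, 1), na.rm = TRUE)
    t <- v / hi
  }
  ramp <- .gradient_fun(spec$gradient)
  col <- rep(spec$no_signal_color, length(values))
  ok <- !is.na(t)
  if (any(ok)) {
    rgb <- ramp(pmin(pmax(t[ok], 0), 1))
    col[ok] <- grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
  }
  list(colors = col, scale = list(type = "gradient", lo = lo, hi = hi,
                                  gradient = spec$gradient,
                                  log_scale = isTRUE(spec$log_scale)))
}

.view_coords <- function(embedding, spec, method = NULL) {
  if (is.null(method)) method <- names(embedding$coords)[1]
  co <- embedding$coords[[method]]
  if (is.null(co)) stop("embedding has no '", method, "' coordinates")
  if (spec$dims == 3 && ncol(co) < 3) {
    stop("3D plot requested but the '", method, "' embedding is ",
         ncol(co), "-dimensional")
  }
  co[, seq_len(spec$dims), drop = FALSE]
}

#' Tabular view of an embedding plus per-cell quantities
#'
#' The common currency of the plot and selection operations: one row per
#' embedded cell, with coordinates, cluster (and sample / externally
#' supplied cell-type columns when present) and, optionally, the
#' per-cell set metrics and one SNV's `n_var` / `n_ref` / `vaf`.
#'
#' @param embedding a `cell_embedding`.
#' @param metrics optional `cell_metrics` (matched by barcode).
#' @param m optional `cell_snv_matrix`, with `snv` the id whose
#'   per-cell counts to attach.
#' @param snv optional SNV id (requires `m`).
#' @param method which coordinate set to use (default: first).
#' @return data.frame with class `cell_view`.
#' @export
cell_view <- function(embedding, metrics = NULL, m = NULL, snv = NULL,
                      method = NULL) {
  if (is.null(method)) method <- names(embedding$coords)[1]
  co <- embedding$coords[[method]]
  df <- data.frame(barcode = embedding$barcodes,
                   x = co[, 1], y = co[, 2], stringsAsFactors = FALSE)
  if (ncol(co) >= 3) df$z <- co[, 3]
  extra <- embedding$meta[, setdiff(names(embedding$meta), "barcode"),
                          drop = FALSE]
  df <- cbind(df, extra)
  if (!is.null(metrics)) {
    i <- match(df$barcode, metrics$barcode)
    for (col in setdiff(names(metrics), "barcode")) df[[col]] <- metrics[[col]][i]
  }
  if (!is.null(snv)) {
    if (is.null(m)) stop("attaching an SNV requires the cell_snv_matrix")
    j <- match(snv, m$snvs$snv_id)
    if (is.na(j)) stop("unknown SNV: ", snv)
    i <- match(df$barcode, m$cells)
    nv <- as.numeric(m$var_counts[, j])[i]
    nr <- as.numeric(m$ref_counts[, j])[i]
    cov <- !is.na(nv) & (nv + nr) >= 1
    df$n_var <- ifelse(cov, nv, NA_real_)
    df$n_ref <- ifelse(cov, nr, NA_real_)
    df$vaf <- ifelse(cov, nv / (nv + nr), NA_real_)
  }
  rownames(df) <- NULL
  class(df) <- c("cell_view", "data.frame")
  df
}

#' Select cells of a view by predicate
#'
#' The predicate is an expression over the view's columns (e.g.
#' `"vaf >= 0.5"`, `"n_var > 2 & cell_type == 'tumor'"`) or a function
#' of the view returning a logical vector. Cells where the predicate is
#' undefined (`NA`, e.g. VAF at an uncovered locus) are never selected.
#'
#' @param view a `cell_view` data.frame.
#' @param predicate character expression or function.
#' @return the filtered view (same class); warns when nothing matches.
#' @export
select_cells <- function(view, predicate) {
  keep <- if (is.function(predicate)) {
    predicate(view)
  } else {
    e <- tryCatch(parse(text = predicate)[[1]],
                  error = function(err) stop("unparseable predicate: ", predicate))
    tryCatch(eval(e, envir = view, enclos = parent.frame()),
             error = function(err) {
               stop("predicate references an unknown field: ",
                    conditionMessage(err), " (available: ",
                    paste(names(view), collapse = ", "), ")")
             })
  }
  keep <- !is.na(keep) & keep
  out <- view[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("no cells satisfy the predicate")
  rownames(out) <- NULL
  out
}

.panel_points <- function(view, values, spec) {
  mapped <- .map_colors(values, spec)
  pts <- data.frame(b = view$barcode, x = view$x, y = view$y,
                    stringsAsFactors = FALSE)
  if (spec$dims == 3) pts$z <- view$z
  pts$v <- values
  pts$c <- mapped$colors
  list(points = pts, scale = mapped$scale)
}

new_snv_plot <- function(panels, spec, title) {
  structure(list(panels = panels, spec = spec, title = title),
            class = "snv_plot")
}

#' Plot set-level metrics over an embedding
#'
#' One point per cell in the (possibly selected) view, colored by the
#' requested metric.
#'
#' @param view a `cell_view` (from [cell_view()] / [select_cells()]), or
#'   a `cell_embedding` when `metrics` is supplied.
#' @param spec a [plot_spec()]; `spec$metric` must name a view column.
#' @param metrics optional `cell_metrics` when `view` is an embedding.
#' @param path if non-NULL, write the interactive HTML document here.
#' @return an `snv_plot` (invisibly `path`-annotated when written).
#' @export
plot_set <- function(view, spec = plot_spec(), metrics = NULL, path = NULL) {
  if (inherits(view, "cell_embedding")) view <- cell_view(view, metrics = metrics)
  valid <- setdiff(names(view), c("barcode", "x", "y", "z"))
  if (!spec$metric %in% names(view)) {
    stop("unknown metric '", spec$metric, "'; available: ",
         paste(valid, collapse = ", "))
  }
  if (spec$dims == 3 && is.null(view$z)) {
    stop("3D plot requested but the view holds 2D coordinates")
  }
  values <- view[[spec$metric]]
  if (all(is.na(values))) {
    warning("metric '", spec$metric, "' is undefined for every cell in view")
  }
  p <- new_snv_plot(list(c(list(title = spec$metric),
                           .panel_points(view, values, spec))),
                    spec, paste0("SNV set: ", spec$metric))
  if (!is.null(path)) write_plot_html(p, path)
  p
}

#' Plot one SNV's N_VAR, N_REF and VAF_RNA as linked panels
#'
#' Three panels over the same coordinates. Cells without coverage at the
#' locus take the reserved no-signal color in all three; variant-only
#' cells show VAF 1 and reference-only cells VAF 0, so monoallelic
#' variant and monoallelic reference expression are visually distinct.
#'
#' @param embedding a `cell_embedding` (or ready `cell_view`).
#' @param m a `cell_snv_matrix` containing `snv`.
#' @param snv canonical SNV id.
#' @param spec a [plot_spec()] (its `metric` field is ignored).
#' @param path if non-NULL, write the interactive HTML document here.
#' @return an `snv_plot` with three panels.
#' @export
plot_individual_snv <- function(embedding, m, snv, spec = plot_spec(),
                                path = NULL) {
  view <- if (inherits(embedding, "cell_view")) embedding
          else cell_view(embedding, m = m, snv = snv)
  if (spec$dims == 3 && is.null(view$z)) {
    stop("3D plot requested but the view holds 2D coordinates")
  }
  panels <- lapply(c("n_var", "n_ref", "vaf"), function(metric) {
    pspec <- spec
    pspec$metric <- metric
    c(list(title = toupper(metric)), .panel_points(view, view[[metric]], pspec))
  })
  p <- new_snv_plot(panels, spec, paste0("SNV ", snv))
  if (!is.null(path)) write_plot_html(p, path)
  p
}

#' Histogram figures for per-group metric summaries
#'
#' One figure per metric, one facet per group, bar heights exactly the
#' [histogram_data()] counts.
#'
#' @param summaries a `cluster_metrics_summary` from
#'   [summarize_by_group()].
#' @param dir if non-NULL, write one PNG per metric into this directory.
#' @return named list of ggplot objects, invisibly when writing.
#' @export
plot_histograms <- function(summaries, dir = NULL) {
  groups <- names(summaries$histograms)
  plots <- list()
  for (metric in .metric_cols) {
    df <- do.call(rbind, lapply(groups, function(g) {
      h <- summaries$histograms[[g]][[metric]]
      mid <- (utils::head(h$edges, -1) + utils::tail(h$edges, -1)) / 2
      data.frame(group = g, mid = mid, count = h$counts,
                 width = diff(h$edges), stringsAsFactors = FALSE)
    }))
    plots[[metric]] <- ggplot2::ggplot(df, ggplot2::aes(x = mid, y = count)) +
      ggplot2::geom_col(width = df$width, fill = "#4477AA") +
      ggplot2::facet_wrap(~group) +
      ggplot2::labs(title = metric, x = metric, y = "cells") +
      ggplot2::theme_minimal()
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      grDevices::png(file.path(dir, paste0("hist_", metric, ".png")),
                     width = 900, height = 500, res = 110)
      print(plots[[metric]])
      grDevices::dev.off()
    }
  }
  if (is.null(dir)) plots else invisible(plots)
}

#' Write an interactive plot as a single self-contained HTML document
#'
#' The document embeds the full point data as a JSON island
#' (`<script type="application/json" id="cellsnv-data">`) rendered by a
#' small dependency-free canvas viewer (pan/zoom in 2D, drag-to-rotate
#' in 3D, hover tooltips). The data block is byte-deterministic for
#' identical inputs and machine-readable via [read_plot_data()].
#'
#' @param plot an `snv_plot`.
#' @param path output `.html` path.
#' @return `path`, invisibly.
#' @export
write_plot_html <- function(plot, path) {
  payload <- list(
    title = plot$title,
    dims = plot$spec$dims,
    reserved_color = plot$spec$no_signal_color,
    point_size = plot$spec$point_size,
    border = isTRUE(plot$spec$border),
    show_axes = isTRUE(plot$spec$show_axes),
    show_legend = isTRUE(plot$spec$show_legend),
    show_labels = isTRUE(plot$spec$show_labels),
    panels = lapply(plot$panels, function(p) {
      list(title = p$title, scale = p$scale, points = p$points)
    })
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", na = "null")
  html <- paste0(
    "<!DOCTYPE html>\n<html>\n<head>\n<meta charset=\"utf-8\">\n<title>",
    plot$title,
    "</title>\n<style>body{font-family:sans-serif;margin:12px}",
    ".panel{display:inline-block;margin:6px;vertical-align:top}",
    "canvas{border:1px solid #ddd}h3{margin:4px 0}",
    "#tip{position:fixed;background:#222;color:#fff;padding:3px 6px;",
    "border-radius:3px;font-size:12px;pointer-events:none;display:none}",
    "</style>\n</head>\n<body>\n<h2>", plot$title, "</h2>\n",
    "<div id=\"plots\"></div>\n<div id=\"tip\"></div>\n",
    "<script type=\"application/json\" id=\"cellsnv-data\">", json,
    "</script>\n<script>", .viewer_js, "</script>\n</body>\n</html>\n")
  con <- file(path, open = "wb")
  writeLines(html, con, sep = "")
  close(con)
  invisible(path)
}

#' Read back the data block of an emitted interactive document
#'
#' @param path path to an HTML file written by [write_plot_html()].
#' @return the parsed payload list (panels carry their point
#'   data.frames).
#' @export
read_plot_data <- function(path) {
  html <- paste(readLines(path, warn = FALSE), collapse = "\n")
  m <- regmatches(html, regexpr(
    "<script type=\"application/json\" id=\"cellsnv-data\">.*?</script>", html))
  if (length(m) == 0) stop("no cellsnv data block found in ", path)
  json <- sub("^<script[^>]*>", "", sub("</script>$", "", m))
  jsonlite::fromJSON(json, simplifyDataFrame = TRUE)
}

#' Export a static snapshot of a plot
#'
#' Renders the same point data with ggplot2 into a raster (PNG) or
#' vector (PDF) file.
#'
#' @param plot an `snv_plot`.
#' @param path output file path.
#' @param format `"png"` (default) or `"pdf"`.
#' @param width,height,res device geometry (pixels for png, inches for
#'   pdf).
#' @return `path`, invisibly.
#' @export
export_snapshot <- function(plot, path, format = c("png", "pdf"),
                            width = 700, height = 600, res = 110) {
  format <- match.arg(format)
  n_panels <- length(plot$panels)
  if (format == "png") {
    grDevices::png(path, width = width * n_panels, height = height, res = res)
  } else {
    grDevices::pdf(path, width = 7 * n_panels, height = 6)
  }
  on.exit(grDevices::dev.off())
  gs <- lapply(plot$panels, function(p) {
    df <- p$points
    g <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
      ggplot2::geom_point(color = df$c, size = plot$spec$point_size / 2,
                          shape = if (isTRUE(plot$spec$border)) 21 else 16) +
      ggplot2::labs(title = p$title) +
      ggplot2::theme_minimal()
    if (!isTRUE(plot$spec$show_axes)) g <- g + ggplot2::theme_void()
    g
  })
  if (n_panels == 1) {
    print(gs[[1]])
  } else {
    grid_cols <- n_panels
    grid::grid.newpage()
    grid::pushViewport(grid::viewport(layout = grid::grid.layout(1, grid_cols)))
    for (i in seq_len(n_panels)) {
      print(gs[[i]], vp = grid::viewport(layout.pos.row = 1,
                                         layout.pos.col = i))
    }
  }
  invisible(path)
}
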