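# Spatial heatmap rendering: assay values -> feature fills through a
# color key; panels laid out over genes x conditions.

# Aggregate assay values to gene x feature x condition means (or medians).
.aggregate_values <- function(assay, genes, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  meta <- assay$sample_meta
  feats <- unique(meta$feature)
  conds <- unique(meta$condition)
  fun <- if (aggregate == "mean") mean else stats::median
  arr <- array(NA_real_, dim = c(length(genes), length(feats), length(conds)),
               dimnames = list(genes, feats, conds))
  for (f in feats) for (cd in conds) {
    sel <- meta$feature == f & meta$condition == cd
    if (!any(sel)) next
    sub <- assay$values[genes, sel, drop = FALSE]
    arr[, f, cd] <- apply(sub, 1L, fun)
  }
  arr
}

.default_palette <- function(value_space) {
  if (value_space == "lfc") "bwr" else "yorrd"
}

#' Render a spatial heatmap figure
#'
#' Produces one colored panel per (gene, condition): each mapped feature's
#' fill is \code{color_of(key, value)} where the value is the replicate
#' aggregate (mean by default) of that gene in that feature and condition.
#' Unmapped features keep their original fill; mapped features without a
#' measurement get the key's NA color. With \code{scale_mode = "shared"}
#' one key spans all panels; \code{"per_gene"} builds one key per gene.
#'
#' @param doc an \code{svg_doc}.
#' @param assay an \code{assay_table} (any value space; lfc space selects a
#'   zero-centered diverging key by default).
#' @param genes character vector of gene ids to plot.
#' @param map a \code{feature_sample_map} from \code{\link{map_features}};
#'   computed automatically when NULL.
#' @param layout list; \code{genes_axis} "row" (default) or "col" decides
#'   whether genes vary along rows or columns of the panel grid.
#' @param key_opts list of key options: \code{palette}, \code{k},
#'   \code{scale_mode}, \code{symmetric}, \code{aggregate}.
#' @return an object of class \code{shm_figure}: panels (named
#'   \code{gene__condition} list of colored \code{svg_doc}s), \code{keys}
#'   (per gene or single shared), \code{legend} doc with fixed per-feature
#'   colors, \code{genes}, \code{conditions}, \code{layout}, \code{values}.
#' @export
render_shm <- function(doc, assay, genes, map = NULL,
                       layout = list(genes_axis = "row"),
                       key_opts = list()) {
  unknown <- setdiff(genes, rownames(assay$values))
  if (length(unknown))
    stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  if (is.null(map)) map <- suppressWarnings(map_features(assay, doc))
  if (!nrow(map$pairs)) stop("zero mapped features; cannot render")

  aggregate <- if (!is.null(key_opts$aggregate)) key_opts$aggregate else "mean"
  arr <- .aggregate_values(assay, genes, aggregate)
  conds <- dimnames(arr)[[3]]
  palette <- if (!is.null(key_opts$palette)) key_opts$palette
             else .default_palette(assay$value_space)
  k <- if (!is.null(key_opts$k)) key_opts$k else 50L
  scale_mode <- if (!is.null(key_opts$scale_mode)) key_opts$scale_mode else "shared"
  symmetric <- if (!is.null(key_opts$symmetric)) key_opts$symmetric
               else assay$value_space == "lfc"

  mapped <- map$pairs
  keys <- list()
  if (scale_mode == "shared") {
    vals <- arr[, mapped$assay_label, , drop = FALSE]
    shared_key <- make_color_key(as.numeric(vals), palette, k,
                                 scale_mode = "shared", symmetric = symmetric)
  }
  panels <- list()
  for (g in genes) {
    if (scale_mode == "per_gene") {
      vals <- arr[g, mapped$assay_label, , drop = FALSE]
      keys[[g]] <- make_color_key(as.numeric(vals), palette, k,
                                  scale_mode = "per_gene",
                                  symmetric = symmetric)
    } else keys[[g]] <- shared_key
    for (cd in conds) {
      p <- doc
      for (i in seq_len(nrow(mapped))) {
        v <- arr[g, mapped$assay_label[i], cd]
        fid <- mapped$svg_id[i]
        j <- which(feature_ids(p) == fid)
        p$features[[j]]$style$fill <- color_of(keys[[g]], v)
      }
      panels[[paste0(g, "__", cd)]] <- p
    }
  }

  # legend: fixed categorical colors distinguishing mapped features
  legend <- doc
  cat_cols <- .categorical_colors(nrow(mapped))
  for (i in seq_len(nrow(mapped))) {
    j <- which(feature_ids(legend) == mapped$svg_id[i])
    legend$features[[j]]$style$fill <- cat_cols[i]
  }

  structure(list(panels = panels, keys = keys,
                 key = keys[[genes[1]]], legend = legend,
                 genes = genes, conditions = conds,
                 layout = layout, values = arr, map = map),
            class = "shm_figure")
}

#' @export
print.shm_figure <- function(x, ...) {
  cat(sprintf("<shm_figure> %d gene(s) x %d condition(s) = %d panel(s)\n",
              length(x$genes), length(x$conditions), length(x$panels)))
  invisible(x)
}

.categorical_colors <- function(n) {
  base <- c("#E41A1C", "#377EB8", "#4DAF4A", "#984EA3", "#FF7F00",
            "#A65628", "#F781BF", "#17BECF", "#BCBD22", "#999999")
  if (n <= length(base)) base[seq_len(n)]
  else grDevices::colorRampPalette(base)(n)
}

#' Attach a raster image below the vector layers
#'
#' Emulates photo-realistic spatial heatmaps: the raster (PNG or JPEG) is
#' embedded as the bottom layer of the written SVG at the given opacity,
#' optionally desaturated to grayscale (PNG input only).
#'
#' @param doc an \code{svg_doc}.
#' @param raster_path path to the raster file; must be readable.
#' @param alpha_raster raster opacity in [0, 1].
#' @param grayscale desaturate the raster before embedding.
#' @return the modified \code{svg_doc}.
#' @export
render_with_raster <- function(doc, raster_path = doc$raster_path,
                               alpha_raster = 0.5, grayscale = FALSE) {
  if (is.null(raster_path) || !file.exists(raster_path))
    stop("raster not readable: ",
         if (is.null(raster_path)) "<unset>" else raster_path)
  if (alpha_raster < 0 || alpha_raster > 1)
    stop("alpha_raster must be in [0, 1]")
  doc$raster_path <- raster_path
  doc$raster_alpha <- alpha_raster
  doc$raster_grayscale <- isTRUE(grayscale)
  doc
}

# Draw one svg_doc into the active base-graphics device (y flipped so the
# SVG y-down frame displays upright).
.draw_doc <- function(doc, main = NULL) {
  graphics::par(mar = c(0.2, 0.2, if (is.null(main)) 0.2 else 1.2, 0.2))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, doc$width), ylim = c(doc$height, 0),
                        asp = 1)
  if (!is.null(doc$raster_path) && file.exists(doc$raster_path) &&
      tolower(tools::file_ext(doc$raster_path)) == "png") {
    img <- png::readPNG(doc$raster_path)
    graphics::rasterImage(img, 0, doc$height, doc$width, 0)
  }
  ord <- order(vapply(doc$features, `[[`, 0L, "layer_index"))
  for (f in doc$features[ord]) {
    fill <- if (is.na(f$style$fill)) NA else f$style$fill
    alpha <- if (is.na(f$style$opacity)) 1 else f$style$opacity
    col <- if (is.na(fill) || fill == "none") NA
           else grDevices::adjustcolor(fill, alpha.f = alpha)
    border <- if (is.na(f$style$stroke) || f$style$stroke == "none") NA
              else f$style$stroke
    for (m in feature_polygons(f))
      graphics::polygon(m[, 1], m[, 2], col = col, border = border)
  }
  if (!is.null(main)) graphics::title(main = main, cex.main = 0.8)
}

# Write the color key as a small standalone SVG (horizontal bar + labels).
.write_key_svg <- function(key, path, width = 320, height = 60) {
  k <- length(key$colors)
  bw <- (width - 40) / k
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                            'version="1.1" width="%d" height="%d">'),
                     width, height))
  for (i in seq_len(k))
    lines <- c(lines, sprintf(
      '  <rect x="%s" y="10" width="%s" height="20" fill="%s"/>',
      .fmt_num(20 + (i - 1) * bw), .fmt_num(bw), key$colors[i]))
  labs <- seq(1L, k + 1L, length.out = 5L)
  for (j in unique(round(labs)))
    lines <- c(lines, sprintf(
      '  <text x="%s" y="48" font-size="10" text-anchor="middle">%s</text>',
      .fmt_num(20 + (j - 1) * bw), .fmt_num(key$breaks[j])))
  lines <- c(lines, "</svg>")
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Write a spatial heatmap figure to disk
#'
#' Writes one SVG per panel named \code{{gene}__{condition}.svg}, the color
#' key as \code{key.svg} (per-gene keys as \code{key_{gene}.svg}), the
#' legend as \code{legend.svg}, and a composite raster \code{composite.png}
#' with panels on a genes x conditions grid (transposed when
#' \code{genes_axis = "col"}).
#'
#' @param fig an \code{shm_figure}.
#' @param dir output directory (created if needed).
#' @param dpi raster resolution for the composite (default 150).
#' @param png write the composite PNG (default TRUE).
#' @return character vector of written paths, invisibly.
#' @export
write_shm <- function(fig, dir, dpi = 150, png = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(fig$panels)) {
    p <- file.path(dir, paste0(nm, ".svg"))
    write_svg(fig$panels[[nm]], p)
    paths <- c(paths, p)
  }
  if (fig$key$scale_mode == "shared") {
    p <- file.path(dir, "key.svg")
    .write_key_svg(fig$key, p)
    paths <- c(paths, p)
  } else {
    for (g in fig$genes) {
      p <- file.path(dir, paste0("key_", g, ".svg"))
      .write_key_svg(fig$keys[[g]], p)
      paths <- c(paths, p)
    }
  }
  lp <- file.path(dir, "legend.svg")
  write_svg(fig$legend, lp)
  paths <- c(paths, lp)
  if (png) {
    cp <- file.path(dir, "composite.png")
    rasterize_shm(fig, cp, dpi = dpi)
    paths <- c(paths, cp)
  }
  invisible(paths)
}

#' Rasterize a spatial heatmap figure to PNG
#'
#' @param fig an \code{shm_figure}.
#' @param path output PNG path.
#' @param dpi resolution (default 150).
#' @return \code{path}, invisibly.
#' @export
rasterize_shm <- function(fig, path, dpi = 150) {
  genes_axis <- if (!is.null(fig$layout$genes_axis)) fig$layout$genes_axis
                else "row"
  ng <- length(fig$genes); nc <- length(fig$conditions)
  nrow_ <- if (genes_axis == "row") ng else nc
  ncol_ <- if (genes_axis == "row") nc else ng
  d1 <- fig$panels[[1]]
  pw <- max(2, d1$width / 72); ph <- max(2, d1$height / 72)
  grDevices::png(path, width = pw * ncol_, height = ph * nrow_,
                 units = "in", res = dpi)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(nrow_, ncol_))
  for (r in seq_len(nrow_)) for (cc in seq_len(ncol_)) {
    g <- if (genes_axis == "row") fig$genes[r] else fig$genes[cc]
    cd <- if (genes_axis == "row") fig$conditions[cc] else fig$conditions[r]
    .draw_doc(fig$panels[[paste0(g, "__", cd)]], main = paste(g, cd, sep = " / "))
  }
  invisible(path)
}

#' Rasterize a single document to PNG
#'
#' @param doc an \code{svg_doc}.
#' @param path output PNG path.
#' @param dpi resolution (default 150).
#' @return \code{path}, invisibly.
#' @export
rasterize_doc <- function(doc, path, dpi = 150) {
  grDevices::png(path, width = max(2, doc$width / 72),
                 height = max(2, doc$height / 72), units = "in", res = dpi)
  on.exit(grDevices::dev.off())
  .draw_doc(doc)
  invisible(path)
}
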