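# Co-visualization: link single-cell groups to anatomical features and
# render composite figures (embedding plot + SHM with shared colors),
# spatially resolved overlays (scSHM), and deconvolution-result views.

#' Dimensionality reduction of a single-cell assay
#'
#' PCA is implemented natively (centering + SVD, deterministic; each
#' component's sign is fixed so its largest-magnitude loading is positive).
#' UMAP and tSNE are capability-gated plug-ins: they require the optional
#' \pkg{uwot} / \pkg{Rtsne} packages and honor the seed; when the package is
#' missing a capability error is raised.
#'
#' @param sc an \code{sc_assay}; counts are log-normalized internally.
#' @param method \code{"pca"}, \code{"umap"} or \code{"tsne"}.
#' @param n_components number of output dimensions (default 2).
#' @param seed integer seed (mandatory for the stochastic reducers).
#' @return an \code{embedding}: list with \code{coords} (cells x
#'   n_components, rownames = cell ids), \code{method}, \code{seed},
#'   \code{variance_explained} (PCA only).
#' @export
reduce_dims <- function(sc, method = c("pca", "umap", "tsne"),
                        n_components = 2L, seed = 1L) {
  method <- match.arg(method)
  if (ncol(sc$values) < 3L) stop("need at least 3 cells")
  x <- t(.sc_lognorm(sc)$values)  # cells x genes
  if (method == "pca") {
    xc <- sweep(x, 2L, colMeans(x))
    sv <- svd(xc, nu = n_components, nv = n_components)
    # sign fix: largest-|loading| entry of each component positive
    for (j in seq_len(n_components)) {
      i <- which.max(abs(sv$v[, j]))
      if (sv$v[i, j] < 0) { sv$v[, j] <- -sv$v[, j]; sv$u[, j] <- -sv$u[, j] }
    }
    coords <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
    ve <- sv$d^2 / sum(sv$d^2)
    rownames(coords) <- colnames(sc$values)
    colnames(coords) <- paste0("PC", seq_len(n_components))
    return(structure(list(coords = coords, method = "pca",
                          seed = as.integer(seed),
                          variance_explained = ve[seq_len(n_components)]),
                     class = "embedding"))
  }
  pkg <- c(umap = "uwot", tsne = "Rtsne")[[method]]
  if (!requireNamespace(pkg, quietly = TRUE))
    stop("method '", method, "' needs the optional package '", pkg,
         "', which is not installed")
  set.seed(seed)
  coords <- if (method == "umap")
    uwot::umap(x, n_components = n_components)
  else Rtsne::Rtsne(x, dims = n_components)$Y
  rownames(coords) <- colnames(sc$values)
  structure(list(coords = coords, method = method, seed = as.integer(seed),
                 variance_explained = NULL),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("<embedding> %d cells x %d dims (%s)\n",
              nrow(x$coords), ncol(x$coords), x$method))
  invisible(x)
}

.tissue_cell_map <- function(pairs, orphan_groups, provenance) {
  structure(list(pairs = pairs, orphan_groups = orphan_groups,
                 provenance = provenance),
            class = "tissue_cell_map")
}

#' @export
print.tissue_cell_map <- function(x, ...) {
  cat(sprintf("<tissue_cell_map> %d pair(s) [%s], %d orphan group(s)\n",
              nrow(x$pairs), x$provenance, length(x$orphan_groups)))
  if (nrow(x$pairs))
    for (i in seq_len(nrow(x$pairs)))
      cat(sprintf("  %s -> %s\n", x$pairs$group[i], x$pairs$svg_id[i]))
  invisible(x)
}

#' Assign cell groups to anatomical features
#'
#' Five mapping methods: \describe{
#'   \item{annotation}{cell-metadata group labels matched to SVG ids (via an
#'     optional translation table, as \code{\link{map_features}}).}
#'   \item{marker}{each feature's enriched marker set (from an
#'     \code{enrichment_result} on the bulk data) scores every cell group by
#'     mean log expression; a group is assigned to the argmax feature when
#'     its score beats the runner-up by margin \code{delta} (default 0.5
#'     log2 units), otherwise it is orphaned.}
#'   \item{manual}{verbatim pairs table (\code{group}, \code{svg_id}),
#'     validated against the document.}
#'   \item{cluster}{kmeans (k clusters, mandatory seed) on the top principal
#'     components; cluster labels are then mapped via a provided
#'     \code{cluster_map} table.}
#'   \item{cocluster}{see \code{\link{cocluster}}.}
#' }
#'
#' @param sc an \code{sc_assay}.
#' @param bulk bulk \code{assay_table} (marker and cocluster methods).
#' @param doc an \code{svg_doc}.
#' @param method one of annotation, marker, manual, cluster, cocluster.
#' @param enrichment an \code{enrichment_result} (marker method).
#' @param pairs data.frame (\code{group}, \code{svg_id}) for manual.
#' @param translation translation table for annotation.
#' @param k,seed clustering parameters (cluster/cocluster methods).
#' @param cluster_map data.frame (\code{cluster}, \code{svg_id}) for cluster.
#' @param delta marker score margin (log2 units).
#' @param n_markers markers used per feature (marker method, default 20).
#' @return a \code{tissue_cell_map}: \code{pairs} (data.frame \code{group},
#'   \code{svg_id}), \code{orphan_groups}, \code{provenance}.
#' @export
assign_cells <- function(sc, bulk = NULL, doc,
                         method = c("annotation", "marker", "manual",
                                    "cluster", "cocluster"),
                         enrichment = NULL, pairs = NULL, translation = NULL,
                         k = NULL, seed = 1L, cluster_map = NULL,
                         delta = 0.5, n_markers = 20L) {
  method <- match.arg(method)
  ids <- feature_ids(doc)
  if (method == "annotation") {
    if (!"group" %in% names(sc$cell_meta))
      stop("annotation method needs a 'group' column in cell metadata")
    groups <- unique(sc$cell_meta$group)
    fm <- suppressWarnings(map_features(groups, doc, translation))
    return(.tissue_cell_map(
      data.frame(group = fm$pairs$assay_label, svg_id = fm$pairs$svg_id,
                 stringsAsFactors = FALSE),
      orphan_groups = fm$unmatched_assay, provenance = "annotation"))
  }
  if (method == "manual") {
    if (is.null(pairs)) stop("manual method needs a pairs table")
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    bad <- setdiff(pairs$svg_id, ids)
    if (length(bad))
      stop("manual pairs name unknown feature(s): ",
           paste(bad, collapse = ", "))
    groups <- unique(sc$cell_meta$group)
    return(.tissue_cell_map(pairs[, c("group", "svg_id")],
                            orphan_groups = setdiff(groups, pairs$group),
                            provenance = "manual"))
  }
  if (method == "marker") {
    if (is.null(enrichment) || !inherits(enrichment, "enrichment_result"))
      stop("marker method needs an enrichment_result on the bulk data")
    if (!"group" %in% names(sc$cell_meta))
      stop("marker method needs a 'group' column in cell metadata")
    scl <- .sc_lognorm(sc)
    groups <- unique(sc$cell_meta$group)
    feats <- intersect(enrichment$query_features, ids)
    scores <- matrix(NA_real_, length(groups), length(feats),
                     dimnames = list(groups, feats))
    for (f in feats) {
      mk <- utils::head(enriched_genes(enrichment, f), n_markers)
      mk <- intersect(mk, rownames(scl$values))
      if (!length(mk)) next
      for (g in groups) {
        cells <- scl$cell_meta$group == g
        scores[g, f] <- mean(scl$values[mk, cells, drop = FALSE])
      }
    }
    assigned <- character(); orphans <- character()
    out <- list()
    for (g in groups) {
      s <- scores[g, ]
      if (all(is.na(s))) { orphans <- c(orphans, g); next }
      ord <- order(-s)
      best <- s[ord[1]]
      second <- if (length(s) > 1L) s[ord[2]] else -Inf
      if (is.finite(best) && best - second >= delta) {
        out[[g]] <- data.frame(group = g, svg_id = feats[ord[1]],
                               stringsAsFactors = FALSE)
      } else orphans <- c(orphans, g)
    }
    pairs <- if (length(out)) do.call(rbind, out)
             else data.frame(group = character(), svg_id = character(),
                             stringsAsFactors = FALSE)
    rownames(pairs) <- NULL
    return(.tissue_cell_map(pairs, orphans, "marker"))
  }
  if (method == "cluster") {
    if (is.null(k)) stop("cluster method needs k")
    if (is.null(cluster_map)) stop("cluster method needs a cluster_map table")
    emb <- reduce_dims(sc, "pca",
                       n_components = min(10L, ncol(sc$values) - 1L,
                                          nrow(sc$values)),
                       seed = seed)
    set.seed(seed)
    cl <- stats::kmeans(emb$coords, centers = k, nstart = 10L)$cluster
    cluster_map <- as.data.frame(cluster_map, stringsAsFactors = FALSE)
    bad <- setdiff(cluster_map$svg_id, ids)
    if (length(bad))
      stop("cluster_map names unknown feature(s): ",
           paste(bad, collapse = ", "))
    groups <- paste0("cluster_", sort(unique(cl)))
    hit <- match(sort(unique(cl)), cluster_map$cluster)
    pairs <- data.frame(group = groups[!is.na(hit)],
                        svg_id = cluster_map$svg_id[hit[!is.na(hit)]],
                        stringsAsFactors = FALSE)
    map <- .tissue_cell_map(pairs, groups[is.na(hit)], "cluster")
    map$cell_clusters <- stats::setNames(paste0("cluster_", cl),
                                         colnames(sc$values))
    return(map)
  }
  # cocluster
  cocluster(bulk, sc, doc = doc, k = k, seed = seed)
}

#' Co-cluster bulk features and single cells
#'
#' Simplified co-clustering: (1) intersect gene ids of bulk and single-cell
#' data (>= 50 required); (2) log-normalize both; (3) form preliminary cell
#' clusters by kmeans on the top PCA components (k = number of bulk features
#' by default, fixed seed) and average cells within each cluster into
#' pseudo-profiles; (4) correlate pseudo-profiles with bulk feature means;
#' (5) assign each cluster to the bulk feature of maximum correlation when
#' that correlation is >= \code{min_cor} (default 0.3), else orphan.
#'
#' @param bulk bulk \code{assay_table} (>= 2 features).
#' @param sc an \code{sc_assay}.
#' @param doc optional \code{svg_doc}; when given, features absent from the
#'   document stay assignable but are reported unmatched downstream.
#' @param k number of preliminary clusters (default = number of features).
#' @param seed integer seed for kmeans.
#' @param min_cor correlation floor for an assignment.
#' @param use_groups use existing cell group labels as the preliminary
#'   clusters instead of kmeans (default TRUE when present).
#' @return a \code{tissue_cell_map} with provenance \code{"cocluster"}; the
#'   per-cell cluster labels are attached as \code{cell_clusters}.
#' @export
cocluster <- function(bulk, sc, doc = NULL, k = NULL, seed = 1L,
                      min_cor = 0.3,
                      use_groups = "group" %in% names(sc$cell_meta)) {
  if (is.null(bulk)) stop("cocluster needs bulk data")
  shared <- intersect(rownames(bulk$values), rownames(sc$values))
  if (length(shared) < 50L)
    stop("need >= 50 shared genes, got ", length(shared))
  feats <- unique(bulk$sample_meta$feature)
  if (length(feats) < 2L) stop("need >= 2 bulk features")

  bl <- if (bulk$value_space == "counts")
    normalize_assay(bulk, "cpm", log2 = TRUE) else bulk
  scl <- .sc_lognorm(sc)
  bv <- bl$values[shared, , drop = FALSE]
  sv <- scl$values[shared, , drop = FALSE]

  bulk_means <- vapply(feats, function(f)
    rowMeans(bv[, bl$sample_meta$feature == f, drop = FALSE]),
    numeric(length(shared)))

  if (isTRUE(use_groups)) {
    cl <- sc$cell_meta$group
  } else {
    if (is.null(k)) k <- length(feats)
    emb <- reduce_dims(sc, "pca",
                       n_components = min(10L, ncol(sc$values) - 1L),
                       seed = seed)
    set.seed(seed)
    cl <- paste0("cluster_", stats::kmeans(emb$coords, centers = k,
                                           nstart = 10L)$cluster)
  }
  groups <- unique(cl)
  pseudo <- vapply(groups, function(g)
    rowMeans(sv[, cl == g, drop = FALSE]), numeric(length(shared)))

  cors <- stats::cor(pseudo, bulk_means)  # groups x features
  out <- list(); orphans <- character()
  for (i in seq_along(groups)) {
    j <- which.max(cors[i, ])
    if (cors[i, j] >= min_cor)
      out[[groups[i]]] <- data.frame(group = groups[i], svg_id = feats[j],
                                     stringsAsFactors = FALSE)
    else orphans <- c(orphans, groups[i])
  }
  pairs <- if (length(out)) do.call(rbind, out)
           else data.frame(group = character(), svg_id = character(),
                           stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  map <- .tissue_cell_map(pairs, orphans, "cocluster")
  map$cell_clusters <- stats::setNames(cl, colnames(sc$values))
  map$correlations <- cors
  map
}

#' Colors for cells and features under a coloring scheme
#'
#' Schemes: \describe{
#'   \item{fixed_by_group}{one categorical color per mapped feature, applied
#'     to the feature and its cell group; no key.}
#'   \item{cell_by_group}{per-group summary (mean/median) of single-cell
#'     expression of \code{gene}; one key color per group, applied to its
#'     cells and matched feature.}
#'   \item{feature_by_group}{bulk value per feature applied to the feature
#'     and its cells.}
#'   \item{cell_by_value}{each cell colored by its own value; features by
#'     the bulk value; one shared key.}
#' }
#' Orphan groups are always grey.
#'
#' @param scheme coloring scheme (above).
#' @param map a \code{tissue_cell_map}.
#' @param sc an \code{sc_assay}.
#' @param bulk bulk \code{assay_table} (feature_by_group / cell_by_value).
#' @param gene gene id; required for every scheme except fixed_by_group.
#' @param summary \code{"mean"} or \code{"median"} (cell_by_group).
#' @param key_opts list of \code{\link{make_color_key}} options.
#' @return list with \code{cell_colors} (named by cell id),
#'   \code{feature_colors} (named by svg id), \code{key} (NULL for
#'   fixed_by_group).
#' @export
colorize <- function(scheme = c("fixed_by_group", "cell_by_group",
                                "feature_by_group", "cell_by_value"),
                     map, sc, bulk = NULL, gene = NULL,
                     summary = c("mean", "median"), key_opts = list()) {
  scheme <- match.arg(scheme)
  summary <- match.arg(summary)
  if (scheme != "fixed_by_group" && is.null(gene))
    stop("scheme '", scheme, "' requires a gene")
  groups_of_cells <- .cell_groups(sc, map)
  mapped <- map$pairs
  palette <- if (!is.null(key_opts$palette)) key_opts$palette else "yorrd"
  kbins <- if (!is.null(key_opts$k)) key_opts$k else 50L
  sfun <- if (summary == "mean") mean else stats::median

  cell_colors <- rep(.NA_COLOR, ncol(sc$values))
  names(cell_colors) <- colnames(sc$values)
  feature_colors <- character()

  if (scheme == "fixed_by_group") {
    cols <- .categorical_colors(nrow(mapped))
    feature_colors <- stats::setNames(cols, mapped$svg_id)
    for (i in seq_len(nrow(mapped)))
      cell_colors[groups_of_cells == mapped$group[i]] <- cols[i]
    return(list(cell_colors = cell_colors,
                feature_colors = feature_colors, key = NULL))
  }

  scl <- .sc_lognorm(sc)
  if (!gene %in% rownames(scl$values) &&
      scheme %in% c("cell_by_group", "cell_by_value"))
    stop("gene '", gene, "' absent from single-cell data")

  if (scheme == "cell_by_group") {
    gv <- scl$values[gene, ]
    groups <- unique(groups_of_cells[!is.na(groups_of_cells)])
    gsum <- vapply(groups, function(g) sfun(gv[groups_of_cells == g]), 0)
    key <- make_color_key(gsum, palette, kbins)
    gcol <- stats::setNames(color_of(key, gsum), groups)
    for (g in groups) cell_colors[groups_of_cells == g] <- gcol[[g]]
    hit <- mapped$group %in% groups
    feature_colors <- stats::setNames(gcol[mapped$group[hit]],
                                      mapped$svg_id[hit])
    # orphan groups stay grey even though they have a summary value
    orphan_cells <- groups_of_cells %in% map$orphan_groups
    cell_colors[orphan_cells] <- .NA_COLOR
    return(list(cell_colors = cell_colors,
                feature_colors = feature_colors, key = key))
  }

  if (is.null(bulk)) stop("scheme '", scheme, "' requires bulk data")
  bl <- if (bulk$value_space == "counts")
    normalize_assay(bulk, "cpm", log2 = TRUE) else bulk
  if (!gene %in% rownames(bl$values))
    stop("gene '", gene, "' absent from bulk data")
  fmeans <- vapply(mapped$group, function(f)
    mean(bl$values[gene, bl$sample_meta$feature == f]), 0)

  if (scheme == "feature_by_group") {
    key <- make_color_key(fmeans, palette, kbins)
    fcol <- color_of(key, fmeans)
    feature_colors <- stats::setNames(fcol, mapped$svg_id)
    for (i in seq_len(nrow(mapped)))
      cell_colors[groups_of_cells == mapped$group[i]] <- fcol[i]
    return(list(cell_colors = cell_colors,
                feature_colors = feature_colors, key = key))
  }

  # cell_by_value: one shared key over cell values and bulk feature values
  cv <- scl$values[gene, ]
  key <- make_color_key(c(cv, fmeans), palette, kbins)
  mapped_cells <- !is.na(groups_of_cells) &
    groups_of_cells %in% mapped$group
  cell_colors[mapped_cells] <- color_of(key, cv[mapped_cells])
  feature_colors <- stats::setNames(color_of(key, fmeans), mapped$svg_id)
  list(cell_colors = cell_colors, feature_colors = feature_colors,
       key = key)
}

.cell_groups <- function(sc, map) {
  if (!is.null(map$cell_clusters))
    return(map$cell_clusters[colnames(sc$values)])
  if ("group" %in% names(sc$cell_meta))
    return(stats::setNames(sc$cell_meta$group, sc$cell_meta$cell_id))
  stats::setNames(rep(NA_character_, ncol(sc$values)), colnames(sc$values))
}

#' Render a co-visualization composite figure
#'
#' Left panel: scatter of the embedding colored by \code{cell_colors};
#' right panel: SHM of the document with \code{feature_colors}; matching
#' components share colors. Written as SVG (deterministic) and optionally
#' PNG.
#'
#' @param doc an \code{svg_doc}.
#' @param embedding an \code{embedding}.
#' @param colors output of \code{\link{colorize}}.
#' @param map a \code{tissue_cell_map}.
#' @param path output SVG path (a sibling \code{.png} is written when
#'   \code{png = TRUE}).
#' @param png also rasterize (default FALSE).
#' @param point_r dot radius in SVG units.
#' @return list with the colored \code{svg_doc} and written paths.
#' @export
render_covis <- function(doc, embedding, colors, map, path, png = FALSE,
                         point_r = 2.5) {
  cc <- colors$cell_colors
  if (length(cc) != nrow(embedding$coords))
    stop("cells in embedding (", nrow(embedding$coords),
         ") and colors (", length(cc), ") differ")
  shm <- doc
  for (id in names(colors$feature_colors)) {
    j <- which(feature_ids(shm) == id)
    if (length(j)) shm$features[[j]]$style$fill <- colors$feature_colors[[id]]
  }

  W <- doc$width * 2.1; H <- doc$height
  xy <- embedding$coords[, 1:2, drop = FALSE]
  rngx <- range(xy[, 1]); rngy <- range(xy[, 2])
  pad <- 0.05
  sx <- function(v) {
    span <- diff(rngx); if (span == 0) span <- 1
    (v - rngx[1]) / span * doc$width * (1 - 2 * pad) + doc$width * pad
  }
  sy <- function(v) {
    span <- diff(rngy); if (span == 0) span <- 1
    # embedding y up -> SVG y down
    H - ((v - rngy[1]) / span * H * (1 - 2 * pad) + H * pad)
  }
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                            'version="1.1" width="%s" height="%s">'),
                     .fmt_num(W), .fmt_num(H)),
             '  <g id="embedding_panel">')
  for (i in seq_len(nrow(xy)))
    lines <- c(lines, sprintf(
      '    <circle class="cell" cx="%s" cy="%s" r="%s" fill="%s"/>',
      .fmt_num(sx(xy[i, 1])), .fmt_num(sy(xy[i, 2])),
      .fmt_num(point_r), cc[i]))
  lines <- c(lines, "  </g>",
             sprintf('  <g id="shm_panel" transform="translate(%s,0)">',
                     .fmt_num(doc$width * 1.1)))
  ord <- order(vapply(shm$features, `[[`, 0L, "layer_index"))
  for (f in shm$features[ord]) {
    sty <- .style_attr_str(f$style, f$offset)
    if (f$container != "g" && length(f$elements) == 1L) {
      e <- f$elements[[1L]]
      lines <- c(lines, sprintf('    <%s id="%s"%s%s/>',
                                e$tag, .xml_escape(f$id),
                                .attrs_str(e$attrs), sty))
    } else {
      lines <- c(lines, sprintf('    <g id="%s"%s>', .xml_escape(f$id), sty))
      for (e in f$elements)
        lines <- c(lines, sprintf('      <%s%s/>', e$tag,
                                  .attrs_str(e$attrs)))
      lines <- c(lines, "    </g>")
    }
  }
  lines <- c(lines, "  </g>", "</svg>")
  con <- file(path, "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  paths <- path
  if (isTRUE(png)) {
    pp <- sub("\\.svg$", ".png", path)
    grDevices::png(pp, width = 8, height = 4, units = "in", res = 150)
    graphics::layout(matrix(1:2, 1))
    graphics::par(mar = c(2, 2, 1, 1))
    plot(xy, col = cc, pch = 16, cex = 0.6, xlab = "", ylab = "",
         main = "embedding")
    .draw_doc(shm, main = "SHM")
    grDevices::dev.off()
    paths <- c(paths, pp)
  }
  invisible(list(shm_doc = shm, paths = paths))
}

#' Overlay spatially resolved cells on a target feature (scSHM)
#'
#' Registers the cells' coordinate bounding box onto the target feature's
#' bounding box by translation plus one uniform scale (aspect preserved,
#' centers aligned), draws each cell as a dot at its transformed position
#' over the anatomy. Cells outside \code{plot_groups} are drawn grey.
#'
#' @param doc an \code{svg_doc}.
#' @param sc an \code{sc_assay} whose cell metadata has \code{x}, \code{y}.
#' @param target_feature SVG feature id receiving the overlay.
#' @param colors named cell color vector (e.g. \code{colorize()$cell_colors}).
#' @param path output SVG path.
#' @param plot_groups groups drawn in color; others grey (default: all).
#' @param point_r dot radius.
#' @return list with the transform (\code{scale}, \code{tx}, \code{ty}),
#'   transformed coordinates, and the written path.
#' @export
render_scshm <- function(doc, sc, target_feature, colors, path,
                         plot_groups = NULL, point_r = 1.5) {
  cm <- sc$cell_meta
  if (!all(c("x", "y") %in% names(cm)))
    stop("single-cell data has no spatial coordinates")
  miss <- cm$cell_id[is.na(cm$x) | is.na(cm$y)]
  if (length(miss))
    stop("cells missing coordinates: ",
         paste(utils::head(miss, 5), collapse = ", "))
  ids <- feature_ids(doc)
  if (!target_feature %in% ids)
    stop("unknown target feature: ", target_feature)
  f <- doc$features[[which(ids == target_feature)]]
  bb <- feature_bbox(f)

  cx <- cm$x; cy <- cm$y
  src_w <- max(cx) - min(cx); src_h <- max(cy) - min(cy)
  dst_w <- bb["xmax"] - bb["xmin"]; dst_h <- bb["ymax"] - bb["ymin"]
  s <- min(if (src_w > 0) dst_w / src_w else Inf,
           if (src_h > 0) dst_h / src_h else Inf)
  if (!is.finite(s)) s <- 1
  # align bounding-box centers; uniform scale preserves aspect
  tx <- (bb["xmin"] + bb["xmax"]) / 2 - s * (min(cx) + max(cx)) / 2
  ty <- (bb["ymin"] + bb["ymax"]) / 2 - s * (min(cy) + max(cy)) / 2
  X <- s * cx + tx
  Y <- s * cy + ty

  col <- colors[cm$cell_id]
  col[is.na(col)] <- .NA_COLOR
  if (!is.null(plot_groups) && "group" %in% names(cm))
    col[!(cm$group %in% plot_groups)] <- .NA_COLOR

  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                            'version="1.1" width="%s" height="%s">'),
                     .fmt_num(doc$width), .fmt_num(doc$height)))
  ord <- order(vapply(doc$features, `[[`, 0L, "layer_index"))
  for (ff in doc$features[ord]) {
    sty <- .style_attr_str(ff$style, ff$offset)
    if (ff$container != "g" && length(ff$elements) == 1L) {
      e <- ff$elements[[1L]]
      lines <- c(lines, sprintf('  <%s id="%s"%s%s/>', e$tag,
                                .xml_escape(ff$id), .attrs_str(e$attrs), sty))
    } else {
      lines <- c(lines, sprintf('  <g id="%s"%s>', .xml_escape(ff$id), sty))
      for (e in ff$elements)
        lines <- c(lines, sprintf('    <%s%s/>', e$tag, .attrs_str(e$attrs)))
      lines <- c(lines, "  </g>")
    }
  }
  for (i in seq_along(X))
    lines <- c(lines, sprintf(
      '  <circle class="sc_cell" cx="%s" cy="%s" r="%s" fill="%s"/>',
      .fmt_num(X[i]), .fmt_num(Y[i]), .fmt_num(point_r), col[i]))
  lines <- c(lines, "</svg>")
  con <- file(path, "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  invisible(list(scale = unname(s), tx = unname(tx), ty = unname(ty),
                 coords = cbind(x = X, y = Y), colors = col, path = path))
}

#' Co-visualize bulk deconvolution results
#'
#' Displays inferred cell types (columns of \code{cell_type_expr}) as an
#' embedding-style panel colored cell-by-value for \code{gene}, with the
#' estimated proportion printed ("0.50") beside each type, next to an SHM
#' of the bulk data. Computing the cell-type expression matrix is the
#' deconvolution method's job and must be supplied.
#'
#' @param bulk bulk \code{assay_table}.
#' @param cell_type_expr genes x cell-types numeric matrix.
#' @param proportions named numeric vector (cell type -> fraction); must
#'   sum to 1 within 1e-6.
#' @param gene gene id used for heat coloring.
#' @param doc an \code{svg_doc}.
#' @param map a \code{feature_sample_map} (bulk labels vs svg ids).
#' @param path output SVG path.
#' @return list with the per-type colors, label strings, and written path.
#' @export
deconv_view <- function(bulk, cell_type_expr, proportions, gene, doc, map,
                        path) {
  if (abs(sum(proportions) - 1) > 1e-6)
    stop("cell-type proportions must sum to 1 (got ",
         format(sum(proportions)), ")")
  types <- colnames(cell_type_expr)
  if (is.null(types)) stop("cell_type_expr needs cell-type column names")
  if (!gene %in% rownames(cell_type_expr))
    stop("gene '", gene, "' absent from cell_type_expr")
  bl <- if (bulk$value_space == "counts")
    normalize_assay(bulk, "cpm", log2 = TRUE) else bulk
  tv <- cell_type_expr[gene, ]
  fmeans <- vapply(map$pairs$assay_label, function(f)
    mean(bl$values[gene, bl$sample_meta$feature == f]), 0)
  key <- make_color_key(c(tv, fmeans), "yorrd", 50L)
  tcol <- color_of(key, tv)
  labels <- sprintf("%s (%.2f)", types, proportions[types])

  shm <- doc
  fcol <- color_of(key, fmeans)
  for (i in seq_len(nrow(map$pairs))) {
    j <- which(feature_ids(shm) == map$pairs$svg_id[i])
    shm$features[[j]]$style$fill <- fcol[i]
  }
  W <- doc$width * 2.1; H <- doc$height
  n <- length(types)
  ys <- seq(H * 0.15, H * 0.85, length.out = n)
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                            'version="1.1" width="%s" height="%s">'),
                     .fmt_num(W), .fmt_num(H)),
             '  <g id="celltype_panel">')
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf(
      '    <circle class="celltype" cx="%s" cy="%s" r="6" fill="%s"/>',
      .fmt_num(doc$width * 0.2), .fmt_num(ys[i]), tcol[i]))
    lines <- c(lines, sprintf(
      '    <text x="%s" y="%s" font-size="9">%s</text>',
      .fmt_num(doc$width * 0.3), .fmt_num(ys[i] + 3),
      .xml_escape(labels[i])))
  }
  lines <- c(lines, "  </g>",
             sprintf('  <g id="shm_panel" transform="translate(%s,0)">',
                     .fmt_num(doc$width * 1.1)))
  ord <- order(vapply(shm$features, `[[`, 0L, "layer_index"))
  for (f in shm$features[ord]) {
    sty <- .style_attr_str(f$style, f$offset)
    e <- f$elements[[1L]]
    if (f$container != "g" && length(f$elements) == 1L)
      lines <- c(lines, sprintf('    <%s id="%s"%s%s/>', e$tag,
                                .xml_escape(f$id), .attrs_str(e$attrs), sty))
    else {
      lines <- c(lines, sprintf('    <g id="%s"%s>', .xml_escape(f$id), sty))
      for (e2 in f$elements)
        lines <- c(lines, sprintf('      <%s%s/>', e2$tag,
                                  .attrs_str(e2$attrs)))
      lines <- c(lines, "    </g>")
    }
  }
  lines <- c(lines, "  </g>", "</svg>")
  con <- file(path, "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  invisible(list(type_colors = stats::setNames(tcol, types),
                 labels = labels, key = key, path = path))
}

#' Write an embedding as TSV
#' @param embedding an \code{embedding}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_embedding <- function(embedding, path) {
  df <- data.frame(cell = rownames(embedding$coords),
                   dim1 = embedding$coords[, 1],
                   dim2 = embedding$coords[, 2],
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a tissue-cell map as TSV
#' @param map a \code{tissue_cell_map}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_map <- function(map, path) {
  df <- map$pairs
  df$provenance <- map$provenance
  if (length(map$orphan_groups))
    df <- rbind(df, data.frame(group = map$orphan_groups, svg_id = NA,
                               provenance = map$provenance,
                               stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
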