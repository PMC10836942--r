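# Synthetic fixtures: toy anatomies and simulated bulk/single-cell count
# data with recorded ground truth. All generators are pure functions of
# their seed, so fixed seeds give byte-identical outputs.

#' Generate a toy annotated anatomy
#'
#' Lays out \code{n_features} non-overlapping polygonal features (ids
#' \code{feat_1}, ...) on a grid on layer 0; with \code{n_layers = 2} a
#' semi-transparent overlay polygon (\code{overlay_1}) is added on top,
#' covering part of the base layer, for transparency tests. The file is
#' valid standalone SVG 1.1.
#'
#' @param n_features number of base features (>= 1).
#' @param n_layers 1 (base only) or 2 (adds overlay).
#' @param seed integer seed controlling the polygon jitter.
#' @param path output SVG path; a temporary file when NULL.
#' @return the parsed \code{svg_doc} (round-tripped through the file); the
#'   path is attached as \code{source_paths}.
#' @export
make_toy_asvg <- function(n_features, n_layers = 1L, seed = 1L,
                          path = NULL) {
  if (n_features < 1L) stop("n_features must be >= 1")
  if (is.null(path)) path <- tempfile(fileext = ".svg")
  set.seed(seed)
  ncol_ <- ceiling(sqrt(n_features))
  nrow_ <- ceiling(n_features / ncol_)
  cw <- 100; ch <- 80; margin <- 10
  W <- ncol_ * cw + 2 * margin; H <- nrow_ * ch + 2 * margin
  fills <- .categorical_colors(n_features)

  feats <- list()
  for (i in seq_len(n_features)) {
    r <- (i - 1) %/% ncol_; cc <- (i - 1) %% ncol_
    x0 <- margin + cc * cw + 8; y0 <- margin + r * ch + 8
    x1 <- x0 + cw - 16; y1 <- y0 + ch - 16
    # irregular hexagon inside the cell, jittered but well inside bounds
    mx <- (x0 + x1) / 2; my <- (y0 + y1) / 2
    rx <- (x1 - x0) / 2; ry <- (y1 - y0) / 2
    th <- seq(0, 2 * pi, length.out = 7L)[-7L]
    rad <- stats::runif(6L, 0.7, 1)
    px <- mx + rx * rad * cos(th)
    py <- my + ry * rad * sin(th)
    pts <- paste(paste(.fmt_num(px), .fmt_num(py), sep = ","),
                 collapse = " ")
    feats[[i]] <- spatial_feature(
      id = paste0("feat_", i),
      elements = list(list(tag = "polygon", attrs = c(points = pts))),
      container = "polygon",
      style = list(fill = fills[i], stroke = "#333333", stroke_width = 1,
                   opacity = 1),
      layer_index = i - 1L)
  }
  if (n_layers >= 2L) {
    # overlay rectangle covering the left half of the canvas (intersects
    # at least the first base feature's bounding box)
    feats[[length(feats) + 1L]] <- spatial_feature(
      id = "overlay_1",
      elements = list(list(tag = "rect",
                           attrs = c(x = .fmt_num(margin),
                                     y = .fmt_num(margin),
                                     width = .fmt_num(W / 2),
                                     height = .fmt_num(H - 2 * margin)))),
      container = "rect",
      style = list(fill = "#AAAAAA", stroke = "#333333", stroke_width = 1,
                   opacity = 0.8),
      layer_index = length(feats))
  }
  doc <- svg_doc(feats, W, H)
  write_svg(doc, path)
  parse_asvg(path)
}

#' Simulate bulk negative-binomial counts with planted spatial effects
#'
#' Gene base means are log-normal(log 50, sdlog 1); counts are negative
#' binomial with variance mu + dispersion * mu^2; per-sample library-size
#' multipliers are log-normal(0, 0.15). A fraction of genes is planted with
#' a multiplicative 2^lfc effect in one assigned feature (round-robin over
#' features), and the truth is recorded.
#'
#' @param n_genes number of genes.
#' @param features character vector of feature labels.
#' @param replicates replicates per feature (>= 2).
#' @param planted_frac fraction of genes carrying an effect (default 0.05).
#' @param lfc planted log2 fold change (default 3).
#' @param dispersion NB dispersion phi (default 0.1).
#' @param seed integer seed.
#' @param conditions optional condition labels; each feature gets all
#'   conditions (planted effects stay feature-wise).
#' @return list with \code{assay} (counts \code{assay_table}) and
#'   \code{truth} (\code{sim_truth}: \code{library_multipliers},
#'   \code{planted} data.frame \code{gene}, \code{feature}, \code{lfc},
#'   \code{base_means}).
#' @export
simulate_bulk <- function(n_genes, features, replicates = 4L,
                          planted_frac = 0.05, lfc = 3, dispersion = 0.1,
                          seed = 1L, conditions = "all") {
  if (replicates < 2L) stop("replicates must be >= 2")
  set.seed(seed)
  base <- exp(stats::rnorm(n_genes, log(50), 1))
  genes <- sprintf("g%04d", seq_len(n_genes))

  n_pl <- round(planted_frac * n_genes)
  planted <- if (n_pl > 0) {
    data.frame(gene = genes[seq_len(n_pl)],
               feature = rep(features, length.out = n_pl),
               lfc = lfc, stringsAsFactors = FALSE)
  } else data.frame(gene = character(), feature = character(),
                    lfc = numeric(), stringsAsFactors = FALSE)

  meta <- expand.grid(replicate = seq_len(replicates),
                      condition = conditions, feature = features,
                      stringsAsFactors = FALSE)
  meta <- meta[, c("feature", "condition", "replicate")]
  meta$sample_id <- paste0(meta$feature, "_", meta$condition, "_r",
                           meta$replicate)
  libmult <- exp(stats::rnorm(nrow(meta), 0, 0.15))
  names(libmult) <- meta$sample_id

  values <- matrix(0, n_genes, nrow(meta),
                   dimnames = list(genes, meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    mu <- base
    pl <- planted$feature == meta$feature[j]
    if (any(pl)) {
      i <- match(planted$gene[pl], genes)
      mu[i] <- mu[i] * 2^planted$lfc[pl]
    }
    mu <- mu * libmult[j]
    values[, j] <- stats::rnbinom(n_genes, mu = mu, size = 1 / dispersion)
  }
  truth <- structure(list(library_multipliers = libmult, planted = planted,
                          base_means = stats::setNames(base, genes),
                          dispersion = dispersion, lfc = lfc),
                     class = "sim_truth")
  assay <- assay_table(values,
                       meta[, c("sample_id", "feature", "condition",
                                "replicate")],
                       value_space = "counts")
  list(assay = assay, truth = truth)
}

#' Simulate single cells from bulk feature profiles
#'
#' Per feature, one cell group with negative-binomial counts around the
#' feature's true mean profile at higher dispersion (default 0.3), scaled
#' to single-cell depth. With \code{spatial = TRUE} each group receives a
#' disjoint rectangular coordinate region plus uniform jitter.
#'
#' @param bulk result of \code{\link{simulate_bulk}} (or its \code{truth}
#'   plus \code{features}).
#' @param cells_per_group cells per feature group (>= 1).
#' @param spatial attach per-group disjoint x/y regions.
#' @param dispersion single-cell NB dispersion (default 0.3).
#' @param depth_factor single-cell depth relative to bulk means
#'   (default 0.2).
#' @param seed integer seed.
#' @return an \code{sc_assay} in counts space with \code{group} metadata
#'   (group label = source feature) and, when spatial, \code{x}, \code{y};
#'   the per-group regions are attached as attribute \code{"regions"}.
#' @export
simulate_cells <- function(bulk, cells_per_group = 50L, spatial = FALSE,
                           dispersion = 0.3, depth_factor = 0.2, seed = 1L) {
  set.seed(seed + 1000L)
  truth <- bulk$truth
  features <- unique(bulk$assay$sample_meta$feature)
  genes <- names(truth$base_means)
  n_cells <- cells_per_group * length(features)
  values <- matrix(0, length(genes), n_cells)
  rownames(values) <- genes
  groups <- character(n_cells)
  xs <- ys <- numeric(n_cells)
  regions <- list()
  idx <- 0L
  for (fi in seq_along(features)) {
    f <- features[fi]
    mu <- truth$base_means
    pl <- truth$planted$feature == f
    if (any(pl)) {
      i <- match(truth$planted$gene[pl], genes)
      mu[i] <- mu[i] * 2^truth$planted$lfc[pl]
    }
    mu <- mu * depth_factor
    x0 <- (fi - 1) * 120
    regions[[f]] <- c(xmin = x0, ymin = 0, xmax = x0 + 100, ymax = 100)
    for (cc in seq_len(cells_per_group)) {
      idx <- idx + 1L
      values[, idx] <- stats::rnbinom(length(genes), mu = mu,
                                      size = 1 / dispersion)
      groups[idx] <- f
      xs[idx] <- stats::runif(1, x0, x0 + 100)
      ys[idx] <- stats::runif(1, 0, 100)
    }
  }
  colnames(values) <- sprintf("cell_%04d", seq_len(n_cells))
  meta <- data.frame(cell_id = colnames(values), group = groups,
                     stringsAsFactors = FALSE)
  if (spatial) { meta$x <- xs; meta$y <- ys }
  sc <- sc_assay(values, meta, value_space = "counts")
  attr(sc, "regions") <- regions
  sc
}

#' Write an assay table (matrix + metadata) as TSV files
#'
#' @param assay an \code{assay_table}.
#' @param matrix_path,meta_path output paths.
#' @return character vector of the two paths, invisibly.
#' @export
write_assay <- function(assay, matrix_path, meta_path) {
  df <- data.frame(gene_id = rownames(assay$values), assay$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- assay$sample_meta
  names(meta)[names(meta) == "feature"] <- "feature"
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, meta_path))
}

#' Write a checkerboard PNG (raster-overlay fixture)
#'
#' @param path output PNG path.
#' @param n cells per side.
#' @param px pixels per cell.
#' @return \code{path}, invisibly.
#' @export
write_checkerboard_png <- function(path, n = 8L, px = 16L) {
  board <- outer(seq_len(n), seq_len(n), function(i, j) (i + j) %% 2)
  img <- board[rep(seq_len(n), each = px), rep(seq_len(n), each = px)]
  arr <- array(0, dim = c(dim(img), 3))
  arr[, , 1] <- 0.3 + 0.6 * img
  arr[, , 2] <- 0.5 + 0.3 * img
  arr[, , 3] <- 0.7 - 0.4 * img
  png::writePNG(arr, path)
  invisible(path)
}
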