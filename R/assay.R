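#' Construct a bulk assay table
#'
#' A genes x samples numeric matrix with per-sample metadata (spatial-feature
#' label, condition label, replicate number) and a value-space tag recording
#' what the numbers mean.
#'
#' @param values numeric matrix, rownames = gene ids, colnames = sample ids.
#' @param sample_meta data.frame with columns \code{sample_id},
#'   \code{feature}, \code{condition}, \code{replicate}, one row per column
#'   of \code{values}, in column order.
#' @param value_space one of \code{"counts"}, \code{"normalized"},
#'   \code{"log"}, \code{"lfc"}.
#' @return an object of class \code{assay_table}.
#' @export
assay_table <- function(values, sample_meta,
                        value_space = c("counts", "normalized", "log", "lfc")) {
  value_space <- match.arg(value_space)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("assay values must be numeric")
  if (is.null(rownames(values))) stop("assay matrix needs gene ids as rownames")
  if (is.null(colnames(values))) stop("assay matrix needs sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in assay matrix")
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  need <- c("sample_id", "feature")
  if (!all(need %in% names(sample_meta)))
    stop("sample_meta needs columns: ", paste(need, collapse = ", "))
  if (!"condition" %in% names(sample_meta)) sample_meta$condition <- "all"
  if (!"replicate" %in% names(sample_meta)) {
    sample_meta$replicate <- stats::ave(
      seq_len(nrow(sample_meta)),
      sample_meta$feature, sample_meta$condition, FUN = seq_along)
  }
  if (nrow(sample_meta) != ncol(values))
    stop("sample_meta rows (", nrow(sample_meta),
         ") do not match assay columns (", ncol(values), ")")
  if (!identical(as.character(sample_meta$sample_id), colnames(values)))
    stop("sample_meta order must follow assay columns")
  key <- paste(sample_meta$feature, sample_meta$condition,
               sample_meta$replicate, sep = "\r")
  if (anyDuplicated(key))
    stop("(feature, condition, replicate) triples must be unique")
  if (value_space == "counts" && any(values < 0))
    stop("counts space implies non-negative values")
  structure(list(values = values, sample_meta = sample_meta,
                 value_space = value_space),
            class = "assay_table")
}

#' @export
print.assay_table <- function(x, ...) {
  cat(sprintf("<assay_table> %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$value_space))
  cat("  features:", paste(unique(x$sample_meta$feature), collapse = ", "), "\n")
  cat("  conditions:", paste(unique(x$sample_meta$condition), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.assay_table <- function(x) dim(x$values)

.read_table_auto <- function(path) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Load a bulk assay from matrix + metadata files
#'
#' The matrix file (TSV or CSV, chosen by extension) has a header of sample
#' ids and gene ids in the first column. The metadata file is keyed by
#' \code{sample_id} with a \code{feature} column and optional
#' \code{condition} (default \code{"all"}) and \code{replicate}
#' (auto-numbered within feature/condition when absent). Only samples
#' present in both files are kept, ordered as the matrix columns; a sample
#' present on one side only is an error.
#'
#' @param matrix_path,meta_path input file paths.
#' @param value_space declared value space of the matrix (default counts).
#' @return an \code{\link{assay_table}}.
#' @export
load_assay <- function(matrix_path, meta_path, value_space = "counts") {
  raw <- .read_table_auto(matrix_path)
  genes <- as.character(raw[[1]])
  m <- raw[, -1, drop = FALSE]
  for (j in seq_along(m)) {
    v <- suppressWarnings(as.numeric(m[[j]]))
    bad <- which(is.na(v) & !is.na(m[[j]]) & m[[j]] != "NA")
    if (length(bad))
      stop("non-numeric value in '", matrix_path, "' at gene '",
           genes[bad[1]], "', sample '", colnames(m)[j], "'")
    m[[j]] <- v
  }
  values <- as.matrix(m)
  rownames(values) <- genes

  meta <- .read_table_auto(meta_path)
  if (!"sample_id" %in% names(meta)) names(meta)[1] <- "sample_id"
  meta$sample_id <- as.character(meta$sample_id)
  only_matrix <- setdiff(colnames(values), meta$sample_id)
  only_meta <- setdiff(meta$sample_id, colnames(values))
  if (length(only_matrix) || length(only_meta))
    stop("sample-id mismatch between matrix and metadata; ",
         "matrix-only: {", paste(only_matrix, collapse = ", "),
         "}, metadata-only: {", paste(only_meta, collapse = ", "), "}")
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  assay_table(values, meta, value_space = value_space)
}

#' Normalize a counts-space assay
#'
#' \code{size_factor} is median-of-ratios: per sample j, the size factor is
#' the median over genes (with positive geometric mean across samples) of
#' count_gj / geomean_g, rescaled so the factors have geometric mean 1;
#' values are divided by the factor. \code{cpm} scales each column to one
#' million. Optionally log2-transforms with a pseudo-count.
#'
#' @param assay counts-space \code{assay_table}.
#' @param method \code{"size_factor"} or \code{"cpm"}.
#' @param pseudo pseudo-count added before log2 (default 1).
#' @param log2 apply log2 after scaling (default TRUE).
#' @return an \code{assay_table} in \code{normalized} or \code{log} space.
#' @export
normalize_assay <- function(assay, method = c("size_factor", "cpm"),
                            pseudo = 1, log2 = TRUE) {
  method <- match.arg(method)
  if (assay$value_space != "counts")
    stop("normalize_assay expects counts space, got ", assay$value_space)
  if (pseudo < 0) stop("pseudo-count must be >= 0")
  v <- assay$values
  zero <- which(colSums(v) == 0)
  if (length(zero))
    stop("all-zero column(s): ",
         paste(colnames(v)[zero], collapse = ", "))
  if (method == "size_factor") {
    logg <- rowMeans(log(v))
    use <- is.finite(logg)  # genes with positive geometric mean
    if (!any(use)) stop("no gene has all-positive counts; cannot compute size factors")
    s <- apply(v[use, , drop = FALSE], 2L,
               function(col) stats::median(exp(log(col) - logg[use])))
    s <- s / exp(mean(log(s)))  # rescale to geometric mean 1
    out <- sweep(v, 2L, s, "/")
    attr(out, "size_factors") <- s
  } else {
    out <- sweep(v, 2L, colSums(v), "/") * 1e6
  }
  space <- "normalized"
  if (isTRUE(log2)) {
    out <- log2(out + pseudo)
    space <- "log"
  }
  res <- assay_table(out, assay$sample_meta, value_space = space)
  if (method == "size_factor")
    res$size_factors <- attr(out, "size_factors")
  res
}

#' Per-feature log2 fold changes relative to a control condition
#'
#' For every gene, feature and non-control condition: mean of log values
#' over treatment replicates minus mean over control replicates. Control
#' columns are dropped; the result is in \code{lfc} space with one column
#' per (feature, condition).
#'
#' @param assay log-space \code{assay_table}.
#' @param control_condition condition label used as the baseline; must be
#'   present for every feature.
#' @return an \code{assay_table} in \code{lfc} space.
#' @export
relative_values <- function(assay, control_condition) {
  if (assay$value_space != "log")
    stop("relative_values expects log space, got ", assay$value_space)
  meta <- assay$sample_meta
  if (!control_condition %in% meta$condition)
    stop("control condition '", control_condition, "' not found")
  feats <- unique(meta$feature)
  for (f in feats)
    if (!any(meta$feature == f & meta$condition == control_condition))
      stop("feature '", f, "' lacks control samples")
  conds <- setdiff(unique(meta$condition), control_condition)
  if (!length(conds)) stop("no non-control condition present")
  cols <- list(); meta_rows <- list()
  for (f in feats) {
    ctrl <- rowMeans(assay$values[, meta$feature == f &
                                    meta$condition == control_condition,
                                  drop = FALSE])
    for (cd in conds) {
      sel <- meta$feature == f & meta$condition == cd
      if (!any(sel)) next
      trt <- rowMeans(assay$values[, sel, drop = FALSE])
      nm <- paste0(f, "__", cd)
      cols[[nm]] <- trt - ctrl
      meta_rows[[nm]] <- data.frame(sample_id = nm, feature = f,
                                    condition = cd, replicate = 1L,
                                    stringsAsFactors = FALSE)
    }
  }
  values <- do.call(cbind, cols)
  rownames(values) <- rownames(assay$values)
  assay_table(values, do.call(rbind, meta_rows), value_space = "lfc")
}

#' Resolve assay feature labels against SVG feature ids
#'
#' Exact, case-sensitive matching of assay feature labels to SVG ids, after
#' applying an optional translation table (columns \code{assay_label},
#' \code{svg_id}). Labels unmatched on either side are reported, never fatal.
#'
#' @param assay an \code{assay_table}, or a character vector of labels.
#' @param doc an \code{svg_doc}.
#' @param translation optional data.frame mapping assay labels to SVG ids;
#'   a row naming a nonexistent SVG id is an error.
#' @return a \code{feature_sample_map}: list with \code{pairs} (data.frame
#'   \code{assay_label}, \code{svg_id}), \code{unmatched_assay},
#'   \code{unmatched_svg}.
#' @export
map_features <- function(assay, doc, translation = NULL) {
  labels <- if (inherits(assay, "assay_table"))
    unique(assay$sample_meta$feature) else unique(as.character(assay))
  ids <- feature_ids(doc)
  target <- stats::setNames(labels, labels)
  if (!is.null(translation)) {
    translation <- as.data.frame(translation, stringsAsFactors = FALSE)
    if (!all(c("assay_label", "svg_id") %in% names(translation)))
      stop("translation needs columns assay_label, svg_id")
    bad <- setdiff(translation$svg_id, ids)
    if (length(bad))
      stop("translation names nonexistent svg id(s): ",
           paste(bad, collapse = ", "))
    hit <- translation$assay_label %in% labels
    target[translation$assay_label[hit]] <- translation$svg_id[hit]
  }
  matched <- target %in% ids
  pairs <- data.frame(assay_label = labels[matched],
                      svg_id = unname(target[matched]),
                      stringsAsFactors = FALSE)
  res <- structure(list(pairs = pairs,
                        unmatched_assay = labels[!matched],
                        unmatched_svg = setdiff(ids, pairs$svg_id)),
                   class = "feature_sample_map")
  if (!nrow(pairs))
    warning("no assay label matched any svg feature id")
  res
}

#' @export
print.feature_sample_map <- function(x, ...) {
  cat(sprintf("<feature_sample_map> %d pair(s), %d unmatched assay, %d unmatched svg\n",
              nrow(x$pairs), length(x$unmatched_assay), length(x$unmatched_svg)))
  invisible(x)
}

#' Construct a single-cell assay
#'
#' @param values genes x cells numeric matrix (rownames = gene ids,
#'   colnames = cell ids).
#' @param cell_meta data.frame with \code{cell_id} and optional
#'   \code{group}, \code{x}, \code{y} columns; \code{x} must be present iff
#'   \code{y} is.
#' @param value_space as in \code{\link{assay_table}}.
#' @return an object of class \code{sc_assay}.
#' @export
sc_assay <- function(values, cell_meta = NULL, value_space = "counts") {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("single-cell matrix needs cell ids as colnames")
  if (is.null(rownames(values))) stop("single-cell matrix needs gene ids as rownames")
  if (anyDuplicated(colnames(values))) stop("duplicate cell ids")
  if (is.null(cell_meta))
    cell_meta <- data.frame(cell_id = colnames(values),
                            stringsAsFactors = FALSE)
  cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(cell_meta)) names(cell_meta)[1] <- "cell_id"
  if (!identical(as.character(cell_meta$cell_id), colnames(values)))
    stop("cell_meta order must follow matrix columns")
  if (xor("x" %in% names(cell_meta), "y" %in% names(cell_meta)))
    stop("spatial coordinates need both x and y")
  structure(list(values = values, cell_meta = cell_meta,
                 value_space = value_space),
            class = "sc_assay")
}

#' @export
print.sc_assay <- function(x, ...) {
  cat(sprintf("<sc_assay> %d genes x %d cells [%s]\n",
              nrow(x$values), ncol(x$values), x$value_space))
  if ("group" %in% names(x$cell_meta))
    cat("  groups:", paste(unique(x$cell_meta$group), collapse = ", "), "\n")
  invisible(x)
}

#' Load a single-cell assay from dense TSV/CSV or MTX triplet
#'
#' For MTX input, \code{matrix_path} names the \code{.mtx} file and sidecar
#' files \code{<stem>_genes.tsv} and \code{<stem>_barcodes.tsv} (one id per
#' line) are expected next to it, unless given explicitly.
#'
#' @param matrix_path dense matrix file or MTX file.
#' @param meta_path optional cell metadata TSV keyed by \code{cell_id}.
#' @param genes_path,barcodes_path explicit sidecar paths for MTX input.
#' @param value_space declared value space (default counts).
#' @return an \code{\link{sc_assay}}.
#' @export
load_sc <- function(matrix_path, meta_path = NULL, genes_path = NULL,
                    barcodes_path = NULL, value_space = "counts") {
  ext <- tolower(tools::file_ext(matrix_path))
  if (ext == "mtx") {
    stem <- sub("\\.mtx$", "", matrix_path)
    if (is.null(genes_path)) genes_path <- paste0(stem, "_genes.tsv")
    if (is.null(barcodes_path)) barcodes_path <- paste0(stem, "_barcodes.tsv")
    m <- as.matrix(Matrix::readMM(matrix_path))
    rownames(m) <- readLines(genes_path)
    colnames(m) <- readLines(barcodes_path)
  } else {
    raw <- .read_table_auto(matrix_path)
    m <- as.matrix(raw[, -1, drop = FALSE])
    rownames(m) <- as.character(raw[[1]])
  }
  meta <- NULL
  if (!is.null(meta_path)) {
    meta <- .read_table_auto(meta_path)
    if (!"cell_id" %in% names(meta)) names(meta)[1] <- "cell_id"
    meta$cell_id <- as.character(meta$cell_id)
    meta <- meta[match(colnames(m), meta$cell_id), , drop = FALSE]
    if (anyNA(meta$cell_id))
      stop("cell metadata missing for some cells")
    rownames(meta) <- NULL
  }
  sc_assay(m, meta, value_space = value_space)
}

# Log-normalize a counts-space sc_assay (cpm + log2), pass log data through.
.sc_lognorm <- function(sc, pseudo = 1) {
  if (sc$value_space %in% c("log", "lfc")) return(sc)
  v <- sc$values
  cs <- colSums(v)
  cs[cs == 0] <- 1
  out <- log2(sweep(v, 2L, cs, "/") * 1e6 + pseudo)
  sc_assay(out, sc$cell_meta, value_space = "log")
}
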