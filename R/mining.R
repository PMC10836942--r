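# Co-abundance mining: similarity search around a query gene, hierarchical
# clustering with tree cut, soft-threshold adjacency networks with module
# detection and connectivity, and hypergeometric gene-set enrichment.

.row_similarity <- function(values, query_gene,
                            metric = c("pearson", "spearman", "euclidean")) {
  metric <- match.arg(metric)
  q <- values[query_gene, ]
  if (metric == "spearman") {
    # rank transform (average ranks for ties), then Pearson
    values <- t(apply(values, 1L, rank))
    q <- values[query_gene, ]
  }
  if (metric %in% c("pearson", "spearman")) {
    if (ncol(values) < 3L) stop("correlations need >= 3 samples")
    as.numeric(stats::cor(t(values), q))
  } else {
    -sqrt(colSums((t(values) - q)^2))  # negated: larger = more similar
  }
}

#' Similarity search around a query gene
#'
#' Ranks all genes by similarity to the query (correlations descending,
#' Euclidean distance ascending) and selects by one of three rules:
#' \code{top_n} fixed count, \code{top_pct} percentage (ceil(p/100 * n),
#' counting the query), or \code{threshold} minimum similarity. The query is
#' always included and ranked first; ties break by gene id lexicographic
#' order.
#'
#' @param assay an \code{assay_table} (or bare numeric matrix).
#' @param query_gene gene id present in the assay.
#' @param metric \code{"pearson"}, \code{"spearman"} or \code{"euclidean"}.
#' @param selector list with exactly one of \code{top_n}, \code{top_pct}
#'   (in (0, 100]), \code{threshold}. Default \code{list(top_pct = 15)},
#'   the conventional neighborhood size for downstream clustering.
#' @return character vector of gene ids, query first.
#' @export
similarity_search <- function(assay, query_gene,
                              metric = c("pearson", "spearman", "euclidean"),
                              selector = list(top_pct = 15)) {
  metric <- match.arg(metric)
  values <- if (inherits(assay, "assay_table")) assay$values else as.matrix(assay)
  if (!query_gene %in% rownames(values))
    stop("unknown gene: ", query_gene)
  if (length(selector) != 1L ||
      !names(selector) %in% c("top_n", "top_pct", "threshold"))
    stop("selector must be exactly one of top_n, top_pct, threshold")
  sim <- .row_similarity(values, query_gene, metric)
  names(sim) <- rownames(values)
  ord <- order(names(sim) != query_gene, -sim, names(sim))  # query first
  ranked <- names(sim)[ord]
  n <- length(ranked)
  sel <- names(selector)
  if (sel == "top_n") {
    m <- as.integer(selector$top_n)
    if (m < 1L || m > n) stop("top_n out of range [1, ", n, "]")
    ranked[seq_len(m)]
  } else if (sel == "top_pct") {
    p <- selector$top_pct
    if (p <= 0 || p > 100) stop("top_pct must be in (0, 100]")
    ranked[seq_len(ceiling(p / 100 * n))]
  } else {
    thr <- selector$threshold
    keep <- sim[ord] >= thr
    keep[1L] <- TRUE  # query always included
    ranked[keep]
  }
}

#' Hierarchical clustering of assay rows
#'
#' Agglomerative clustering with correlation distance (1 - Pearson) or
#' Euclidean distance and average/complete/single linkage, optionally after
#' per-row z-scaling.
#'
#' @param matrix numeric matrix (or \code{assay_table}); rows are clustered.
#' @param row_scaling \code{"none"} or \code{"z"}.
#' @param distance \code{"correlation"} or \code{"euclidean"}.
#' @param linkage \code{"average"}, \code{"complete"} or \code{"single"}.
#' @return an object of class \code{hclust} (merge order, heights, labels).
#' @export
hcluster <- function(matrix, row_scaling = c("none", "z"),
                     distance = c("correlation", "euclidean"),
                     linkage = c("average", "complete", "single")) {
  row_scaling <- match.arg(row_scaling)
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  values <- if (inherits(matrix, "assay_table")) matrix$values else as.matrix(matrix)
  if (nrow(values) < 2L) stop("need at least 2 rows to cluster")
  if (distance == "correlation") {
    sds <- apply(values, 1L, stats::sd)
    if (any(sds == 0))
      stop("constant row(s) under correlation distance: ",
           paste(rownames(values)[sds == 0], collapse = ", "))
  }
  if (row_scaling == "z") {
    values <- t(scale(t(values)))
  }
  d <- if (distance == "correlation")
    stats::as.dist(1 - stats::cor(t(values)))
  else stats::dist(values)
  stats::hclust(d, method = linkage)
}

#' Cut a clustering tree
#'
#' @param dend an \code{hclust} object.
#' @param h cut height; groups are the connected leaf sets below h.
#' @param k desired number of clusters. Exactly one of \code{h}, \code{k}.
#' @return integer cluster labels named by leaf; labels are numbered by
#'   first leaf appearance (smallest leaf index).
#' @export
cut_tree <- function(dend, h = NULL, k = NULL) {
  if (is.null(h) == is.null(k))
    stop("give exactly one of h, k")
  n <- length(dend$labels %||% dend$order)
  if (!is.null(k) && k > n) stop("k = ", k, " exceeds ", n, " leaves")
  stats::cutree(dend, h = h, k = k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Soft-threshold adjacency network
#'
#' Unsigned adjacency a_ij = |pearson(i, j)|^beta with unit diagonal. The
#' default beta = 6 is the common unsigned-network soft threshold.
#'
#' @param matrix numeric genes x samples matrix (or \code{assay_table});
#'   needs >= 3 samples and no constant rows.
#' @param beta soft-threshold power (>= 1).
#' @return a \code{module_graph}: list with \code{adjacency}, \code{beta},
#'   \code{module_labels} (NULL until \code{\link{detect_modules}}),
#'   \code{connectivity}.
#' @export
adjacency <- function(matrix, beta = 6) {
  values <- if (inherits(matrix, "assay_table")) matrix$values else as.matrix(matrix)
  if (ncol(values) < 3L) stop("adjacency needs >= 3 samples")
  if (beta < 1) stop("beta must be >= 1")
  sds <- apply(values, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant row(s): ",
         paste(rownames(values)[sds == 0], collapse = ", "))
  a <- abs(stats::cor(t(values)))^beta
  diag(a) <- 1
  structure(list(adjacency = a, beta = beta,
                 module_labels = NULL, connectivity = NULL),
            class = "module_graph")
}

#' @export
print.module_graph <- function(x, ...) {
  cat(sprintf("<module_graph> %d nodes, beta = %g", nrow(x$adjacency), x$beta))
  if (!is.null(x$module_labels)) {
    nm <- sum(unique(x$module_labels) != 0)
    cat(sprintf(", %d module(s), %d unassigned",
                nm, sum(x$module_labels == 0)))
  }
  cat("\n")
  invisible(x)
}

#' Detect network modules by cutting the adjacency dissimilarity tree
#'
#' Hierarchically clusters the dissimilarity 1 - adjacency (average linkage),
#' cuts at \code{cut_height}, relabels clusters by smallest leaf index, marks
#' clusters smaller than \code{min_size} as unassigned (label 0), and
#' computes each gene's connectivity as the sum of its adjacencies to the
#' other members of its module.
#'
#' @param graph a \code{module_graph} from \code{\link{adjacency}}.
#' @param min_size minimum module size (>= 2).
#' @param cut_height tree-cut height on the 1 - adjacency scale
#'   (default 0.6).
#' @return the \code{module_graph} with \code{module_labels} and
#'   \code{connectivity} filled.
#' @export
detect_modules <- function(graph, min_size = 5L, cut_height = 0.6) {
  if (min_size < 2L) stop("min_size must be >= 2")
  a <- graph$adjacency
  n <- nrow(a)
  dend <- stats::hclust(stats::as.dist(1 - a), method = "average")
  labels <- stats::cutree(dend, h = cut_height)
  sizes <- table(labels)
  labels[labels %in% as.integer(names(sizes)[sizes < min_size])] <- 0L
  # renumber surviving modules 1..m by smallest member index
  mods <- setdiff(unique(labels), 0L)
  if (length(mods)) {
    firsts <- vapply(mods, function(m) min(which(labels == m)), 0L)
    remap <- stats::setNames(order(order(firsts)), mods)
    labels[labels != 0L] <- remap[as.character(labels[labels != 0L])]
  }
  conn <- numeric(n)
  for (i in seq_len(n)) {
    if (labels[i] == 0L) { conn[i] <- 0; next }
    mates <- which(labels == labels[i])
    mates <- mates[mates != i]
    conn[i] <- sum(a[i, mates])
  }
  names(labels) <- rownames(a)
  names(conn) <- rownames(a)
  graph$module_labels <- labels
  graph$connectivity <- conn
  graph$cut_height <- cut_height
  graph$min_size <- as.integer(min_size)
  graph
}

#' The module containing a query gene
#'
#' @param graph a \code{module_graph} with labels filled.
#' @param query_gene gene id.
#' @return character vector of the module members (empty when the query is
#'   unassigned).
#' @export
module_of <- function(graph, query_gene) {
  if (is.null(graph$module_labels)) stop("run detect_modules first")
  lab <- graph$module_labels[query_gene]
  if (is.na(lab)) stop("unknown gene: ", query_gene)
  if (lab == 0L) return(character())
  names(graph$module_labels)[graph$module_labels == lab]
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test P(X >= overlap) for each set, with
#' population = |universe|, successes = |set after intersection with the
#' universe|, draws = |cluster|; BH adjustment across sets.
#'
#' @param cluster_genes character vector (must be a subset of the universe).
#' @param gene_sets named list of character vectors (e.g. from
#'   \code{\link{read_gmt}}).
#' @param universe character vector of all assayed genes.
#' @return data.frame with \code{set_id}, \code{overlap}, \code{set_size},
#'   \code{cluster_size}, \code{p}, \code{padj}, sorted by p.
#' @export
hypergeom_enrich <- function(cluster_genes, gene_sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  extra <- setdiff(cluster_genes, universe)
  if (length(extra))
    stop("cluster genes outside the universe: ",
         paste(utils::head(extra, 5), collapse = ", "))
  cluster_genes <- unique(cluster_genes)
  N <- length(universe); n <- length(cluster_genes)
  rows <- lapply(names(gene_sets), function(id) {
    s <- intersect(gene_sets[[id]], universe)
    ov <- length(intersect(cluster_genes, s))
    p <- stats::phyper(ov - 1L, length(s), N - length(s), n,
                       lower.tail = FALSE)
    data.frame(set_id = id, overlap = ov, set_size = length(s),
               cluster_size = n, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p, out$set_id), , drop = FALSE]
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: set id, description, then member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors; descriptions kept as the
#'   \code{"description"} attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  attr(sets, "description") <- vapply(parts, `[[`, "", 2L)
  sets
}

#' Export a module graph as GraphML
#'
#' Node attributes: \code{module}, \code{connectivity}; edge attribute:
#' \code{adjacency}. Edges below \code{prune} (default 0.1) are dropped for
#' display-sized output.
#'
#' @param graph a \code{module_graph} (labels filled or not).
#' @param path output GraphML file.
#' @param prune minimum adjacency for an exported edge.
#' @return \code{path}, invisibly.
#' @export
write_graphml <- function(graph, path, prune = 0.1) {
  a <- graph$adjacency
  n <- nrow(a)
  idx <- which(upper.tri(a) & a >= prune, arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = rownames(a)[idx[, 1]], to = colnames(a)[idx[, 2]],
               adjacency = a[idx], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(
      name = rownames(a),
      module = if (is.null(graph$module_labels)) rep(0L, n)
               else as.integer(graph$module_labels),
      connectivity = if (is.null(graph$connectivity)) rep(0, n)
                     else as.numeric(graph$connectivity),
      stringsAsFactors = FALSE))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
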