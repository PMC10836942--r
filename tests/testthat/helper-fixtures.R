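# Shared fixture builders; everything is generated in code at test time.

# Minimal hand-written aSVG with two features (a path and a rect).
write_two_feature_svg <- function(path = tempfile(fileext = ".svg")) {
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<svg xmlns="http://www.w3.org/2000/svg" width="100" height="60">',
    '  <path id="tissueA" d="M10 10 L40 10 L40 40 L10 40 Z" fill="#FF0000"/>',
    '  <rect id="tissueB" x="50" y="10" width="30" height="30" fill="#0000FF" opacity="0.9"/>',
    '</svg>'), path)
  path
}

# Small deterministic assay: genes x (features x replicates), log space.
make_log_assay <- function(means, replicates = 3L, noise_sd = 0,
                           seed = 42L) {
  # means: genes x features matrix of log2 expectations
  set.seed(seed)
  feats <- colnames(means)
  meta <- expand.grid(replicate = seq_len(replicates), feature = feats,
                      stringsAsFactors = FALSE)
  meta$condition <- "all"
  meta$sample_id <- paste0(meta$feature, "_r", meta$replicate)
  v <- matrix(NA_real_, nrow(means), nrow(meta),
              dimnames = list(rownames(means), meta$sample_id))
  for (j in seq_len(nrow(meta)))
    v[, j] <- means[, meta$feature[j]] +
      if (noise_sd > 0) rnorm(nrow(means), 0, noise_sd) else 0
  assay_table(v, meta[, c("sample_id", "feature", "condition", "replicate")],
              value_space = "log")
}

# Independent XML walk: count id-bearing drawable/group elements in document
# order (oracle for parse_asvg, using raw xml2 node traversal).
count_id_elements <- function(path) {
  x <- xml2::read_xml(path)
  xml2::xml_ns_strip(x)
  drawable <- c("path", "rect", "circle", "ellipse", "polygon",
                "polyline", "line", "g")
  n <- 0L
  walk <- function(node) {
    for (ch in xml2::xml_children(node)) {
      tag <- xml2::xml_name(ch)
      id <- xml2::xml_attr(ch, "id")
      if (tag %in% drawable && !is.na(id) && nzchar(id)) n <<- n + 1L
      if (tag == "g") walk(ch)
    }
  }
  walk(x)
  n
}

# Naive O(n^3) agglomerative clustering oracle: returns the sorted merge
# heights for the given linkage over a distance matrix.
naive_agglom_heights <- function(d, linkage = "average") {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  link <- function(ci, cj) {
    vals <- d[ci, cj, drop = FALSE]
    switch(linkage, average = mean(vals), complete = max(vals),
           single = min(vals))
  }
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      h <- link(clusters[[i]], clusters[[j]])
      if (h < best) { best <- h; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# Textbook BH step-up oracle: largest k with p_(k) <= k/m * alpha.
bh_reject_oracle <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= seq_len(m) / m * alpha)
  rej <- logical(m)
  if (length(k)) rej[ord[seq_len(max(k))]] <- TRUE
  rej
}

# Extract fills of id-bearing elements from a written SVG, named by id.
svg_fills <- function(path) {
  doc <- parse_asvg(path)
  stats::setNames(vapply(doc$features, function(f) f$style$fill, ""),
                  feature_ids(doc))
}
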