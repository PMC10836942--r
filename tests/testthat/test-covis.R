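# Co-visualization: embeddings, tissue-cell maps, coloring schemes,
# composite rendering, spatial overlays, deconvolution views.

make_sim_pair <- function(seed = 1, n_genes = 300, feats = paste0("feat_", 1:4),
                          cells = 30, spatial = FALSE) {
  bulk <- simulate_bulk(n_genes, feats, replicates = 3, planted_frac = 0.2,
                        lfc = 3, seed = seed)
  sc <- simulate_cells(bulk, cells_per_group = cells, spatial = spatial,
                       seed = seed)
  list(bulk = bulk, sc = sc)
}

test_that("native PCA is deterministic and captures known structure", {
  # rank-1 data: PC1 explains essentially all variance
  set.seed(1)
  line <- outer(rnorm(20), runif(5, 1, 2))
  line <- line + 8
  dimnames(line) <- list(paste0("g", 1:20), paste0("c", 1:5))
  sc <- sc_assay(2^line, value_space = "counts")
  emb <- reduce_dims(sc, "pca")
  expect_gte(emb$variance_explained[1], 0.999)

  # duplicated cells land on identical embedding rows
  dup <- sc_assay(cbind(c1 = c(a = 4, b = 9, c = 2), c2 = c(8, 3, 7),
                        c3 = c(8, 3, 7)), value_space = "counts")
  e2 <- reduce_dims(dup, "pca")
  expect_equal(e2$coords["c2", ], e2$coords["c3", ], tolerance = 1e-10)

  # deterministic across calls
  p <- make_sim_pair(seed = 3)
  ea <- reduce_dims(p$sc, "pca"); eb <- reduce_dims(p$sc, "pca")
  expect_identical(ea$coords, eb$coords)
})

test_that("plug-in reducers return cell-ordered coordinates when available", {
  p <- make_sim_pair(seed = 3)
  emb <- reduce_dims(p$sc, "umap", seed = 3)
  expect_equal(dim(emb$coords), c(ncol(p$sc$values), 2L))
  expect_identical(rownames(emb$coords), colnames(p$sc$values))
})

test_that("simulated groups separate in PCA space", {
  p <- make_sim_pair(seed = 5)
  emb <- reduce_dims(p$sc, "pca")
  gr <- p$sc$cell_meta$group
  cent <- vapply(unique(gr), function(g)
    colMeans(emb$coords[gr == g, , drop = FALSE]), numeric(2))
  wsd <- mean(vapply(unique(gr), function(g)
    mean(apply(emb$coords[gr == g, , drop = FALSE], 2, sd)), 0))
  dmin <- min(dist(t(cent)))
  expect_gte(dmin, 2 * wsd)
})

test_that("annotation mapping matches group labels to svg ids", {
  p <- make_sim_pair(seed = 2)
  doc <- make_toy_asvg(4, seed = 2)  # ids feat_1..feat_4 = group labels
  map <- assign_cells(p$sc, doc = doc, method = "annotation")
  expect_equal(nrow(map$pairs), 4)
  expect_length(map$orphan_groups, 0)
  expect_identical(map$provenance, "annotation")
  expect_identical(map$pairs$group, map$pairs$svg_id)
})

test_that("manual pairs are validated against the document", {
  p <- make_sim_pair(seed = 2)
  doc <- make_toy_asvg(4, seed = 2)
  mp <- data.frame(group = c("feat_1", "feat_2"),
                   svg_id = c("feat_2", "feat_1"))
  map <- assign_cells(p$sc, doc = doc, method = "manual", pairs = mp)
  expect_identical(map$pairs$svg_id, c("feat_2", "feat_1"))
  expect_setequal(map$orphan_groups, c("feat_3", "feat_4"))
  bad <- data.frame(group = "g", svg_id = "nope")
  expect_error(assign_cells(p$sc, doc = doc, method = "manual", pairs = bad),
               "nope")
})

test_that("marker scores assign groups to their source features or orphan them", {
  p <- make_sim_pair(seed = 7)
  doc <- make_toy_asvg(4, seed = 7)
  enr <- spatial_enrichment(p$bulk$assay, paste0("feat_", 1:4))
  map <- assign_cells(p$sc, p$bulk$assay, doc, method = "marker",
                      enrichment = enr)
  hit <- map$pairs
  expect_gt(nrow(hit), 0)
  expect_identical(hit$group, hit$svg_id)  # groups named after source

  # a group mixing cells from two tissues scores both features about
  # equally: the margin rule orphans it
  gr <- p$sc$cell_meta$group
  mix_cells <- c(which(gr == "feat_1")[1:15], which(gr == "feat_2")[1:15])
  mixed <- p$sc$values[, mix_cells]
  colnames(mixed) <- paste0("m", seq_along(mix_cells))
  scm <- sc_assay(mixed, data.frame(cell_id = colnames(mixed),
                                    group = "mix"),
                  value_space = "counts")
  map2 <- assign_cells(scm, p$bulk$assay, doc, method = "marker",
                       enrichment = enr, delta = 0.5)
  expect_identical(map2$orphan_groups, "mix")
  expect_error(assign_cells(p$sc, p$bulk$assay, doc, method = "marker"),
               "enrichment_result")
})

test_that("cocluster assigns every simulated group to its source feature", {
  p <- make_sim_pair(seed = 11, cells = 100)
  map <- cocluster(p$bulk$assay, p$sc, seed = 11)
  expect_identical(map$provenance, "cocluster")
  expect_length(map$orphan_groups, 0)
  expect_equal(nrow(map$pairs), 4)
  expect_identical(map$pairs$group, map$pairs$svg_id)  # 100% accuracy

  # a group built from means uncorrelated with every feature is orphaned
  set.seed(99)
  v <- p$sc$values
  rnd <- matrix(rnbinom(nrow(v) * 20, mu = sample(exp(rnorm(nrow(v), 4, 1))),
                        size = 2), nrow(v), 20)
  rownames(rnd) <- rownames(v); colnames(rnd) <- paste0("r", 1:20)
  joint <- cbind(v, rnd)
  meta <- rbind(p$sc$cell_meta[, c("cell_id", "group")],
                data.frame(cell_id = colnames(rnd), group = "mystery"))
  sc2 <- sc_assay(joint, meta, value_space = "counts")
  map2 <- cocluster(p$bulk$assay, sc2, seed = 11)
  expect_true("mystery" %in% map2$orphan_groups)
  expect_error(cocluster(p$bulk$assay,
                         sc_assay(p$sc$values[1:10, ],
                                  p$sc$cell_meta, "counts")),
               "50 shared genes")
})

test_that("kmeans-based cocluster works without group labels", {
  p <- make_sim_pair(seed = 13, cells = 40)
  anon <- sc_assay(p$sc$values, value_space = "counts")
  map <- cocluster(p$bulk$assay, anon, seed = 13, use_groups = FALSE)
  expect_true(all(grepl("^cluster_", names(map$cell_clusters))
                  | grepl("^cluster_", map$cell_clusters)))
  expect_gte(nrow(map$pairs) + length(map$orphan_groups), 4)
})

test_that("coloring schemes share colors between matched cells and features", {
  p <- make_sim_pair(seed = 4)
  doc <- make_toy_asvg(4, seed = 4)
  map <- assign_cells(p$sc, doc = doc, method = "annotation")
  gene <- rownames(p$bulk$assay$values)[1]

  fx <- colorize("fixed_by_group", map, p$sc)
  expect_equal(length(unique(fx$feature_colors)), 4)
  expect_null(fx$key)
  gr <- p$sc$cell_meta$group
  for (i in seq_len(nrow(map$pairs)))
    expect_true(all(fx$cell_colors[gr == map$pairs$group[i]] ==
                      fx$feature_colors[[map$pairs$svg_id[i]]]))

  cbg <- colorize("cell_by_group", map, p$sc, gene = gene)
  # mean rule: a group's cells all share color_of(key, group mean)
  scl <- anatomap:::.sc_lognorm(p$sc)
  g1 <- map$pairs$group[1]
  expect_true(all(cbg$cell_colors[gr == g1] ==
                    color_of(cbg$key, mean(scl$values[gene, gr == g1]))))
  expect_equal(unname(cbg$feature_colors[map$pairs$svg_id[1]]),
               unname(cbg$cell_colors[which(gr == g1)[1]]))

  fbg <- colorize("feature_by_group", map, p$sc, bulk = p$bulk$assay,
                  gene = gene)
  expect_length(fbg$feature_colors, 4)

  cbv <- colorize("cell_by_value", map, p$sc, bulk = p$bulk$assay,
                  gene = gene)
  # per-cell bins equal brute-force lookup
  cv <- scl$values[gene, ]
  expect_identical(unname(cbv$cell_colors),
                   unname(color_of(cbv$key, cv)))
  expect_error(colorize("cell_by_value", map, p$sc, bulk = p$bulk$assay),
               "requires a gene")
})

test_that("orphan groups stay grey under every scheme", {
  p <- make_sim_pair(seed = 8)
  doc <- make_toy_asvg(3, seed = 8)  # only 3 features: feat_4 is orphan
  map <- suppressWarnings(assign_cells(p$sc, doc = doc, method = "annotation"))
  expect_identical(map$orphan_groups, "feat_4")
  gr <- p$sc$cell_meta$group
  gene <- rownames(p$bulk$assay$values)[2]
  grey <- "#D3D3D3"
  for (scheme in c("fixed_by_group", "cell_by_group", "feature_by_group")) {
    cols <- colorize(scheme, map, p$sc, bulk = p$bulk$assay,
                     gene = if (scheme == "fixed_by_group") NULL else gene)
    expect_true(all(cols$cell_colors[gr == "feat_4"] == grey),
                info = scheme)
  }
})

test_that("group-summary coloring agrees with cell_by_value on constant groups", {
  # every cell in a group shares the same value, and the bulk feature means
  # span the same range -> the numeric schemes give identical cell colors
  v <- cbind(matrix(8, 3, 4), matrix(32, 3, 4))
  rownames(v) <- c("gX", "gY", "gZ"); colnames(v) <- paste0("c", 1:8)
  sc <- sc_assay(v, data.frame(cell_id = colnames(v),
                               group = rep(c("feat_1", "feat_2"), each = 4)),
                 value_space = "log")
  bulk_means <- cbind(feat_1 = c(gX = 8, gY = 5, gZ = 5),
                      feat_2 = c(gX = 32, gY = 5, gZ = 5))
  bulk <- make_log_assay(bulk_means, replicates = 2)
  doc <- make_toy_asvg(2, seed = 1)
  map <- assign_cells(sc, doc = doc, method = "annotation")
  a <- colorize("cell_by_group", map, sc, gene = "gX")
  b <- colorize("cell_by_value", map, sc, gene = "gX", bulk = bulk)
  cfg <- colorize("feature_by_group", map, sc, gene = "gX", bulk = bulk)
  expect_identical(unname(a$cell_colors), unname(b$cell_colors))
  expect_identical(unname(cfg$cell_colors), unname(b$cell_colors))
  expect_identical(a$feature_colors[map$pairs$svg_id],
                   b$feature_colors[map$pairs$svg_id])
})

test_that("composite co-visualization uses identical colors in both panels", {
  p <- make_sim_pair(seed = 6)
  doc <- make_toy_asvg(4, seed = 6)
  map <- assign_cells(p$sc, doc = doc, method = "annotation")
  cols <- colorize("fixed_by_group", map, p$sc)
  emb <- reduce_dims(p$sc, "pca")
  out <- tempfile(fileext = ".svg")
  render_covis(doc, emb, cols, map, out)
  x <- xml2::read_xml(out); xml2::xml_ns_strip(x)
  dots <- xml2::xml_find_all(x, ".//circle[@class='cell']")
  dot_fill <- xml2::xml_attr(dots, "fill")
  expect_length(dots, ncol(p$sc$values))
  expect_length(unique(dot_fill), 4)  # no orphans -> no grey dots
  expect_false("#D3D3D3" %in% dot_fill)
  # feature fills in the SHM panel equal the matching cell colors
  for (i in seq_len(nrow(map$pairs))) {
    feat <- xml2::xml_find_first(
      x, sprintf(".//*[@id='%s']", map$pairs$svg_id[i]))
    expect_equal(xml2::xml_attr(feat, "fill"),
                 unname(cols$feature_colors[[map$pairs$svg_id[i]]]))
  }
  # length mismatch is an error
  bad <- cols; bad$cell_colors <- bad$cell_colors[-1]
  expect_error(render_covis(doc, emb, bad, map, tempfile()), "differ")

  # a single cell still renders
  one <- sc_assay(p$sc$values[, 1, drop = FALSE],
                  p$sc$cell_meta[1, ], "counts")
  m1 <- assign_cells(one, doc = doc, method = "annotation") |>
    suppressWarnings()
  c1 <- colorize("fixed_by_group", m1, one)
  e1 <- structure(list(coords = matrix(c(0, 0), 1,
                                       dimnames = list(colnames(one$values),
                                                       NULL)),
                       method = "pca", seed = 1L), class = "embedding")
  expect_no_error(render_covis(doc, e1, c1, m1, tempfile(fileext = ".svg")))
})

test_that("the scSHM affine map lands cells inside the target feature", {
  p <- make_sim_pair(seed = 9, spatial = TRUE)
  doc <- make_toy_asvg(4, seed = 9)
  map <- assign_cells(p$sc, doc = doc, method = "annotation")
  cols <- colorize("fixed_by_group", map, p$sc)
  out <- tempfile(fileext = ".svg")
  res <- render_scshm(doc, p$sc, "feat_2", cols$cell_colors, out,
                      plot_groups = "feat_2")
  f <- doc$features[[which(feature_ids(doc) == "feat_2")]]
  bb <- feature_bbox(f)
  expect_true(all(res$coords[, "x"] >= bb["xmin"] - 1e-9 &
                    res$coords[, "x"] <= bb["xmax"] + 1e-9))
  expect_true(all(res$coords[, "y"] >= bb["ymin"] - 1e-9 &
                    res$coords[, "y"] <= bb["ymax"] + 1e-9))

  # the center of the cell bounding box maps to the feature bbox center
  cm <- p$sc$cell_meta
  cx <- (min(cm$x) + max(cm$x)) / 2; cy <- (min(cm$y) + max(cm$y)) / 2
  expect_equal(unname(res$scale * cx + res$tx),
               unname((bb["xmin"] + bb["xmax"]) / 2), tolerance = 1e-9)
  expect_equal(unname(res$scale * cy + res$ty),
               unname((bb["ymin"] + bb["ymax"]) / 2), tolerance = 1e-9)

  # relative pairwise distances preserved up to the single global scale
  d_src <- dist(cbind(cm$x, cm$y))
  d_dst <- dist(res$coords)
  expect_equal(as.numeric(d_dst), as.numeric(d_src) * res$scale,
               tolerance = 1e-9)

  # grey vs colored dot counts match the plotted cluster sizes
  x <- xml2::read_xml(out); xml2::xml_ns_strip(x)
  dots <- xml2::xml_find_all(x, ".//circle[@class='sc_cell']")
  fills <- xml2::xml_attr(dots, "fill")
  expect_equal(sum(fills == "#D3D3D3"),
               sum(p$sc$cell_meta$group != "feat_2"))
  expect_error(render_scshm(doc, p$sc, "nope", cols$cell_colors,
                            tempfile()), "nope")
  nosp <- sc_assay(p$sc$values, p$sc$cell_meta[, c("cell_id", "group")],
                   "counts")
  expect_error(render_scshm(doc, nosp, "feat_1", cols$cell_colors,
                            tempfile()), "coordinates")
})

test_that("deconvolution views print proportions and validate their sum", {
  p <- make_sim_pair(seed = 10)
  doc <- make_toy_asvg(4, seed = 10)
  fm <- map_features(p$bulk$assay, doc)
  gene <- rownames(p$bulk$assay$values)[1]
  types <- paste0("ct", 1:6)
  cte <- matrix(rnorm(6 * nrow(p$bulk$assay$values), 6), ncol = 6,
                dimnames = list(rownames(p$bulk$assay$values), types))
  prop <- stats::setNames(c(0.3, 0.3, 0.2, 0.1, 0.05, 0.05), types)
  out <- tempfile(fileext = ".svg")
  res <- deconv_view(p$bulk$assay, cte, prop, gene, doc, fm, out)
  expect_length(res$labels, 6)
  x <- xml2::read_xml(out); xml2::xml_ns_strip(x)
  expect_length(xml2::xml_find_all(x, ".//circle[@class='celltype']"), 6)
  labs <- xml2::xml_text(xml2::xml_find_all(x, ".//text"))
  expect_true(any(grepl("0.30", labs, fixed = TRUE)))
  expect_true(any(grepl("0.05", labs, fixed = TRUE)))

  half <- stats::setNames(c(0.5, 0.5), c("a", "b"))
  cte2 <- cte[, 1:2]; colnames(cte2) <- c("a", "b")
  r2 <- deconv_view(p$bulk$assay, cte2, half, gene, doc, fm,
                    tempfile(fileext = ".svg"))
  expect_true(all(grepl("(0.50)", r2$labels, fixed = TRUE)))
  expect_error(deconv_view(p$bulk$assay, cte2,
                           stats::setNames(c(0.7, 0.2), c("a", "b")),
                           gene, doc, fm, tempfile()), "sum to 1")
})

test_that("embedding and mapping tables are written as TSV", {
  p <- make_sim_pair(seed = 12)
  emb <- reduce_dims(p$sc, "pca")
  ep <- tempfile(fileext = ".tsv")
  write_embedding(emb, ep)
  tab <- read.delim(ep)
  expect_identical(names(tab), c("cell", "dim1", "dim2"))
  expect_equal(nrow(tab), ncol(p$sc$values))
  doc <- make_toy_asvg(4, seed = 12)
  map <- assign_cells(p$sc, doc = doc, method = "annotation")
  mp <- tempfile(fileext = ".tsv")
  write_map(map, mp)
  mt <- read.delim(mp)
  expect_true(all(c("group", "svg_id", "provenance") %in% names(mt)))
})
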