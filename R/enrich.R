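# One-vs-rest spatial enrichment: Welch two-sample t-tests on log-normalized
# values per pairwise feature comparison, BH adjustment per comparison, and a
# supporting-comparison count with a user-definable outlier allowance.

.group_cols <- function(meta, label, mode) {
  if (mode == "feature") which(meta$feature == label)
  else which(meta$condition == label)
}

#' Pairwise differential test between two spatial features
#'
#' Per gene: lfc = mean(a) - mean(b) of log values; p from a Welch
#' two-sample t-test across replicates (Welch-Satterthwaite df); padj by
#' Benjamini-Hochberg across all genes of this comparison. Genes with
#' identical means and zero variance in both groups get p = 1. A group with
#' zero within-group variance uses a variance floor of 1e-8 so the statistic
#' stays defined.
#'
#' @param assay log-space \code{assay_table}.
#' @param a,b labels of the two groups being compared.
#' @param mode \code{"feature"} (compare spatial features) or
#'   \code{"condition"} (compare condition labels).
#' @return data.frame with columns \code{gene}, \code{lfc}, \code{p},
#'   \code{padj}.
#' @export
pairwise_de <- function(assay, a, b, mode = c("feature", "condition")) {
  mode <- match.arg(mode)
  if (!assay$value_space %in% c("log", "lfc"))
    stop("pairwise_de expects log-space values, got ", assay$value_space)
  ia <- .group_cols(assay$sample_meta, a, mode)
  ib <- .group_cols(assay$sample_meta, b, mode)
  if (length(ia) < 2L) stop("fewer than 2 replicates for '", a, "'")
  if (length(ib) < 2L) stop("fewer than 2 replicates for '", b, "'")
  xa <- assay$values[, ia, drop = FALSE]
  xb <- assay$values[, ib, drop = FALSE]
  n1 <- ncol(xa); n2 <- ncol(xb)
  m1 <- rowMeans(xa); m2 <- rowMeans(xb)
  v1 <- apply(xa, 1L, stats::var); v2 <- apply(xb, 1L, stats::var)
  v1 <- pmax(v1, 1e-8); v2 <- pmax(v2, 1e-8)  # variance floor
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[m1 == m2] <- 1  # constant-gene rule: equal means => no evidence
  data.frame(gene = rownames(assay$values), lfc = m1 - m2, p = p,
             padj = stats::p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Pre-filter: drop genes with zero variance across all replicates of the
# compared groups; with counts input, additionally require CPM >= 1 in at
# least min(group size) samples (standard low-count hygiene).
.prefilter_genes <- function(values, counts, cols_by_group) {
  cols <- unique(unlist(cols_by_group))
  keep <- apply(values[, cols, drop = FALSE], 1L, stats::var) > 0
  if (!is.null(counts)) {
    cpm <- sweep(counts[, cols, drop = FALSE], 2L,
                 colSums(counts[, cols, drop = FALSE]), "/") * 1e6
    min_n <- min(lengths(cols_by_group))
    keep <- keep & rowSums(cpm >= 1) >= min_n
  }
  keep
}

# --- empirical-Bayes variance moderation -----------------------------------
# Per-gene residual variances s2 (df residual df each) are modeled as scaled
# F deviates around a prior (s0^2, d0); the prior is fitted by moment
# matching on log s2 (Smyth-style) and each variance squeezed to
# (d0 s0^2 + df s2) / (d0 + df). Tests then use the squeezed variance with
# df + d0 degrees of freedom, which restores power at small replicate
# numbers without touching the mean model.

.trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (iter in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (-dif / x < 1e-8) break
  }
  x
}

.fit_var_prior <- function(s2, df) {
  s2 <- pmax(s2, 1e-8)
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) * (length(e) - 1) / length(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    # variances are essentially exchangeable: infinite prior df
    return(list(df_prior = Inf, var_prior = exp(emean)))
  }
  d0 <- 2 * .trigamma_inverse(evar)
  s0 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(df_prior = d0, var_prior = s0)
}

.squeeze_var <- function(s2, df, prior) {
  if (!is.finite(prior$df_prior))
    return(list(var_post = rep(prior$var_prior, length(s2)), df_total = Inf))
  list(var_post = (prior$df_prior * prior$var_prior + df * s2) /
         (prior$df_prior + df),
       df_total = df + prior$df_prior)
}

# One-way within-group residual variance across the query groups.
.residual_var <- function(values, cols_by_group) {
  n <- sum(lengths(cols_by_group))
  K <- length(cols_by_group)
  rss <- 0
  for (cols in cols_by_group) {
    sub <- values[, cols, drop = FALSE]
    rss <- rss + rowSums((sub - rowMeans(sub))^2)
  }
  list(s2 = rss / (n - K), df = n - K)
}

#' One-vs-rest spatial enrichment with outlier allowance
#'
#' For each query feature F, a gene is called enriched when, in at least
#' (K - 1 - outliers) of its K - 1 pairwise comparisons F vs G, the
#' BH-adjusted p-value is <= alpha and the log2 fold change is >= lfc_min
#' (depleted: lfc <= -lfc_min). K counts the query feature itself. Counts
#' input is log-normalized internally (cpm + log2, pseudo-count 1) and the
#' low-count pre-filter applied; already-log data is used as-is after a
#' zero-variance filter.
#'
#' @param assay \code{assay_table} in counts or log space.
#' @param query_features K >= 2 feature labels (condition labels in
#'   condition mode).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param lfc_min minimum |log2 fold change| (default 1).
#' @param outliers number of comparisons allowed to fail, 0 <= outliers <=
#'   K - 2.
#' @param mode \code{"feature"} or \code{"condition"}.
#' @param engine \code{"moderated"} (default) squeezes per-gene one-way
#'   residual variances toward an empirical-Bayes prior before the pairwise
#'   t-tests, which keeps power usable at few replicates; \code{"welch"}
#'   runs plain per-pair Welch tests (\code{\link{pairwise_de}}).
#' @return an \code{enrichment_result}: per query feature, \code{enriched}
#'   and \code{depleted} data.frames with columns \code{gene}, \code{lfc}
#'   (signed minimum-magnitude lfc over supporting comparisons), \code{padj}
#'   (maximum over supporting comparisons), \code{n_support}; plus the
#'   parameters used.
#' @export
spatial_enrichment <- function(assay, query_features, alpha = 0.05,
                               lfc_min = 1, outliers = 0L,
                               mode = c("feature", "condition"),
                               engine = c("moderated", "welch")) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  K <- length(query_features)
  if (K < 2L) stop("need at least 2 query features")
  if (outliers < 0L || outliers > K - 2L)
    stop("outliers must satisfy 0 <= outliers <= K - 2 (here K = ", K, ")")
  counts <- NULL
  if (assay$value_space == "counts") {
    counts <- assay$values
    assay <- normalize_assay(assay, method = "cpm", pseudo = 1, log2 = TRUE)
  } else if (assay$value_space == "normalized") {
    assay <- assay_table(log2(assay$values + 1), assay$sample_meta,
                         value_space = "log")
  }
  meta <- assay$sample_meta
  cols_by_group <- lapply(query_features, .group_cols, meta = meta, mode = mode)
  names(cols_by_group) <- query_features
  empty <- query_features[lengths(cols_by_group) < 2L]
  if (length(empty))
    stop("fewer than 2 replicates for: ", paste(empty, collapse = ", "))

  keep <- .prefilter_genes(assay$values, counts, cols_by_group)
  sub <- assay_table(assay$values[keep, , drop = FALSE], meta,
                     value_space = "log")
  genes <- rownames(sub$values)

  # one test per unordered pair; the reverse comparison is the negation
  # (same p-values)
  mod <- NULL
  if (engine == "moderated") {
    cbg <- lapply(query_features, .group_cols, meta = meta, mode = mode)
    rv <- .residual_var(sub$values, cbg)
    prior <- .fit_var_prior(rv$s2, rv$df)
    sq <- .squeeze_var(pmax(rv$s2, 1e-8), rv$df, prior)
    mod <- list(var_post = sq$var_post, df_total = sq$df_total)
  }
  pair_test <- function(a, b) {
    if (engine == "welch") return(pairwise_de(sub, a, b, mode = mode))
    ia <- .group_cols(meta, a, mode); ib <- .group_cols(meta, b, mode)
    xa <- sub$values[, ia, drop = FALSE]; xb <- sub$values[, ib, drop = FALSE]
    m1 <- rowMeans(xa); m2 <- rowMeans(xb)
    se <- sqrt(mod$var_post * (1 / ncol(xa) + 1 / ncol(xb)))
    tstat <- (m1 - m2) / se
    p <- if (is.finite(mod$df_total)) 2 * stats::pt(-abs(tstat), mod$df_total)
         else 2 * stats::pnorm(-abs(tstat))
    p[m1 == m2] <- 1
    data.frame(gene = rownames(sub$values), lfc = m1 - m2, p = p,
               padj = stats::p.adjust(p, method = "BH"),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  pair_res <- list()
  for (i in seq_len(K - 1L)) for (j in seq((i + 1L), K)) {
    a <- query_features[i]; b <- query_features[j]
    pair_res[[paste0(a, "\r", b)]] <- pair_test(a, b)
  }
  get_pair <- function(a, b) {
    key <- paste0(a, "\r", b)
    if (key %in% names(pair_res)) return(pair_res[[key]])
    r <- pair_res[[paste0(b, "\r", a)]]
    r$lfc <- -r$lfc
    r
  }

  per_feature <- list()
  for (f in query_features) {
    others <- setdiff(query_features, f)
    up_ok <- dn_ok <- matrix(FALSE, length(genes), length(others))
    lfc_m <- padj_m <- matrix(NA_real_, length(genes), length(others))
    for (j in seq_along(others)) {
      r <- get_pair(f, others[j])
      sig <- r$padj <= alpha
      up_ok[, j] <- sig & r$lfc >= lfc_min
      dn_ok[, j] <- sig & r$lfc <= -lfc_min
      lfc_m[, j] <- r$lfc
      padj_m[, j] <- r$padj
    }
    need <- (K - 1L) - outliers
    mk_table <- function(ok, sign) {
      n_support <- rowSums(ok)
      hit <- which(n_support >= need)
      if (!length(hit))
        return(data.frame(gene = character(), lfc = numeric(),
                          padj = numeric(), n_support = integer(),
                          stringsAsFactors = FALSE))
      rows <- lapply(hit, function(i) {
        supp <- which(ok[i, ])
        lf <- lfc_m[i, supp]
        data.frame(gene = genes[i],
                   lfc = lf[which.min(abs(lf))],  # conservative summary
                   padj = max(padj_m[i, supp]),
                   n_support = length(supp),
                   stringsAsFactors = FALSE)
      })
      out <- do.call(rbind, rows)
      out[order(out$padj, out$gene), , drop = FALSE]
    }
    per_feature[[f]] <- list(enriched = mk_table(up_ok, +1),
                             depleted = mk_table(dn_ok, -1))
  }
  structure(list(query_features = query_features, results = per_feature,
                 parameters = list(alpha = alpha, lfc_min = lfc_min,
                                   outliers = as.integer(outliers),
                                   mode = mode, engine = engine),
                 n_tested = length(genes)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %d features, %d genes tested (alpha=%g, lfc_min=%g, outliers=%d)\n",
              length(x$query_features), x$n_tested,
              x$parameters$alpha, x$parameters$lfc_min, x$parameters$outliers))
  for (f in x$query_features)
    cat(sprintf("  %s: %d enriched, %d depleted\n", f,
                nrow(x$results[[f]]$enriched), nrow(x$results[[f]]$depleted)))
  invisible(x)
}

#' Genes called for a feature
#' @param result an \code{enrichment_result}.
#' @param feature query feature label.
#' @param direction \code{"enriched"} or \code{"depleted"}.
#' @return character vector of gene ids.
#' @export
enriched_genes <- function(result, feature,
                           direction = c("enriched", "depleted")) {
  direction <- match.arg(direction)
  result$results[[feature]][[direction]]$gene
}

#' Overlap summaries of enrichment sets
#'
#' @param result an \code{enrichment_result}.
#' @param direction \code{"enriched"} or \code{"depleted"}.
#' @return list with \code{matrix} (K x K pairwise intersection counts,
#'   diagonal = set sizes), \code{upset} (data.frame of non-empty exclusive
#'   membership patterns; the \code{count} column sums to the union size),
#'   and \code{venn} (all 2^K - 1 region counts; only for K <= 5, otherwise
#'   NULL).
#' @export
overlap_summaries <- function(result, direction = c("enriched", "depleted")) {
  direction <- match.arg(direction)
  sets <- lapply(result$query_features, enriched_genes,
                 result = result, direction = direction)
  names(sets) <- result$query_features
  overlap_sets(sets)
}

#' Overlap summaries of arbitrary named sets
#'
#' @param sets named list of character vectors.
#' @param venn_max maximum number of sets for Venn region counts (default 5).
#' @return see \code{\link{overlap_summaries}}.
#' @export
overlap_sets <- function(sets, venn_max = 5L) {
  K <- length(sets)
  if (!K) stop("no sets given")
  nms <- names(sets)
  mat <- matrix(0L, K, K, dimnames = list(nms, nms))
  for (i in seq_len(K)) for (j in seq_len(K))
    mat[i, j] <- length(intersect(sets[[i]], sets[[j]]))

  all_genes <- unique(unlist(sets))
  membership <- matrix(FALSE, length(all_genes), K,
                       dimnames = list(all_genes, nms))
  for (j in seq_len(K)) membership[, j] <- all_genes %in% sets[[j]]
  if (length(all_genes)) {
    pattern <- apply(membership, 1L, function(r) paste(nms[r], collapse = "&"))
    tab <- table(pattern)
    upset <- data.frame(pattern = names(tab), count = as.integer(tab),
                        degree = lengths(strsplit(names(tab), "&",
                                                  fixed = TRUE)),
                        stringsAsFactors = FALSE)
    upset <- upset[order(-upset$count, upset$pattern), , drop = FALSE]
    rownames(upset) <- NULL
  } else {
    upset <- data.frame(pattern = character(), count = integer(),
                        degree = integer(), stringsAsFactors = FALSE)
  }

  venn <- NULL
  if (K <= venn_max) {
    combos <- unlist(lapply(seq_len(K), function(m)
      utils::combn(nms, m, simplify = FALSE)), recursive = FALSE)
    venn <- data.frame(
      region = vapply(combos, paste, "", collapse = "&"),
      count = vapply(combos, function(cb) {
        sum(apply(membership, 1L, function(r)
          all(r[match(cb, nms)]) && !any(r[-match(cb, nms)])))
      }, 0L),
      stringsAsFactors = FALSE)
  }
  list(matrix = mat, upset = upset, venn = venn)
}

#' Request Venn region counts for enrichment sets
#'
#' @inheritParams overlap_summaries
#' @return data.frame of region counts; error when K > 5.
#' @export
venn_counts <- function(result, direction = c("enriched", "depleted")) {
  direction <- match.arg(direction)
  K <- length(result$query_features)
  if (K > 5L) stop("Venn diagrams support at most 5 sets, got ", K)
  overlap_summaries(result, direction)$venn
}

#' Write enrichment results as TSV files
#'
#' One file per feature and direction (\code{<feature>_<direction>.tsv}),
#' plus the overlap matrix and UpSet table.
#'
#' @param result an \code{enrichment_result}.
#' @param dir output directory.
#' @return character vector of written paths, invisibly.
#' @export
write_enrichment <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (f in result$query_features) for (d in c("enriched", "depleted")) {
    p <- file.path(dir, paste0(f, "_", d, ".tsv"))
    utils::write.table(result$results[[f]][[d]], p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  for (d in c("enriched", "depleted")) {
    ov <- overlap_summaries(result, d)
    mp <- file.path(dir, paste0("overlap_matrix_", d, ".tsv"))
    utils::write.table(ov$matrix, mp, sep = "\t", quote = FALSE)
    up <- file.path(dir, paste0("upset_", d, ".tsv"))
    utils::write.table(ov$upset, up, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, mp, up)
  }
  invisible(paths)
}
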