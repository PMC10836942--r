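.PALETTES <- list(
  # diverging yellow-orange-red for absolute abundances
  yorrd = c("#FFFFCC", "#FED976", "#FD8D3C", "#E31A1C", "#800026"),
  # blue-white-red for fold changes (centered at 0 by the caller)
  bwr = c("#2166AC", "#67A9CF", "#F7F7F7", "#EF8A62", "#B2182B"),
  viridis = c("#440154", "#3B528B", "#21918C", "#5EC962", "#FDE725")
)

.NA_COLOR <- "#D3D3D3"  # light grey: unmeasured features, orphan cells

#' Build a number-to-color key
#'
#' The key has k color bins over k+1 equally spaced breaks spanning the data
#' range. When all values are equal the breaks are centered on that value
#' with unit half-width so every value maps to the middle bin. With
#' \code{symmetric = TRUE} the range is extended to be symmetric around 0
#' (the convention for log fold changes with a diverging palette).
#'
#' @param values finite numeric values the key must span (at least one).
#' @param palette palette name: \code{"yorrd"}, \code{"bwr"} or
#'   \code{"viridis"}.
#' @param k number of color bins (>= 2).
#' @param scale_mode \code{"shared"} (one key for all panels) or
#'   \code{"per_gene"}.
#' @param symmetric center the key at zero.
#' @return an object of class \code{color_key} with fields \code{colors}
#'   (length k), \code{breaks} (length k+1, strictly ascending),
#'   \code{scale_mode}, \code{na_color}.
#' @export
make_color_key <- function(values, palette = "yorrd", k = 50L,
                           scale_mode = c("shared", "per_gene"),
                           symmetric = FALSE) {
  scale_mode <- match.arg(scale_mode)
  values <- values[is.finite(values)]
  if (!length(values)) stop("make_color_key needs at least one finite value")
  if (k < 2L) stop("k must be >= 2")
  if (!palette %in% names(.PALETTES))
    stop("unknown palette '", palette, "'")
  vmin <- min(values); vmax <- max(values)
  if (symmetric) {
    half <- max(abs(c(vmin, vmax)))
    vmin <- -half; vmax <- half
  }
  if (vmin == vmax) { vmin <- vmin - 1; vmax <- vmax + 1 }
  breaks <- seq(vmin, vmax, length.out = k + 1L)
  colors <- grDevices::colorRampPalette(.PALETTES[[palette]])(k)
  structure(list(colors = colors, breaks = breaks, scale_mode = scale_mode,
                 na_color = .NA_COLOR, palette = palette),
            class = "color_key")
}

#' @export
print.color_key <- function(x, ...) {
  cat(sprintf("<color_key> %d bins over [%g, %g] (%s, %s)\n",
              length(x$colors), min(x$breaks), max(x$breaks),
              x$palette, x$scale_mode))
  invisible(x)
}

#' Bin index of values under a key
#'
#' Bin i covers [breaks[i], breaks[i+1]); the last bin is right-closed and a
#' value exactly on an interior break falls in the higher bin. Values outside
#' the range clamp to the end bins. Non-finite values return NA.
#'
#' @param key a \code{color_key}.
#' @param values numeric vector.
#' @return integer bin indices in 1..k (NA for non-finite values).
#' @export
key_bin <- function(key, values) {
  k <- length(key$colors)
  idx <- findInterval(values, key$breaks)
  idx[idx < 1L] <- 1L
  idx[idx > k] <- k
  idx[!is.finite(values)] <- NA_integer_
  as.integer(idx)
}

#' Color of values under a key
#'
#' @param key a \code{color_key}.
#' @param values numeric vector; non-finite values map to the key's
#'   \code{na_color}.
#' @return character vector of colors.
#' @export
color_of <- function(key, values) {
  idx <- key_bin(key, values)
  out <- key$colors[idx]
  out[is.na(idx)] <- key$na_color
  out
}
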