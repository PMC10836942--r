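#' @importFrom stats var sd median cor kmeans cutree hclust as.dist dist
#'   p.adjust pt pnorm phyper quantile rnbinom rnorm runif setNames ave
#' @importFrom utils read.delim write.table head tail
#' @importFrom grDevices colorRampPalette png dev.off col2rgb rgb
#' @importFrom graphics par plot.new plot.window polygon rect text points
#'   lines rasterImage layout segments
NULL

# Presentation attributes recognised as style; everything else on an element
# is preserved verbatim (geometry or foreign attributes).
.STYLE_ATTRS <- c("fill", "stroke", "stroke-width", "opacity")
.DRAWABLE_TAGS <- c("path", "rect", "circle", "ellipse", "polygon",
                    "polyline", "line")

#' Construct a spatial feature
#'
#' A spatial feature is one colorable anatomical element of an annotated SVG
#' (aSVG): a drawable element or a group carrying a unique \code{id}. The
#' geometry is kept verbatim as the element's SVG attributes so that writing
#' a document back reproduces the source exactly; flattened polygon outlines
#' for rendering are derived on demand (see \code{\link{feature_bbox}}).
#'
#' @param id unique identifier (non-empty string).
#' @param elements list of element records, each \code{list(tag, attrs)} with
#'   \code{attrs} a named character vector of verbatim SVG attributes.
#' @param container \code{"g"} when the feature was a group, otherwise the
#'   drawable tag name.
#' @param style list with entries \code{fill}, \code{stroke},
#'   \code{stroke_width}, \code{opacity} (any may be \code{NA}) and
#'   \code{extra}, a named character vector of unrecognised style keys kept
#'   verbatim.
#' @param layer_index 0-based document-order index (0 = bottom layer).
#' @param group_path character vector of ancestor group ids.
#' @param offset numeric length-2 translation (SVG user units, y down).
#' @return an object of class \code{spatial_feature}.
#' @export
spatial_feature <- function(id, elements, container = "g",
                            style = list(), layer_index = 0L,
                            group_path = character(), offset = c(0, 0)) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("feature id must be a non-empty string")
  if (length(elements) < 1L)
    stop("feature '", id, "' has no geometry elements")
  style <- .complete_style(style)
  if (!is.na(style$opacity) && (style$opacity < 0 || style$opacity > 1))
    stop("opacity must be in [0, 1] for feature '", id, "'")
  structure(list(id = id, elements = elements, container = container,
                 style = style, layer_index = as.integer(layer_index),
                 group_path = group_path, offset = as.numeric(offset)),
            class = "spatial_feature")
}

.complete_style <- function(style) {
  out <- list(fill = NA_character_, stroke = NA_character_,
              stroke_width = NA_real_, opacity = NA_real_,
              extra = character())
  for (nm in names(style)) if (nm %in% names(out)) out[[nm]] <- style[[nm]]
  out$stroke_width <- suppressWarnings(as.numeric(out$stroke_width))
  out$opacity <- suppressWarnings(as.numeric(out$opacity))
  out
}

#' Construct an annotated-SVG document
#'
#' @param features list of \code{\link{spatial_feature}} objects; ids must be
#'   unique.
#' @param width,height canvas dimensions in SVG user units (> 0).
#' @param source_paths character vector of source file paths.
#' @param raster_path optional path to a PNG/JPEG placed below all vector
#'   layers when the document is written (photo-realistic overlay).
#' @param raster_alpha opacity of the raster layer in [0, 1].
#' @param raster_grayscale logical; desaturate the raster (PNG only).
#' @return an object of class \code{svg_doc}.
#' @export
svg_doc <- function(features, width, height, source_paths = character(),
                    raster_path = NULL, raster_alpha = 1,
                    raster_grayscale = FALSE) {
  if (!is.numeric(width) || !is.numeric(height) || width <= 0 || height <= 0)
    stop("canvas width and height must be positive numbers")
  ids <- vapply(features, `[[`, "", "id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate feature ids: ", paste(dup, collapse = ", "))
  if (!is.null(raster_path) && !file.exists(raster_path))
    stop("raster file does not exist: ", raster_path)
  structure(list(features = features, width = as.numeric(width),
                 height = as.numeric(height),
                 source_paths = as.character(source_paths),
                 raster_path = raster_path,
                 raster_alpha = as.numeric(raster_alpha),
                 raster_grayscale = isTRUE(raster_grayscale)),
            class = "svg_doc")
}

#' @export
print.svg_doc <- function(x, ...) {
  cat(sprintf("<svg_doc> %g x %g, %d spatial feature(s)\n",
              x$width, x$height, length(x$features)))
  ids <- feature_ids(x)
  if (length(ids))
    cat("  ids:", paste(utils::head(ids, 10), collapse = ", "),
        if (length(ids) > 10) "..." else "", "\n")
  if (!is.null(x$raster_path)) cat("  raster:", x$raster_path, "\n")
  invisible(x)
}

#' Feature ids of a document, in layer order
#' @param doc an \code{svg_doc}.
#' @return character vector of ids.
#' @export
feature_ids <- function(doc) {
  vapply(doc$features, `[[`, "", "id")
}

.num_attr <- function(x) suppressWarnings(as.numeric(gsub("[a-zA-Z%]+\\s*$", "", x)))

.parse_style_decl <- function(s) {
  # "fill: red; stroke-width:2" -> named character vector
  if (is.na(s) || !nzchar(s)) return(character())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(trimws(parts))]
  kv <- strsplit(parts, ":", fixed = TRUE)
  keys <- vapply(kv, function(p) trimws(p[[1]]), "")
  vals <- vapply(kv, function(p) trimws(paste(p[-1], collapse = ":")), "")
  stats::setNames(vals, keys)
}

.style_from_attrs <- function(attrs) {
  # Presentation attributes first, inline `style` overrides them; keys not in
  # .STYLE_ATTRS are preserved verbatim in `extra`.
  decl <- attrs[names(attrs) %in% .STYLE_ATTRS]
  inline <- if ("style" %in% names(attrs)) .parse_style_decl(attrs[["style"]])
            else character()
  merged <- decl
  merged[names(inline)] <- inline
  list(fill = if ("fill" %in% names(merged)) unname(merged[["fill"]]) else NA_character_,
       stroke = if ("stroke" %in% names(merged)) unname(merged[["stroke"]]) else NA_character_,
       stroke_width = if ("stroke-width" %in% names(merged))
         .num_attr(merged[["stroke-width"]]) else NA_real_,
       opacity = if ("opacity" %in% names(merged))
         .num_attr(merged[["opacity"]]) else NA_real_,
       extra = merged[!(names(merged) %in% .STYLE_ATTRS)])
}

.parse_translate <- function(tf) {
  if (is.na(tf) || !nzchar(tf)) return(c(0, 0))
  m <- regmatches(tf, regexec(
    "translate\\(\\s*([-+0-9.eE]+)[ ,]*([-+0-9.eE]+)?\\s*\\)", tf))[[1]]
  if (length(m) < 2L) return(c(0, 0))
  tx <- as.numeric(m[2])
  ty <- if (length(m) >= 3L && nzchar(m[3])) as.numeric(m[3]) else 0
  c(tx, ty)
}

.elem_record <- function(node) {
  at <- xml2::xml_attrs(node)
  list(tag = xml2::xml_name(node), attrs = at)
}

# Collect drawable descendants of a feature group that lack their own id:
# they inherit the group's styling ("the group covers its descendants").
.collect_group_geom <- function(node) {
  out <- list()
  for (ch in xml2::xml_children(node)) {
    tag <- xml2::xml_name(ch)
    id <- xml2::xml_attr(ch, "id")
    has_id <- !is.na(id) && nzchar(id)
    if (has_id) next  # id-bearing descendants are features of their own
    if (tag %in% .DRAWABLE_TAGS) out[[length(out) + 1L]] <- .elem_record(ch)
    else if (tag == "g") out <- c(out, .collect_group_geom(ch))
  }
  out
}

#' Parse an annotated SVG file
#'
#' Every drawable element (\code{path}, \code{rect}, \code{circle},
#' \code{ellipse}, \code{polygon}, \code{polyline}, \code{line}) or group
#' (\code{g}) carrying an \code{id} attribute becomes one spatial feature;
#' document order defines the 0-based \code{layer_index}. A group's id covers
#' its id-less drawable descendants (they inherit the group fill at render
#' time), while id-bearing descendants become features of their own. Canvas
#' dimensions come from the root \code{width}/\code{height} attributes or,
#' failing that, the \code{viewBox}.
#'
#' @param path path to an SVG 1.1 file.
#' @return an \code{\link{svg_doc}}.
#' @export
parse_asvg <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- tryCatch(xml2::read_xml(path),
                error = function(e) stop("malformed XML in '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  xml2::xml_ns_strip(x)
  if (xml2::xml_name(x) != "svg")
    stop("root element is <", xml2::xml_name(x), ">, expected <svg>")

  w <- .num_attr(xml2::xml_attr(x, "width"))
  h <- .num_attr(xml2::xml_attr(x, "height"))
  if (is.na(w) || is.na(h)) {
    vb <- xml2::xml_attr(x, "viewBox")
    if (!is.na(vb)) {
      v <- as.numeric(strsplit(trimws(vb), "[ ,]+")[[1]])
      if (length(v) == 4L) { w <- v[3]; h <- v[4] }
    }
  }
  if (is.na(w) || is.na(h))
    stop("cannot determine canvas dimensions: no width/height or viewBox")

  feats <- list()
  walk <- function(node, group_path) {
    for (ch in xml2::xml_children(node)) {
      tag <- xml2::xml_name(ch)
      id <- xml2::xml_attr(ch, "id")
      has_id <- !is.na(id) && nzchar(id)
      if (tag %in% .DRAWABLE_TAGS && has_id) {
        at <- xml2::xml_attrs(ch)
        keep <- at[!(names(at) %in% c("id", "style", "transform", .STYLE_ATTRS))]
        feats[[length(feats) + 1L]] <<- spatial_feature(
          id = id,
          elements = list(list(tag = tag, attrs = keep)),
          container = tag,
          style = .style_from_attrs(at),
          layer_index = length(feats),
          group_path = group_path,
          offset = .parse_translate(xml2::xml_attr(ch, "transform")))
      } else if (tag == "g") {
        if (has_id) {
          at <- xml2::xml_attrs(ch)
          geom <- .collect_group_geom(ch)
          if (length(geom)) {
            feats[[length(feats) + 1L]] <<- spatial_feature(
              id = id, elements = geom, container = "g",
              style = .style_from_attrs(at),
              layer_index = length(feats),
              group_path = group_path,
              offset = .parse_translate(xml2::xml_attr(ch, "transform")))
          }
          walk(ch, c(group_path, id))
        } else {
          walk(ch, group_path)
        }
      }
      # drawables without id outside feature groups are decorative: skipped
    }
  }
  walk(x, character())

  ids <- vapply(feats, `[[`, "", "id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate feature ids in '", path, "': ",
         paste(dup, collapse = ", "))
  if (!length(feats))
    warning("no id-bearing drawable elements found in '", path, "'")
  for (i in seq_along(feats)) feats[[i]]$layer_index <- i - 1L

  raster <- xml2::xml_attr(x, "data-raster")
  svg_doc(feats, w, h, source_paths = path,
          raster_path = if (!is.na(raster) && file.exists(raster)) raster else NULL)
}

#' Subset a document to named features
#'
#' Pure transform: the input is unmodified; the returned document keeps the
#' original feature order and styles.
#'
#' @param doc an \code{svg_doc}.
#' @param ids character vector of feature ids to keep.
#' @return an \code{svg_doc} with exactly the named features.
#' @export
subset_features <- function(doc, ids) {
  have <- feature_ids(doc)
  missing <- setdiff(ids, have)
  if (length(missing))
    stop("unknown feature id(s): ", paste(missing, collapse = ", "))
  keep <- doc$features[have %in% ids]
  for (i in seq_along(keep)) keep[[i]]$layer_index <- i - 1L
  out <- doc
  out$features <- keep
  out
}

#' Combine documents by tiling canvases
#'
#' Canvases tile left-to-right (\code{horizontal}) or top-to-bottom
#' (\code{vertical}) with a gap of 2\% of the larger canvas dimension.
#' Geometries of later documents are translated accordingly. Feature-id
#' collisions are resolved deterministically by suffixing \code{"__k"} where
#' k is the 2-based position of the document in the list.
#'
#' @param docs list of at least two \code{svg_doc} objects.
#' @param arrangement \code{"horizontal"} or \code{"vertical"}.
#' @return a combined \code{svg_doc}.
#' @export
combine_docs <- function(docs, arrangement = c("horizontal", "vertical")) {
  arrangement <- match.arg(arrangement)
  if (!is.list(docs) || length(docs) < 2L)
    stop("combine_docs needs at least 2 documents")
  widths <- vapply(docs, `[[`, 0, "width")
  heights <- vapply(docs, `[[`, 0, "height")
  gap <- 0.02 * max(widths, heights)

  seen <- character()
  feats <- list()
  off_x <- 0; off_y <- 0
  for (k in seq_along(docs)) {
    d <- docs[[k]]
    for (f in d$features) {
      if (f$id %in% seen) f$id <- paste0(f$id, "__", k)
      if (f$id %in% seen)
        stop("feature id collision not resolvable: ", f$id)
      seen <- c(seen, f$id)
      f$offset <- f$offset + c(off_x, off_y)
      f$layer_index <- length(feats)
      feats[[length(feats) + 1L]] <- f
    }
    if (arrangement == "horizontal") off_x <- off_x + d$width + gap
    else off_y <- off_y + d$height + gap
  }
  if (arrangement == "horizontal") {
    W <- sum(widths) + gap * (length(docs) - 1L); H <- max(heights)
  } else {
    W <- max(widths); H <- sum(heights) + gap * (length(docs) - 1L)
  }
  svg_doc(feats, W, H,
          source_paths = unlist(lapply(docs, `[[`, "source_paths")))
}

#' Set the opacity of selected layers or features
#'
#' @param doc an \code{svg_doc}.
#' @param layer_selector character vector of feature ids, or an integer
#'   vector of \code{layer_index} values (0-based).
#' @param alpha opacity in [0, 1]; 0 is fully transparent.
#' @return the modified \code{svg_doc} (input untouched).
#' @export
set_layer_opacity <- function(doc, layer_selector, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1)
    stop("alpha must be a single number in [0, 1]")
  ids <- feature_ids(doc)
  sel <- if (is.character(layer_selector)) {
    missing <- setdiff(layer_selector, ids)
    if (length(missing))
      stop("unknown feature id(s): ", paste(missing, collapse = ", "))
    ids %in% layer_selector
  } else {
    vapply(doc$features, `[[`, 0L, "layer_index") %in% as.integer(layer_selector)
  }
  for (i in which(sel)) doc$features[[i]]$style$opacity <- alpha
  doc
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

.fmt_num <- function(x) {
  s <- sprintf("%.4f", x)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

.attrs_str <- function(attrs) {
  if (!length(attrs)) return("")
  paste0(vapply(names(attrs), function(k)
    sprintf(' %s="%s"', k, .xml_escape(attrs[[k]])), ""), collapse = "")
}

.style_attr_str <- function(style, offset) {
  s <- ""
  if (!is.na(style$fill)) s <- paste0(s, sprintf(' fill="%s"', style$fill))
  if (!is.na(style$stroke)) s <- paste0(s, sprintf(' stroke="%s"', style$stroke))
  if (!is.na(style$stroke_width))
    s <- paste0(s, sprintf(' stroke-width="%s"', .fmt_num(style$stroke_width)))
  if (!is.na(style$opacity))
    s <- paste0(s, sprintf(' opacity="%s"', .fmt_num(style$opacity)))
  if (length(style$extra)) {
    decl <- paste(sprintf("%s:%s", names(style$extra), style$extra),
                  collapse = ";")
    s <- paste0(s, sprintf(' style="%s"', .xml_escape(decl)))
  }
  if (any(offset != 0))
    s <- paste0(s, sprintf(' transform="translate(%s,%s)"',
                           .fmt_num(offset[1]), .fmt_num(offset[2])))
  s
}

.raster_data_uri <- function(path, grayscale = FALSE) {
  ext <- tolower(tools::file_ext(path))
  if (grayscale && ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) {
      gray <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
      out <- array(gray, dim = c(dim(gray), dim(img)[3]))
      out[, , seq_len(min(3, dim(img)[3]))] <- gray
      if (dim(img)[3] == 4L) out[, , 4] <- img[, , 4]
    } else out <- img
    raw <- png::writePNG(out)
    return(paste0("data:image/png;base64,",
                  gsub("\n", "", jsonlite::base64_enc(raw), fixed = TRUE)))
  }
  mime <- if (ext %in% c("jpg", "jpeg")) "image/jpeg" else "image/png"
  raw <- readBin(path, "raw", n = file.info(path)$size)
  paste0("data:", mime, ";base64,",
         gsub("\n", "", jsonlite::base64_enc(raw), fixed = TRUE))
}

#' Write a document as standalone SVG 1.1
#'
#' Output is deterministic (fixed float formatting), so identical documents
#' produce byte-identical files. \code{parse_asvg(write_svg(doc))} reproduces
#' feature ids, layer order, and style fields. When \code{raster_path} is set
#' the raster is embedded as a base64 \code{<image>} element below all vector
#' layers.
#'
#' @param doc an \code{svg_doc}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_svg <- function(doc, path) {
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                            'xmlns:xlink="http://www.w3.org/1999/xlink" ',
                            'version="1.1" width="%s" height="%s" ',
                            'viewBox="0 0 %s %s"%s>'),
                     .fmt_num(doc$width), .fmt_num(doc$height),
                     .fmt_num(doc$width), .fmt_num(doc$height),
                     if (!is.null(doc$raster_path))
                       sprintf(' data-raster="%s"',
                               .xml_escape(doc$raster_path)) else ""))
  if (!is.null(doc$raster_path)) {
    if (!file.exists(doc$raster_path))
      stop("raster file not readable: ", doc$raster_path)
    uri <- .raster_data_uri(doc$raster_path, doc$raster_grayscale)
    lines <- c(lines, sprintf(
      '  <image x="0" y="0" width="%s" height="%s" opacity="%s" xlink:href="%s"/>',
      .fmt_num(doc$width), .fmt_num(doc$height),
      .fmt_num(doc$raster_alpha), uri))
  }
  ord <- order(vapply(doc$features, `[[`, 0L, "layer_index"))
  for (f in doc$features[ord]) {
    sty <- .style_attr_str(f$style, f$offset)
    if (f$container != "g" && length(f$elements) == 1L) {
      e <- f$elements[[1L]]
      lines <- c(lines, sprintf('  <%s id="%s"%s%s/>',
                                e$tag, .xml_escape(f$id),
                                .attrs_str(e$attrs), sty))
    } else {
      lines <- c(lines, sprintf('  <g id="%s"%s>', .xml_escape(f$id), sty))
      for (e in f$elements)
        lines <- c(lines, sprintf('    <%s%s/>', e$tag, .attrs_str(e$attrs)))
      lines <- c(lines, "  </g>")
    }
  }
  lines <- c(lines, "</svg>")
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
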