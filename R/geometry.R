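# Geometry flattening: SVG shapes -> polyline matrices (x, y), y DOWN,
# SVG user units. Used for bounding boxes and base-graphics rasterization;
# the verbatim attributes remain the authority for SVG output.

.path_tokens <- function(d) {
  pat <- "[A-DF-Za-df-z]|[-+]?(?:[0-9]*\\.[0-9]+|[0-9]+)(?:[eE][-+]?[0-9]+)?"
  regmatches(d, gregexpr(pat, d))[[1]]
}

.bezier3 <- function(p0, p1, p2, p3, n = 12L) {
  t <- seq(0, 1, length.out = n + 1L)[-1L]
  b <- cbind((1 - t)^3, 3 * (1 - t)^2 * t, 3 * (1 - t) * t^2, t^3)
  cbind(b %*% c(p0[1], p1[1], p2[1], p3[1]),
        b %*% c(p0[2], p1[2], p2[2], p3[2]))
}

.bezier2 <- function(p0, p1, p2, n = 12L) {
  t <- seq(0, 1, length.out = n + 1L)[-1L]
  b <- cbind((1 - t)^2, 2 * (1 - t) * t, t^2)
  cbind(b %*% c(p0[1], p1[1], p2[1]), b %*% c(p0[2], p1[2], p2[2]))
}

# Flatten an SVG path `d` string into a list of subpath matrices. Supports
# M/L/H/V/C/S/Q/T/Z in both cases; elliptical arcs (A) degrade to straight
# lines to the endpoint, which is adequate for bounding boxes.
parse_path_d <- function(d) {
  toks <- .path_tokens(d)
  subpaths <- list()
  pts <- NULL
  cur <- c(0, 0); start <- c(0, 0); prev_ctrl <- NULL; prev_cmd <- ""
  i <- 1L
  nextnum <- function() {
    v <- as.numeric(toks[i]); i <<- i + 1L; v
  }
  cmd <- ""
  while (i <= length(toks)) {
    if (grepl("^[A-Za-z]$", toks[i])) { cmd <- toks[i]; i <- i + 1L }
    rel <- cmd %in% letters
    up <- toupper(cmd)
    if (up == "M") {
      p <- c(nextnum(), nextnum()); if (rel) p <- cur + p
      if (!is.null(pts) && nrow(pts) > 1L)
        subpaths[[length(subpaths) + 1L]] <- pts
      pts <- matrix(p, ncol = 2); cur <- p; start <- p
      cmd <- if (rel) "l" else "L"  # subsequent pairs are implicit linetos
    } else if (up == "L") {
      p <- c(nextnum(), nextnum()); if (rel) p <- cur + p
      pts <- rbind(pts, p); cur <- p
    } else if (up == "H") {
      x <- nextnum(); p <- c(if (rel) cur[1] + x else x, cur[2])
      pts <- rbind(pts, p); cur <- p
    } else if (up == "V") {
      y <- nextnum(); p <- c(cur[1], if (rel) cur[2] + y else y)
      pts <- rbind(pts, p); cur <- p
    } else if (up == "C") {
      c1 <- c(nextnum(), nextnum()); c2 <- c(nextnum(), nextnum())
      p <- c(nextnum(), nextnum())
      if (rel) { c1 <- cur + c1; c2 <- cur + c2; p <- cur + p }
      pts <- rbind(pts, .bezier3(cur, c1, c2, p)); prev_ctrl <- c2; cur <- p
    } else if (up == "S") {
      c2 <- c(nextnum(), nextnum()); p <- c(nextnum(), nextnum())
      if (rel) { c2 <- cur + c2; p <- cur + p }
      c1 <- if (toupper(prev_cmd) %in% c("C", "S") && !is.null(prev_ctrl))
        2 * cur - prev_ctrl else cur
      pts <- rbind(pts, .bezier3(cur, c1, c2, p)); prev_ctrl <- c2; cur <- p
    } else if (up == "Q") {
      c1 <- c(nextnum(), nextnum()); p <- c(nextnum(), nextnum())
      if (rel) { c1 <- cur + c1; p <- cur + p }
      pts <- rbind(pts, .bezier2(cur, c1, p)); prev_ctrl <- c1; cur <- p
    } else if (up == "T") {
      p <- c(nextnum(), nextnum()); if (rel) p <- cur + p
      c1 <- if (toupper(prev_cmd) %in% c("Q", "T") && !is.null(prev_ctrl))
        2 * cur - prev_ctrl else cur
      pts <- rbind(pts, .bezier2(cur, c1, p)); prev_ctrl <- c1; cur <- p
    } else if (up == "A") {
      for (k in 1:5) nextnum()  # rx ry rot large-arc sweep
      p <- c(nextnum(), nextnum()); if (rel) p <- cur + p
      pts <- rbind(pts, p); cur <- p
    } else if (up == "Z") {
      pts <- rbind(pts, start); cur <- start
    } else {
      stop("unsupported path command: ", cmd)
    }
    prev_cmd <- cmd
  }
  if (!is.null(pts) && nrow(pts) > 1L)
    subpaths[[length(subpaths) + 1L]] <- pts
  lapply(subpaths, function(m) {
    dimnames(m) <- NULL
    m
  })
}

.circle_poly <- function(cx, cy, rx, ry, n = 32L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)
  cbind(cx + rx * cos(th), cy + ry * sin(th))
}

.points_attr <- function(s) {
  v <- as.numeric(strsplit(trimws(s), "[ ,]+")[[1]])
  matrix(v, ncol = 2, byrow = TRUE)
}

# One SVG element record -> list of polyline matrices.
.elem_polys <- function(e) {
  a <- e$attrs
  g <- function(k, default = 0) {
    if (k %in% names(a)) .num_attr(a[[k]]) else default
  }
  switch(e$tag,
    path = parse_path_d(a[["d"]]),
    rect = {
      x <- g("x"); y <- g("y"); w <- g("width"); h <- g("height")
      list(cbind(c(x, x + w, x + w, x, x), c(y, y, y + h, y + h, y)))
    },
    circle = list(.circle_poly(g("cx"), g("cy"), g("r"), g("r"))),
    ellipse = list(.circle_poly(g("cx"), g("cy"), g("rx"), g("ry"))),
    polygon = {
      m <- .points_attr(a[["points"]])
      list(rbind(m, m[1, , drop = FALSE]))
    },
    polyline = list(.points_attr(a[["points"]])),
    line = list(cbind(c(g("x1"), g("x2")), c(g("y1"), g("y2")))),
    stop("cannot flatten element <", e$tag, ">")
  )
}

#' Flattened polygon outlines of a feature
#'
#' @param feature a \code{spatial_feature}.
#' @return list of two-column matrices (x, y) in SVG user units with the
#'   feature's translation applied; curves are sampled, arcs linearized.
#' @export
feature_polygons <- function(feature) {
  polys <- do.call(c, lapply(feature$elements, .elem_polys))
  lapply(polys, function(m)
    cbind(m[, 1] + feature$offset[1], m[, 2] + feature$offset[2]))
}

#' Bounding box of a feature
#'
#' @param feature a \code{spatial_feature}.
#' @return named numeric vector \code{c(xmin, ymin, xmax, ymax)} (y down).
#' @export
feature_bbox <- function(feature) {
  polys <- feature_polygons(feature)
  xs <- unlist(lapply(polys, function(m) m[, 1]))
  ys <- unlist(lapply(polys, function(m) m[, 2]))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}
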