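#' Ordered 2D contour polyline
#'
#' The basic geometric container: an ordered list of vertices tracing either
#' a closed EDJ/front outline or an open vertical profile. Vertices are in
#' source pixel units when read from a digitized trace and in domain units
#' (the unit square) once converted for simulation.
#'
#' @param vertices Two-column numeric matrix of (x, y) vertices.
#' @param closed Logical; closed outlines must have >= 3 vertices.
#' @param units `"pixel"` or `"domain"`.
#' @return Object of class `contour_polyline` with fields `vertices`,
#'   `closed`, `units`.
#' @export
contour_polyline <- function(vertices, closed = TRUE, units = c("domain", "pixel")) {
  units <- match.arg(units)
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2) stop("vertices must be a two-column matrix")
  storage.mode(vertices) <- "double"
  if (any(!is.finite(vertices))) stop("non-finite vertex coordinates")
  # drop exactly repeated consecutive vertices (and a repeated closing vertex)
  m <- nrow(vertices)
  if (m >= 2) {
    keep <- c(TRUE, rowSums(abs(diff(vertices))) > 0)
    vertices <- vertices[keep, , drop = FALSE]
  }
  if (closed && nrow(vertices) >= 2 &&
      all(vertices[1, ] == vertices[nrow(vertices), ]))
    vertices <- vertices[-nrow(vertices), , drop = FALSE]
  if (closed && nrow(vertices) < 3) stop("closed contour needs >= 3 distinct vertices")
  if (!closed && nrow(vertices) < 2) stop("open contour needs >= 2 distinct vertices")
  dimnames(vertices) <- NULL
  structure(list(vertices = vertices, closed = closed, units = units),
            class = "contour_polyline")
}

#' @export
print.contour_polyline <- function(x, ...) {
  cat(sprintf("<contour_polyline: %d vertices, %s, units=%s>\n",
              nrow(x$vertices), if (x$closed) "closed" else "open", x$units))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## segment list (a = from, b = to) of a polyline
polyline_segments <- function(poly) {
  v <- poly$vertices
  m <- nrow(v)
  if (poly$closed) list(a = v, b = v[c(2:m, 1L), , drop = FALSE])
  else list(a = v[-m, , drop = FALSE], b = v[-1L, , drop = FALSE])
}

#' Signed area and perimeter of a contour
#'
#' Shoelace signed area (positive for counter-clockwise closed contours) and
#' total arc length.
#' @param poly A [contour_polyline()].
#' @return `polygon_area`: signed area (0 for open polylines);
#'   `contour_perimeter`: total arc length.
#' @export
polygon_area <- function(poly) {
  if (!poly$closed) return(0)
  v <- poly$vertices
  m <- nrow(v)
  j <- c(2:m, 1L)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

#' @rdname polygon_area
#' @export
contour_perimeter <- function(poly) {
  s <- polyline_segments(poly)
  sum(sqrt(rowSums((s$b - s$a)^2)))
}

## normalize a closed contour to counter-clockwise orientation
orient_ccw <- function(poly) {
  if (poly$closed && polygon_area(poly) < 0)
    poly$vertices <- poly$vertices[rev(seq_len(nrow(poly$vertices))), , drop = FALSE]
  poly
}

## even-odd point-in-polygon test, vectorized over probe points
point_in_polygon <- function(px, py, poly) {
  v <- poly$vertices
  m <- nrow(v)
  j <- c(2:m, 1L)
  inside <- logical(length(px))
  for (e in seq_len(m)) {
    x1 <- v[e, 1]; y1 <- v[e, 2]; x2 <- v[j[e], 1]; y2 <- v[j[e], 2]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xi <- x1 + (py[crosses] - y1) / (y2 - y1) * (x2 - x1)
      inside[crosses] <- xor(inside[crosses], px[crosses] < xi)
    }
  }
  inside
}

#' Minimum distance from points to one or more polylines
#'
#' Exact point-to-segment distances, vectorized over probe points. This is
#' the workhorse behind level-set conversion and all thickness/distance
#' measurements.
#'
#' @param px,py Probe point coordinates.
#' @param polys A [contour_polyline()] or list of them.
#' @return Numeric vector of unsigned distances.
#' @export
dist_to_polylines <- function(px, py, polys) {
  if (inherits(polys, "contour_polyline")) polys <- list(polys)
  d2 <- rep(Inf, length(px))
  for (poly in polys) {
    s <- polyline_segments(poly)
    for (e in seq_len(nrow(s$a))) {
      ax <- s$a[e, 1]; ay <- s$a[e, 2]
      bx <- s$b[e, 1]; by <- s$b[e, 2]
      dx <- bx - ax; dy <- by - ay
      L2 <- dx * dx + dy * dy
      t <- if (L2 > 0) pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / L2)) else 0
      qx <- ax + t * dx; qy <- ay + t * dy
      d2 <- pmin(d2, (px - qx)^2 + (py - qy)^2)
    }
  }
  sqrt(d2)
}

## signed distance: negative inside the (closed) contour
signed_dist_to_contour <- function(px, py, poly) {
  d <- dist_to_polylines(px, py, poly)
  if (poly$closed) {
    inside <- point_in_polygon(px, py, poly)
    d[inside] <- -d[inside]
  }
  d
}

## pairwise proper/touching segment self-intersection test (vectorized over
## segment pairs); adjacent segments share an endpoint and are skipped
is_self_intersecting <- function(poly) {
  s <- polyline_segments(poly)
  m <- nrow(s$a)
  if (m < 4 || m > 4096) return(FALSE) # large contours: trust construction
  idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  adjacent <- (j - i == 1L) | (poly$closed & i == 1L & j == m)
  i <- i[!adjacent]; j <- j[!adjacent]
  if (!length(i)) return(FALSE)
  p1x <- s$a[i, 1]; p1y <- s$a[i, 2]; p2x <- s$b[i, 1]; p2y <- s$b[i, 2]
  q1x <- s$a[j, 1]; q1y <- s$a[j, 2]; q2x <- s$b[j, 1]; q2y <- s$b[j, 2]
  o <- function(ax, ay, bx, by, cx, cy) (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  d1 <- o(p1x, p1y, p2x, p2y, q1x, q1y)
  d2 <- o(p1x, p1y, p2x, p2y, q2x, q2y)
  d3 <- o(q1x, q1y, q2x, q2y, p1x, p1y)
  d4 <- o(q1x, q1y, q2x, q2y, p2x, p2y)
  any(d1 * d2 < 0 & d3 * d4 < 0)
}

## all intersections of the ray anchor + t * dir (t > 0) with a polyline;
## returns sorted positive t values
ray_polyline_intersections <- function(anchor, dir, polys) {
  if (inherits(polys, "contour_polyline")) polys <- list(polys)
  dir <- dir / sqrt(sum(dir^2))
  ts <- numeric(0)
  for (poly in polys) {
    s <- polyline_segments(poly)
    ax <- s$a[, 1]; ay <- s$a[, 2]
    ex <- s$b[, 1] - ax; ey <- s$b[, 2] - ay
    den <- dir[1] * (-ey) - dir[2] * (-ex) # det([dir, -e])
    ok <- abs(den) > 1e-14
    if (!any(ok)) next
    rx <- ax - anchor[1]; ry <- ay - anchor[2]
    t <- (rx * (-ey) + ry * ex)[ok] / den[ok]
    u <- (dir[1] * ry - dir[2] * rx)[ok] / den[ok]
    hit <- t > 1e-12 & u >= -1e-12 & u <= 1 + 1e-12
    ts <- c(ts, t[hit])
  }
  sort(ts)
}

## resample a polyline to exactly n vertices, equally spaced in arc length
resample_to_n <- function(poly, n) {
  v <- poly$vertices
  if (poly$closed) v <- rbind(v, v[1, ])
  seg <- sqrt(rowSums(diff(v)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  target <- if (poly$closed) L * (seq_len(n) - 1L) / n else L * (seq_len(n) - 1L) / (n - 1L)
  x <- stats::approx(s, v[, 1], xout = target, rule = 2)$y
  y <- stats::approx(s, v[, 2], xout = target, rule = 2)$y
  contour_polyline(cbind(x, y), closed = poly$closed, units = poly$units)
}
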