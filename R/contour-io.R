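#' Read a two-column XY contour file
#'
#' Reads digitized EDJ traces exported as plain-text XY coordinates: one
#' vertex per line, two numeric columns separated by whitespace, comma, or
#' tab. Blank lines are skipped. The contour is treated as closed when the
#' first and last vertices coincide or when `closed = TRUE` is forced.
#'
#' @param path Path to the text file.
#' @param closed `NA` (infer from first == last vertex) or logical.
#' @return A [contour_polyline()] with `units = "pixel"`.
#' @export
read_xy_contour <- function(path, closed = NA) {
  lines <- readLines(path, warn = FALSE)
  raw_idx <- seq_along(lines)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]; raw_idx <- raw_idx[keep]
  if (length(lines) < 3) stop("format error: fewer than 3 coordinate lines in ", path)
  xs <- ys <- numeric(length(lines))
  for (k in seq_along(lines)) {
    tok <- strsplit(trimws(lines[k]), "[,\t ]+")[[1]]
    if (length(tok) < 2)
      stop("parse error at line ", raw_idx[k], ": expected two columns")
    v <- suppressWarnings(as.numeric(tok[1:2]))
    if (any(is.na(v)))
      stop("parse error at line ", raw_idx[k], ": non-numeric token")
    xs[k] <- v[1]; ys[k] <- v[2]
  }
  if (is.na(closed))
    closed <- xs[1] == xs[length(xs)] && ys[1] == ys[length(ys)]
  poly <- contour_polyline(cbind(xs, ys), closed = closed, units = "pixel")
  if (poly$closed) poly <- orient_ccw(poly)
  poly
}

#' @rdname read_xy_contour
#' @param poly Contour to write.
#' @export
write_xy_contour <- function(poly, path) {
  v <- poly$vertices
  writeLines(sprintf("%.10g %.10g", v[, 1], v[, 2]), path)
  invisible(path)
}

#' Resample a contour at a fixed arc-length interval
#'
#' Vertices are placed equally spaced (in arc length) along the polyline,
#' mirroring trace interpolation at a fixed pixel interval. Closure is
#' preserved; for closed contours the number of output vertices is
#' `round(perimeter / interval)`.
#'
#' @param poly A [contour_polyline()].
#' @param interval Target spacing, in the contour's own units.
#' @return Resampled [contour_polyline()].
#' @export
resample_contour <- function(poly, interval) {
  L <- contour_perimeter(poly)
  if (L <= 0) stop("degenerate (zero-length) contour")
  if (interval <= 0 || interval >= L / 3)
    stop("interval must be positive and < total arc length / 3")
  n <- max(if (poly$closed) 3L else 2L, round(L / interval))
  out <- resample_to_n(poly, if (poly$closed) n else n + 1L)
  out
}

#' Contour-to-level-set conversion specification
#'
#' @param node_density Number of nodes along the longest axis of the regular
#'   triangular mesh (>= 16).
#' @param border Proportional size of the margins surrounding the EDJ shape,
#'   in (0, 0.5).
#' @param registration_triangles If `TRUE`, two small static solid triangles
#'   are placed in diagonally opposite corners so that differently sized EDJ
#'   slices of one stack share a uniform scale; they are excluded from growth
#'   and from all measurements.
#' @param triangle_size Leg length of the registration triangles as a
#'   fraction of the domain side; keep `<= border / 2` so they never touch
#'   the scaled EDJ.
#' @return Object of class `conversion_spec`.
#' @export
conversion_spec <- function(node_density = 129L, border = 0.25,
                            registration_triangles = FALSE,
                            triangle_size = 0.06) {
  if (node_density < 16) stop("node_density must be >= 16")
  if (border <= 0 || border >= 0.5)
    stop("border must be in (0, 0.5): it is the margin on each side")
  if (triangle_size <= 0 || triangle_size >= 0.5) stop("invalid triangle_size")
  structure(list(node_density = as.integer(node_density), border = border,
                 registration_triangles = registration_triangles,
                 triangle_size = triangle_size),
            class = "conversion_spec")
}

#' Similarity transform fitting contours into the simulation domain
#'
#' Uniform scale + translation mapping the joint bounding box of the given
#' contours into the unit square minus the border margins; the longest
#' bounding-box axis spans `1 - 2 * border`. Passing all slices of a stack
#' yields the shared transform that keeps them uniformly scaled.
#'
#' @param contours A contour or list of contours.
#' @param border Margin fraction.
#' @return List with `scale`, `offset` (length-2), usable by
#'   [apply_transform()].
#' @export
fit_transform <- function(contours, border = 0.25) {
  if (inherits(contours, "contour_polyline")) contours <- list(contours)
  allv <- do.call(rbind, lapply(contours, `[[`, "vertices"))
  lo <- apply(allv, 2, min); hi <- apply(allv, 2, max)
  span <- max(hi - lo)
  if (span <= 0) stop("degenerate contour extent")
  scale <- (1 - 2 * border) / span
  mid <- (lo + hi) / 2
  list(scale = scale, offset = c(0.5, 0.5) - scale * mid)
}

#' @rdname fit_transform
#' @param poly Contour to transform into domain units.
#' @param transform A transform from [fit_transform()].
#' @export
apply_transform <- function(poly, transform) {
  v <- sweep(poly$vertices * transform$scale, 2, transform$offset, "+")
  contour_polyline(v, closed = poly$closed, units = "domain")
}

## close an open vertical profile along the domain base line: both endpoints
## are dropped to y = base and joined along it, so the solid is the closed
## region between the relief and the base
close_on_base <- function(poly, base) {
  if (poly$closed) return(poly)
  v <- poly$vertices
  first <- v[1, ]; last <- v[nrow(v), ]
  extra <- rbind(c(last[1], base), c(first[1], base))
  orient_ccw(contour_polyline(rbind(v, extra), closed = TRUE, units = poly$units))
}

## corner registration triangles as polygons (domain units)
registration_triangle_polygons <- function(t) {
  list(contour_polyline(rbind(c(0, 0), c(t, 0), c(0, t)), closed = TRUE),
       contour_polyline(rbind(c(1, 1), c(1 - t, 1), c(1, 1 - t)), closed = TRUE))
}

#' Convert a contour to a signed-distance level set on a mesh
#'
#' Computes the per-node signed distance to the (scaled) contour, negative
#' inside the solid dentine region. The contour is translated and scaled so
#' its bounding box fills the domain minus the border margins, unless a
#' shared `transform` (e.g. from a slice stack) is supplied. Open vertical
#' profiles are first closed along the domain base line. Registration
#' triangles and braces become static solid obstacles: part of the solid
#' phase, but flagged so they neither grow nor enter any measurement.
#'
#' @param poly A [contour_polyline()] (pixel or domain units).
#' @param spec A [conversion_spec()].
#' @param mesh A [build_mesh()] mesh (defaults to one built from `spec`).
#' @param transform Optional shared transform from [fit_transform()];
#'   by default fitted to `poly` itself. Contours already in domain units
#'   with `fit = FALSE` are used as-is.
#' @param fit If `FALSE`, skip fitting (contour already in domain units).
#' @param braces Optional list of axis-aligned obstacle rectangles, each
#'   `c(xmin, xmax, ymin, ymax)` in domain units.
#' @param base_y Base line y for closing open profiles (defaults to the
#'   bottom margin `spec$border`).
#' @return Object of class `level_set`: `phi` (per-node signed distance),
#'   `obstacle` (per-node logical), `polygons` (obstacle outlines),
#'   `contour` (the scaled, closed solid outline), `transform`.
#' @export
contour_to_levelset <- function(poly, spec, mesh = NULL, transform = NULL,
                                fit = TRUE, braces = NULL, base_y = NULL) {
  if (is.null(mesh)) mesh <- build_mesh(spec$node_density)
  if (is_self_intersecting(poly)) stop("contour is self-intersecting")
  if (fit) {
    if (is.null(transform)) transform <- fit_transform(poly, spec$border)
    if (!poly$closed) {
      # open vertical profiles sit on the base line, not centered in y
      vy <- poly$vertices[, 2] * transform$scale
      transform$offset[2] <- (if (is.null(base_y)) spec$border else base_y) -
        min(vy)
    }
    poly <- apply_transform(poly, transform)
  } else if (is.null(transform)) transform <- list(scale = 1, offset = c(0, 0))
  v <- poly$vertices
  if (any(v < 0) || any(v > 1))
    stop("contour larger than domain after scaling; increase border or ",
         "supply a tighter transform")
  if (!poly$closed) {
    if (is.null(base_y)) base_y <- max(min(v[, 2]), spec$border)
    poly <- close_on_base(poly, base_y)
  } else poly <- orient_ccw(poly)

  phi <- signed_dist_to_contour(mesh$x, mesh$y, poly)
  obstacle <- rep(FALSE, mesh$n_nodes)
  polygons <- list()
  if (isTRUE(spec$registration_triangles)) {
    if (spec$triangle_size > spec$border / 2)
      warning("triangle_size > border/2: registration triangles may touch the EDJ")
    polygons <- c(polygons, registration_triangle_polygons(spec$triangle_size))
  }
  if (!is.null(braces)) {
    for (r in braces) {
      stopifnot(length(r) == 4, r[1] < r[2], r[3] < r[4])
      polygons <- c(polygons, list(contour_polyline(
        rbind(c(r[1], r[3]), c(r[2], r[3]), c(r[2], r[4]), c(r[1], r[4])),
        closed = TRUE)))
    }
  }
  for (pg in polygons) {
    phig <- signed_dist_to_contour(mesh$x, mesh$y, pg)
    obstacle <- obstacle | (phig <= 1e-12) # includes nodes on the outline
    phi <- pmin(phi, phig)
  }
  structure(list(phi = phi, obstacle = obstacle, polygons = polygons,
                 contour = poly, transform = transform),
            class = "level_set")
}

#' @export
print.level_set <- function(x, ...) {
  cat(sprintf("<level_set: %d nodes, %.1f%% solid, %d obstacle polygon(s)>\n",
              length(x$phi), 100 * mean(x$phi < 0), length(x$polygons)))
  invisible(x)
}

#' Render a simulation state to a lossless raster
#'
#' Draws the solid mask (gray), obstacles (dark gray), the zero-contour
#' interface (black) and optionally the nutrient field (blue shading on the
#' exterior) at one pixel per mesh node times `upscale`. Output is
#' deterministic for a fixed state and canvas size.
#'
#' @param mesh,ls Mesh and level set.
#' @param u Optional nutrient vector.
#' @param path Output PNG path.
#' @param upscale Integer pixel replication factor.
#' @return `path`, invisibly.
#' @export
write_step_image <- function(mesh, ls, path, u = NULL, upscale = 2L) {
  n <- mesh$n
  solid <- matrix(ls$phi < 0 & !ls$obstacle, n, n)
  obst <- matrix(ls$obstacle, n, n)
  r <- g <- b <- matrix(1, n, n)
  if (!is.null(u) && max(u) > 0) {
    un <- matrix(pmin(1, u / max(u)), n, n)
    r <- 1 - 0.6 * un; g <- 1 - 0.3 * un # blue shading where nutrients high
  }
  r[solid] <- 0.75; g[solid] <- 0.72; b[solid] <- 0.70
  r[obst] <- 0.35; g[obst] <- 0.35; b[obst] <- 0.35
  near <- matrix(abs(ls$phi) < mesh$h / 2 & !ls$obstacle, n, n)
  r[near] <- 0; g[near] <- 0; b[near] <- 0
  # node (ix, iy) -> image row = flip of iy (origin top-left), column = ix
  flip <- function(m) t(m[, n:1, drop = FALSE])
  img <- array(0, dim = c(n, n, 3))
  img[, , 1] <- flip(r); img[, , 2] <- flip(g); img[, , 3] <- flip(b)
  if (upscale > 1L) {
    idx <- rep(seq_len(n), each = upscale)
    img <- img[idx, idx, , drop = FALSE]
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Write a stacked surface as a Wavefront OBJ file
#'
#' Plain-text `v`/`f` records triangulating consecutive slice contours, for
#' viewing reconstructed 3D enamel surfaces in any mesh viewer.
#'
#' @param stack A `surface_stack` from [stack_slices()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_surface_obj <- function(stack, path) {
  if (!inherits(stack, "surface_stack")) stop("expected a surface_stack")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.8g %.8g %.8g",
                     stack$vertices[, 1], stack$vertices[, 2], stack$vertices[, 3]),
             con)
  writeLines(sprintf("f %d %d %d",
                     stack$faces[, 1], stack$faces[, 2], stack$faces[, 3]),
             con)
  invisible(path)
}
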