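#' Ridge and valley probe landmarks
#'
#' Builds labeled probe rays for a closed cusp-section EDJ: rays shoot
#' radially outward from the contour centroid; ridge rays at the lobe angles
#' `2*pi*k / n_ridges`, valley rays midway between lobes. Each anchor is the
#' outermost intersection of the ray with the EDJ.
#'
#' @param edj Closed EDJ contour in domain units.
#' @param n_ridges Number of lobes.
#' @param phase Angular offset of the first ridge (radians).
#' @return Data frame with columns `label`, `ax`, `ay`, `dx`, `dy`.
#' @export
cusp_landmarks <- function(edj, n_ridges = 4L, phase = 0) {
  cen <- colMeans(edj$vertices)
  rows <- list()
  for (k in seq_len(n_ridges)) {
    for (lab in c("ridge", "valley")) {
      th <- phase + 2 * pi * (k - 1) / n_ridges +
        if (lab == "valley") pi / n_ridges else 0
      dir <- c(cos(th), sin(th))
      ts <- ray_polyline_intersections(cen, dir, edj)
      if (!length(ts)) stop("landmark ray misses the EDJ")
      anchor <- cen + max(ts) * dir
      rows[[length(rows) + 1L]] <-
        data.frame(label = lab, ax = anchor[1], ay = anchor[2],
                   dx = dir[1], dy = dir[2])
    }
  }
  do.call(rbind, rows)
}

#' Matrix thickness progression at labeled landmarks
#'
#' For every recorded front and every probe ray, the distance along the ray
#' from its EDJ anchor to the (outermost) front crossing — the virtual
#' incremental-line measurement. Rays that miss the front at a step yield
#' `NA` (absent), not zero.
#'
#' @param history A `front_history` from [run_simulation()] or
#'   [extrapolation_history()].
#' @param landmarks Data frame as from [cusp_landmarks()]: columns `label`,
#'   `ax`, `ay`, `dx`, `dy`. Anchors must lie on the EDJ (within one node
#'   spacing).
#' @return Object of class `thickness_series`: `thickness` (steps x
#'   landmarks matrix), `landmarks`, `steps`, and `summary` (per step and
#'   label: mean and sd).
#' @export
thickness_profile <- function(history, landmarks) {
  h <- history$mesh_h
  d_anchor <- dist_to_polylines(landmarks$ax, landmarks$ay, history$edj)
  if (any(d_anchor > h))
    stop("landmark(s) ", paste(which(d_anchor > h), collapse = ", "),
         " not anchored on the EDJ (distance > h)")
  nk <- nrow(landmarks)
  th <- matrix(NA_real_, length(history$steps), nk)
  for (s in seq_along(history$steps)) {
    fr <- history$fronts[[s]]
    if (!length(fr)) next
    for (k in seq_len(nk)) {
      ts <- ray_polyline_intersections(c(landmarks$ax[k], landmarks$ay[k]),
                                       c(landmarks$dx[k], landmarks$dy[k]), fr)
      if (length(ts)) th[s, k] <- max(ts)
    }
  }
  summ <- do.call(rbind, lapply(seq_along(history$steps), function(s) {
    do.call(rbind, lapply(unique(landmarks$label), function(lab) {
      v <- th[s, landmarks$label == lab]
      data.frame(step = history$steps[s], label = lab,
                 mean = mean(v, na.rm = TRUE),
                 sd = stats::sd(v[!is.na(v)]))
    }))
  }))
  structure(list(thickness = th, landmarks = landmarks,
                 steps = history$steps, summary = summ),
            class = "thickness_series")
}

#' @export
print.thickness_series <- function(x, ...) {
  cat(sprintf("<thickness_series: %d steps x %d landmarks>\n",
              length(x$steps), nrow(x$landmarks)))
  print(utils::tail(x$summary, 4))
  invisible(x)
}

#' Enamel area and front perimeter of one slice
#'
#' @param front Closed front contour containing the EDJ.
#' @param edj Closed EDJ contour, or `NULL` for the bare front polygon.
#' @return Named numeric: `area` (front polygon minus EDJ polygon) and
#'   `perimeter` (front arc length).
#' @export
area_perimeter <- function(front, edj = NULL) {
  if (!front$closed) stop("front must be closed")
  a_front <- abs(polygon_area(front))
  a_edj <- 0
  if (!is.null(edj)) {
    if (!edj$closed) stop("EDJ must be closed")
    inside <- point_in_polygon(edj$vertices[, 1], edj$vertices[, 2], front) |
      dist_to_polylines(edj$vertices[, 1], edj$vertices[, 2], front) < 1e-9
    if (!all(inside)) stop("EDJ is not contained in the front")
    a_edj <- abs(polygon_area(edj))
  }
  c(area = a_front - a_edj, perimeter = contour_perimeter(front))
}

#' Rasterize a contour to a binary outline image
#'
#' Draws the polyline as an approximately 1-pixel-wide outline into a square
#' logical matrix (TRUE = contour pixel), the input expected by
#' [box_counting_dimension()].
#'
#' @param poly Contour (any units).
#' @param side Image side in pixels.
#' @param margin Fractional empty margin around the contour.
#' @return `side x side` logical matrix.
#' @export
rasterize_contour <- function(poly, side = 1024L, margin = 0.05) {
  v <- poly$vertices
  lo <- apply(v, 2, min); hi <- apply(v, 2, max)
  span <- max(hi - lo)
  if (span <= 0) span <- 1
  scale <- (1 - 2 * margin) * (side - 1) / span
  off <- (side - 1) / 2 - scale * (lo + hi) / 2
  s <- polyline_segments(poly)
  img <- matrix(FALSE, side, side)
  for (e in seq_len(nrow(s$a))) {
    a <- s$a[e, ] * scale + off
    b <- s$b[e, ] * scale + off
    L <- sqrt(sum((b - a)^2))
    t <- seq(0, 1, length.out = max(2L, ceiling(L / 0.4) + 1L))
    px <- round(a[1] + t * (b[1] - a[1])) + 1L
    py <- round(a[2] + t * (b[2] - a[2])) + 1L
    ok <- px >= 1 & px <= side & py >= 1 & py <= side
    img[cbind(px[ok], py[ok])] <- TRUE
  }
  img
}

## nearest-neighbor rotation of the on-pixel set about the image center;
## each source pixel is supersampled so rotated 1-px curves stay connected
rotate_pixels <- function(img, angle_deg) {
  if (angle_deg %% 360 == 0) return(img)
  side <- nrow(img)
  on <- which(img, arr.ind = TRUE)
  c0 <- (side + 1) / 2
  a <- angle_deg * pi / 180
  sub <- rbind(c(0, 0), c(0.35, 0.35), c(-0.35, 0.35),
               c(0.35, -0.35), c(-0.35, -0.35))
  out <- matrix(FALSE, side, side)
  for (k in seq_len(nrow(sub))) {
    x <- on[, 1] + sub[k, 1] - c0
    y <- on[, 2] + sub[k, 2] - c0
    xr <- round(cos(a) * x - sin(a) * y + c0)
    yr <- round(sin(a) * x + cos(a) * y + c0)
    ok <- xr >= 1 & xr <= side & yr >= 1 & yr <= side
    out[cbind(xr[ok], yr[ok])] <- TRUE
  }
  out
}

#' Box-counting fractal dimension of a binary contour image
#'
#' For each rotation of the contour (steps of `rotation_step` degrees) and
#' each of `grid_origins` grid offsets, counts the boxes occupied by contour
#' pixels over a geometric series of box sizes (2 px doubling up to a
#' quarter of the image side) and estimates `D_B` as minus the slope of
#' `log N` against `log s`. Defaults reproduce 12 origins x 10 rotations =
#' 120 estimates per contour.
#'
#' @param img Logical (or 0/1) square matrix with a 1-px-wide contour. The
#'   image is padded so rotations cannot clip the contour.
#' @param grid_origins Number of grid starting positions.
#' @param rotation_step Rotation increment in degrees.
#' @return Object of class `boxcount_result`: `estimates` (data frame
#'   `origin`, `rotation`, `D_B`), `mean`, `sd`, `box_sizes`.
#' @export
box_counting_dimension <- function(img, grid_origins = 12L, rotation_step = 36) {
  img <- img > 0
  if (!any(img)) stop("empty image: no contour pixels")
  side0 <- nrow(img)
  # pad to the diagonal so rotation never clips
  side <- 2L * ceiling(side0 * sqrt(2) / 2) + 1L
  pad <- matrix(FALSE, side, side)
  o <- floor((side - side0) / 2)
  pad[o + seq_len(side0), o + seq_len(side0)] <- img
  sizes <- 2^(1:floor(log2(side0 / 4)))
  if (length(sizes) < 4)
    stop("image too small: need >= 4 box sizes (side >= 128)")
  rotations <- seq(0, 360 - rotation_step, by = rotation_step)
  # 2D spread of grid origins: fractional offsets of the box size
  ogrid <- cbind((seq_len(grid_origins) - 1L) %% 4L / 4,
                 (seq_len(grid_origins) - 1L) %/% 4L / 3)
  est <- vector("list", length(rotations) * grid_origins)
  r <- 0L
  logs <- log(sizes)
  for (ang in rotations) {
    rot <- rotate_pixels(pad, ang)
    on <- which(rot, arr.ind = TRUE)
    for (g in seq_len(grid_origins)) {
      counts <- vapply(sizes, function(s) {
        off <- floor(ogrid[g, ] * s)
        bx <- (on[, 1] - 1L + off[1]) %/% s
        by <- (on[, 2] - 1L + off[2]) %/% s
        length(unique(bx * 1e6 + by))
      }, numeric(1))
      keep <- counts >= 1
      fit <- stats::lm.fit(cbind(1, logs[keep]), log(counts[keep]))
      r <- r + 1L
      est[[r]] <- data.frame(origin = g, rotation = ang,
                             D_B = -fit$coefficients[2])
    }
  }
  est <- do.call(rbind, est)
  rownames(est) <- NULL
  structure(list(estimates = est, mean = mean(est$D_B), sd = stats::sd(est$D_B),
                 box_sizes = sizes),
            class = "boxcount_result")
}

#' @export
print.boxcount_result <- function(x, ...) {
  cat(sprintf("<boxcount_result: %d estimates, mean D_B = %.4f (sd %.4f)>\n",
              nrow(x$estimates), x$mean, x$sd))
  invisible(x)
}

#' Stack 2D slice contours into a triangulated 3D surface
#'
#' Slices are resampled to a common vertex count; vertices correspond by
#' arc-length parameter (closed slices are additionally rotated so start
#' vertices align); consecutive rings are joined by triangle pairs.
#'
#' @param slices List of >= 2 contours with consistent closure.
#' @param z_spacing Uniform spacing between slices.
#' @param n_vertices Common vertex count (default: the largest slice count).
#' @return Object of class `surface_stack`: `vertices` (x, y, z), `faces`
#'   (vertex index triples), `slices`, `z_spacing`.
#' @export
stack_slices <- function(slices, z_spacing, n_vertices = NULL) {
  if (length(slices) < 2L) stop("a stack needs >= 2 slices")
  closed <- vapply(slices, `[[`, logical(1), "closed")
  if (length(unique(closed)) != 1L) stop("mixed open/closed slices")
  closed <- closed[1]
  if (z_spacing <= 0) stop("z_spacing must be > 0")
  if (is.null(n_vertices))
    n_vertices <- max(vapply(slices, function(s) nrow(s$vertices), integer(1)))
  n_vertices <- max(n_vertices, if (closed) 3L else 2L)
  rs <- lapply(slices, function(s) {
    s <- if (closed) orient_ccw(s) else s
    resample_to_n(s, n_vertices)
  })
  if (closed) {
    # align ring starts with slice 1 to avoid twisting
    for (i in seq_along(rs)[-1]) {
      ref <- rs[[i - 1]]$vertices[1, ]
      d2 <- rowSums(sweep(rs[[i]]$vertices, 2, ref, "-")^2)
      k <- which.min(d2)
      if (k > 1) {
        v <- rs[[i]]$vertices
        rs[[i]]$vertices <- v[c(k:nrow(v), seq_len(k - 1L)), , drop = FALSE]
      }
    }
  }
  ns <- length(rs)
  verts <- do.call(rbind, lapply(seq_len(ns), function(i)
    cbind(rs[[i]]$vertices, (i - 1) * z_spacing)))
  m <- n_vertices
  faces <- list()
  nseg <- if (closed) m else m - 1L
  for (i in seq_len(ns - 1L)) {
    b0 <- (i - 1L) * m
    j <- seq_len(nseg)
    jn <- if (closed) c(2:m, 1L) else j + 1L
    faces[[i]] <- rbind(cbind(b0 + j, b0 + jn, b0 + m + j),
                        cbind(b0 + jn, b0 + m + jn, b0 + m + j))
  }
  structure(list(vertices = verts, faces = do.call(rbind, faces),
                 slices = rs, z_spacing = z_spacing, n_per_ring = m),
            class = "surface_stack")
}

#' @export
print.surface_stack <- function(x, ...) {
  cat(sprintf("<surface_stack: %d slices x %d vertices, %d faces>\n",
              length(x$slices), x$n_per_ring, nrow(x$faces)))
  invisible(x)
}

## distances from 3D points to the nearest triangle of a surface stack
points_to_surface <- function(pts, stack) {
  V <- stack$vertices; F <- stack$faces
  best <- rep(Inf, nrow(pts))
  px <- pts[, 1]; py <- pts[, 2]; pz <- pts[, 3]
  for (f in seq_len(nrow(F))) {
    a <- V[F[f, 1], ]; b <- V[F[f, 2], ]; c0 <- V[F[f, 3], ]
    ab <- b - a; ac <- c0 - a
    d1 <- (px - a[1]) * ab[1] + (py - a[2]) * ab[2] + (pz - a[3]) * ab[3]
    d2 <- (px - a[1]) * ac[1] + (py - a[2]) * ac[2] + (pz - a[3]) * ac[3]
    aa <- sum(ab * ab); bb <- sum(ac * ac); abac <- sum(ab * ac)
    det <- aa * bb - abac^2
    v <- pmax(0, pmin(1, if (det > 1e-300) (bb * d1 - abac * d2) / det else 0))
    w <- pmax(0, pmin(1, if (det > 1e-300) (aa * d2 - abac * d1) / det else 0))
    s <- v + w
    scale <- ifelse(s > 1, 1 / s, 1)
    v <- v * scale; w <- w * scale
    qx <- a[1] + v * ab[1] + w * ac[1]
    qy <- a[2] + v * ab[2] + w * ac[2]
    qz <- a[3] + v * ab[3] + w * ac[3]
    d2p <- (px - qx)^2 + (py - qy)^2 + (pz - qz)^2
    # clamped barycentric projection is approximate off the edges; refine
    # by also testing the three edges
    for (ed in list(c(1, 2), c(1, 3), c(2, 3))) {
      p0 <- V[F[f, ed[1]], ]; p1 <- V[F[f, ed[2]], ]
      e <- p1 - p0; L2 <- sum(e * e)
      t <- pmax(0, pmin(1, ((px - p0[1]) * e[1] + (py - p0[2]) * e[2] +
                              (pz - p0[3]) * e[3]) / max(L2, 1e-300)))
      d2e <- (px - p0[1] - t * e[1])^2 + (py - p0[2] - t * e[2])^2 +
        (pz - p0[3] - t * e[3])^2
      d2p <- pmin(d2p, d2e)
    }
    best <- pmin(best, d2p)
  }
  sqrt(best)
}

#' Hausdorff-type distance summary between two surfaces or contours
#'
#' Densely samples each input and measures point-to-segment (2D contours) or
#' point-to-triangle (3D stacks) distances to the other, in both directions.
#'
#' @param a,b Two [contour_polyline()]s or two `surface_stack`s.
#' @param n_samples Sample count per contour (2D only).
#' @return Object of class `distance_summary`: per-direction `mean`, `max`,
#'   `sd`, plus `hausdorff` (symmetric max) and `mean_symmetric`.
#' @export
surface_distance <- function(a, b, n_samples = 2000L) {
  two_d <- inherits(a, "contour_polyline")
  if (two_d != inherits(b, "contour_polyline"))
    stop("inputs must have the same dimensionality")
  if (two_d) {
    pa <- resample_to_n(a, n_samples)$vertices
    pb <- resample_to_n(b, n_samples)$vertices
    dab <- dist_to_polylines(pa[, 1], pa[, 2], b)
    dba <- dist_to_polylines(pb[, 1], pb[, 2], a)
  } else {
    if (!inherits(a, "surface_stack") || !inherits(b, "surface_stack"))
      stop("3D inputs must be surface_stack objects")
    dab <- points_to_surface(a$vertices, b)
    dba <- points_to_surface(b$vertices, a)
  }
  structure(list(
    a_to_b = c(mean = mean(dab), max = max(dab), sd = stats::sd(dab)),
    b_to_a = c(mean = mean(dba), max = max(dba), sd = stats::sd(dba)),
    hausdorff = max(max(dab), max(dba)),
    mean_symmetric = mean(c(dab, dba))),
    class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  cat(sprintf(paste0("<distance_summary: hausdorff = %.5g, symmetric mean = ",
                     "%.5g>\n  a->b mean %.5g max %.5g | b->a mean %.5g max %.5g\n"),
              x$hausdorff, x$mean_symmetric, x$a_to_b["mean"], x$a_to_b["max"],
              x$b_to_a["mean"], x$b_to_a["max"]))
  invisible(x)
}
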