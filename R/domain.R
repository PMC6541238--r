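#' Build a regular triangular mesh on the unit square
#'
#' Structured triangulation with `node_density` nodes per axis: every cell of
#' the square grid is split along the same diagonal, so each interior node
#' has 6 neighbors. Linear (P1) finite-element stiffness and lumped mass
#' matrices are assembled once and cached on the mesh.
#'
#' Node numbering: node (ix, iy) has index `ix + (iy - 1) * n`, so a per-node
#' vector reshapes to an `n x n` matrix indexed `[ix, iy]` with y increasing
#' upward.
#'
#' @param node_density Nodes per axis (>= 16; smaller allowed internally for
#'   toy meshes via `strict = FALSE`).
#' @param fem Assemble FEM matrices (set `FALSE` for purely geometric use).
#' @param strict Enforce the `node_density >= 16` contract.
#' @return Object of class `tri_mesh`: `n`, `h`, `x`, `y`, `triangles`,
#'   boundary index sets, and (if `fem`) stiffness `K` and lumped mass
#'   `mlump`.
#' @export
build_mesh <- function(node_density, fem = TRUE, strict = TRUE) {
  n <- as.integer(node_density)
  if (strict && n < 16) stop("node_density must be >= 16")
  if (n < 2) stop("node_density must be >= 2")
  h <- 1 / (n - 1)
  ix <- rep(seq_len(n), times = n)
  iy <- rep(seq_len(n), each = n)
  x <- (ix - 1) * h
  y <- (iy - 1) * h
  id <- function(i, j) i + (j - 1L) * n
  ci <- rep(seq_len(n - 1L), times = n - 1L)
  cj <- rep(seq_len(n - 1L), each = n - 1L)
  a <- id(ci, cj); b <- id(ci + 1L, cj); cc <- id(ci, cj + 1L); d <- id(ci + 1L, cj + 1L)
  triangles <- rbind(cbind(a, b, d), cbind(a, d, cc))
  mesh <- structure(list(
    n = n, h = h, n_nodes = n * n, x = x, y = y, triangles = triangles,
    boundary = list(left = id(1L, seq_len(n)), right = id(n, seq_len(n)),
                    bottom = id(seq_len(n), 1L), top = id(seq_len(n), n))),
    class = "tri_mesh")
  if (fem) {
    fm <- assemble_fem(mesh)
    mesh$K <- fm$K
    mesh$mlump <- fm$mlump
  }
  mesh
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh: %d x %d nodes (h = %.4g), %d triangles>\n",
              x$n, x$n, x$h, nrow(x$triangles)))
  invisible(x)
}

## P1 stiffness and lumped mass over all triangles (vectorized assembly)
assemble_fem <- function(mesh) {
  tri <- mesh$triangles
  x <- mesh$x; y <- mesh$y
  x1 <- x[tri[, 1]]; x2 <- x[tri[, 2]]; x3 <- x[tri[, 3]]
  y1 <- y[tri[, 1]]; y2 <- y[tri[, 2]]; y3 <- y[tri[, 3]]
  b1 <- y2 - y3; b2 <- y3 - y1; b3 <- y1 - y2
  c1 <- x3 - x2; c2 <- x1 - x3; c3 <- x2 - x1
  area <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  area <- abs(area) / 2
  bb <- cbind(b1, b2, b3); cc <- cbind(c1, c2, c3)
  ii <- jj <- vv <- vector("list", 9L)
  k <- 0L
  for (p in 1:3) for (q in 1:3) {
    k <- k + 1L
    ii[[k]] <- tri[, p]; jj[[k]] <- tri[, q]
    vv[[k]] <- (bb[, p] * bb[, q] + cc[, p] * cc[, q]) / (4 * area)
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                            dims = c(mesh$n_nodes, mesh$n_nodes))
  ml <- numeric(mesh$n_nodes)
  for (p in 1:3) {
    add <- rowsum(area / 3, group = tri[, p])
    ml[as.integer(rownames(add))] <- ml[as.integer(rownames(add))] + add[, 1]
  }
  list(K = K, mlump = ml)
}

## reshape node vector to [ix, iy] matrix and back
node_mat <- function(v, n) matrix(v, n, n)

## shifted copies replicating the boundary (for one-sided differences)
shift_xm <- function(P) P[c(1L, seq_len(nrow(P) - 1L)), , drop = FALSE]
shift_xp <- function(P) P[c(2:nrow(P), nrow(P)), , drop = FALSE]
shift_ym <- function(P) P[, c(1L, seq_len(ncol(P) - 1L)), drop = FALSE]
shift_yp <- function(P) P[, c(2:ncol(P), ncol(P)), drop = FALSE]

#' Extract the zero isocontour of a level-set field
#'
#' Marching-triangles extraction: each triangle crossed by the zero level
#' contributes one segment with endpoints linearly interpolated along its
#' edges; segments are stitched into polylines. Contours belonging to static
#' obstacles (registration triangles, braces) are excluded by default.
#'
#' @param mesh A [build_mesh()] mesh.
#' @param ls A `level_set` (or bare numeric `phi` vector).
#' @param exclude_obstacles Drop contours whose centroid lies in (or within
#'   one node spacing of) an obstacle polygon.
#' @return List of [contour_polyline()] (possibly empty).
#' @export
extract_interface <- function(mesh, ls, exclude_obstacles = TRUE) {
  phi <- if (inherits(ls, "level_set")) ls$phi else as.numeric(ls)
  polygons <- if (inherits(ls, "level_set")) ls$polygons else list()
  phi[phi == 0] <- 1e-300
  tri <- mesh$triangles
  s1 <- phi[tri[, 1]] > 0; s2 <- phi[tri[, 2]] > 0; s3 <- phi[tri[, 3]] > 0
  mixed <- (s1 != s2) | (s2 != s3)
  if (!any(mixed)) return(list())
  tri <- tri[mixed, , drop = FALSE]
  s1 <- s1[mixed]; s2 <- s2[mixed]; s3 <- s3[mixed]
  # odd vertex: the one whose sign differs from the other two
  odd <- ifelse(s1 != s2 & s1 != s3, 1L, ifelse(s2 != s1 & s2 != s3, 2L, 3L))
  m <- nrow(tri)
  take <- function(k) tri[cbind(seq_len(m), k)]
  vo <- take(odd)
  o1 <- take((odd %% 3L) + 1L)
  o2 <- take(((odd + 1L) %% 3L) + 1L)
  ekey <- function(i, j) pmin(i, j) * (mesh$n_nodes + 1) + pmax(i, j)
  e1 <- ekey(vo, o1); e2 <- ekey(vo, o2)
  keys <- unique(c(e1, e2))
  id1 <- match(e1, keys); id2 <- match(e2, keys)
  # interpolated crossing point per unique edge
  ka <- floor(keys / (mesh$n_nodes + 1)); kb <- keys - ka * (mesh$n_nodes + 1)
  t <- phi[ka] / (phi[ka] - phi[kb])
  px <- mesh$x[ka] + t * (mesh$x[kb] - mesh$x[ka])
  py <- mesh$y[ka] + t * (mesh$y[kb] - mesh$y[ka])
  # stitch: each unique edge appears in at most 2 segments
  ne <- length(keys)
  nb1 <- integer(ne); nb2 <- integer(ne) # neighbor edge ids (0 = none)
  for (seg in seq_len(m)) {
    a <- id1[seg]; b <- id2[seg]
    if (nb1[a] == 0L) nb1[a] <- b else nb2[a] <- b
    if (nb1[b] == 0L) nb1[b] <- a else nb2[b] <- a
  }
  visited <- logical(ne)
  out <- list()
  walk <- function(start) {
    path <- integer(0)
    prev <- 0L; cur <- start
    repeat {
      path <- c(path, cur)
      visited[cur] <<- TRUE
      nxt <- if (nb1[cur] != 0L && nb1[cur] != prev && !visited[nb1[cur]]) nb1[cur]
             else if (nb2[cur] != 0L && nb2[cur] != prev && !visited[nb2[cur]]) nb2[cur]
             else 0L
      if (nxt == 0L) break
      prev <- cur; cur <- nxt
    }
    path
  }
  deg <- (nb1 != 0L) + (nb2 != 0L)
  for (start in c(which(deg == 1L), seq_len(ne))) {
    if (visited[start]) next
    path <- walk(start)
    if (length(path) < 2L) next
    closed <- deg[path[1]] == 2L && deg[path[length(path)]] == 2L &&
      (nb1[path[1]] == path[length(path)] || nb2[path[1]] == path[length(path)])
    pts <- cbind(px[path], py[path])
    if (closed && length(path) < 3L) next
    poly <- tryCatch(contour_polyline(pts, closed = closed),
                     error = function(e) NULL) # degenerate sliver
    if (is.null(poly)) next
    out[[length(out) + 1L]] <- poly
  }
  if (exclude_obstacles && length(polygons) && length(out)) {
    keep <- vapply(out, function(p) {
      cen <- colMeans(p$vertices)
      !any(vapply(polygons, function(pg)
        point_in_polygon(cen[1], cen[2], pg) ||
          dist_to_polylines(cen[1], cen[2], pg) < mesh$h, logical(1)))
    }, logical(1))
    out <- out[keep]
  }
  out
}

#' Restore the signed-distance property of a level-set field
#'
#' Two schemes. `"pde"` (the engine default) relaxes the reinitialization
#' equation `phi_t = sgn(phi0) (1 - |grad phi|)` with a subcell fix that
#' pins the interface using the incoming field's zero crossings; it uses
#' only axis-aligned differences, so it treats the two grid diagonals
#' symmetrically. `"contour"` recomputes exact distances to the marching-
#' triangles isocontour; it is the sharper choice for static geometry but
#' its linear interpolation cuts corners in concave features aligned with
#' the mesh diagonal, so the growth loop avoids it.
#'
#' @param mesh Mesh.
#' @param ls `level_set` (or numeric phi).
#' @param band Half-width of the reinitialized band; `Inf` for all nodes
#'   (`"contour"` method only; the PDE relaxation iterates to
#'   `max(band, 8h)`).
#' @param method `"pde"` or `"contour"`.
#' @return Updated `level_set` (or numeric phi, matching the input type).
#' @export
reinitialize <- function(mesh, ls, band = Inf, method = c("pde", "contour")) {
  method <- match.arg(method)
  phi <- if (inherits(ls, "level_set")) ls$phi else as.numeric(ls)
  if (all(phi >= 0) || all(phi <= 0))
    stop("cannot reinitialize a single-sign level-set field")
  if (method == "contour") {
    contours <- extract_interface(mesh, phi, exclude_obstacles = FALSE)
    sel <- if (is.finite(band)) which(abs(phi) <= band) else seq_along(phi)
    d <- dist_to_polylines(mesh$x[sel], mesh$y[sel], contours)
    phi[sel] <- sign(phi[sel]) * d
  } else {
    n <- mesh$n; h <- mesh$h
    P0 <- node_mat(phi, n)
    sgn <- ifelse(P0 >= 0, 1, -1)
    ssm <- P0 / sqrt(P0^2 + h^2) # smoothed sign for the far-field update
    near <- (shift_xm(P0) * P0 < 0) | (shift_xp(P0) * P0 < 0) |
            (shift_ym(P0) * P0 < 0) | (shift_yp(P0) * P0 < 0)
    gx0 <- (shift_xp(P0) - shift_xm(P0)) / 2
    gy0 <- (shift_yp(P0) - shift_ym(P0)) / 2
    den <- pmax(sqrt(gx0^2 + gy0^2), 1e-10)
    D0 <- h * P0 / den # subcell signed distance estimate at interface nodes
    reach <- if (is.finite(band)) max(band, 8 * h) else 1.5
    nit <- ceiling(reach / (0.45 * h))
    P <- P0
    for (it in seq_len(nit)) {
      dxm <- (P - shift_xm(P)) / h; dxp <- (shift_xp(P) - P) / h
      dym <- (P - shift_ym(P)) / h; dyp <- (shift_yp(P) - P) / h
      Gp <- sqrt(pmax(dxm, 0)^2 + pmin(dxp, 0)^2 +
                 pmax(dym, 0)^2 + pmin(dyp, 0)^2)
      Gm <- sqrt(pmin(dxm, 0)^2 + pmax(dxp, 0)^2 +
                 pmin(dym, 0)^2 + pmax(dyp, 0)^2)
      # near the interface relax toward the subcell distance D0 (contractive
      # regardless of transient sign disagreements); elsewhere the usual
      # upwind |grad phi| = 1 relaxation
      upd <- ifelse(near, (P - D0) / h,
                    ssm * (ifelse(P0 >= 0, Gp, Gm) - 1))
      P <- P - 0.45 * h * upd
    }
    phi <- pmin(pmax(as.vector(P), -2), 2)
  }
  if (inherits(ls, "level_set")) { ls$phi <- phi; ls } else phi
}

#' Mean curvature of the level-set interface
#'
#' `kappa = div(grad phi / |grad phi|)` by central differences; positive
#' where the solid bulges into the exterior (convex ridges), negative in
#' concavities. Values are clamped to the grid-resolvable bound `1/h`;
#' nodes with vanishing gradient get `kappa = 0`.
#'
#' @param mesh Mesh.
#' @param ls `level_set` (or numeric phi), ideally reinitialized.
#' @return Per-node curvature vector.
#' @export
curvature <- function(mesh, ls) {
  phi <- if (inherits(ls, "level_set")) ls$phi else as.numeric(ls)
  n <- mesh$n; h <- mesh$h
  P <- node_mat(phi, n)
  px <- (shift_xp(P) - shift_xm(P)) / (2 * h)
  py <- (shift_yp(P) - shift_ym(P)) / (2 * h)
  pxx <- (shift_xp(P) - 2 * P + shift_xm(P)) / h^2
  pyy <- (shift_yp(P) - 2 * P + shift_ym(P)) / h^2
  pxy <- (shift_yp(shift_xp(P)) - shift_ym(shift_xp(P)) -
          shift_yp(shift_xm(P)) + shift_ym(shift_xm(P))) / (4 * h^2)
  g2 <- px^2 + py^2
  k <- (pxx * py^2 - 2 * px * py * pxy + pyy * px^2) / pmax(g2, 1e-12)^1.5
  k[g2 < 1e-10] <- 0
  k <- pmin(pmax(k, -1 / h), 1 / h)
  as.vector(k)
}

#' Advect a level-set field in its normal direction
#'
#' Solves one step of `phi_t + Vn |grad phi| = 0` with the first-order
#' Godunov upwind scheme, sub-stepping internally so that
#' `max |Vn| * dt_sub <= h / 2`. Obstacle nodes never move.
#'
#' @param mesh Mesh.
#' @param ls `level_set` (or numeric phi).
#' @param Vn Per-node normal speed (positive = outward solid growth).
#' @param dt Time increment.
#' @return Updated `level_set` (or numeric phi).
#' @export
advect <- function(mesh, ls, Vn, dt) {
  phi <- if (inherits(ls, "level_set")) ls$phi else as.numeric(ls)
  obstacle <- if (inherits(ls, "level_set")) ls$obstacle else rep(FALSE, length(phi))
  if (any(is.na(Vn))) stop("NaN in interface velocity")
  n <- mesh$n; h <- mesh$h
  vmax <- max(abs(Vn))
  if (vmax == 0) return(ls)
  nsub <- max(1L, ceiling(vmax * dt / (h / 2)))
  dts <- dt / nsub
  V <- node_mat(Vn, n)
  P <- node_mat(phi, n)
  keep <- node_mat(obstacle, n)
  for (s in seq_len(nsub)) {
    dxm <- (P - shift_xm(P)) / h
    dxp <- (shift_xp(P) - P) / h
    dym <- (P - shift_ym(P)) / h
    dyp <- (shift_yp(P) - P) / h
    gp <- sqrt(pmax(dxm, 0)^2 + pmin(dxp, 0)^2 + pmax(dym, 0)^2 + pmin(dyp, 0)^2)
    gm <- sqrt(pmin(dxm, 0)^2 + pmax(dxp, 0)^2 + pmin(dym, 0)^2 + pmax(dyp, 0)^2)
    Pn <- P - dts * (pmax(V, 0) * gp + pmin(V, 0) * gm)
    Pn[keep] <- P[keep]
    P <- Pn
  }
  phi <- as.vector(P)
  if (inherits(ls, "level_set")) { ls$phi <- phi; ls } else phi
}

#' Area of the solid region of a level-set field
#'
#' Sub-cell-accurate area of \{phi < 0\} by clipping each linear triangle
#' against the zero level.
#'
#' @param mesh Mesh.
#' @param ls `level_set` or numeric phi.
#' @return Scalar area (domain units squared), including obstacle area.
#' @export
solid_area <- function(mesh, ls) {
  phi <- if (inherits(ls, "level_set")) ls$phi else as.numeric(ls)
  tri <- mesh$triangles
  A <- mesh$h^2 / 2
  p1 <- phi[tri[, 1]]; p2 <- phi[tri[, 2]]; p3 <- phi[tri[, 3]]
  neg <- (p1 < 0) + (p2 < 0) + (p3 < 0)
  total <- sum(neg == 3L) * A
  one <- which(neg == 1L)
  if (length(one)) {
    q <- cbind(p1[one], p2[one], p3[one])
    # fraction cut off by the single negative vertex
    wn <- apply(q, 1, function(r) {
      i <- which(r < 0)
      a <- r[i]; b <- r[-i]
      a^2 / ((a - b[1]) * (a - b[2]))
    })
    total <- total + sum(wn) * A
  }
  two <- which(neg == 2L)
  if (length(two)) {
    q <- cbind(p1[two], p2[two], p3[two])
    wp <- apply(q, 1, function(r) {
      i <- which(r >= 0)
      a <- r[i]; b <- r[-i]
      a^2 / ((a - b[1]) * (a - b[2]))
    })
    total <- total + sum(1 - wp) * A
  }
  total
}
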