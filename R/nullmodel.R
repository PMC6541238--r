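#' Geometric extrapolation of enamel thickness (uniform-thickness null model)
#'
#' The outer boundary of the morphological dilation of the solid EDJ region
#' by a disk of fixed radius — equivalently, the `phi = radius` offset
#' contour of the signed-distance field. This is the null hypothesis against
#' which diffusion-limited simulations are compared: it fills in fissures
#' narrower than twice the radius and never reproduces locally thickened
#' ridges.
#'
#' @param edj Closed EDJ contour in domain units (use `fit = TRUE` to scale
#'   an arbitrary contour into the unit square first).
#' @param radius Dilation radius (the uniform enamel thickness), > 0.
#' @param node_density Grid resolution used for the offset extraction.
#' @param fit Scale the contour into the domain (with margin `border`) first.
#' @param border Margin used when `fit = TRUE`.
#' @return The offset [contour_polyline()] (the largest one, when the offset
#'   of a multi-part solid still has several components).
#' @export
geometric_extrapolation <- function(edj, radius, node_density = 257L,
                                    fit = FALSE, border = 0.25) {
  if (radius <= 0) stop("radius must be > 0")
  if (is_self_intersecting(edj)) stop("EDJ contour is self-intersecting")
  if (fit) edj <- apply_transform(edj, fit_transform(edj, border))
  mesh <- build_mesh(node_density, fem = FALSE)
  phi <- signed_dist_to_contour(mesh$x, mesh$y, edj)
  on_bnd <- unique(unlist(mesh$boundary))
  if (min(phi[on_bnd]) <= radius)
    stop("offset by ", radius, " exits the domain; reduce radius or refit")
  offs <- extract_interface(mesh, phi - radius, exclude_obstacles = FALSE)
  if (!length(offs)) stop("empty offset contour")
  offs[[which.max(vapply(offs, function(p) abs(polygon_area(p)), numeric(1)))]]
}

#' Uniform-thickness front history from the null model
#'
#' Offsets of the EDJ at a sequence of increasing radii, packaged like a
#' simulated [run_simulation()] history so the same thickness-progression
#' measurements apply to both.
#'
#' @param edj Closed EDJ contour in domain units.
#' @param radii Increasing dilation radii.
#' @param node_density Grid resolution.
#' @return A `front_history`-like object (fronts, steps, edj).
#' @export
extrapolation_history <- function(edj, radii, node_density = 257L) {
  if (any(diff(radii) <= 0)) stop("radii must be strictly increasing")
  mesh <- build_mesh(node_density, fem = FALSE)
  phi <- signed_dist_to_contour(mesh$x, mesh$y, edj)
  fronts <- lapply(radii, function(r)
    extract_interface(mesh, phi - r, exclude_obstacles = FALSE))
  structure(list(steps = seq_along(radii), radii = radii, fronts = fronts,
                 edj = orient_ccw(edj), mesh_h = mesh$h,
                 node_density = mesh$n, stop_reason = "radii"),
            class = "front_history")
}
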