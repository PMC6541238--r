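#' Domain boundary specification
#'
#' All EDJ simulations default to no-flux (Neumann) domain boundaries; runs
#' with a basal sink additionally impose u = 0 on the horizontal line
#' `y = base_y` intersected with the exterior region (mixed
#' Dirichlet/Neumann), emulating the shorter matrix-secretion period towards
#' the crown base.
#'
#' @param left,right,bottom,top `"neumann"` or `"dirichlet_zero"` per side.
#' @param base_y y-position of the basal sink line in (0, 1), or `NULL`.
#' @return Object of class `boundary_spec`.
#' @export
boundary_spec <- function(left = "neumann", right = "neumann",
                          bottom = "neumann", top = "neumann",
                          base_y = NULL) {
  sides <- c(left = left, right = right, bottom = bottom, top = top)
  if (!all(sides %in% c("neumann", "dirichlet_zero")))
    stop("sides must be 'neumann' or 'dirichlet_zero'")
  if (!is.null(base_y) && (base_y <= 0 || base_y >= 1))
    stop("base_y must be in (0, 1)")
  structure(list(sides = sides, base_y = base_y), class = "boundary_spec")
}

## Exterior nodes (phi > 0) and the interface ring where the Gibbs-Thomson
## value is imposed. The ring is every exterior node with a solid
## 4-neighbor, plus diagonal-contact nodes within one spacing of the
## interface: the unconditional axis part keeps the ring hole-free under
## level-set drift, the distance-gated diagonal part keeps it
## orientation-symmetric and one node thin.
exterior_masks <- function(mesh, ls) {
  n <- mesh$n
  ext <- ls$phi > 0
  # static obstacles are solid for diffusion (excluded from the system,
  # hence no-flux) but never act as interface: no sink, no growth seed
  S <- node_mat(ls$phi < 0 & !ls$obstacle, n)
  axis <- shift_xm(S) | shift_xp(S) | shift_ym(S) | shift_yp(S)
  diag <- shift_xm(shift_ym(S)) | shift_xp(shift_yp(S)) |
    shift_xm(shift_yp(S)) | shift_xp(shift_ym(S))
  adjacent <- ext & (as.vector(axis) |
                       (as.vector(diag) & ls$phi <= mesh$h))
  list(exterior = ext, adjacent = adjacent)
}

## Dirichlet node set and values for one diffusion step
dirichlet_nodes <- function(mesh, ls, params, bc, kappa = NULL) {
  masks <- exterior_masks(mesh, ls)
  fixed <- logical(mesh$n_nodes)
  value <- numeric(mesh$n_nodes)
  # Gibbs-Thomson interface condition on interface-adjacent exterior nodes:
  # the required nutrient level rises with convexity, penalizing
  # high-curvature protrusions; sigma = 0 leaves a perfect sink (u = 0).
  adj <- masks$adjacent
  fixed[adj] <- TRUE
  if (params$sigma > 0 && identical(params$sigma_mode, "interface_value")) {
    if (is.null(kappa)) kappa <- curvature(mesh, ls)
    value[adj] <- pmax(0, params$u_star + params$sigma * kappa[adj])
  }
  for (side in names(bc$sides)) {
    if (bc$sides[[side]] == "dirichlet_zero") {
      idx <- mesh$boundary[[side]]
      fixed[idx] <- TRUE
      value[idx] <- 0
    }
  }
  if (!is.null(bc$base_y)) {
    iy <- round(bc$base_y / mesh$h) + 1L
    iy <- min(max(iy, 1L), mesh$n)
    idx <- seq_len(mesh$n) + (iy - 1L) * mesh$n
    idx <- idx[masks$exterior[idx]]
    fixed[idx] <- TRUE
    value[idx] <- 0
  }
  fixed <- fixed & masks$exterior
  list(fixed = fixed, value = value, exterior = masks$exterior,
       adjacent = masks$adjacent)
}

#' Initialize the nutrient field
#'
#' Nutrients are initially present only exterior to the dentine (the solid
#' region, including obstacles, acts as an internal nutrient barrier).
#'
#' @param mesh Mesh.
#' @param ls Level set.
#' @param u_init Initial exterior concentration (>= 0).
#' @return Per-node concentration vector.
#' @export
initialize_nutrients <- function(mesh, ls, u_init = 1) {
  if (u_init < 0) stop("u_init must be >= 0")
  u <- numeric(mesh$n_nodes)
  u[ls$phi > 0] <- u_init
  u
}

#' One implicit finite-element diffusion step
#'
#' Advances `u_t = D * Lap(u) + f` on the exterior (non-solid) region by one
#' implicit Euler step of length `params$dt`. Solid nodes are removed from
#' the system (no-flux across the interface); interface-adjacent exterior
#' nodes carry the Gibbs-Thomson value `u = max(0, u_star + sigma * kappa)`;
#' sides marked `dirichlet_zero` and the basal sink line are held at zero;
#' the background production `f` acts on the exterior only.
#'
#' With `params$quasi_static = TRUE` the steady state `-D * Lap(u) = f` under
#' the same constraints is solved instead (requires at least one Dirichlet
#' node).
#'
#' @param mesh Mesh.
#' @param u Current concentration vector.
#' @param ls Level set.
#' @param params A [growth_params()] (fields `D`, `f`, `dt`, `sigma`,
#'   `u_star`, `quasi_static` are used).
#' @param bc A [boundary_spec()].
#' @param kappa Optional precomputed curvature (recomputed when needed).
#' @return List: `u` (updated field), `produced` (nutrient mass added by the
#'   background source this step), `fixed` (Dirichlet node mask),
#'   `interface_flux` (nutrient mass absorption rate through the solid
#'   interface, from the discrete reaction at the constrained nodes), and
#'   `sink_flux` (absorption rate of domain-side and basal sinks).
#' @export
diffusion_step <- function(mesh, u, ls, params, bc = boundary_spec(),
                           kappa = NULL) {
  dn <- dirichlet_nodes(mesh, ls, params, bc, kappa)
  unknown <- dn$exterior & !dn$fixed
  u_new <- numeric(mesh$n_nodes)
  u_new[dn$fixed] <- dn$value[dn$fixed]
  produced <- 0
  interface_flux <- sink_flux <- 0
  flux_nodes <- numeric(mesh$n_nodes)
  if (any(unknown)) {
    K <- mesh$K; ml <- mesh$mlump
    iu <- which(unknown); ifx <- which(dn$fixed)
    Kuu <- K[iu, iu, drop = FALSE]
    load_fixed <- if (length(ifx))
      as.numeric(K[iu, ifx, drop = FALSE] %*% dn$value[ifx]) else 0
    if (isTRUE(params$quasi_static)) {
      if (!length(ifx))
        stop("quasi-static solve requires at least one Dirichlet node ",
             "(a solid interface or sink)")
      A <- params$D * Kuu
      rhs <- ml[iu] * params$f - params$D * load_fixed
    } else {
      A <- Matrix::Diagonal(x = ml[iu]) + params$dt * params$D * Kuu
      rhs <- ml[iu] * u[iu] + params$dt * ml[iu] * params$f -
        params$dt * params$D * load_fixed
      produced <- params$dt * params$f * sum(ml[iu])
    }
    sol <- tryCatch(
      as.numeric(Matrix::solve(Matrix::forceSymmetric(A), rhs)),
      error = function(e) stop("diffusion linear solve failed: ",
                               conditionMessage(e)))
    if (any(!is.finite(sol))) stop("diffusion solve produced non-finite values")
    u_new[iu] <- pmax(sol, 0)
    if (length(ifx)) {
      # reaction at constrained nodes = mass absorption rate there:
      # inflow from neighbours minus storage change of the held value, plus
      # the discrete drain into the excluded solid rows when the held value
      # is positive (stencil legs crossing the interface see a zero ghost)
      inflow <- -params$D * as.numeric(mesh$K[ifx, , drop = FALSE] %*% u_new)
      storage <- if (isTRUE(params$quasi_static)) 0
                 else mesh$mlump[ifx] * (dn$value[ifx] - u[ifx]) / params$dt
      active <- which(unknown | dn$fixed)
      wall <- params$D * dn$value[ifx] *
        Matrix::rowSums(mesh$K[ifx, active, drop = FALSE])
      q <- inflow - storage + wall
      flux_nodes[ifx] <- q
      at_interface <- dn$adjacent[ifx]
      interface_flux <- sum(q[at_interface])
      sink_flux <- sum(q[!at_interface])
    }
  }
  list(u = u_new, produced = produced, fixed = dn$fixed,
       adjacent = dn$adjacent, interface_flux = interface_flux,
       sink_flux = sink_flux, flux_nodes = flux_nodes)
}
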