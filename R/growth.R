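#' Dimensionless growth-model parameters
#'
#' All parameters are dimensionless; only their relative magnitudes matter.
#' Defaults place the reference simulation in the diffusion-limited regime
#' (background production `f = 30`); `f = 75` gives a weak diffusion-limited
#' effect and `f = 160` the excess-nutrient regime with near-uniform matrix
#' thickness.
#'
#' @param D Nutrient diffusion rate.
#' @param lambda Nutrient mass required per unit area of deposited matrix.
#' @param sigma Interfacial tension (stiffness of the ameloblast layer);
#'   scales the curvature penalty in the interface condition.
#' @param u_star Reference interface concentration of the Gibbs-Thomson
#'   condition `u = max(0, u_star + sigma * kappa)`.
#' @param f Constant background nutrient production on the exterior.
#' @param u_init Initial exterior concentration.
#' @param dt Fixed time step.
#' @param n_iter Number of growth steps.
#' @param record_every Record the front every this many steps (virtual
#'   incremental lines).
#' @param reinit_every Reinitialize the level set every this many steps.
#' @param band_width Velocity-extension band half-width, in node spacings.
#' @param smooth_width Tangential velocity smoothing radius on the interface,
#'   in node spacings (0 disables); a numerical stabilizer against staircase
#'   noise in the one-sided gradients.
#' @param clamp_nonnegative Clamp the front speed at zero (matrix deposition
#'   is irreversible); disable to explore signed classical Stefan motion.
#' @param flux_conservative Renormalize the front speed each step so the
#'   integrated flux matches the nutrient mass actually absorbed at the
#'   interface (see [interface_velocity()]).
#' @param quasi_static Solve the steady diffusion problem each step instead
#'   of the implicit time step.
#' @param sigma_mode `"interface_value"` (tension enters the interface
#'   boundary value, the default) or `"velocity_penalty"`
#'   (`Vn = max(0, (D / lambda) du/dn - sigma * kappa)`).
#' @param velocity_source `"gradient"` (speed from the one-sided normal
#'   derivative of u) or `"flux"` (speed from the discrete nutrient
#'   absorption per unit interface length — the local Stefan balance).
#' @param seed Integer seed; the engine itself is deterministic, the seed
#'   only feeds synthetic-shape noise.
#' @return Object of class `growth_params`.
#' @export
growth_params <- function(D = 0.01, lambda = 5, sigma = 0.002, u_star = 0,
                          f = 30, u_init = 1, dt = 0.001, n_iter = 150L,
                          record_every = 4L, reinit_every = 5L,
                          band_width = 5, smooth_width = 1.5, clamp_nonnegative = TRUE,
                          flux_conservative = TRUE, quasi_static = FALSE,
                          sigma_mode = c("interface_value", "velocity_penalty"),
                          velocity_source = c("gradient", "flux"),
                          seed = 1L) {
  sigma_mode <- match.arg(sigma_mode)
  velocity_source <- match.arg(velocity_source)
  if (D <= 0 || lambda <= 0) stop("D and lambda must be > 0")
  if (sigma < 0 || f < 0 || u_init < 0) stop("sigma, f, u_init must be >= 0")
  if (dt <= 0) stop("dt must be > 0")
  structure(list(D = D, lambda = lambda, sigma = sigma, u_star = u_star,
                 f = f, u_init = u_init, dt = dt, n_iter = as.integer(n_iter),
                 record_every = as.integer(record_every),
                 reinit_every = as.integer(reinit_every),
                 band_width = band_width, smooth_width = smooth_width,
                 clamp_nonnegative = isTRUE(clamp_nonnegative),
                 flux_conservative = isTRUE(flux_conservative),
                 quasi_static = isTRUE(quasi_static),
                 sigma_mode = sigma_mode, velocity_source = velocity_source,
                 seed = as.integer(seed)),
            class = "growth_params")
}

#' Interface normal velocity from the nutrient influx
#'
#' The Stefan velocity law: `Vn = (D / lambda) * du/dn`, with the normal
#' derivative taken one-sided on the exterior side of the interface
#' (`n = grad phi / |grad phi|`, pointing out of the solid). Values are
#' computed on interface-adjacent exterior nodes, clamped at zero when
#' deposition is irreversible, and extended as constants along the normal to
#' a band of half-width `band_width * h` so the level set can be advected.
#'
#' @param mesh Mesh.
#' @param u Nutrient field.
#' @param ls Level set.
#' @param params [growth_params()].
#' When `flux_rate` (the discrete nutrient absorption rate through the
#' interface, from [diffusion_step()]) is supplied, the velocity field is
#' renormalized so that the integrated front flux `lambda * integral(Vn ds)`
#' matches it exactly — the Stefan balance between consumed nutrients and
#' deposited area is then enforced through the velocity law while the
#' gradient field sets the spatial (ridge-versus-valley) pattern.
#'
#' @param kappa Optional curvature (only used by the `velocity_penalty`
#'   tension mode).
#' @param flux_rate Optional interface absorption rate for the conservative
#'   renormalization.
#' @return Per-node normal speed, zero outside the band and on obstacles.
#' @export
interface_velocity <- function(mesh, u, ls, params, kappa = NULL,
                               flux_rate = NULL, flux_nodes = NULL) {
  n <- mesh$n; h <- mesh$h
  masks <- exterior_masks(mesh, ls)
  P <- node_mat(ls$phi, n)
  nx <- (shift_xp(P) - shift_xm(P)) / (2 * h)
  ny <- (shift_yp(P) - shift_ym(P)) / (2 * h)
  gn <- sqrt(nx^2 + ny^2)
  nx <- nx / pmax(gn, 1e-12); ny <- ny / pmax(gn, 1e-12)
  U <- node_mat(u, n)
  E <- node_mat(masks$exterior, n)
  fwx <- (shift_xp(U) - U) / h; bwx <- (U - shift_xm(U)) / h
  fwy <- (shift_yp(U) - U) / h; bwy <- (U - shift_ym(U)) / h
  okfx <- shift_xp(E); okbx <- shift_xm(E)
  okfy <- shift_yp(E); okby <- shift_ym(E)
  gx <- ifelse(nx > 0, ifelse(okfx, fwx, ifelse(okbx, bwx, 0)),
                        ifelse(okbx, bwx, ifelse(okfx, fwx, 0)))
  gy <- ifelse(ny > 0, ifelse(okfy, fwy, ifelse(okby, bwy, 0)),
                        ifelse(okby, bwy, ifelse(okfy, fwy, 0)))
  dudn <- as.vector(gx * nx + gy * ny)
  vn_adj <- (params$D / params$lambda) * dudn

  Vn <- numeric(mesh$n_nodes)
  adj <- which(masks$adjacent & !ls$obstacle)
  if (!length(adj)) return(Vn)

  # interface length attributed to each adjacent node (nearest-segment
  # assignment on the extracted zero contour)
  seg_len <- NULL; seg_nn <- NULL
  if (!is.null(flux_rate)) {
    contours <- extract_interface(mesh, ls, exclude_obstacles = TRUE)
    if (length(contours)) {
      mids <- lens <- list()
      for (ct in contours) {
        s <- polyline_segments(ct)
        mids[[length(mids) + 1L]] <- (s$a + s$b) / 2
        lens[[length(lens) + 1L]] <- sqrt(rowSums((s$b - s$a)^2))
      }
      mids <- do.call(rbind, mids); seg_len <- unlist(lens)
      d2 <- outer(mids[, 1], mesh$x[adj], "-")^2 +
            outer(mids[, 2], mesh$y[adj], "-")^2
      seg_nn <- max.col(-d2, ties.method = "first")
    }
  }
  if (identical(params$velocity_source, "flux") && !is.null(flux_nodes) &&
      !is.null(seg_nn)) {
    # local Stefan balance: speed = absorbed nutrient rate per interface
    # length, divided by the area requirement lambda
    li <- numeric(length(adj))
    agg <- rowsum(seg_len, group = seg_nn)
    li[as.integer(rownames(agg))] <- agg[, 1]
    vloc <- rep(NA_real_, length(adj))
    got <- li > 0
    vloc[got] <- flux_nodes[adj][got] / (params$lambda * li[got])
    if (any(!got) && any(got)) {
      gi <- which(got)
      d2 <- outer(mesh$x[adj][!got], mesh$x[adj][gi], "-")^2 +
            outer(mesh$y[adj][!got], mesh$y[adj][gi], "-")^2
      vloc[!got] <- vloc[gi][max.col(-d2, ties.method = "first")]
    }
    vn_adj[adj] <- vloc
  }
  if (identical(params$sigma_mode, "velocity_penalty") && params$sigma > 0) {
    if (is.null(kappa)) kappa <- curvature(mesh, ls)
    vn_adj <- vn_adj - params$sigma * kappa
  }
  if (params$clamp_nonnegative) vn_adj <- pmax(vn_adj, 0)
  # tangential smoothing over the interface-adjacent set at the grid scale:
  # suppresses staircase noise without touching feature-scale (multi-node)
  # velocity contrasts
  sw <- params$smooth_width %||% 1.5
  if (length(adj) > 3 && sw > 0) {
    ax0 <- mesh$x[adj]; ay0 <- mesh$y[adj]
    w2 <- (sw * h)^2
    sm <- numeric(length(adj))
    chunk0 <- 2048L
    for (s in seq(1L, length(adj), by = chunk0)) {
      ii <- s:min(s + chunk0 - 1L, length(adj))
      d2 <- outer(ax0[ii], ax0, "-")^2 + outer(ay0[ii], ay0, "-")^2
      Wm <- exp(-d2 / w2)
      sm[ii] <- (Wm %*% vn_adj[adj]) / rowSums(Wm)
    }
    vn_adj[adj] <- sm
  }
  if (!is.null(flux_rate) && flux_rate > 0 && !is.null(seg_nn) &&
      any(vn_adj[adj] > 0)) {
    denom <- sum(seg_len * vn_adj[adj][seg_nn])
    if (denom > 0) vn_adj <- vn_adj * flux_rate / (params$lambda * denom)
  }
  band <- which(abs(ls$phi) <= params$band_width * h & !ls$obstacle)
  # constant-along-normal extension by nearest interface-adjacent node;
  # nodes whose nearest front node is outside the band (e.g. small-|phi|
  # nodes hugging an obstacle face away from the front) stay at zero
  ax <- mesh$x[adj]; ay <- mesh$y[adj]; av <- vn_adj[adj]
  reach2 <- (1.5 * params$band_width * h)^2
  chunk <- 2048L
  for (s in seq(1L, length(band), by = chunk)) {
    idx <- band[s:min(s + chunk - 1L, length(band))]
    d2 <- outer(mesh$x[idx], ax, "-")^2 + outer(mesh$y[idx], ay, "-")^2
    nn <- max.col(-d2, ties.method = "first")
    v <- av[nn]
    v[d2[cbind(seq_along(nn), nn)] > reach2] <- 0
    Vn[idx] <- v
  }
  Vn[adj] <- av
  Vn
}

#' Initialize a coupled simulation state
#'
#' @param edj Initial EDJ contour (pixel or domain units).
#' @param params [growth_params()].
#' @param conversion [conversion_spec()].
#' @param bc [boundary_spec()].
#' @param braces Optional list of obstacle rectangles
#'   `c(xmin, xmax, ymin, ymax)` mimicking adjacent teeth and bone.
#' @param transform Optional shared [fit_transform()] (slice stacks).
#' @param fit Fit the contour into the domain (disable for contours already
#'   in domain units).
#' @return Object of class `simulation_state`.
#' @export
init_simulation <- function(edj, params, conversion = conversion_spec(),
                            bc = boundary_spec(), braces = NULL,
                            transform = NULL, fit = TRUE) {
  mesh <- build_mesh(conversion$node_density)
  ls <- contour_to_levelset(edj, conversion, mesh, transform = transform,
                            fit = fit, braces = braces)
  u <- initialize_nutrients(mesh, ls, params$u_init)
  structure(list(mesh = mesh, ls = ls, u = u, params = params, bc = bc,
                 step = 0L, produced = 0,
                 initial_mass = sum(mesh$mlump * u),
                 initial_area = solid_area(mesh, ls)),
            class = "simulation_state")
}

#' @export
print.simulation_state <- function(x, ...) {
  cat(sprintf("<simulation_state: step %d, %.1f%% solid, total nutrients %.4g>\n",
              x$step, 100 * mean(x$ls$phi < 0), sum(x$mesh$mlump * x$u)))
  invisible(x)
}

#' Advance the coupled system by one growth step
#'
#' One cycle of: periodic level-set reinitialization, curvature evaluation,
#' implicit diffusion step, Stefan velocity from the interface influx,
#' level-set advection, and nutrient bookkeeping (nutrients stored on nodes
#' overrun by the front are consumed).
#'
#' @param state A `simulation_state`.
#' @return Updated `simulation_state`.
#' @export
sim_step <- function(state) {
  p <- state$params
  mesh <- state$mesh
  if (state$step > 0L && p$reinit_every > 0L &&
      state$step %% p$reinit_every == 0L)
    state$ls <- reinitialize(mesh, state$ls, band = (p$band_width + 3) * mesh$h,
                             method = "pde")
  kappa <- if (p$sigma > 0) curvature(mesh, state$ls) else NULL
  ds <- diffusion_step(mesh, state$u, state$ls, p, state$bc, kappa)
  state$u <- ds$u
  state$produced <- state$produced + ds$produced
  state$sink_consumed <- (state$sink_consumed %||% 0) + p$dt * ds$sink_flux
  Vn <- interface_velocity(mesh, state$u, state$ls, p, kappa,
                           flux_rate = if (p$flux_conservative)
                             ds$interface_flux else NULL,
                           flux_nodes = ds$flux_nodes)
  phi_old <- state$ls$phi
  state$ls <- advect(mesh, state$ls, Vn, p$dt)
  swallowed <- state$ls$phi < 0 & phi_old >= 0
  if (any(swallowed)) state$u[swallowed] <- 0
  state$step <- state$step + 1L
  state
}

## front thickness along a probe ray: farthest crossing of the current front
probe_thickness <- function(fronts, anchor, dir) {
  ts <- ray_polyline_intersections(anchor, dir, fronts)
  if (!length(ts)) NA_real_ else max(ts)
}

#' Run a full matrix-secretion simulation
#'
#' Converts the EDJ contour to a level set, then repeatedly steps the coupled
#' nutrient/front system, recording the interface every `record_every` steps
#' (the virtual incremental lines). Stops after `n_iter` steps, or earlier
#' when the matrix thickness along `stop_probe` reaches its target (within
#' one node spacing), mirroring runs terminated when the lateral matrix
#' thickness matches an empirical value.
#'
#' @inheritParams init_simulation
#' @param stop_probe Optional list `(anchor, dir, target)`: a probe ray
#'   anchored on the EDJ.
#' @param stop_area Optional enamel-area target: stop once the deposited
#'   area (checked at record steps) reaches it — used to compare runs of
#'   different speed at matched enamel amounts.
#' @param on_boundary `"error"` aborts when the front touches a free domain
#'   side (the domain was too small); `"stop"` ends the run there and keeps
#'   the recorded history.
#' @param verbose Print progress every 25 steps.
#' @return Object of class `front_history`: `steps`, `fronts` (a list of
#'   contour lists), the scaled `edj` contour, the final `state`, and a
#'   nutrient `bookkeeping` list.
#' @export
run_simulation <- function(edj, params, conversion = conversion_spec(),
                           bc = boundary_spec(), braces = NULL,
                           transform = NULL, fit = TRUE, stop_probe = NULL,
                           stop_area = NULL,
                           on_boundary = c("error", "stop"),
                           verbose = FALSE) {
  on_boundary <- match.arg(on_boundary)
  state <- init_simulation(edj, params, conversion, bc, braces, transform, fit)
  mesh <- state$mesh
  steps <- integer(0)
  fronts <- list()
  record <- function(st) {
    steps[[length(steps) + 1L]] <<- st$step
    fronts[[length(fronts) + 1L]] <<- extract_interface(mesh, st$ls)
  }
  record(state)
  free_sides <- if (is.null(state$bc$base_y)) mesh$boundary
                else mesh$boundary[c("left", "right", "top")]
  free_boundary <- unique(unlist(free_sides))
  stop_reason <- "n_iter"
  for (k in seq_len(params$n_iter)) {
    state <- sim_step(state)
    if (any(state$ls$phi[free_boundary] < 0 &
              !state$ls$obstacle[free_boundary])) {
      if (on_boundary == "error")
        stop("front reached the domain boundary at step ", state$step,
             ": domain too small or border too low")
      stop_reason <- "boundary"
      record(state)
      break
    }
    at_record <- state$step %% params$record_every == 0L
    if (at_record || k == params$n_iter) record(state)
    if (!is.null(stop_probe) && at_record) {
      th <- probe_thickness(fronts[[length(fronts)]],
                            stop_probe$anchor, stop_probe$dir)
      if (!is.na(th) && th >= stop_probe$target - mesh$h) {
        stop_reason <- "probe_target"
        break
      }
    }
    if (!is.null(stop_area) && at_record &&
        solid_area(mesh, state$ls) - state$initial_area >= stop_area) {
      stop_reason <- "area_target"
      break
    }
    if (verbose && state$step %% 25L == 0L)
      message(sprintf("step %d: solid %.1f%%", state$step,
                      100 * mean(state$ls$phi < 0)))
  }
  final_area <- solid_area(mesh, state$ls)
  structure(list(
    steps = steps, fronts = fronts, edj = state$ls$contour,
    mesh_h = mesh$h, node_density = mesh$n, params = params,
    conversion = conversion, bc = state$bc, state = state,
    stop_reason = stop_reason,
    bookkeeping = list(
      initial_mass = state$initial_mass, produced = state$produced,
      remaining_mass = sum(mesh$mlump * state$u),
      initial_area = state$initial_area, final_area = final_area,
      enamel_area = final_area - state$initial_area)),
    class = "front_history")
}

#' @export
print.front_history <- function(x, ...) {
  cat(sprintf(paste0("<front_history: %d recorded fronts over %d steps, ",
                     "enamel area %.4g (%s)>\n"),
              length(x$steps), max(x$steps), x$bookkeeping$enamel_area,
              x$stop_reason))
  invisible(x)
}

#' Simulate a stack of EDJ slices with shared parameters
#'
#' Runs independent 2D simulations for each tomography slice using identical
#' parameters and a single shared scaling transform (computed from the joint
#' bounding box; registration triangles mark the common scale in every
#' slice), so the per-slice fronts can be stacked into a 3D surface.
#'
#' @param slices List of EDJ contours (>= 2, consistent closure).
#' @inheritParams run_simulation
#' @return List of `front_history`, one per slice.
#' @export
run_stack <- function(slices, params, conversion = conversion_spec(),
                      bc = boundary_spec(), braces = NULL) {
  if (length(slices) < 2L) stop("a stack needs >= 2 slices")
  closed <- vapply(slices, `[[`, logical(1), "closed")
  if (length(unique(closed)) != 1L) stop("slices have mismatched closure")
  transform <- fit_transform(slices, conversion$border)
  lapply(seq_along(slices), function(i) {
    tryCatch(
      run_simulation(slices[[i]], params, conversion, bc, braces,
                     transform = transform),
      error = function(e) stop("slice ", i, " failed: ", conditionMessage(e)))
  })
}
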