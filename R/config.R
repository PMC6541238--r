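## registry of run-configuration keys: name -> c(type, default)
config_registry <- function() {
  list(
    mode = list(type = "choice", default = "demo",
                choices = c("simulate", "extrapolate", "stack", "boxcount",
                            "shapes", "demo")),
    input = list(type = "string", default = ""),
    input_dir = list(type = "string", default = ""),
    output_dir = list(type = "string", default = "enamelsim_out"),
    # growth parameters
    D = list(type = "numeric", default = 0.01),
    lambda = list(type = "numeric", default = 5),
    sigma = list(type = "numeric", default = 0.002),
    u_star = list(type = "numeric", default = 0),
    f = list(type = "numeric", default = 30),
    u_init = list(type = "numeric", default = 1),
    dt = list(type = "numeric", default = 0.001),
    n_iter = list(type = "integer", default = 150L),
    record_every = list(type = "integer", default = 4L),
    reinit_every = list(type = "integer", default = 5L),
    band_width = list(type = "numeric", default = 5),
    clamp_nonnegative = list(type = "logical", default = TRUE),
    flux_conservative = list(type = "logical", default = TRUE),
    quasi_static = list(type = "logical", default = FALSE),
    sigma_mode = list(type = "choice", default = "interface_value",
                      choices = c("interface_value", "velocity_penalty")),
    velocity_source = list(type = "choice", default = "gradient",
                           choices = c("gradient", "flux")),
    seed = list(type = "integer", default = 1L),
    # conversion
    node_density = list(type = "integer", default = 129L),
    border = list(type = "numeric", default = 0.25),
    registration_triangles = list(type = "logical", default = FALSE),
    triangle_size = list(type = "numeric", default = 0.06),
    # boundaries
    left = list(type = "choice", default = "neumann",
                choices = c("neumann", "dirichlet_zero")),
    right = list(type = "choice", default = "neumann",
                 choices = c("neumann", "dirichlet_zero")),
    bottom = list(type = "choice", default = "neumann",
                  choices = c("neumann", "dirichlet_zero")),
    top = list(type = "choice", default = "neumann",
               choices = c("neumann", "dirichlet_zero")),
    base = list(type = "numeric", default = NA_real_), # basal sink y, NA = off
    braces = list(type = "string", default = ""), # "x0,x1,y0,y1[;...]"
    # synthetic shape
    shape_kind = list(type = "choice", default = "cusp_section",
                      choices = c("cusp_section", "vertical_profile",
                                  "circle", "square", "koch_curve")),
    size = list(type = "numeric", default = 0.3),
    n_ridges = list(type = "integer", default = 4L),
    ridge_amplitude = list(type = "numeric", default = 0.2),
    concavity_amplitude = list(type = "numeric", default = 0),
    waviness_wavelength = list(type = "numeric", default = 0.25),
    waviness_amplitude = list(type = "numeric", default = 0.02),
    noise_amplitude = list(type = "numeric", default = 0),
    n_vertices = list(type = "integer", default = 192L),
    koch_level = list(type = "integer", default = 4L),
    # extrapolation / metrics
    radius = list(type = "numeric", default = 0.08),
    z_spacing = list(type = "numeric", default = 0.02),
    image_side = list(type = "integer", default = 512L),
    grid_origins = list(type = "integer", default = 12L),
    rotation_step = list(type = "numeric", default = 36),
    write_images = list(type = "logical", default = TRUE)
  )
}

#' Default run configuration
#'
#' @return Named list of every configuration key with its default value.
#' @export
default_config <- function() {
  lapply(config_registry(), `[[`, "default")
}

coerce_key <- function(name, value, entry) {
  switch(entry$type,
    numeric = { v <- suppressWarnings(as.numeric(value)); v },
    integer = { v <- suppressWarnings(as.integer(value)); v },
    logical = {
      if (is.logical(value)) value
      else tolower(as.character(value)) %in% c("true", "1", "yes")
    },
    string = as.character(value),
    choice = as.character(value))
}

#' Validate a run configuration
#'
#' Fills unset keys with defaults; rejects unknown keys; checks types,
#' choice values and basic ranges. All offending keys are reported in a
#' single error.
#'
#' @param cfg Named list (possibly partial).
#' @return The completed, validated configuration.
#' @export
validate_config <- function(cfg) {
  reg <- config_registry()
  bad <- character(0)
  unknown <- setdiff(names(cfg), names(reg))
  if (length(unknown)) bad <- c(bad, paste0("unknown key: ", unknown))
  out <- default_config()
  for (nm in intersect(names(cfg), names(reg))) {
    v <- coerce_key(nm, cfg[[nm]], reg[[nm]])
    if (reg[[nm]]$type %in% c("numeric", "integer") &&
        (length(v) != 1 || is.na(v)) && nm != "base") {
      bad <- c(bad, paste0("non-numeric value for key: ", nm))
      next
    }
    if (reg[[nm]]$type == "choice" && !v %in% reg[[nm]]$choices) {
      bad <- c(bad, paste0("invalid value for key: ", nm,
                           " (must be one of ",
                           paste(reg[[nm]]$choices, collapse = "/"), ")"))
      next
    }
    out[[nm]] <- v
  }
  if (!is.na(out$border) && (out$border <= 0 || out$border >= 0.5))
    bad <- c(bad, "border (must be in (0, 0.5))")
  if (!is.na(out$dt) && out$dt <= 0) bad <- c(bad, "dt (must be > 0)")
  if (!is.na(out$node_density) && out$node_density < 16)
    bad <- c(bad, "node_density (must be >= 16)")
  if (!is.na(out$base) && (out$base <= 0 || out$base >= 1))
    bad <- c(bad, "base (must be in (0, 1))")
  if (length(bad))
    stop("invalid configuration:\n  ", paste(bad, collapse = "\n  "))
  out
}

#' Read a run configuration file
#'
#' Accepts either a JSON object (file ending in `.json`, or starting with
#' `{`) or flat `key = value` text (one pair per line, `#` comments).
#'
#' @param path File path.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path) {
  txt <- readLines(path, warn = FALSE)
  first <- trimws(paste(txt, collapse = " "))
  cfg <- if (grepl("\\.json$", path) || startsWith(first, "{")) {
    jsonlite::fromJSON(paste(txt, collapse = "\n"), simplifyVector = TRUE)
  } else {
    txt <- txt[!grepl("^\\s*(#|$)", txt)]
    kv <- strsplit(txt, "=", fixed = TRUE)
    stats::setNames(lapply(kv, function(p) trimws(paste(p[-1], collapse = "="))),
                    vapply(kv, function(p) trimws(p[1]), character(1)))
  }
  validate_config(cfg)
}

config_to_params <- function(cfg) {
  growth_params(D = cfg$D, lambda = cfg$lambda, sigma = cfg$sigma,
                u_star = cfg$u_star, f = cfg$f, u_init = cfg$u_init,
                dt = cfg$dt, n_iter = cfg$n_iter,
                record_every = cfg$record_every,
                reinit_every = cfg$reinit_every, band_width = cfg$band_width,
                clamp_nonnegative = cfg$clamp_nonnegative,
                flux_conservative = cfg$flux_conservative,
                quasi_static = cfg$quasi_static, sigma_mode = cfg$sigma_mode,
                velocity_source = cfg$velocity_source, seed = cfg$seed)
}

config_to_conversion <- function(cfg) {
  conversion_spec(node_density = cfg$node_density, border = cfg$border,
                  registration_triangles = cfg$registration_triangles,
                  triangle_size = cfg$triangle_size)
}

config_to_bc <- function(cfg) {
  boundary_spec(left = cfg$left, right = cfg$right, bottom = cfg$bottom,
                top = cfg$top,
                base_y = if (is.na(cfg$base)) NULL else cfg$base)
}

config_to_braces <- function(cfg) {
  if (!nzchar(cfg$braces)) return(NULL)
  lapply(strsplit(cfg$braces, ";", fixed = TRUE)[[1]],
         function(s) as.numeric(strsplit(s, ",", fixed = TRUE)[[1]]))
}

config_shape <- function(cfg) {
  if (cfg$shape_kind == "koch_curve") return(make_koch_contour(cfg$koch_level))
  make_shape(shape_spec(kind = cfg$shape_kind, size = cfg$size,
                        n_ridges = cfg$n_ridges,
                        ridge_amplitude = cfg$ridge_amplitude,
                        concavity_amplitude = cfg$concavity_amplitude,
                        waviness_wavelength = cfg$waviness_wavelength,
                        waviness_amplitude = cfg$waviness_amplitude,
                        noise_amplitude = cfg$noise_amplitude,
                        seed = cfg$seed),
             n_vertices = cfg$n_vertices)
}

write_manifest <- function(cfg, out_dir) {
  jsonlite::write_json(cfg, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

fronts_to_csv <- function(history, path) {
  rows <- list()
  for (s in seq_along(history$steps)) {
    for (ci in seq_along(history$fronts[[s]])) {
      v <- history$fronts[[s]][[ci]]$vertices
      rows[[length(rows) + 1L]] <-
        data.frame(step = history$steps[s], contour = ci,
                   vertex = seq_len(nrow(v)), x = v[, 1], y = v[, 2])
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

history_measurements <- function(history) {
  do.call(rbind, lapply(seq_along(history$steps), function(s) {
    fr <- history$fronts[[s]]
    if (!length(fr)) return(NULL)
    outer_front <- fr[[which.max(vapply(fr, function(p)
      abs(polygon_area(p)), numeric(1)))]]
    ap <- tryCatch(area_perimeter(outer_front, history$edj),
                   error = function(e) c(area = NA_real_, perimeter = NA_real_))
    data.frame(step = history$steps[s], area = ap[["area"]],
               perimeter = ap[["perimeter"]])
  }))
}

#' Execute a run configuration
#'
#' Configuration-driven entry point tying the pipeline together. Modes:
#' `simulate` (full diffusion-limited run), `extrapolate` (uniform-thickness
#' null model), `stack` (per-slice simulations combined into OBJ surfaces),
#' `boxcount` (box-counting dimension of a contour), `shapes` (emit a
#' synthetic contour as a two-column XY file), `demo` (seeded synthetic cusp
#' end-to-end: simulate + extrapolate + metrics). Every run writes a
#' `manifest.json` from which it can be reproduced byte-identically.
#'
#' @param cfg Configuration list (validated with [validate_config()]).
#' @param quiet Suppress progress messages.
#' @return List of artifact paths and key results, invisibly.
#' @export
run_config <- function(cfg, quiet = FALSE) {
  cfg <- validate_config(cfg)
  out_dir <- cfg$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_manifest(cfg, out_dir)
  say <- function(...) if (!quiet) message(...)
  res <- list(output_dir = out_dir)

  get_input <- function() {
    if (nzchar(cfg$input)) read_xy_contour(cfg$input) else config_shape(cfg)
  }

  if (cfg$mode == "shapes") {
    path <- file.path(out_dir, "shape.xy")
    write_xy_contour(config_shape(cfg), path)
    say("wrote ", path)
    res$contour <- path
  } else if (cfg$mode == "simulate" || cfg$mode == "demo") {
    edj <- get_input()
    params <- config_to_params(cfg)
    conv <- config_to_conversion(cfg)
    if (cfg$mode == "demo") {
      conv$node_density <- min(conv$node_density, 65L)
      params$n_iter <- min(params$n_iter, 60L)
    }
    hist <- run_simulation(edj, params, conv, config_to_bc(cfg),
                           braces = config_to_braces(cfg))
    fronts_to_csv(hist, file.path(out_dir, "fronts.csv"))
    meas <- history_measurements(hist)
    utils::write.csv(meas, file.path(out_dir, "area_perimeter.csv"),
                     row.names = FALSE)
    if (cfg$write_images)
      write_step_image(hist$state$mesh, hist$state$ls,
                       file.path(out_dir, "final.png"), u = hist$state$u)
    say(sprintf("simulate: %d steps, enamel area %.5g, stop: %s",
                max(hist$steps), hist$bookkeeping$enamel_area,
                hist$stop_reason))
    res$history <- hist
    if (cfg$mode == "demo") {
      meanth <- sqrt((hist$bookkeeping$final_area) / pi) -
        sqrt(hist$bookkeeping$initial_area / pi)
      off <- geometric_extrapolation(hist$edj, max(meanth, 2 * hist$mesh_h),
                                     node_density = conv$node_density)
      write_xy_contour(off, file.path(out_dir, "extrapolation.xy"))
      lm <- cusp_landmarks(hist$edj, cfg$n_ridges)
      ts <- thickness_profile(hist, lm)
      utils::write.csv(ts$summary, file.path(out_dir, "thickness.csv"),
                       row.names = FALSE)
      final_front <- hist$fronts[[length(hist$fronts)]][[1]]
      bc <- box_counting_dimension(
        rasterize_contour(final_front, side = min(cfg$image_side, 512L)),
        cfg$grid_origins, cfg$rotation_step)
      utils::write.csv(bc$estimates, file.path(out_dir, "boxcount.csv"),
                       row.names = FALSE)
      say(sprintf("demo: final front D_B = %.3f (sd %.3f), %d estimates",
                  bc$mean, bc$sd, nrow(bc$estimates)))
      res$boxcount <- bc
      res$thickness <- ts
    }
  } else if (cfg$mode == "extrapolate") {
    edj <- get_input()
    off <- geometric_extrapolation(edj, cfg$radius,
                                   node_density = cfg$node_density,
                                   fit = TRUE, border = cfg$border)
    write_xy_contour(off, file.path(out_dir, "extrapolation.xy"))
    say("extrapolate: offset radius ", cfg$radius)
    res$offset <- off
  } else if (cfg$mode == "stack") {
    if (!nzchar(cfg$input_dir)) stop("stack mode requires input_dir")
    files <- sort(list.files(cfg$input_dir, pattern = "\\.(xy|txt|csv)$",
                             full.names = TRUE))
    if (length(files) < 2) stop("stack mode needs >= 2 contour files")
    slices <- lapply(files, read_xy_contour)
    hists <- run_stack(slices, config_to_params(cfg),
                       config_to_conversion(cfg), config_to_bc(cfg),
                       braces = config_to_braces(cfg))
    finals <- lapply(hists, function(h) {
      fr <- h$fronts[[length(h$fronts)]]
      fr[[which.max(vapply(fr, function(p) abs(polygon_area(p)), numeric(1)))]]
    })
    stk <- stack_slices(finals, cfg$z_spacing)
    write_surface_obj(stk, file.path(out_dir, "front_stack.obj"))
    edj_stk <- stack_slices(lapply(hists, `[[`, "edj"), cfg$z_spacing)
    write_surface_obj(edj_stk, file.path(out_dir, "edj_stack.obj"))
    say("stack: ", length(hists), " slices -> front_stack.obj")
    res$histories <- hists
  } else if (cfg$mode == "boxcount") {
    poly <- get_input()
    bc <- box_counting_dimension(
      rasterize_contour(poly, side = cfg$image_side),
      cfg$grid_origins, cfg$rotation_step)
    utils::write.csv(bc$estimates, file.path(out_dir, "boxcount.csv"),
                     row.names = FALSE)
    say(sprintf("boxcount: mean D_B = %.4f (sd %.4f) over %d estimates",
                bc$mean, bc$sd, nrow(bc$estimates)))
    res$boxcount <- bc
  }
  invisible(res)
}
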