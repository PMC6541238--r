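#' Extract the occlusal relief portion of a recorded front
#'
#' From a set of front contours, takes the longest one and returns its
#' longest contiguous run of vertices inside the given window — the enamel
#' surface over the crown top, excluding the lateral walls and any brace
#' faces ("without the outer walls").
#'
#' @param fronts List of [contour_polyline()] (one recorded step).
#' @param y_min Keep vertices above this height.
#' @param x_range Keep vertices inside this x interval.
#' @return An open [contour_polyline()], or `NULL` if the window is empty.
#' @export
occlusal_relief <- function(fronts, y_min = 0.33, x_range = c(0.17, 0.83)) {
  if (!length(fronts)) return(NULL)
  lens <- vapply(fronts, contour_perimeter, numeric(1))
  v <- fronts[[which.max(lens)]]$vertices
  keep <- v[, 2] > y_min & v[, 1] > x_range[1] & v[, 1] < x_range[2]
  runs <- rle(keep)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  iz <- which(runs$values)
  if (!length(iz)) return(NULL)
  big <- iz[which.max(runs$lengths[iz])]
  if (runs$lengths[big] < 2) return(NULL)
  contour_polyline(v[starts[big]:ends[big], , drop = FALSE], closed = FALSE)
}

## reference wavy vertical EDJ and run geometry shared by the vertical
## (basal-sink) experiments
vertical_reference <- function(node_density = 129L) {
  list(
    profile = make_shape(shape_spec("vertical_profile", size = 0.45,
                                    waviness_wavelength = 0.18,
                                    waviness_amplitude = 0.05,
                                    noise_amplitude = 0.06, seed = 5L), 220L),
    conversion = conversion_spec(node_density, border = 0.18),
    bc = boundary_spec(base_y = 0.24),
    braces = list(c(0, 0.16, 0, 1), c(0.84, 1, 0, 1)),
    y_min = 0.33, x_range = c(0.17, 0.83))
}

#' Surface-complexity experiment across nutrient production levels
#'
#' Simulates one synthetic wavy vertical EDJ (with basal sink and lateral
#' braces) under strong, weak, and excess background nutrient production,
#' stops each run when the mean occlusal matrix thickness reaches a common
#' target, and box-counts the resulting enamel relief together with the EDJ
#' relief itself. Measured contours are resampled at twice the node spacing
#' before rasterization so that sub-grid extraction noise does not enter the
#' complexity estimate.
#'
#' @param production Background production levels, strongest diffusion
#'   limitation first.
#' @param node_density Mesh resolution.
#' @param target Mean occlusal thickness at which runs are compared.
#' @param n_iter_cap Per-run iteration caps (recycled).
#' @return Data frame with one row per production level plus one for the
#'   EDJ: `label`, `f`, `steps`, `thickness`, `D_B`, `D_B_sd`.
#' @export
complexity_experiment <- function(production = c(30, 75, 160),
                                  node_density = 129L, target = 0.045,
                                  n_iter_cap = c(300L, 160L, 100L)) {
  ref <- vertical_reference(node_density)
  n_iter_cap <- rep_len(n_iter_cap, length(production))
  rows <- list()
  edj <- NULL
  for (i in seq_along(production)) {
    f <- production[i]
    params <- growth_params(n_iter = n_iter_cap[i], f = f, record_every = 2L)
    h <- run_simulation(ref$profile, params, ref$conversion, ref$bc,
                        braces = ref$braces, on_boundary = "stop")
    edj <- h$edj
    sel <- NULL
    for (s in seq_along(h$steps)) {
      rel <- occlusal_relief(h$fronts[[s]], ref$y_min, ref$x_range)
      if (is.null(rel) || nrow(rel$vertices) < 20) next
      d <- dist_to_polylines(rel$vertices[, 1], rel$vertices[, 2], h$edj)
      if (mean(d) >= target) {
        sel <- list(rel = rel, step = h$steps[s], thick = mean(d))
        break
      }
    }
    if (is.null(sel)) { # compare at the furthest state this run reached
      rel <- occlusal_relief(h$fronts[[length(h$fronts)]], ref$y_min,
                             ref$x_range)
      d <- dist_to_polylines(rel$vertices[, 1], rel$vertices[, 2], h$edj)
      sel <- list(rel = rel, step = max(h$steps), thick = mean(d))
    }
    rel <- resample_contour(sel$rel, 2 * h$mesh_h)
    bcnt <- box_counting_dimension(rasterize_contour(rel, 1024L))
    rows[[i]] <- data.frame(label = paste0("f", f), f = f, steps = sel$step,
                            thickness = sel$thick, D_B = bcnt$mean,
                            D_B_sd = bcnt$sd)
  }
  ev <- resample_contour(edj, 2 / (node_density - 1))$vertices
  keep <- ev[, 2] > ref$y_min - 0.07 & ev[, 1] > ref$x_range[1] &
    ev[, 1] < ref$x_range[2]
  erel <- contour_polyline(ev[keep, , drop = FALSE], closed = FALSE)
  bcnt <- box_counting_dimension(rasterize_contour(erel, 1024L))
  rows[[length(rows) + 1L]] <- data.frame(label = "edj", f = NA, steps = 0L,
                                          thickness = 0, D_B = bcnt$mean,
                                          D_B_sd = bcnt$sd)
  do.call(rbind, rows)
}

#' Basal-sink thickness gradient experiment
#'
#' Runs a vertical simulation with the basal nutrient sink and summarizes
#' mean matrix thickness along the crown by height bins; with the sink
#' active, mean thickness should fall from the cusp tip toward the base.
#'
#' @param node_density Mesh resolution.
#' @param n_iter Iterations.
#' @param f Background production.
#' @param n_bins Height bins.
#' @return List: `bins` (data frame `height`, `thickness`), `spearman`
#'   (rank correlation of bin mean thickness with height).
#' @export
basal_sink_experiment <- function(node_density = 129L, n_iter = 120L, f = 30,
                                  n_bins = 8L) {
  prof <- make_shape(shape_spec("vertical_profile", size = 0.45,
                                waviness_wavelength = 0.22,
                                waviness_amplitude = 0.015, seed = 3L), 160L)
  conv <- conversion_spec(node_density, border = 0.12)
  bc <- boundary_spec(base_y = 0.2)
  h <- run_simulation(prof, growth_params(n_iter = n_iter, f = f), conv, bc)
  fr <- h$fronts[[length(h$fronts)]]
  frv <- do.call(rbind, lapply(fr, `[[`, "vertices"))
  frv <- frv[frv[, 2] > bc$base_y + 2 * h$mesh_h, , drop = FALSE]
  ev <- h$edj$vertices
  evr <- ev[ev[, 2] > conv$border + 0.01, , drop = FALSE]
  relief <- contour_polyline(evr, closed = FALSE)
  d <- dist_to_polylines(frv[, 1], frv[, 2], relief)
  near_y <- vapply(seq_len(nrow(frv)), function(i)
    evr[which.min((evr[, 1] - frv[i, 1])^2 + (evr[, 2] - frv[i, 2])^2), 2],
    numeric(1))
  bins <- cut(near_y, breaks = seq(min(near_y), max(near_y),
                                   length.out = n_bins + 1L))
  bm <- tapply(d, bins, mean)
  bh <- tapply(near_y, bins, mean)
  ok <- !is.na(bm)
  list(bins = data.frame(height = as.numeric(bh[ok]),
                         thickness = as.numeric(bm[ok])),
       spearman = stats::cor(bm[ok], bh[ok], method = "spearman"),
       history = h)
}
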