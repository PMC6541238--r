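# shared small fixtures; everything is generated in code

unit_circle_contour <- function(r = 0.25, n = 96, center = c(0.5, 0.5)) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  contour_polyline(cbind(center[1] + r * cos(th), center[2] + r * sin(th)),
                   closed = TRUE)
}

# level set for a circle without going through contour_to_levelset
circle_levelset <- function(mesh, r = 0.25, center = c(0.5, 0.5)) {
  phi <- sqrt((mesh$x - center[1])^2 + (mesh$y - center[2])^2) - r
  structure(list(phi = phi, obstacle = rep(FALSE, mesh$n_nodes),
                 polygons = list(), contour = unit_circle_contour(r, 128, center),
                 transform = list(scale = 1, offset = c(0, 0))),
            class = "level_set")
}

all_exterior_levelset <- function(mesh) {
  structure(list(phi = rep(1, mesh$n_nodes),
                 obstacle = rep(FALSE, mesh$n_nodes), polygons = list()),
            class = "level_set")
}

# independent scalar point-to-segment distance (oracle; no vectorization,
# different formulation than the package's)
oracle_dist_to_polyline <- function(px, py, poly) {
  v <- poly$vertices
  m <- nrow(v)
  idx <- if (poly$closed) rbind(seq_len(m), c(2:m, 1)) else
    rbind(seq_len(m - 1), 2:m)
  best <- Inf
  for (e in seq_len(ncol(idx))) {
    a <- v[idx[1, e], ]; b <- v[idx[2, e], ]
    ab <- b - a
    t <- sum((c(px, py) - a) * ab) / sum(ab * ab)
    t <- min(1, max(0, t))
    q <- a + t * ab
    best <- min(best, sqrt((px - q[1])^2 + (py - q[2])^2))
  }
  best
}

fast_params <- function(...) growth_params(n_iter = 10L, ...)
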