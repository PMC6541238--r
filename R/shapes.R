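#' Synthetic EDJ shape specification
#'
#' Describes a synthetic enamel-dentine-junction (EDJ) geometry used as the
#' initial solid boundary of a simulation. Two families emulate real sections:
#' closed cusp cross-sections with convex ridges and concave valleys
#' (pig-molar-like horizontal slices), and open low-relief wavy vertical
#' profiles sitting on a crown base (human-like longitudinal sections).
#'
#' @param kind One of `"cusp_section"`, `"vertical_profile"`, `"circle"`,
#'   `"square"`, `"koch_curve"`.
#' @param size Dimensionless base radius (closed kinds) or half-width
#'   (vertical profiles).
#' @param n_ridges Integer count of convex lobes (cusp sections).
#' @param ridge_amplitude Lobe amplitude as a fraction of `size` (>= 0, < 1).
#' @param concavity_amplitude Amplitude of localized Gaussian-bump concavities
#'   carved between lobes, as a fraction of `size` (>= 0, < 1).
#' @param waviness_wavelength,waviness_amplitude Wavelength and amplitude of
#'   the sinusoidal relief of a vertical profile (domain units).
#' @param noise_amplitude Amplitude of seeded band-limited smooth noise, as a
#'   fraction of `size`.
#' @param seed Integer seed for the noise; the same spec always yields the
#'   same vertices.
#' @return An object of class `shape_spec`.
#' @seealso [make_shape()], [make_koch_contour()]
#' @export
shape_spec <- function(kind = c("cusp_section", "vertical_profile", "circle",
                                "square", "koch_curve"),
                       size = 0.3, n_ridges = 4L,
                       ridge_amplitude = 0, concavity_amplitude = 0,
                       waviness_wavelength = 0.25, waviness_amplitude = 0.02,
                       noise_amplitude = 0, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(size > 0, n_ridges >= 1)
  if (ridge_amplitude < 0 || concavity_amplitude < 0 || noise_amplitude < 0)
    stop("amplitudes must be >= 0")
  if (ridge_amplitude >= 1 || concavity_amplitude >= 1 || noise_amplitude >= 1)
    stop("amplitudes must be < 1 (fractions of the base size)")
  structure(list(kind = kind, size = size, n_ridges = as.integer(n_ridges),
                 ridge_amplitude = ridge_amplitude,
                 concavity_amplitude = concavity_amplitude,
                 waviness_wavelength = waviness_wavelength,
                 waviness_amplitude = waviness_amplitude,
                 noise_amplitude = noise_amplitude, seed = as.integer(seed)),
            class = "shape_spec")
}

## Band-limited periodic noise: sum of a few low-order harmonics with seeded
## coefficients. Smoothness matters: per-vertex white noise would inject
## sub-mesh roughness that confounds the interfacial-tension term.
smooth_noise <- function(t, seed, n_harmonics = 6L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(seed)
  amp <- stats::rnorm(n_harmonics) / seq_len(n_harmonics)
  ph <- stats::runif(n_harmonics, 0, 2 * pi)
  z <- numeric(length(t))
  for (k in seq_len(n_harmonics))
    z <- z + amp[k] * cos(2 * pi * k * t + ph[k])
  z / sqrt(sum((amp / sqrt(2))^2)) # unit RMS
}

#' Generate a synthetic EDJ contour
#'
#' Cusp sections use the radius function
#' `r(theta) = size * (1 + ridge_amplitude * cos(n_ridges * theta))` minus
#' localized Gaussian concavity bumps centered between the lobes, optionally
#' perturbed by seeded smooth noise. Vertical profiles are open sinusoidal
#' reliefs whose two endpoints lie on the domain base line (y = 0 in shape
#' coordinates).
#'
#' @param spec A [shape_spec()].
#' @param n_vertices Number of vertices (>= 8).
#' @return A [contour_polyline()]; closed for all kinds except
#'   `"vertical_profile"`.
#' @examples
#' cusp <- make_shape(shape_spec("cusp_section", ridge_amplitude = 0.2), 128)
#' range(sqrt(rowSums(cusp$vertices^2)))
#' @export
make_shape <- function(spec, n_vertices = 128L) {
  stopifnot(inherits(spec, "shape_spec"), n_vertices >= 8)
  n <- as.integer(n_vertices)
  out <- switch(spec$kind,
    circle = {
      th <- 2 * pi * (seq_len(n) - 1L) / n
      cbind(spec$size * cos(th), spec$size * sin(th))
    },
    square = {
      s <- spec$size
      per <- seq(0, 1, length.out = n + 1L)[-(n + 1L)]
      t4 <- per * 4
      side <- pmin(floor(t4), 3)
      f <- t4 - side
      x <- ifelse(side == 0, -s + 2 * s * f,
           ifelse(side == 1, s,
           ifelse(side == 2, s - 2 * s * f, -s)))
      y <- ifelse(side == 0, -s,
           ifelse(side == 1, -s + 2 * s * f,
           ifelse(side == 2, s, s - 2 * s * f)))
      cbind(x, y)
    },
    cusp_section = {
      th <- 2 * pi * (seq_len(n) - 1L) / n
      r <- spec$size * (1 + spec$ridge_amplitude * cos(spec$n_ridges * th))
      if (spec$concavity_amplitude > 0) {
        # Gaussian notches centered midway between lobes
        centers <- (2 * pi * (seq_len(spec$n_ridges) - 0.5)) / spec$n_ridges
        w <- pi / (4 * spec$n_ridges)
        for (c0 in centers) {
          d <- atan2(sin(th - c0), cos(th - c0)) # wrapped angular distance
          r <- r - spec$size * spec$concavity_amplitude * exp(-(d / w)^2 / 2)
        }
      }
      if (spec$noise_amplitude > 0)
        r <- r + spec$size * spec$noise_amplitude *
          smooth_noise(th / (2 * pi), spec$seed)
      if (any(r <= 0))
        stop("self-intersecting parameter combination: radius function ",
             "becomes non-positive (reduce amplitudes)")
      cbind(r * cos(th), r * sin(th))
    },
    vertical_profile = {
      x <- seq(-spec$size, spec$size, length.out = n)
      y <- rep(0.65 * spec$size, n)
      y <- y + spec$waviness_amplitude *
        sin(2 * pi * x / spec$waviness_wavelength)
      if (spec$noise_amplitude > 0)
        y <- y + spec$size * spec$noise_amplitude *
          smooth_noise((x + spec$size) / (2 * spec$size), spec$seed)
      # crown-like silhouette: steep lateral walls, low-relief occlusal top,
      # endpoints on the base line
      taper <- sin(pi * (x + spec$size) / (2 * spec$size))^0.5
      y <- y * taper
      cbind(x, pmax(y, 0))
    },
    koch_curve = {
      k <- make_koch_contour(level = 3L, size = spec$size)
      return(k)
    })
  poly <- contour_polyline(out, closed = spec$kind != "vertical_profile",
                           units = "domain")
  if (poly$closed) poly <- orient_ccw(poly)
  if (is_self_intersecting(poly))
    stop("self-intersecting parameter combination for shape '", spec$kind, "'")
  poly
}

#' Koch snowflake boundary
#'
#' Closed-form fractal contour used as an oracle for the box-counting
#' dimension estimator: its similarity dimension is log(4)/log(3) ~= 1.2619
#' and its level-k perimeter is `3 * size * (4/3)^k` exactly.
#'
#' @param level Recursion level, 0..7. Level 0 is an equilateral triangle.
#' @param size Side length of the base triangle.
#' @return A closed [contour_polyline()] with `3 * 4^level` segments.
#' @export
make_koch_contour <- function(level = 4L, size = 1) {
  stopifnot(level >= 0, level <= 7, size > 0)
  # equilateral triangle, counter-clockwise, centered at origin
  th <- pi / 2 + 2 * pi * (0:2) / 3
  r <- size / sqrt(3)
  pts <- cbind(r * cos(th), r * sin(th))
  for (i in seq_len(level)) {
    m <- nrow(pts)
    a <- pts
    b <- pts[c(2:m, 1L), , drop = FALSE]
    d <- b - a
    p1 <- a + d / 3
    p2 <- a + 2 * d / 3
    # outward apex: rotate (p2 - p1) by -60 degrees (outward for a CCW polygon)
    rot <- cbind(c(cos(-pi / 3), sin(-pi / 3)), c(-sin(-pi / 3), cos(-pi / 3)))
    apex <- p1 + t(rot %*% t(p2 - p1))
    new_pts <- matrix(0, 4L * m, 2L)
    new_pts[seq(1L, 4L * m, by = 4L), ] <- a
    new_pts[seq(2L, 4L * m, by = 4L), ] <- p1
    new_pts[seq(3L, 4L * m, by = 4L), ] <- apex
    new_pts[seq(4L, 4L * m, by = 4L), ] <- p2
    pts <- new_pts
  }
  orient_ccw(contour_polyline(pts, closed = TRUE, units = "domain"))
}
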