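test_that("disk dilation of a disk is a disk of summed radius", {
  circ <- unit_circle_contour(r = 0.15, n = 128)
  off <- geometric_extrapolation(circ, 0.1, node_density = 257)
  r <- sqrt(rowSums(sweep(off$vertices, 2, c(0.5, 0.5))^2))
  expect_lt(max(abs(r - 0.25)), 1 / 256) # within one grid pixel
  expect_error(geometric_extrapolation(circ, 0.45, node_density = 129),
               "exits the domain")
  expect_error(geometric_extrapolation(circ, -1), "radius")
})

test_that("offset equals every-output-vertex-at-distance-d (offset property)", {
  set.seed(3)
  for (seed in c(1, 2, 5)) {
    poly <- make_shape(shape_spec("cusp_section", size = 0.28,
                                  ridge_amplitude = 0.15, n_ridges = 3,
                                  noise_amplitude = 0.05, seed = seed), 96)
    poly$vertices <- poly$vertices + 0.5
    d <- 0.06
    off <- geometric_extrapolation(poly, d, node_density = 257)
    dist <- dist_to_polylines(off$vertices[, 1], off$vertices[, 2], poly)
    # distance from output back to the EDJ equals d (within grid resolution)
    expect_lt(max(abs(dist - d)), 1.5 / 256)
  }
})

test_that("dilation is monotone in radius", {
  poly <- make_shape(shape_spec("cusp_section", size = 0.28,
                                ridge_amplitude = 0.2, n_ridges = 4), 96)
  poly$vertices <- poly$vertices + 0.5
  off1 <- geometric_extrapolation(poly, 0.04, node_density = 129)
  off2 <- geometric_extrapolation(poly, 0.09, node_density = 129)
  # every vertex of the smaller offset lies inside the larger offset region
  inside <- enamelsim:::point_in_polygon(off1$vertices[, 1],
                                         off1$vertices[, 2], off2)
  expect_true(all(inside))
})

test_that("narrow fissures are filled in by the dilation", {
  # deep narrow notch: mouth much narrower than twice the radius
  poly <- make_shape(shape_spec("cusp_section", size = 0.28,
                                ridge_amplitude = 0.08,
                                concavity_amplitude = 0.6, n_ridges = 2), 256)
  poly$vertices <- poly$vertices + 0.5
  d <- 0.1
  off <- geometric_extrapolation(poly, d, node_density = 257)
  # notch centers lie between the lobes at angles pi/4-ish: take the deepest
  # EDJ point toward each notch; after dilation it must be interior
  th <- atan2(poly$vertices[, 2] - 0.5, poly$vertices[, 1] - 0.5)
  r <- sqrt(rowSums(sweep(poly$vertices, 2, c(0.5, 0.5))^2))
  notch_idx <- which.min(r)
  notch_pt <- poly$vertices[notch_idx, ]
  expect_true(enamelsim:::point_in_polygon(notch_pt[1], notch_pt[2], off))
  # and the offset contour is simple (the fissure seam is resolved)
  expect_false(enamelsim:::is_self_intersecting(off))
})

test_that("extrapolation history mimics a front history for measurements", {
  circ <- unit_circle_contour(r = 0.15, n = 128)
  hist <- extrapolation_history(circ, c(0.03, 0.06, 0.09), node_density = 129)
  lm <- cusp_landmarks(circ, 4)
  ts <- thickness_profile(hist, lm)
  # uniform thickness: ridge and valley labels agree at every step
  for (s in seq_along(hist$steps)) {
    m <- ts$summary[ts$summary$step == hist$steps[s], ]
    expect_equal(m$mean[1], m$mean[2], tolerance = 1 / 128)
    expect_equal(m$mean[1], hist$radii[s], tolerance = 1.5 / 128)
  }
  expect_error(extrapolation_history(circ, c(0.05, 0.02)), "increasing")
})
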