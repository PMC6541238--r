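test_that("enamel area and perimeter match analytic slices", {
  sq <- contour_polyline(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  ap <- area_perimeter(sq)
  expect_equal(unname(ap["area"]), 1)
  expect_equal(unname(ap["perimeter"]), 4)

  front <- unit_circle_contour(0.3, 256)
  edj <- unit_circle_contour(0.2, 256)
  ap <- area_perimeter(front, edj)
  expect_equal(unname(ap["area"]), pi * (0.09 - 0.04), tolerance = 0.01)
  expect_equal(unname(area_perimeter(front, front)["area"]), 0,
               tolerance = 1e-12)
  expect_error(area_perimeter(edj, front), "not contained")
})

test_that("box counting returns 12 x 10 estimates and unit dimension lines", {
  # horizontal line segment
  img <- matrix(FALSE, 256, 256)
  img[20:230, 128] <- TRUE
  bc <- box_counting_dimension(img)
  expect_equal(nrow(bc$estimates), 120)
  expect_gte(bc$mean, 0.95)
  expect_lte(bc$mean, 1.05)
  expect_true(all(table(bc$estimates$origin) == 10))
  expect_true(all(table(bc$estimates$rotation) == 12))
  expect_error(box_counting_dimension(matrix(FALSE, 256, 256)), "empty")
  expect_error(box_counting_dimension(matrix(TRUE, 32, 32)), "box sizes")
})

test_that("rasterized smooth closed contours have near-unit dimension", {
  circ <- unit_circle_contour(0.3, 512)
  bc <- box_counting_dimension(rasterize_contour(circ, 512))
  expect_lt(abs(bc$mean - 1), 0.08)
})

test_that("thickness profile errors on anchors off the EDJ and handles
           missing intersections as absent", {
  circ <- unit_circle_contour(0.2, 128)
  hist <- extrapolation_history(circ, c(0.05), node_density = 129)
  bad <- data.frame(label = "ridge", ax = 0.95, ay = 0.95, dx = 1, dy = 0)
  expect_error(thickness_profile(hist, bad), "not anchored")
  # a ray pointing inward never crosses the offset front: value is NA
  lm <- data.frame(label = c("ridge", "valley"),
                   ax = c(0.7, 0.5), ay = c(0.5, 0.7),
                   dx = c(-1, 0), dy = c(0, 1))
  ts <- thickness_profile(hist, lm)
  expect_equal(unname(ts$thickness[1, 2]), 0.05, tolerance = 1.5 / 128)
})

test_that("stacked identical circles form a cylinder of known lateral area", {
  circ <- unit_circle_contour(0.3, 128)
  stk <- stack_slices(list(circ, circ), z_spacing = 0.1)
  tri_area <- function(stk) {
    V <- stk$vertices; F <- stk$faces
    a <- V[F[, 2], ] - V[F[, 1], ]; b <- V[F[, 3], ] - V[F[, 1], ]
    cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                a[, 1] * b[, 2] - a[, 2] * b[, 1])
    sum(sqrt(rowSums(cr^2))) / 2
  }
  expect_equal(tri_area(stk), 2 * pi * 0.3 * 0.1, tolerance = 0.02)
  open_slice <- contour_polyline(cbind(0:4 / 4, 0), closed = FALSE)
  expect_error(stack_slices(list(circ, open_slice), 0.1), "mixed")
})

test_that("surface distance summaries match concentric-circle analytics", {
  a <- unit_circle_contour(0.2, 256)
  b <- unit_circle_contour(0.3, 256)
  ds <- surface_distance(a, b)
  expect_equal(unname(ds$a_to_b["mean"]), 0.1, tolerance = 0.003)
  expect_equal(ds$hausdorff, 0.1, tolerance = 0.003)
  expect_lte(ds$a_to_b["max"], ds$hausdorff + 1e-12)
  same <- surface_distance(a, a)
  expect_lt(same$hausdorff, 1e-9)
  # 3D: two coaxial cylinders
  sa <- stack_slices(list(a, a), z_spacing = 0.05)
  sb <- stack_slices(list(b, b), z_spacing = 0.05)
  d3 <- surface_distance(sa, sb)
  expect_equal(unname(d3$a_to_b["mean"]), 0.1, tolerance = 0.01)
  expect_error(surface_distance(a, sa), "dimensionality")
})

test_that("occlusal relief extraction windows the longest front", {
  # synthetic: one long open front plus a sliver
  long <- contour_polyline(cbind(seq(0, 1, length.out = 100),
                                 0.5 + 0.05 * sin(8 * seq(0, 1, length.out = 100))),
                           closed = FALSE)
  sliver <- contour_polyline(rbind(c(0.4, 0.1), c(0.42, 0.1), c(0.41, 0.12)))
  rel <- occlusal_relief(list(sliver, long), y_min = 0.3,
                         x_range = c(0.2, 0.8))
  expect_false(rel$closed)
  expect_true(all(rel$vertices[, 1] > 0.2 & rel$vertices[, 1] < 0.8))
  expect_true(all(rel$vertices[, 2] > 0.3))
  expect_null(occlusal_relief(list(sliver), y_min = 0.5))
})
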