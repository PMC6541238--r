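test_that("XY contour files round-trip and infer closure", {
  path <- withr::local_tempfile(fileext = ".xy")
  writeLines(c("0 0", "1 0", "1 1", "0 1"), path)
  sq <- read_xy_contour(path, closed = TRUE)
  expect_equal(nrow(sq$vertices), 4)
  expect_identical(sq$units, "pixel")

  # round trip preserves the vertex list
  circ <- make_shape(shape_spec("circle", size = 0.3), 48)
  p2 <- withr::local_tempfile(fileext = ".xy")
  write_xy_contour(circ, p2)
  back <- read_xy_contour(p2, closed = TRUE)
  expect_equal(back$vertices, circ$vertices, tolerance = 1e-9)

  # closure inferred when first == last
  writeLines(c("0 0", "2 0", "1 2", "0 0"), path)
  expect_true(read_xy_contour(path)$closed)
})

test_that("malformed files produce located parse errors", {
  path <- withr::local_tempfile(fileext = ".xy")
  writeLines(c("0 0", "a b", "1 1", "0 1"), path)
  expect_error(read_xy_contour(path), "line 2")
  writeLines(c("0 0", "1 1"), path)
  expect_error(read_xy_contour(path), "fewer than 3")
  writeLines(c("0,0", "1,\t0", "1 1", "0 1"), path) # mixed delimiters accepted
  expect_equal(nrow(read_xy_contour(path, closed = TRUE)$vertices), 4)
})

test_that("arc-length resampling matches the partition oracle", {
  sq <- contour_polyline(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))
  out <- resample_contour(sq, 10) # perimeter 40, interval 10
  expect_equal(nrow(out$vertices), 4)
  # interval = L / n gives exactly n vertices for closed input
  circ <- unit_circle_contour(r = 1, n = 50, center = c(0, 0))
  L <- contour_perimeter(circ)
  for (n in c(12, 33, 64))
    expect_equal(nrow(resample_contour(circ, L / n)$vertices), n)
  # resampling twice at the same interval keeps the vertex count
  once <- resample_contour(circ, L / 40)
  twice <- resample_contour(once, L / 40)
  expect_equal(nrow(twice$vertices), nrow(once$vertices))
  # vertices are equally spaced
  seg <- sqrt(rowSums(diff(rbind(once$vertices, once$vertices[1, ]))^2))
  expect_lt(diff(range(seg)) / mean(seg), 0.01) # chords of equal arc steps
  expect_error(resample_contour(sq, 20), "interval")
})

test_that("level-set conversion equals the point-to-segment distance oracle", {
  mesh <- build_mesh(33)
  s <- 0.4
  sq <- contour_polyline(0.5 + rbind(c(-s / 2, -s / 2), c(s / 2, -s / 2),
                                     c(s / 2, s / 2), c(-s / 2, s / 2)))
  ls <- contour_to_levelset(sq, conversion_spec(33), mesh, fit = FALSE)
  # center node: distance to the nearest side
  center <- which(abs(mesh$x - 0.5) < 1e-9 & abs(mesh$y - 0.5) < 1e-9)
  expect_equal(ls$phi[center], -s / 2, tolerance = 1e-12)
  # every node agrees with an independent scalar oracle to 1e-9
  idx <- seq(1, mesh$n_nodes, by = 37)
  for (i in idx) {
    d <- oracle_dist_to_polyline(mesh$x[i], mesh$y[i], sq)
    expect_equal(abs(ls$phi[i]), d, tolerance = 1e-9)
  }
  # sign convention: deep interior negative, exterior positive
  expect_true(all(ls$phi[(mesh$x - 0.5)^2 + (mesh$y - 0.5)^2 > 0.16] > 0))
  expect_lt(ls$phi[center], 0)
})

test_that("registration triangles are obstacles clear of the EDJ", {
  mesh <- build_mesh(65)
  circ <- make_shape(shape_spec("circle", size = 0.3), 96)
  spec <- conversion_spec(65, border = 0.25, registration_triangles = TRUE,
                          triangle_size = 0.1)
  ls <- contour_to_levelset(circ, spec, mesh)
  expect_length(ls$polygons, 2)
  expect_gt(sum(ls$obstacle), 0)
  # triangle_size <= border / 2 keeps the triangles off the scaled EDJ
  d <- dist_to_polylines(mesh$x[ls$obstacle], mesh$y[ls$obstacle], ls$contour)
  expect_gt(min(d), 0.02)
  # obstacle nodes are part of the solid phase
  expect_true(all(ls$phi[ls$obstacle] <= 0))
})

test_that("open profiles are closed along the base line before conversion", {
  mesh <- build_mesh(65)
  prof <- make_shape(shape_spec("vertical_profile", size = 0.4,
                                waviness_amplitude = 0.02), 80)
  ls <- contour_to_levelset(prof, conversion_spec(65, border = 0.2), mesh)
  expect_true(ls$contour$closed)
  expect_gt(sum(ls$phi < 0), 0)
  expect_equal(min(ls$contour$vertices[, 2]), 0.2, tolerance = 1e-9)
})

test_that("step images are deterministic with the expected solid fraction", {
  mesh <- build_mesh(65)
  # solid lower half-plane
  ls <- all_exterior_levelset(mesh)
  ls$phi <- mesh$y - 0.5
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  write_step_image(mesh, ls, p1)
  write_step_image(mesh, ls, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  img <- png::readPNG(p1)
  solid_frac <- mean(img[, , 1] < 0.9)
  expect_equal(solid_frac, 0.5, tolerance = 0.02)
  # empty solid region renders uniform background
  ls$phi <- rep(1, mesh$n_nodes)
  write_step_image(mesh, ls, p1)
  img <- png::readPNG(p1)
  expect_equal(length(unique(as.vector(img))), 1)
})

test_that("OBJ export triangulates slice pairs and round-trips counts", {
  sq <- contour_polyline(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  stk <- stack_slices(list(sq, sq), z_spacing = 1, n_vertices = 4)
  expect_equal(nrow(stk$vertices), 8)
  expect_equal(nrow(stk$faces), 8)
  path <- withr::local_tempfile(fileext = ".obj")
  write_surface_obj(stk, path)
  lines <- readLines(path)
  expect_equal(sum(startsWith(lines, "v ")), 8)
  expect_equal(sum(startsWith(lines, "f ")), 8)
  expect_error(stack_slices(list(sq), 1), ">= 2 slices")
})
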