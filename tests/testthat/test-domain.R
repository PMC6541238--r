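test_that("structured mesh has the expected node, triangle and area counts", {
  m3 <- build_mesh(3, fem = FALSE, strict = FALSE)
  expect_equal(m3$n_nodes, 9)
  expect_equal(nrow(m3$triangles), 8)
  mesh <- build_mesh(17)
  expect_equal(mesh$n_nodes, 17^2)
  # all triangle areas equal h^2 / 2
  tri <- mesh$triangles
  x <- mesh$x; y <- mesh$y
  areas <- abs((x[tri[, 2]] - x[tri[, 1]]) * (y[tri[, 3]] - y[tri[, 1]]) -
               (x[tri[, 3]] - x[tri[, 1]]) * (y[tri[, 2]] - y[tri[, 1]])) / 2
  expect_equal(areas, rep(mesh$h^2 / 2, nrow(tri)), tolerance = 1e-12)
  # stiffness of a linear function is in its kernel up to boundary terms:
  # K %*% 1 == 0 exactly (conservation)
  expect_lt(max(abs(mesh$K %*% rep(1, mesh$n_nodes))), 1e-12)
})

test_that("reinitialization is a near-fixed-point on exact distances and
           restores distorted fields", {
  mesh <- build_mesh(65)
  phi0 <- sqrt((mesh$x - 0.5)^2 + (mesh$y - 0.5)^2) - 0.25
  for (method in c("pde", "contour")) {
    out <- reinitialize(mesh, phi0, method = method)
    near <- abs(phi0) < 3 * mesh$h
    expect_lt(max(abs(out - phi0)[near]), mesh$h / 10)
    # doubling the field must come back to the true distance near the front
    out2 <- reinitialize(mesh, 2 * phi0, method = method)
    expect_lt(max(abs(out2 - phi0)[near]), mesh$h / 5)
  }
  expect_error(reinitialize(mesh, rep(1, mesh$n_nodes)), "single-sign")
})

test_that("reinitialization moves the zero contour by at most h/2", {
  mesh <- build_mesh(65)
  # smooth seeded field with both signs
  set.seed(42)
  phi <- sqrt((mesh$x - 0.5)^2 + (mesh$y - 0.5)^2) - 0.25
  phi <- phi * (1 + 0.3 * sin(7 * mesh$x) * cos(5 * mesh$y)) + 0.02
  before <- extract_interface(mesh, phi)
  after <- extract_interface(mesh, reinitialize(mesh, phi, method = "pde"))
  pa <- do.call(rbind, lapply(before, `[[`, "vertices"))
  d <- dist_to_polylines(pa[, 1], pa[, 2], after)
  expect_lt(max(d), mesh$h / 2)
  # signed-distance property near the interface
  out <- reinitialize(mesh, phi, method = "pde")
  n <- mesh$n
  P <- matrix(out, n, n)
  gx <- (P[c(2:n, n), ] - P[c(1, 1:(n - 1)), ]) / (2 * mesh$h)
  gy <- (P[, c(2:n, n)] - P[, c(1, 1:(n - 1))]) / (2 * mesh$h)
  g <- sqrt(gx^2 + gy^2)
  near <- abs(out) < 3 * mesh$h
  expect_lt(max(abs(g[matrix(near, n, n)] - 1)), 0.1)
})

test_that("curvature matches the analytic circle and flags flat interfaces", {
  mesh <- build_mesh(129)
  ls <- circle_levelset(mesh, r = 0.25)
  kap <- curvature(mesh, ls)
  near <- abs(ls$phi) < mesh$h
  expect_equal(mean(kap[near]), 4, tolerance = 0.05)
  # straight interface: curvature ~ 0
  flat <- mesh$y - 0.5
  kf <- curvature(mesh, flat)
  expect_lt(max(abs(kf[abs(flat) < mesh$h])), 0.05 / mesh$h)
  # sign flips between ridge tip and valley bottom of a 4-lobe cusp
  cusp <- make_shape(shape_spec("cusp_section", size = 0.3,
                                ridge_amplitude = 0.2, n_ridges = 4), 128)
  lsc <- contour_to_levelset(cusp, conversion_spec(129, border = 0.3), mesh)
  kc <- curvature(mesh, lsc)
  ridge_pt <- which.min(abs(mesh$x - 0.85) + abs(mesh$y - 0.5))
  valley_dir <- c(cos(pi / 4), sin(pi / 4))
  rv <- 0.5 + valley_dir * 0.24 * lsc$transform$scale / 0.3 * 0.3
  # locate interface-adjacent nodes along the ridge and valley directions
  near <- which(abs(lsc$phi) < mesh$h)
  ang <- atan2(mesh$y[near] - 0.5, mesh$x[near] - 0.5)
  ridge_nodes <- near[abs(ang) < 0.15]
  valley_nodes <- near[abs(ang - pi / 4) < 0.15]
  expect_gt(mean(kc[ridge_nodes]), 0)
  expect_lt(mean(kc[valley_nodes]), 0)
})

test_that("advection grows a circle at the prescribed normal speed", {
  mesh <- build_mesh(65)
  ls <- circle_levelset(mesh, r = 0.2)
  expect_identical(advect(mesh, ls, rep(0, mesh$n_nodes), 0.1)$phi, ls$phi)
  out <- advect(mesh, ls, rep(0.5, mesh$n_nodes), 0.2)
  ci <- extract_interface(mesh, out)
  r <- sqrt(rowSums(sweep(ci[[1]]$vertices, 2, c(0.5, 0.5))^2))
  expect_equal(mean(r), 0.3, tolerance = 2 * mesh$h / 0.3)
  # nonnegative speed implies pointwise non-increasing phi (monotone growth)
  expect_true(all(out$phi <= ls$phi + 1e-12))
  expect_error(advect(mesh, ls, rep(NaN, mesh$n_nodes), 0.1), "NaN")
})

test_that("interface extraction recovers geometry within grid resolution", {
  mesh <- build_mesh(65)
  ls <- circle_levelset(mesh, r = 0.25)
  ci <- extract_interface(mesh, ls)
  expect_length(ci, 1)
  expect_true(ci[[1]]$closed)
  r <- sqrt(rowSums(sweep(ci[[1]]$vertices, 2, c(0.5, 0.5))^2))
  expect_lt(max(abs(r - 0.25)), mesh$h)
  expect_identical(extract_interface(mesh, rep(1, mesh$n_nodes)), list())
  # square solid: perimeter within 5%
  s <- 0.5
  sq <- contour_polyline(0.5 + rbind(c(-s / 2, -s / 2), c(s / 2, -s / 2),
                                     c(s / 2, s / 2), c(-s / 2, s / 2)))
  lsq <- contour_to_levelset(sq, conversion_spec(65), mesh, fit = FALSE)
  csq <- extract_interface(mesh, lsq)
  expect_equal(contour_perimeter(csq[[1]]), 4 * s, tolerance = 0.05)
  # conversion -> extraction round trip within Hausdorff h
  circ <- unit_circle_contour(0.25, 128)
  lsc <- contour_to_levelset(circ, conversion_spec(65), mesh, fit = FALSE)
  cc <- extract_interface(mesh, lsc)
  ds <- surface_distance(cc[[1]], circ)
  expect_lt(ds$hausdorff, mesh$h)
})

test_that("solid area is sub-cell accurate", {
  mesh <- build_mesh(65)
  ls <- circle_levelset(mesh, r = 0.25)
  expect_equal(solid_area(mesh, ls), pi * 0.25^2, tolerance = 0.002)
  expect_equal(solid_area(mesh, mesh$y - 0.5), 0.5, tolerance = 1e-6)
})
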