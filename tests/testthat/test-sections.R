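test_that("slicing a cylinder yields the analytic disc", {
  fx <- fx_cyl70()
  sec <- slice_mesh(fx$mesh, c(0, 0, 35), c(0, 0, 1))
  expect_s3_class(sec, "closed_contour")
  expect_equal(sec$area, pi * 9, tolerance = 0.01)
  # counterclockwise about the normal
  expect_gt(polygon_area_2d(sec$polygon2d), 0)
  expect_error(slice_mesh(fx$mesh, c(0, 0, 200), c(0, 0, 1)),
               "open contour")
})

test_that("the seed point selects the correct loop near a junction", {
  fx <- fx_branched(90)
  mesh <- fx$phantom$mesh
  # plane perpendicular to the branch axis (x), 15 mm out: cuts both the
  # branch (around (15, 0, 40)) and the parent tube (centered at x = 0 with
  # radius 8 < 15, so the parent leaves a second loop only if the plane
  # grazes it; use a plane at x = 4 that cuts both)
  sec_branch <- slice_mesh(mesh, c(4, 0, 40), c(1, 0, 0),
                           seed_point = c(4, 0, 40))
  # seeded at the branch axis: small ellipse-ish loop, area ~ pi * 9
  expect_lt(sec_branch$area, 40)
  sec_parent <- slice_mesh(mesh, c(4, 0, 40), c(1, 0, 0),
                           seed_point = c(4, 0, 10))
  # seeded on the parent away from the branch: the big lumen chord loop
  expect_gt(sec_parent$area, 100)
})

test_that("Feret diameters match analytic shapes", {
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  ell <- cbind(4 * cos(th), 2 * sin(th))
  d <- feret_diameters(ell)
  expect_equal(unname(d["d_max"]), 8, tolerance = 0.005)
  expect_equal(unname(d["d_min"]), 4, tolerance = 0.005)
  circ <- cbind(3 * cos(th), 3 * sin(th))
  d <- feret_diameters(circ)
  expect_equal(unname(d["d_min"]), 6, tolerance = 0.005)
  expect_equal(unname(d["d_max"]), 6, tolerance = 0.005)
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  d <- feret_diameters(sq)
  expect_equal(unname(d["d_max"]), 10 * sqrt(2), tolerance = 1e-9)
  expect_equal(unname(d["d_min"]), 10, tolerance = 1e-9)
  expect_equal(unname(d["d_min"] / d["d_max"]), 0.7071068,
               tolerance = 1e-6)
  expect_error(feret_diameters(rbind(c(0, 0), c(1, 1))), "3 points")
})

test_that("rotating calipers agree with the exhaustive direction sweep", {
  set.seed(11)
  for (i in 1:20) {
    poly <- random_convex_polygon(15)
    cal <- feret_diameters(poly)
    swp <- oracle_feret_sweep(poly)
    expect_lt(abs(cal["d_min"] / swp["d_min"] - 1), 1e-3)
    expect_lt(abs(cal["d_max"] / swp["d_max"] - 1), 1e-6)
  }
})

test_that("shape index approaches b/a as polygon density grows", {
  errs <- vapply(c(24, 96, 384), function(n) {
    th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    abs(shape_index(cbind(4 * cos(th), 2 * sin(th))) - 0.5)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-4)
})

test_that("chord diameters offer the alternative definition", {
  tb <- make_tube_mesh(phantom_straight(30, radius = 3, si = 0.5))
  sec <- slice_mesh(tb$mesh, c(0, 0, 15), c(0, 0, 1))
  d <- chord_diameters(sec)
  expect_equal(unname(d["d_max"]), 8, tolerance = 0.01)
  expect_equal(unname(d["d_min"]), 4, tolerance = 0.01)
  expect_equal(shape_index(sec, definition = "chord"), 0.5,
               tolerance = 0.01)
})

test_that("SI is invariant to rigid motion and uniform scaling", {
  tb <- make_tube_mesh(phantom_straight(30, radius = 3, si = 0.7))
  prof <- si_profile(tb$mesh, tb$truth$centerline, 2)
  R <- rotation_matrix(c(3, 1, 2), 1.1)
  moved <- transform_mesh(tb$mesh, R, c(5, 6, 7))
  mc <- centerline_curve(sweep(tb$truth$centerline$points %*% t(R), 2,
                               c(5, 6, 7), "+"))
  prof_m <- si_profile(moved, mc, 2)
  expect_equal(prof_m$si, prof$si, tolerance = 0.01)
  scaled <- surface_mesh(tb$mesh$vertices * 2, tb$mesh$faces,
                         clean = FALSE)
  sc <- centerline_curve(tb$truth$centerline$points * 2)
  prof_s <- si_profile(scaled, sc, 4)
  expect_equal(prof_s$si, prof$si, tolerance = 0.01)
})

test_that("SI profiles cover the tube and respect the endpoint margin", {
  fx <- fx_cyl70()
  prof <- si_profile(fx$mesh, fx$truth$centerline, 1)
  expect_equal(nrow(prof), 69L)
  expect_true(all(abs(prof$si - 1) < 0.02))
  expect_true(all(diff(prof$s) > 0))
  expect_equal(attr(prof, "n_failed"), 0L)
  # constant-eccentricity tube
  tb <- make_tube_mesh(phantom_straight(40, radius = 3, si = 0.5))
  prof2 <- si_profile(tb$mesh, tb$truth$centerline, 1)
  expect_lt(abs(mean(prof2$si) - 0.5), 0.02)
})

test_that("profiles with too many failed sections are rejected", {
  fx <- fx_cyl70()
  # centerline extending far past the mesh: most sections find no loop
  long <- centerline_curve(cbind(0, 0, seq(0, 300, by = 0.5)))
  expect_error(si_profile(fx$mesh, long, 5, gate_mm = 5),
               "profile quality")
})

test_that("kinked phantoms are localized by the SI profile minimum", {
  spec <- inject_kink(phantom_straight(70, radius = 3), 35, 0.4, 20)
  tb <- make_tube_mesh(spec)
  expect_equal(min(tb$truth$si_profile$si), 0.6, tolerance = 1e-6)
  prof <- si_profile(tb$mesh, tb$truth$centerline, 1)
  expect_lt(abs(min(prof$si) - 0.6), 0.03)
  expect_lt(abs(prof$s[which.min(prof$si)] - 35), 2)
})
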