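test_that("phantom specs validate their invariants", {
  expect_error(phantom_spec(rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 1)),
                            radius = 3), "degenerate")
  expect_error(phantom_spec(rbind(c(0, 0, 0), c(0, 0, 10)), radius = -1),
               "radius")
  expect_error(phantom_spec(rbind(c(0, 0, 0), c(0, 0, 10)), radius = 3,
                            si = 1.2), "si")
  expect_error(phantom_spec(rbind(c(0, 0, 0), c(0, 0, 10)), radius = 3,
                            si = 0), "si")
})

test_that("straight circular cylinder has exact ground truth", {
  fx <- fx_cyl70()
  expect_equal(fx$truth$length, 70, tolerance = 1e-9)
  expect_true(all(fx$truth$si_profile$si == 1))
  expect_true(is_watertight(fx$mesh))
  # swept ellipse inscribed in the circle: area slightly below pi r^2
  expect_equal(mesh_volume(fx$mesh), pi * 9 * 70, tolerance = 0.01)
})

test_that("arc phantom ground-truth length matches the analytic arc", {
  fx <- fx_arc()
  expect_equal(fx$truth$length, pi * 20 / 2, tolerance = 1e-3)
  # generator invariant: truth length equals generating-curve arclength
  expect_equal(fx$truth$length, curve_length(fx$truth$centerline),
               tolerance = 1e-9)
})

test_that("eccentric tube emits elliptical sections with the intended diameters", {
  tb <- make_tube_mesh(phantom_straight(40, radius = 3, si = 0.5))
  # independent brute-force slicer, never the package's section machinery
  for (z0 in c(10, 20, 31.5)) {
    pts <- oracle_slice_z(tb$mesh, z0)
    d <- oracle_feret_sweep(pts)
    expect_equal(unname(d["d_max"]), 8, tolerance = 0.005)
    expect_equal(unname(d["d_min"]), 4, tolerance = 0.005)
  }
})

test_that("tube exceeding the local curvature radius is rejected", {
  expect_error(make_tube_mesh(phantom_arc(5, 90, radius = 6)),
               "geometry error.*arclength")
})

test_that("constant-eccentricity tubes have constant independently measured SI", {
  for (si0 in c(0.5, 0.9)) {
    tb <- make_tube_mesh(phantom_straight(30, radius = 3, si = si0))
    sis <- vapply(c(8, 15, 22), function(z0) {
      d <- oracle_feret_sweep(oracle_slice_z(tb$mesh, z0))
      unname(d["d_min"] / d["d_max"])
    }, numeric(1))
    expect_true(all(abs(sis - si0) < 0.02))
    expect_lt(diff(range(sis)), 0.02)
  }
})

test_that("kink injection dips the SI profile as requested", {
  base <- phantom_straight(70, radius = 3)
  expect_identical(inject_kink(base, 35, 0, 20), base)
  k <- inject_kink(base, 35, 0.4, 20)
  tt <- seq(0, 1, length.out = 1001)
  expect_equal(min(k$si(tt)), 0.6, tolerance = 1e-6)
  # dip centred at mid-length, intact near the ends
  expect_equal(k$si(35 / 70), 0.6, tolerance = 1e-9)
  expect_equal(k$si(c(0.1, 0.9)), c(1, 1))
  expect_error(inject_kink(base, 35, 0.4, 200), "window")
  expect_error(inject_kink(phantom_straight(70, radius = 3, si = 0.3),
                           35, 0.4, 20), "zero")
})

test_that("branched phantom records the constructed take-off angle", {
  parent <- phantom_straight(80, radius = 8)
  for (ang in c(90, 120, 180)) {
    ph <- make_branched_phantom(parent, list(
      branch_spec(origin_arclength = 40, takeoff_angle_deg = ang,
                  length = 30, radius = 3, cuff_end_arclength = 8,
                  vessel_origin_arclength = 20)))
    expect_equal(ph$branch_truths[[1]]$takeoff_angle_deg, ang,
                 tolerance = 1e-6)
    expect_true(is_watertight(ph$mesh))
  }
})

test_that("branch ground truth carries zone lengths from the landmarks", {
  fx <- fx_branched(90)
  expect_equal(fx$truth$zone_lengths, c(10, 18, 12), tolerance = 1e-6)
  expect_equal(sum(fx$truth$zone_lengths), fx$truth$length,
               tolerance = 1e-6)
})

test_that("overlapping branch origins are rejected", {
  parent <- phantom_straight(80, radius = 8)
  mk <- function(s) branch_spec(origin_arclength = s,
                                takeoff_angle_deg = 90, length = 20,
                                radius = 3, cuff_end_arclength = 5,
                                vessel_origin_arclength = 12)
  expect_error(make_branched_phantom(parent, list(mk(40), mk(43))),
               "closer than one parent radius")
})

test_that("voxelization reproduces analytic volumes", {
  fx <- fx_cyl70()
  expect_equal(voxel_volume(fx$map), pi * 9 * 70, tolerance = 0.05)
  expect_error(voxelize(surface_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)),
                        0.5), "empty mesh")
})
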