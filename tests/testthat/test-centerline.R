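test_that("centerline curves enforce their invariants", {
  cl <- centerline_curve(rbind(c(0, 0, 0), c(0, 0, 5), c(0, 3, 9)))
  expect_true(all(diff(cl$arclength) > 0))
  expect_equal(sqrt(rowSums(cl$tangents^2)), rep(1, 3), tolerance = 1e-12)
  expect_equal(curve_length(cl), 10, tolerance = 1e-12)
  expect_error(centerline_curve(rbind(c(1, 1, 1), c(1, 1, 1))),
               "degenerate")
})

test_that("resampling spaces points uniformly and preserves endpoints", {
  seg <- centerline_curve(rbind(c(0, 0, 0), c(0, 0, 10)))
  r <- resample_curve(seg, 1)
  expect_equal(nrow(r$points), 11L)
  expect_equal(diff(r$arclength), rep(1, 10), tolerance = 1e-9)
  expect_equal(r$points[1, ], c(0, 0, 0))
  expect_equal(r$points[11, ], c(0, 0, 10))
  # idempotence
  r2 <- resample_curve(r, 1)
  expect_equal(r2$points, r$points, tolerance = 1e-12)
  expect_error(resample_curve(seg, -1), "positive")
  expect_error(resample_curve(seg, 11), "exceeds")
})

test_that("resampling a dense circle preserves the circumference", {
  th <- seq(0, 2 * pi, length.out = 4001)
  circ <- centerline_curve(cbind(10 * cos(th), 10 * sin(th), 0))
  r <- resample_curve(circ, 0.1)
  expect_lt(abs(curve_length(r) / (2 * pi * 10) - 1), 5e-4)
})

test_that("tangents match analytic directions", {
  straight <- centerline_curve(rbind(c(0, 0, 0), c(0, 0, 35), c(0, 0, 70)))
  expect_equal(as.vector(tangent_at(straight, 17)), c(0, 0, 1),
               tolerance = 1e-12)
  # circle: tangent perpendicular to radius
  th <- seq(0, pi, length.out = 2001)
  circ <- centerline_curve(cbind(10 * cos(th), 10 * sin(th), 0))
  s <- curve_length(circ) / 3
  p <- as.vector(point_at(circ, s))
  tg <- as.vector(tangent_at(circ, s))
  expect_lt(abs(sum(p * tg)) / 10, 1e-3)
  # helix tangent at s = 0 vs analytic derivative (dense polyline)
  helix <- centerline_curve(phantom_helix(10, 20, 1, radius = 3)$centerline)
  tg0 <- as.vector(tangent_at(helix, 0))
  ana <- c(0, 2 * pi * 10, 20)
  ana <- ana / sqrt(sum(ana^2))
  expect_lt(acos(min(1, sum(tg0 * ana))), 1e-2)
  expect_error(tangent_at(straight, -5), "out of range")
})

test_that("extracted centerlines recover analytic lengths", {
  fx <- fx_cyl70()
  expect_lt(abs(curve_length(fx$centerline) / 70 - 1), 0.01)
  # all points within half a voxel of the true axis
  expect_lt(max(abs(fx$centerline$points[, 1:2])), 0.25)
  # away from the caps the inscribed radius approaches the tube radius
  interior <- fx$centerline$arclength > 5 & fx$centerline$arclength < 65
  expect_true(all(fx$centerline$inscribed_radius[interior] > 1.5))
  fxa <- fx_arc()
  expect_lt(abs(curve_length(fxa$centerline) / (pi * 10) - 1), 0.015)
  fxh <- fx_helix()
  Lh <- sqrt((2 * pi * 10)^2 + 20^2)
  expect_lt(abs(curve_length(fxh$centerline) / Lh - 1), 0.02)
})

test_that("centerline of a voxelized tube stays near the generating curve", {
  fxa <- fx_arc()
  truth <- fxa$truth$centerline
  d <- vapply(seq_len(nrow(fxa$centerline$points)), function(i) {
    min(sqrt(rowSums(sweep(truth$points, 2,
                           fxa$centerline$points[i, ])^2)))
  }, numeric(1))
  expect_lt(max(d), 0.5)  # one voxel spacing
})

test_that("extraction errors on bad endpoints and disconnected regions", {
  fx <- fx_cyl70()
  expect_error(extract_centerline(fx$map, c(20, 20, 35), c(0, 0, 70)),
               "outside the labeled region")
  # two disjoint blobs
  arr <- array(0L, c(20, 20, 20))
  arr[3:6, 3:6, 3:6] <- 1L
  arr[14:17, 14:17, 14:17] <- 1L
  vm <- voxel_map(arr, 1)
  expect_error(extract_centerline(vm, c(4, 4, 4), c(15, 15, 15)),
               "no path")
})

test_that("centerline length is invariant to rigid motion", {
  fx <- fx_cyl70()
  R <- rotation_matrix(c(1, 2, 3), 0.7)
  m2 <- transform_mesh(fx$mesh, R, c(13, -7, 22))
  vm2 <- voxelize(m2, 0.5)
  e1 <- as.vector(R %*% c(0, 0, 0)) + c(13, -7, 22)
  e2 <- as.vector(R %*% c(0, 0, 70)) + c(13, -7, 22)
  cl2 <- extract_centerline(vm2, e1, e2)
  expect_lt(abs(curve_length(cl2) / curve_length(fx$centerline) - 1),
            0.005)
})

test_that("extraction is deterministic for a fixed input", {
  fx <- fx_cyl70()
  cl2 <- extract_centerline(fx$map, c(0, 0, 0), c(0, 0, 70))
  expect_identical(cl2$points, fx$centerline$points)
})

test_that("branch origins are located on the parent curve", {
  parent <- centerline_curve(cbind(0, 0, seq(0, 70, by = 0.5)))
  branch <- centerline_curve(cbind(seq(0, 20, by = 0.5), 0, 35))
  j <- locate_branch_origin(parent, branch)
  expect_equal(j$s_parent, 35, tolerance = 1e-6)
  expect_equal(j$origin_point, c(0, 0, 35), tolerance = 1e-9)
  far <- centerline_curve(cbind(seq(50, 70, by = 0.5), 0, 35))
  expect_error(locate_branch_origin(parent, far), "no junction")
  # generator phantom: recovered origin within 1 mm of the spec
  fx <- fx_branched(90)
  j2 <- locate_branch_origin(fx$meas$parent_centerline,
                             fx$meas$branch_centerline)
  expect_lt(abs(j2$s_parent - 40), 1)
})
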