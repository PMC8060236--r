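test_that("take-off angle follows the 0-180 convention on constructions", {
  # perpendicular branch -> 90 degrees
  fx <- fx_branched(90)
  expect_lt(abs(fx$meas$toa$angle_deg - 90), 2)
  # caudally parallel branch -> 180 (straight angle)
  parent <- centerline_curve(cbind(0, 0, seq(0, 70, by = 0.5)))
  caudal <- centerline_curve(cbind(0, 0, seq(35, 60, by = 0.5)))
  expect_equal(take_off_angle(parent, caudal)$angle_deg, 180,
               tolerance = 1e-6)
  # cranially recurving branch -> near 0 (most acute)
  cranial <- centerline_curve(cbind(0.5, 0, seq(35, 20, by = -0.5)))
  expect_lt(take_off_angle(parent, cranial)$angle_deg, 5)
})

test_that("generator take-off angles are recovered on meshed phantoms", {
  for (ang in c(60, 150)) {
    fx <- fx_branched(ang)
    expect_lt(abs(fx$meas$toa$angle_deg - ang), 2)
    expect_lt(abs(fx$meas$toa$s_origin_parent - 40), 1)
  }
})

test_that("short branches shrink the averaging window with a warning", {
  parent <- centerline_curve(cbind(0, 0, seq(0, 70, by = 0.5)))
  stub <- centerline_curve(cbind(seq(0, 2, by = 0.5), 0, 35))
  expect_warning(toa <- take_off_angle(parent, stub, window_mm = 5),
                 "shrunk")
  expect_equal(toa$window_mm, 2)
  expect_equal(toa$angle_deg, 90, tolerance = 1e-6)
})

test_that("zone partition is exact and validates landmark order", {
  cl <- centerline_curve(cbind(0, 0, seq(0, 70, by = 0.5)))
  part <- partition_zones(cl, 18, 49)
  expect_equal(part$zone_lengths, c(18, 31, 21))
  expect_equal(sum(part$zone_lengths), part$total_length)
  expect_error(partition_zones(cl, 49, 49), "invalid landmarks")
  expect_error(partition_zones(cl, -1, 20), "invalid landmarks")
  expect_error(partition_zones(cl, 20, 80), "invalid landmarks")
})

test_that("zone metrics aggregate the SI profile per half-open zone", {
  cl <- centerline_curve(cbind(0, 0, seq(0, 70, by = 0.5)))
  part <- partition_zones(cl, 20, 50)
  # constructed step profile: SI 0.9 in zones 1-2, 0.6 in zone 3
  s <- seq(1, 69, by = 1)
  prof <- data.frame(s = s, d_min = 6, d_max = 6,
                     si = ifelse(s < 50, 0.9, 0.6), area = pi * 9)
  m <- zone_metrics(part, prof, nominal_length = 70)
  expect_equal(m$zone_mean_si, c(0.9, 0.9, 0.6), tolerance = 0.01)
  expect_equal(sum(m$zone_n_sections), nrow(prof))
  # boundary sections (s = 20, s = 50) counted downstream only
  expect_equal(m$zone_n_sections, c(19L, 30L, 20L))
  expect_equal(m$total_length, 70)
  expect_equal(m$shortening_pct, 0)
  # a zone with no sections fails loudly
  sparse <- prof[prof$s > 30, ]
  expect_error(zone_metrics(part, sparse, 70), "no sections")
})

test_that("uniform SI yields uniform zone means", {
  fx <- fx_branched(90)
  m <- fx$meas$metrics
  expect_true(all(abs(m$zone_mean_si - 1) < 0.02))
  expect_equal(sum(m$zone_lengths), m$total_length, tolerance = 1e-9)
})

test_that("generator zone lengths are recovered within a millimetre", {
  fx <- fx_branched(90)
  expect_true(all(abs(fx$meas$metrics$zone_lengths -
                      fx$truth$zone_lengths) < 1))
})

test_that("stent shortening is the percentage deficit against nominal", {
  expect_equal(stent_shortening(70, 63), 10)
  expect_equal(stent_shortening(60, 60), 0)
  expect_equal(stent_shortening(60, 53.3), 11.16667, tolerance = 1e-6)
  # measured longer than nominal: negative, reported as-is
  expect_lt(stent_shortening(60, 66), 0)
  expect_error(stent_shortening(0, 10), "positive")
  expect_error(stent_shortening(10, -1), "positive")
})

test_that("multi-stent constructs count overlap once and report it", {
  r <- multi_stent_length(rbind(c(0, 60), c(40, 100)))
  expect_equal(r$total_length, 100)
  expect_equal(r$overlap_length, 20)
  expect_equal(r$n_stents, 2L)
  # mirrors the clinical rule: shortening undefined for multi-stent
  cl <- centerline_curve(cbind(0, 0, seq(0, 100, by = 0.5)))
  part <- partition_zones(cl, 20, 60)
  prof <- data.frame(s = seq(1, 99), d_min = 6, d_max = 6, si = 0.9,
                     area = pi * 9)
  m <- zone_metrics(part, prof, nominal_length = 60, single_stent = FALSE)
  expect_true(is.na(m$shortening_pct))
})

test_that("TOA is stable under rigid motion of the phantom", {
  fx <- fx_branched(120)
  R <- rotation_matrix(c(1, 1, 0), 0.9)
  t0 <- c(-11, 4, 9)
  mesh2 <- transform_mesh(fx$phantom$mesh, R, t0)
  ptr <- fx$parent_truth$centerline$points
  btr <- fx$truth$centerline$points
  tp <- function(p) sweep(p %*% t(R), 2, t0, "+")
  meas2 <- measure_branch(mesh2, 1L,
                          parent_ends = tp(ptr[c(1, nrow(ptr)), ]),
                          branch_ends = tp(btr[c(1, nrow(btr)), ]),
                          cuff_end_s = 10, vessel_origin_s = 28,
                          nominal_length = 44)
  expect_lt(abs(meas2$toa$angle_deg - fx$meas$toa$angle_deg), 2)
})
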