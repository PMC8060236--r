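# Shared phantom fixtures, built once per test run (they exercise the
# generator itself, so failures here surface in the generator tests too).

.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# straight cylinder, radius 3 mm, length 70 mm, full pipeline artefacts
fx_cyl70 <- function() get_fixture("cyl70", function() {
  spec <- phantom_straight(70, radius = 3)
  tb <- make_tube_mesh(spec)
  map <- voxelize(tb$mesh, 0.5)
  cl <- extract_centerline(map, c(0, 0, 0), c(0, 0, 70))
  list(spec = spec, mesh = tb$mesh, truth = tb$truth, map = map,
       centerline = cl)
})

# quarter-circle arc, bend radius 20 mm, tube radius 3 mm
fx_arc <- function() get_fixture("arc20", function() {
  tb <- make_tube_mesh(phantom_arc(20, 90, radius = 3))
  map <- voxelize(tb$mesh, 0.5)
  ends <- tb$truth$centerline$points[c(1, nrow(tb$truth$centerline$points)), ]
  cl <- extract_centerline(map, ends[1, ], ends[2, ])
  list(mesh = tb$mesh, truth = tb$truth, map = map, centerline = cl)
})

# one-turn helix, helix radius 10 mm, pitch 20 mm, tube radius 3 mm
fx_helix <- function() get_fixture("helix", function() {
  tb <- make_tube_mesh(phantom_helix(10, 20, 1, radius = 3))
  map <- voxelize(tb$mesh, 0.5)
  ends <- tb$truth$centerline$points[c(1, nrow(tb$truth$centerline$points)), ]
  cl <- extract_centerline(map, ends[1, ], ends[2, ])
  list(mesh = tb$mesh, truth = tb$truth, map = map, centerline = cl)
})

# branched phantom measured end to end at a given take-off angle
fx_branched <- function(angle_deg) {
  get_fixture(paste0("branched_", angle_deg), function() {
    parent <- phantom_straight(80, radius = 8)
    bs <- branch_spec(origin_arclength = 40, takeoff_angle_deg = angle_deg,
                      length = 40, radius = 3,
                      cuff_end_arclength = 10, vessel_origin_arclength = 28,
                      nominal_stent_length = 44)
    ph <- make_branched_phantom(parent, list(bs))
    tr <- ph$branch_truths[[1]]
    ptr <- ph$parent_truth
    pp <- ptr$centerline$points
    bp <- tr$centerline$points
    meas <- measure_branch(
      ph$mesh, branch_label = 1L,
      parent_ends = pp[c(1, nrow(pp)), ],
      branch_ends = bp[c(1, nrow(bp)), ],
      cuff_end_s = 10, vessel_origin_s = 28, nominal_length = 44)
    list(phantom = ph, truth = tr, parent_truth = ptr, meas = meas)
  })
}
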