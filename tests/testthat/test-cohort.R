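test_that("cohort spec validates structure and vocabularies", {
  expect_s3_class(cohort_spec(n_per_cell = 2), "cohort_spec")
  bad <- data.frame(vessel_type = "AAA", stent_type = "VBX", n = 2)
  expect_error(cohort_spec(cells = bad), "vocabularies")
  empty <- beva_cohort_cells()
  empty$n[1] <- 0
  expect_error(cohort_spec(cells = empty), "empty cells")
  em <- beva_effect_model()
  em$zone1_si$sd[] <- -1
  expect_error(cohort_spec(effect_model = em), "negative SD")
})

test_that("zero-SD cohorts reproduce their cell means exactly", {
  em <- beva_effect_model()
  for (m in names(em)) em[[m]]$sd[] <- 0
  tab <- simulate_cohort(cohort_spec(n_per_cell = 2, effect_model = em,
                                     seed = 4))
  for (m in c("zone2_si", "shortening_pct", "toa_post_deg")) {
    mu <- em[[m]]$mean[tab$stent_type]
    expect_equal(tab[[m]], unname(mu), tolerance = 1e-12)
  }
  mu_pre <- em$toa_pre_deg$mean[tab$vessel_type]
  expect_equal(tab$toa_pre_deg, unname(mu_pre), tolerance = 1e-12)
})

test_that("simulation is bit-reproducible and leaves the RNG alone", {
  spec <- cohort_spec(cells = beva_cohort_cells(), seed = 12)
  set.seed(99)
  t1 <- simulate_cohort(spec)
  probe1 <- rnorm(1)
  t2 <- simulate_cohort(spec)
  expect_identical(t1, t2)
  set.seed(99)
  probe2 <- rnorm(1)
  expect_identical(probe1, probe2)  # caller RNG stream undisturbed
})

test_that("cohort metrics respect their physical ranges", {
  tab <- simulate_cohort(cohort_spec(n_per_cell = 200, seed = 3))
  expect_true(all(tab$zone1_si > 0 & tab$zone1_si <= 1))
  expect_true(all(tab$zone2_si > 0 & tab$zone2_si <= 1))
  expect_true(all(tab$zone3_si > 0 & tab$zone3_si <= 1))
  expect_true(all(tab$toa_pre_deg >= 0 & tab$toa_pre_deg <= 180))
  expect_true(all(tab$toa_post_deg >= 0 & tab$toa_post_deg <= 180))
  expect_true(all(tab$zone1_length > 0))
  expect_true(all(tab$nominal_length > 0))
  expect_equal(tab$total_length,
               tab$nominal_length * (1 - tab$shortening_pct / 100),
               tolerance = 1e-12)
})

test_that("large cohorts concentrate on the configured means", {
  tab <- simulate_cohort(cohort_spec(n_per_cell = 10000, seed = 8))
  em <- beva_effect_model()
  # metrics whose truncation bounds are many SDs away, so the truncated
  # mean is the configured mean: sample mean within 2 SE per cell
  for (m in c("zone1_length", "nominal_length")) {
    for (st in unique(tab$stent_type)) {
      cells <- split(tab[[m]][tab$stent_type == st],
                     tab$vessel_type[tab$stent_type == st])
      mu <- em[[m]]$mean[[st]]
      sdv <- em[[m]]$sd[[st]]
      for (v in cells) {
        expect_lt(abs(mean(v) - mu), 2 * sdv / sqrt(length(v)))
      }
    }
  }
})

test_that("the factorial cell table mirrors the reference cohort", {
  cells <- beva_cohort_cells()
  expect_equal(sum(cells$n), 38)
  by_stent <- tapply(cells$n, cells$stent_type, sum)
  expect_equal(as.vector(by_stent[c("Fluency", "Covera", "VBX")]),
               c(10, 12, 16))
  by_vessel <- tapply(cells$n, cells$vessel_type, sum)
  expect_equal(as.vector(by_vessel[c("CTR", "SMA", "LRA", "RRA")]),
               c(11, 11, 8, 8))
})
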