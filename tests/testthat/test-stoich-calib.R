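test_that("mass to molarity to particles conversion is exact and linear", {
  expect_equal(to_molarity(0, "NfL"), 0)
  expect_equal(to_molarity(68000, "NfL"), 1)
  expect_equal(to_molarity(6.8e-11, "NfL"), 1.0e-15)
  expect_equal(to_particles(0), 0)
  expect_equal(to_particles(1), 6.0221415e23)
  expect_equal(to_particles(1e-15), 6.0221415e8)
  expect_error(to_molarity(-1, "NfL"), class = "nfstoich_domain_error")
  # linearity in the concentration
  for (alpha in c(0.1, 2, 17)) {
    c0 <- 3.2e-9
    expect_equal(to_particles(to_molarity(alpha * c0, "NfM")),
                 alpha * to_particles(to_molarity(c0, "NfM")))
  }
})

test_that("NfH channel combination modes behave as documented", {
  expect_equal(combine_nfh(3, 2, "sum"), 5)
  expect_equal(combine_nfh(3, 2, "smi35_only"), 3)
  expect_equal(combine_nfh(3, 2, "smi34_only"), 2)
  expect_equal(combine_nfh(0, 0, "sum"), 0)
  expect_error(combine_nfh(NA_real_, 5, "smi35_only"),
               class = "nfstoich_missing_data_error")
})

test_that("calibration factors follow target / control median", {
  pr <- control_profiles_with_medians(14e8, 3e8, 1e8)
  cal <- calibration_factors(pr)
  expect_equal(unname(cal$factors), c(5e-9, 1e-8, 2e-8))
  expect_equal(unname(calibration_factors(
    control_profiles_with_medians(7, 3, 2))$factors), c(1, 1, 1))
  expect_error(calibration_factors(pr[1:2, ]), class = "nfstoich_domain_error")
  expect_error(calibration_factors(control_profiles_with_medians(0, 3, 2)),
               class = "nfstoich_calibration_error")
})

test_that("applying calibration hits the targets and refuses to run twice", {
  pr <- control_profiles_with_medians(14e8, 3e8, 1e8)
  cal <- calibration_factors(pr)
  calp <- apply_calibration(pr, cal)
  expect_true(all(calp$calibrated))
  expect_equal(unname(unlist(
    cohort_stoichiometry(calp)[, c("nfl", "nfm", "nfh")])), c(7, 3, 2))
  expect_error(apply_calibration(calp, cal), class = "nfstoich_state_error")
  # identity factors leave the profile unchanged
  same <- apply_calibration(pr, c(x = 1, y = 1, z = 1))
  expect_equal(same[c("nfl", "nfm", "nfh")], pr[c("nfl", "nfm", "nfh")])
})

test_that("calibrated control medians are exactly the targets on any seeded cohort", {
  for (seed in c(1, 23, 99)) {
    pr <- particle_profiles(generate_cohort(cohort_config(seed = seed)))
    calp <- apply_calibration(pr, calibration_factors(pr))
    st <- cohort_stoichiometry(calp)
    ctrl <- st[st$group == "control", ]
    expect_equal(c(ctrl$nfl, ctrl$nfm, ctrl$nfh), c(7, 3, 2))
  }
})

test_that("recalibrating an already-calibrated control cohort gives unit factors", {
  pr <- particle_profiles(generate_cohort(cohort_config(seed = 6)))
  calp <- apply_calibration(pr, calibration_factors(pr))
  refit <- calibration_factors(mutate(calp, calibrated = FALSE))
  expect_equal(unname(refit$factors), c(1, 1, 1))
})

test_that("per-assay scale distortions cancel after calibration", {
  base <- cohort_config(seed = 13)
  st0 <- {
    pr <- particle_profiles(generate_cohort(base))
    cohort_stoichiometry(apply_calibration(pr, calibration_factors(pr)))
  }
  for (alpha in c(0.2, 5)) {
    scaled <- cohort_config(
      seed = 13,
      assay_scale = base$assay_scale * c(alpha, 1, 1, 1))
    pr <- particle_profiles(generate_cohort(scaled))
    st <- cohort_stoichiometry(apply_calibration(pr, calibration_factors(pr)))
    expect_equal(st, st0, tolerance = 1e-12)
  }
})

test_that("calibrated stoichiometry is invariant to the NfH channel choice", {
  # degenerate draws isolate the deterministic part: with per-subject
  # variability the SMI35+SMI34 sum has its own median and the invariance
  # is only approximate
  co <- generate_cohort(cohort_config(
    conc_log_sd = c(nfl = 0.3, nfm = 0.3, nfh_smi35 = 0, nfh_smi34 = 0),
    seed = 17))
  st35 <- {
    pr <- particle_profiles(co, nfh_mode = "smi35_only")
    cohort_stoichiometry(apply_calibration(pr, calibration_factors(pr)))
  }
  stsum <- {
    pr <- particle_profiles(co, nfh_mode = "sum")
    cohort_stoichiometry(apply_calibration(pr, calibration_factors(pr)))
  }
  expect_equal(st35, stsum, tolerance = 1e-9)
})

test_that("pg/mL convenience unit applies the 1e-9 factor", {
  co <- generate_cohort(cohort_config(seed = 2))
  gl <- particle_profiles(co)
  co9 <- mutate(co, across(dplyr::starts_with("conc_"), ~ .x * 1e9))
  pg <- particle_profiles(co9, unit = "pg_per_ml")
  expect_equal(pg$nfl, gl$nfl)
})

test_that("density summaries normalize, translate and locate the mode", {
  set.seed(1)
  x <- rnorm(10000)
  d <- density_summary(x)
  dx <- diff(d$value[1:2])
  expect_true(abs(sum(d$density) * dx - 1) < 0.01)
  expect_lt(abs(d$value[which.max(d$density)]), 0.1)
  # translation equivariance at fixed bandwidth
  d0 <- density_summary(x, bandwidth = 0.3)
  d5 <- density_summary(x + 5, bandwidth = 0.3)
  expect_equal(d5$value, d0$value + 5, tolerance = 1e-10)
  expect_equal(d5$density, d0$density, tolerance = 1e-10)
  expect_error(density_summary(1), class = "nfstoich_domain_error")
})

test_that("calibration tidiers expose factors and medians", {
  pr <- control_profiles_with_medians(14e8, 3e8, 1e8)
  cal <- calibration_factors(pr)
  td <- generics::tidy(cal)
  expect_equal(td$isoform, c("NfL", "NfM", "NfH"))
  expect_equal(td$factor * td$control_median, td$target)
  expect_equal(generics::glance(cal)$n_channels, 3)
})
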