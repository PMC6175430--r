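# a minimal hand-built state: two 2-bead arms, charge only on the tip beads
two_bead_state <- function(tip_sep, q = -1, box_z = 50, box_xy = 200) {
  cfg <- brush_config(n_backbones = 1, arm_specs = tiny_specs(2),
                      excluded_volume = FALSE, seed = 1)
  coords <- rbind(
    c(100, 100, 10), c(100.6, 100, 10),            # arm 1
    c(100, 100, 20), c(100.6 + 0, 100, 20))        # arm 2 tip placed below
  coords[4, ] <- coords[2, ] + c(0, 0, tip_sep)
  beads <- tibble::tibble(arm_id = c(1L, 1L, 2L, 2L),
                          bead_index = c(1L, 2L, 1L, 2L),
                          charge = c(0, q, 0, q),
                          mobile = c(FALSE, TRUE, FALSE, TRUE))
  arms <- tibble::tibble(arm_id = 1:2, backbone = 1L, site = 1:2,
                         species = "NfL", n_beads = 2L)
  cfg$backbone_xy <- matrix(c(-1000, -1000), 1, 2)  # far away: no exclusion
  structure(list(coords = coords, beads = beads, arms = arms,
                 config = cfg, energy = NA_real_), class = "brush_state")
}

test_that("total energy of two isolated charged beads reduces to the pair law", {
  st <- two_bead_state(tip_sep = 1.2)
  e <- total_energy(st)
  # charged tips 1.2 nm apart dominate; the anchor beads are neutral
  expect_equal(e, pair_energy(1.2, -1, -1, st$config), tolerance = 1e-12)
  # neutral system has zero energy
  st0 <- two_bead_state(tip_sep = 1.2, q = 0)
  expect_equal(total_energy(st0), 0)
  # beyond the cutoff the truncated interaction vanishes
  far <- two_bead_state(tip_sep = st$config$cutoff + 0.5)
  expect_equal(total_energy(far), 0)
})

test_that("zero-energy moves are always accepted", {
  cfg <- brush_config(n_backbones = 1, arm_specs = tiny_specs(8),
                      excluded_volume = FALSE, backbone_exclusion = FALSE,
                      seed = 7)
  st <- build_brush(cfg)
  st <- mc_run(st, 20)
  mv <- attr(st, "moves")
  expect_equal(mv[["accepted"]], mv[["attempted"]])
})

test_that("accepted configurations never contain hard-core or backbone overlaps", {
  cfg <- brush_config(n_backbones = 1, arm_specs = scale_sidearms(sidearm_specs(), 0.08),
                      species_assignment = "proportional",
                      sweeps_equil = 0, seed = 15)
  st <- mc_run(build_brush(cfg), 150)
  co <- st$coords
  n <- nrow(co)
  # brute-force minimum-image distances between non-bonded pairs
  mi <- function(d, L) d - L * round(d / L)
  min_d2 <- Inf
  for (i in seq_len(n - 1)) {
    dx <- mi(co[i, 1] - co[(i + 1):n, 1], cfg$box_xy)
    dy <- mi(co[i, 2] - co[(i + 1):n, 2], cfg$box_xy)
    dz <- mi(co[i, 3] - co[(i + 1):n, 3], cfg$box_z)
    d2 <- dx^2 + dy^2 + dz^2
    bonded <- st$beads$arm_id[(i + 1):n] == st$beads$arm_id[i] &
      abs(st$beads$bead_index[(i + 1):n] - st$beads$bead_index[i]) == 1
    d2 <- d2[!bonded]
    if (length(d2)) min_d2 <- min(min_d2, min(d2))
  }
  expect_gte(sqrt(min_d2), cfg$bead_diameter - 1e-9)
  # no mobile bead centre inside the backbone exclusion radius
  mob <- co[st$beads$mobile, ]
  r <- sqrt(mi(mob[, 1] - cfg$backbone_xy[1, 1], cfg$box_xy)^2 +
              mi(mob[, 2] - cfg$backbone_xy[1, 2], cfg$box_xy)^2)
  expect_gte(min(r), cfg$backbone_radius + cfg$bead_diameter / 2 - 1e-6)
  expect_true(is.finite(st$energy))
})

test_that("incrementally tracked energy matches a from-scratch recomputation", {
  cfg <- brush_config(n_backbones = 1,
                      arm_specs = scale_sidearms(sidearm_specs(), 0.08),
                      phosphorylated = TRUE,
                      species_assignment = "proportional",
                      sweeps_equil = 0, seed = 23)
  st <- build_brush(cfg)
  st <- mc_run(st, 400)
  mv <- attr(st, "moves")
  expect_gt(mv[["accepted"]], 1000)  # plenty of accepted moves accumulated
  expect_lt(abs(st$energy - total_energy(st)), 1e-6)
})

test_that("trajectories are deterministic under the seed", {
  cfg <- brush_config(n_backbones = 1, arm_specs = tiny_specs(10, charge = -0.5),
                      sweeps_equil = 10, sweeps_prod = 30, sample_every = 5,
                      seed = 77)
  r1 <- suppressWarnings(run_brush_simulation(cfg, "a"))
  r2 <- suppressWarnings(run_brush_simulation(cfg, "a"))
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$state$coords, r2$state$coords)
  r3 <- suppressWarnings(run_brush_simulation(brush_config(
    n_backbones = 1, arm_specs = tiny_specs(10, charge = -0.5),
    sweeps_equil = 10, sweeps_prod = 30, sample_every = 5, seed = 78), "a"))
  expect_false(identical(r1$state$coords, r3$state$coords))
})

test_that("ideal-chain gyration matches the freely-jointed closed form", {
  specs <- tiny_specs(50)
  cfg <- brush_config(stoichiometry = c(NfL = 1, NfM = 0, NfH = 0),
                      n_backbones = 1, graft_interval = 50,  # one arm
                      excluded_volume = FALSE, backbone_exclusion = FALSE,
                      arm_specs = specs,
                      sweeps_equil = 2000, sweeps_prod = 120000,
                      sample_every = 60, seed = 19)
  res <- run_brush_simulation(cfg, "ideal")
  rg2 <- res$samples$rg^2
  n <- 50; b <- cfg$bond_length
  theory <- b^2 * (n^2 - 1) / (6 * n)
  nb <- 40
  batches <- tapply(rg2, rep(seq_len(nb), each = length(rg2) / nb), mean)
  se <- sd(batches) / sqrt(nb)
  expect_lt(abs(mean(rg2) - theory), 3 * se + 1e-12)
})

test_that("phosphorylation does not shrink charged arms", {
  base <- scale_sidearms(sidearm_specs(), 0.12)
  run_one <- function(ph, seed) {
    cfg <- brush_config(stoichiometry = c(NfL = 0, NfM = 0, NfH = 1),
                        n_backbones = 1, phosphorylated = ph,
                        arm_specs = base,
                        sweeps_equil = 1200, sweeps_prod = 1200,
                        sample_every = 30, seed = seed)
    mean(suppressWarnings(run_brush_simulation(cfg, "x"))$samples$rg)
  }
  deph <- mean(vapply(1:2, function(s) run_one(FALSE, 40 + s), 1))
  phos <- mean(vapply(1:2, function(s) run_one(TRUE, 50 + s), 1))
  expect_gt(phos, deph * 0.98)
})

test_that("gyration contrasts recover construction and reduce to the ANOVA oracle", {
  set.seed(5)
  cells <- tidyr::expand_grid(species = c("NfL", "NfM", "NfH"),
                              phospho = c(FALSE, TRUE),
                              mixture = c("control", "ALS"))
  samples <- purrr::pmap(cells, function(species, phospho, mixture) {
    shift <- if (species == "NfH" && !phospho && mixture == "ALS") -5 else 0
    tibble::tibble(species = species, phospho = phospho, mixture = mixture,
                   rg = rnorm(30, 10 + shift, 0.3))
  }) |> dplyr::bind_rows()
  ct <- gyration_contrasts(samples)
  expect_lt(ct$omnibus$p_value, 1e-6)
  hit <- ct$posthoc[grepl("NfH", ct$posthoc$contrast) &
                      !grepl("phospho", ct$posthoc$contrast), ]
  expect_true(hit$significant)
  expect_equal(ct$posthoc$alpha_corrected[1], 0.05 / 6)
  # identical cells: omnibus far from significant, no contrasts attempted
  flat <- dplyr::mutate(samples, rg = rep(rnorm(30, 10, 0.3), 12))
  ct0 <- gyration_contrasts(flat)
  expect_equal(ct0$omnibus$statistic, 0, tolerance = 1e-9)
  expect_equal(nrow(ct0$posthoc), 0)
})

test_that("trajectory dumps are plain text with one bead per line", {
  cfg <- brush_config(n_backbones = 1, arm_specs = tiny_specs(3), seed = 1)
  st <- build_brush(cfg)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(st, path)
  lines <- readLines(path)
  expect_equal(as.integer(lines[1]), nrow(st$coords))
  expect_equal(length(lines), nrow(st$coords) + 1)
})
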