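#' Build the initial brush system
#'
#' Places graft sites every `box_z / n_sites` along each backbone, assigns a
#' side-arm species to each site by categorical sampling with probabilities
#' proportional to the stoichiometry mixture, fixes the first bead of each
#' arm on the backbone surface at a uniformly random azimuth, and grows the
#' remaining beads as outward-biased self-avoiding walks.
#'
#' @param config A [brush_config()].
#' @param seed_rng Set the RNG from `config$seed` before building (default
#'   `TRUE`; [run_brush_simulation()] manages seeding itself).
#' @return An object of class `brush_state`: list with `coords` (n x 3
#'   matrix, nm, unwrapped), `beads` (tibble `arm_id`, `bead_index`,
#'   `charge`, `mobile`), `arms` (tibble `arm_id`, `backbone`, `site`,
#'   `species`, `n_beads`), `config` and `energy` (kBT).
#' @export
build_brush <- function(config, seed_rng = TRUE) {
  stopifnot(inherits(config, "brush_config"))
  if (seed_rng) set.seed(config$seed)
  n_sites <- config$n_sites
  n_arms <- n_sites * config$n_backbones
  species_pool <- names(config$stoichiometry)
  prob <- config$stoichiometry / sum(config$stoichiometry)
  species <- if (sum(prob > 0) == 1) {
    rep(species_pool[prob > 0], n_arms)
  } else if (config$species_assignment == "multinomial") {
    sample(species_pool, n_arms, replace = TRUE, prob = prob)
  } else {
    # largest-remainder quota, then random placement
    quota <- floor(prob * n_arms)
    rem <- prob * n_arms - quota
    extra <- order(rem, decreasing = TRUE)[seq_len(n_arms - sum(quota))]
    quota[extra] <- quota[extra] + 1
    sample(rep(species_pool, quota))
  }
  arms <- tibble::tibble(
    arm_id = seq_len(n_arms),
    backbone = rep(seq_len(config$n_backbones), each = n_sites),
    site = rep(seq_len(n_sites), config$n_backbones),
    species = species
  )
  arms$n_beads <- vapply(arms$species,
                         function(s) as.integer(config$arm_specs[[s]]$n_beads),
                         integer(1))
  phi <- stats::runif(n_arms, 0, 2 * pi)
  r_anchor <- config$backbone_radius + config$bead_diameter / 2
  bb <- config$backbone_xy[arms$backbone, , drop = FALSE]
  anchors <- cbind(bb[, 1] + r_anchor * cos(phi),
                   bb[, 2] + r_anchor * sin(phi),
                   (arms$site - 1) * config$site_spacing)
  outward <- cbind(cos(phi), sin(phi), 0)
  coords <- .build_arms_cpp(anchors, outward, as.integer(arms$n_beads),
                            .brush_params(config), 80L)
  beads <- tibble::tibble(
    arm_id = rep(arms$arm_id, arms$n_beads),
    bead_index = unlist(lapply(arms$n_beads, seq_len)),
    charge = unlist(lapply(arms$species, .arm_charges, config = config))
  )
  beads$mobile <- beads$bead_index > 1L
  state <- structure(list(coords = coords, beads = beads, arms = arms,
                          config = config, energy = NA_real_),
                     class = "brush_state")
  state$energy <- total_energy(state)
  state
}

#' @export
print.brush_state <- function(x, ...) {
  cat(sprintf("brush_state: %d arms (%d beads) on %d backbone(s), E = %.4g kBT\n",
              nrow(x$arms), nrow(x$coords), x$config$n_backbones, x$energy))
  invisible(x)
}

#' Screened-Coulomb pair energy between two beads
#'
#' Hard core below the bead diameter, Debye-Hueckel screened Coulomb
#' `l_B z_i z_j exp(-kappa r) / r` beyond it, in units of kBT. This is the
#' exact (uncut) pair law; the simulation core additionally truncates it at
#' `config$cutoff`.
#'
#' @param r Separation(s), nm (> 0).
#' @param z_i,z_j Bead charges (elementary charge units).
#' @param config A [brush_config()] supplying the Bjerrum length, inverse
#'   Debye length and bead diameter.
#' @return Energy in kBT (`Inf` inside the hard core).
#' @export
#' @examples
#' cfg <- brush_config(arm_specs = sidearm_specs())
#' pair_energy(1 / cfg$kappa, -1, -1, cfg)
pair_energy <- function(r, z_i, z_j, config) {
  stopifnot(all(r > 0))
  e <- config$bjerrum_length * z_i * z_j * exp(-config$kappa * r) / r
  ifelse(config$excluded_volume & r < config$bead_diameter, Inf, e)
}

#' Total configurational energy of a brush state
#'
#' Sum of the truncated screened-Coulomb pair energy over all non-bonded
#' bead pairs under the minimum-image convention, plus hard-core exclusion
#' against the backbone cylinders. Finite iff the state contains no overlap.
#'
#' @param state A `brush_state`.
#' @return Energy in kBT.
#' @export
total_energy <- function(state) {
  .total_energy_cpp(state$coords,
                    as.integer(state$beads$arm_id - 1L),
                    as.integer(state$beads$bead_index - 1L),
                    state$beads$charge,
                    .brush_params(state$config))
}

#' Run Metropolis Monte Carlo sweeps on a brush state
#'
#' One sweep attempts one move per mobile bead: a crankshaft rotation about
#' the axis through the flanking beads for interior beads and a uniform
#' re-orientation on the bond sphere for terminal beads, each accepted with
#' probability `min(1, exp(-dE))`. Grafted first beads never move; bond
#' lengths are preserved exactly.
#'
#' @param state A `brush_state`.
#' @param sweeps Number of sweeps.
#' @param sample_every If > 0, record per-arm radii of gyration and the
#'   running energy every this many sweeps.
#' @return The updated `brush_state`; recorded samples are attached as
#'   `attr(, "samples")` (tibble `sweep`, `arm_id`, `species`, `rg`),
#'   energies as `attr(, "energy_trace")`, and move counts as
#'   `attr(, "moves")`.
#' @export
mc_run <- function(state, sweeps, sample_every = 0L) {
  res <- .mc_run_cpp(state$coords,
                     as.integer(state$beads$arm_id - 1L),
                     as.integer(state$beads$bead_index - 1L),
                     state$beads$charge,
                     .brush_params(state$config),
                     as.integer(sweeps), as.integer(sample_every))
  state$coords <- res$coords
  state$energy <- res$energy
  if (sample_every > 0 && length(res$sample_sweeps)) {
    samples <- tibble::tibble(
      sweep = rep(res$sample_sweeps, each = nrow(state$arms)),
      arm_id = rep(state$arms$arm_id, length(res$sample_sweeps)),
      species = rep(state$arms$species, length(res$sample_sweeps)),
      rg = as.vector(t(res$rg))
    )
    attr(state, "samples") <- samples
    attr(state, "energy_trace") <- tibble::tibble(
      sweep = res$sample_sweeps, energy = res$energy_samples)
  }
  attr(state, "moves") <- c(attempted = res$attempted, accepted = res$accepted)
  state
}

#' @rdname mc_run
#' @export
mc_sweep <- function(state) mc_run(state, 1L)

#' Radius of gyration of a bead chain
#'
#' Root-mean-square distance of the beads from their centroid. Coordinates
#' must be unwrapped (the simulation keeps arms unwrapped internally).
#'
#' @param coords n x 3 coordinate matrix (n >= 2).
#' @return Radius of gyration in the coordinate units.
#' @export
#' @examples
#' radius_of_gyration(cbind(c(0, 0.6, 1.2), 0, 0))
radius_of_gyration <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2) abort("need at least 2 beads",
                              class = "nfstoich_domain_error")
  centred <- sweep(coords, 2, colMeans(coords))
  sqrt(mean(rowSums(centred^2)))
}

#' Run a full brush simulation and summarize radii of gyration
#'
#' Builds the system, equilibrates for `sweeps_equil`, then samples per-arm
#' radii of gyration every `sample_every` sweeps over `sweeps_prod`
#' production sweeps. Fully reproducible under `config$seed`. Warns if the
#' arm-averaged radius of gyration still drifts monotonically over the last
#' half of production (non-equilibration diagnostic).
#'
#' @param config A [brush_config()].
#' @param label Optional mixture label stored in the outputs (e.g.
#'   `"control"` or `"ALS"`).
#' @return Object of class `brush_result`: list with `summary` (tibble
#'   `species`, `phospho`, `mixture`, `mean_rg`, `sd_rg`, `n_samples`,
#'   `n_arms`), `samples` (per-arm per-sweep tibble), `state`, `config`.
#' @export
run_brush_simulation <- function(config, label = NA_character_) {
  state <- build_brush(config)
  state <- mc_run(state, config$sweeps_equil, 0L)
  state <- mc_run(state, config$sweeps_prod, config$sample_every)
  samples <- attr(state, "samples")
  if (is.null(samples)) {
    abort("production run produced no samples; check sweeps_prod/sample_every",
          class = "nfstoich_config_error")
  }
  samples$phospho <- config$phosphorylated
  samples$mixture <- label
  trace <- samples %>%
    group_by(.data$sweep) %>% summarise(rg = mean(.data$rg), .groups = "drop")
  last_half <- trace[trace$sweep > max(trace$sweep) / 2, ]
  if (nrow(last_half) >= 8) {
    rho <- suppressWarnings(stats::cor(last_half$sweep, last_half$rg,
                                       method = "spearman"))
    if (is.finite(rho) && abs(rho) > 0.8) {
      warn("radius of gyration still drifts over the last half of production; consider more equilibration sweeps")
    }
  }
  summary <- samples %>%
    group_by(.data$species, .data$phospho, .data$mixture) %>%
    summarise(mean_rg = mean(.data$rg), sd_rg = sd(.data$rg),
              n_samples = dplyr::n(), .groups = "drop") %>%
    left_join(dplyr::count(dplyr::distinct(samples, .data$arm_id,
                                           .data$species),
                           .data$species, name = "n_arms"),
              by = "species")
  structure(list(summary = summary, samples = samples,
                 state = state, config = config),
            class = "brush_result")
}

#' @export
print.brush_result <- function(x, ...) {
  cat("brush_result\n")
  print(x$summary)
  invisible(x)
}

#' Omnibus GLM and planned contrasts on radius-of-gyration samples
#'
#' Runs a one-way fixed-effects ANOVA across all species x phosphorylation
#' x mixture cells, then — only if the omnibus test is significant — the
#' planned mixture contrasts (one per species x phosphorylation combination)
#' as Welch t tests at the Bonferroni-corrected threshold `alpha / m`.
#'
#' @param samples Tibble with columns `species`, `phospho`, `mixture`, `rg`
#'   (e.g. row-bound `samples` from two [run_brush_simulation()] results).
#' @param alpha Family-wise significance level.
#' @return List of class `gyration_contrasts` with elements `omnibus`
#'   (tibble: test, statistic, df1, df2, p_value) and `posthoc` (tibble:
#'   contrast, statistic, p_value, alpha_corrected, significant).
#' @export
gyration_contrasts <- function(samples, alpha = 0.05) {
  samples$cell <- interaction(samples$species, samples$phospho,
                              samples$mixture, drop = TRUE)
  if (any(table(samples$cell) < 2)) {
    abort("every cell needs at least 2 samples", class = "nfstoich_domain_error")
  }
  fit <- stats::aov(rg ~ cell, data = samples)
  an <- stats::anova(fit)
  omnibus <- tibble::tibble(
    test = "one-way GLM (ANOVA)",
    statistic = an$`F value`[1],
    df1 = an$Df[1], df2 = an$Df[2],
    p_value = an$`Pr(>F)`[1]
  )
  pairs <- dplyr::distinct(samples, .data$species, .data$phospho)
  mixtures <- unique(samples$mixture)
  posthoc <- tibble::tibble()
  if (length(mixtures) == 2 && omnibus$p_value < alpha) {
    m <- nrow(pairs)
    thr <- bonferroni_threshold(alpha, m)
    posthoc <- purrr::pmap(pairs, function(species, phospho) {
      a <- samples$rg[samples$species == species & samples$phospho == phospho &
                        samples$mixture == mixtures[1]]
      b <- samples$rg[samples$species == species & samples$phospho == phospho &
                        samples$mixture == mixtures[2]]
      if (length(a) < 2 || length(b) < 2) {
        warn(sprintf("contrast for %s skipped: too few samples in one mixture",
                     species))
        return(NULL)
      }
      tt <- stats::t.test(a, b)
      tibble::tibble(
        contrast = sprintf("%s%s: %s vs %s", species,
                           if (phospho) " (phospho)" else "",
                           mixtures[1], mixtures[2]),
        statistic = unname(tt$statistic),
        p_value = tt$p.value,
        alpha_corrected = thr,
        significant = tt$p.value < thr
      )
    }) %>% bind_rows()
  }
  structure(list(omnibus = omnibus, posthoc = posthoc, alpha = alpha),
            class = "gyration_contrasts")
}

#' @export
print.gyration_contrasts <- function(x, ...) {
  cat("Omnibus:\n"); print(x$omnibus)
  if (nrow(x$posthoc)) { cat("Planned contrasts:\n"); print(x$posthoc) }
  invisible(x)
}

#' Write a plain-text trajectory snapshot
#'
#' One bead per line: `arm_id bead_index x y z` (nm, unwrapped), preceded by
#' a count header — an XYZ-like format readable by any text tool.
#'
#' @param state A `brush_state`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(state, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(state$coords)), con)
  writeLines(sprintf("%d %d %.6f %.6f %.6f",
                     state$beads$arm_id, state$beads$bead_index,
                     state$coords[, 1], state$coords[, 2], state$coords[, 3]),
             con)
  invisible(path)
}
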