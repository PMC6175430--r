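#' Configuration of the end-to-end analysis pipeline
#'
#' @param seed Global integer seed; every stochastic stage derives its own
#'   sub-seed via [stage_seed()], so stages never share a random stream.
#' @param stages Character subset of
#'   `c("simulate", "calibrate", "cost", "brush", "stats")` to run, in the
#'   fixed order simulate -> calibrate -> cost -> brush -> stats.
#' @param input_csv Cohort CSV to read when the simulate stage is disabled.
#' @param cohort Named list of overrides passed to [cohort_config()].
#' @param nfh_mode NfH channel combination, see [combine_nfh()].
#' @param anchor Luxury counterfactual anchoring, see
#'   [luxury_counterfactual()].
#' @param brush Named list of overrides for the brush stage:
#'   [brush_config()] arguments plus `length_scale` (arm rescale factor for
#'   [scale_sidearms()], default 0.25).
#' @param out_dir Directory for the JSON report and CSV artifacts (`NULL`
#'   writes nothing).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            stages = c("simulate", "calibrate", "cost",
                                       "brush", "stats"),
                            input_csv = NULL,
                            cohort = list(),
                            nfh_mode = "smi35_only",
                            anchor = "max",
                            brush = list(),
                            out_dir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  brush_defaults <- list(length_scale = 0.25, n_backbones = 1,
                         sweeps_equil = 200L, sweeps_prod = 400L,
                         sample_every = 20L,
                         species_assignment = "proportional")
  structure(list(
    seed = as.integer(seed), stages = stages, input_csv = input_csv,
    cohort = cohort, nfh_mode = nfh_mode, anchor = anchor,
    brush = utils::modifyList(brush_defaults, brush),
    out_dir = out_dir
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat keys mirror the [pipeline_config()] arguments; `seed` is a top-level
#' key.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  keep <- intersect(names(raw), names(formals(pipeline_config)))
  do.call(pipeline_config, raw[keep])
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in order: cohort simulation (or CSV input),
#' particle conversion and one-point stoichiometric calibration, translation
#' cost table, brush Monte Carlo at the control and measured ALS mixtures,
#' and the cohort statistics. Every stage is seeded from the global seed, so
#' the report is fully reproducible.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_report` with elements per executed
#'   stage plus a `constants` echo and the `settings` in effect; written as
#'   `report.json` (and cohort/profile CSVs) under `out_dir` when set.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(
    constants = c(nf_constants(),
                  list(isoforms = nf_isoforms(),
                       targets_physiological = as.list(nf_targets()),
                       targets_adaptive = as.list(nf_targets(adaptive = TRUE)))),
    settings = list(seed = config$seed, stages = config$stages,
                    nfh_mode = config$nfh_mode, anchor = config$anchor,
                    brush = config$brush[setdiff(names(config$brush), "arm_specs")])
  )
  on <- function(s) s %in% config$stages

  cohort <- NULL
  if (on("simulate")) {
    cc <- do.call(cohort_config,
                  utils::modifyList(list(seed = stage_seed(config$seed, "simulate")),
                                    config$cohort))
    cohort <- generate_cohort(cc)
    report$cohort_n <- as.list(table(cohort$group))
  } else if (!is.null(config$input_csv)) {
    if (!file.exists(config$input_csv)) {
      abort(paste0("input CSV not found: ", config$input_csv),
            class = "nfstoich_io_error")
    }
    cohort <- read_cohort_csv(config$input_csv)
  }

  profiles <- NULL
  if (on("calibrate")) {
    if (is.null(cohort)) {
      abort("calibrate stage needs a cohort (enable simulate or set input_csv)",
            class = "nfstoich_io_error")
    }
    raw <- particle_profiles(cohort, nfh_mode = config$nfh_mode)
    calib <- calibration_factors(raw)
    profiles <- apply_calibration(raw, calib)
    stoich <- cohort_stoichiometry(profiles)
    report$calibration <- list(
      factors = as.list(calib$factors),
      control_medians = as.list(calib$control_medians),
      stoichiometry = stoich
    )
  }

  if (on("cost")) {
    if (is.null(profiles)) abort("cost stage needs calibrated profiles",
                                 class = "nfstoich_io_error")
    report$cost <- cohort_cost_table(profiles, anchor = config$anchor)
  }

  if (on("brush")) {
    stoich_ctrl <- nf_targets()
    stoich_als <- if (!is.null(report$calibration)) {
      st <- report$calibration$stoichiometry
      row <- st[st$group != "control", ]
      if (nrow(row)) c(NfL = row$nfl[1], NfM = row$nfm[1], NfH = row$nfh[1])
      else nf_targets(adaptive = TRUE)
    } else nf_targets(adaptive = TRUE)
    bargs <- config$brush
    ls <- bargs$length_scale %||% 1
    bargs$length_scale <- NULL
    if (is.null(bargs$arm_specs)) {
      bargs$arm_specs <- if (ls < 1) scale_sidearms(sidearm_specs(), ls)
                         else sidearm_specs()
    }
    run_mix <- function(stoich, label, tag) {
      cfg <- do.call(brush_config,
                     utils::modifyList(bargs,
                       list(stoichiometry = stoich,
                            seed = stage_seed(config$seed, paste0("brush_", tag)))))
      run_brush_simulation(cfg, label = label)
    }
    ctrl_res <- run_mix(stoich_ctrl, "control", "control")
    als_res <- run_mix(stoich_als, "ALS", "als")
    contrasts <- gyration_contrasts(bind_rows(ctrl_res$samples, als_res$samples))
    report$brush <- list(
      summary = bind_rows(ctrl_res$summary, als_res$summary),
      omnibus = contrasts$omnibus,
      posthoc = contrasts$posthoc
    )
  }

  if (on("stats")) {
    if (is.null(profiles)) abort("stats stage needs calibrated profiles",
                                 class = "nfstoich_io_error")
    costs <- scenario_costs(profiles, anchor = config$anchor)
    scen <- multi_group_glm(costs$atp_total, costs$scenario, posthoc_m = 3)
    report$stats <- list(
      scenario_atp = list(omnibus = scen$omnibus, posthoc = scen$posthoc)
    )
    if (on("simulate") || !is.null(cohort$alsfrs_baseline)) {
      assoc <- tryCatch(progression_association(profiles, cohort),
                        error = function(e) NULL)
      if (!is.null(assoc)) {
        report$stats$progression <- select(assoc, -"posthoc")
      }
    }
  }

  report <- structure(report, class = "pipeline_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(cohort)) write_cohort_csv(cohort, file.path(config$out_dir, "cohort.csv"))
    if (!is.null(profiles)) readr::write_csv(profiles, file.path(config$out_dir, "profiles.csv"))
    jsonlite::write_json(unclass(report), file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report with stages:",
      paste(intersect(c("cohort_n", "calibration", "cost", "brush", "stats"),
                      names(x)), collapse = ", "), "\n")
  if (!is.null(x$calibration)) {
    cat("cohort stoichiometry (medians of calibrated counts):\n")
    print(x$calibration$stoichiometry)
  }
  invisible(x)
}
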