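#' Configuration for the synthetic plasma-neurofilament cohort generator
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: right-skewed (log-normal) per-assay plasma concentrations whose
#' group medians encode a chosen underlying particle-count stoichiometry,
#' per-assay multiplicative calibrator distortions (the systematic error that
#' one-point stoichiometric calibration removes), and ALS clinimetrics
#' (ALSFRS-r scores, onset sites and visit dates) from which progression
#' rates derive.
#'
#' Default group medians are derived from underlying particle-count medians
#' `target x particle_scale`: physiological 7:3:2 for controls and adaptive
#' 24:2.4:1.6 for ALS, at `particle_scale = 2.5e10` particles/L. This puts
#' the control NfL median near 20 pg/mL and the ALS median near 68 pg/mL,
#' typical of plasma measurements in this disease. Both NfH assays report
#' the same underlying NfH particle pool (they differ only in calibrator
#' molar mass and assay scale).
#'
#' @param n_control,n_als Group sizes (each >= 3).
#' @param particle_scale Particles/L corresponding to one stoichiometric
#'   share unit; sets the default concentration medians.
#' @param conc_median Optional list with elements `control` and `als`, each a
#'   named numeric vector over assays `c(nfl, nfm, nfh_smi35, nfh_smi34)` of
#'   true median concentrations in g/L (before assay distortion). Overrides
#'   the particle-scale defaults.
#' @param conc_log_sd Named numeric vector of natural-log standard deviations
#'   per assay (>= 0).
#' @param assay_scale Named numeric vector of per-assay multiplicative
#'   calibrator distortion factors (> 0); defaults reproduce raw assay
#'   outputs that do not sit at 7:3:2.
#' @param sampling `"stratified"` draws each group x assay sample by
#'   inverse-CDF on a randomly permuted mid-quantile grid, so realized
#'   cohort quantiles (in particular the median) match the configured
#'   distribution; `"iid"` draws independent log-normals.
#' @param clinimetrics List of ALS clinimetric parameters:
#'   `alsfrs_mean`, `alsfrs_sd` (baseline ALSFRS-r), `onset_probs` (named
#'   bulbar/limb/both), `months_meanlog`, `months_sdlog` (onset-to-baseline),
#'   `followup_months` (baseline-to-last-visit interval).
#' @param seed Integer seed; fully determines the generated cohort.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 29L,
                          n_als = 60L,
                          particle_scale = 2.5e10,
                          conc_median = NULL,
                          conc_log_sd = c(nfl = 0.5, nfm = 0.5,
                                          nfh_smi35 = 0.5, nfh_smi34 = 0.5),
                          assay_scale = c(nfl = 1.0, nfm = 0.35,
                                          nfh_smi35 = 2.0, nfh_smi34 = 2.0),
                          sampling = c("stratified", "iid"),
                          clinimetrics = list(),
                          seed = 1L) {
  sampling <- match.arg(sampling)
  if (n_control < 3 || n_als < 3) {
    abort("group sizes must be at least 3", class = "nfstoich_config_error")
  }
  if (any(conc_log_sd < 0)) {
    abort("conc_log_sd must be non-negative", class = "nfstoich_config_error")
  }
  if (any(assay_scale <= 0) || particle_scale <= 0) {
    abort("scales must be strictly positive", class = "nfstoich_config_error")
  }
  if (is.null(conc_median)) {
    conc_median <- list(
      control = .shares_to_conc(nf_targets(adaptive = FALSE), particle_scale),
      als     = .shares_to_conc(nf_targets(adaptive = TRUE), particle_scale)
    )
  }
  for (g in c("control", "als")) {
    if (any(conc_median[[g]] <= 0)) {
      abort("concentration medians must be strictly positive",
            class = "nfstoich_config_error")
    }
  }
  clin <- utils::modifyList(list(
    alsfrs_mean = 34, alsfrs_sd = 6.5,
    onset_probs = c(bulbar = 0.25, limb = 0.73, both = 0.02),
    months_meanlog = log(15), months_sdlog = 0.6,
    followup_months = 6
  ), clinimetrics)
  structure(list(
    n_control = as.integer(n_control), n_als = as.integer(n_als),
    particle_scale = particle_scale,
    conc_median = conc_median, conc_log_sd = conc_log_sd,
    assay_scale = assay_scale, sampling = sampling,
    clinimetrics = clin, seed = as.integer(seed)
  ), class = "cohort_config")
}

# median particle counts per combined channel -> true g/L medians per assay;
# both NfH assays see the same NfH particle pool
.shares_to_conc <- function(shares, particle_scale) {
  spec <- nf_isoforms()
  counts <- shares[spec$isoform] * particle_scale
  conc <- counts * spec$molar_mass / nf_constants()$avogadro
  stats::setNames(as.numeric(conc), tolower(spec$assay))
}

# one group x assay sample; median of the law is `med` (before assay scale)
.draw_lognormal <- function(n, med, log_sd, scale, sampling) {
  if (log_sd == 0) return(rep(med * scale, n))
  x <- switch(sampling,
    iid = stats::rlnorm(n, meanlog = log(med), sdlog = log_sd),
    stratified = {
      p <- (seq_len(n) - stats::runif(n)) / n  # jittered stratified quantiles
      sample(stats::qlnorm(sort(p), meanlog = log(med), sdlog = log_sd))
    }
  )
  x * scale
}

#' Generate a synthetic control + ALS cohort
#'
#' Draws per-subject plasma concentrations for the four neurofilament assays
#' (NfL, NfM, NfH-SMI35, NfH-SMI34) from right-skewed log-normal laws with
#' the configured group medians, applies the per-assay calibrator distortion,
#' and samples ALS clinimetrics. Controls carry no onset or ALSFRS-r fields.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per subject and columns `subject_id`,
#'   `group` ("control"/"ALS"), `conc_nfl`, `conc_nfm`, `conc_nfh_smi35`,
#'   `conc_nfh_smi34` (g/L), `onset_site`, `alsfrs_baseline`,
#'   `alsfrs_followup`, `months_onset_to_baseline`,
#'   `months_onset_to_last_visit`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 7))
#' dplyr::count(cohort, group)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  assays <- c("nfl", "nfm", "nfh_smi35", "nfh_smi34")
  draw_group <- function(n, group_key) {
    purrr::map(assays, function(a) {
      .draw_lognormal(n, config$conc_median[[group_key]][[a]],
                      config$conc_log_sd[[a]], config$assay_scale[[a]],
                      config$sampling)
    }) %>% stats::setNames(paste0("conc_", assays)) %>% tibble::as_tibble()
  }
  ctrl <- draw_group(config$n_control, "control") %>%
    mutate(group = "control", .before = 1)
  als <- draw_group(config$n_als, "als") %>%
    mutate(group = "ALS", .before = 1)

  clin <- config$clinimetrics
  n_als <- config$n_als
  als$onset_site <- sample(names(clin$onset_probs), n_als, replace = TRUE,
                           prob = clin$onset_probs)
  als$alsfrs_baseline <- pmin(48L, pmax(0L,
    as.integer(round(stats::rnorm(n_als, clin$alsfrs_mean, clin$alsfrs_sd)))))
  als$months_onset_to_baseline <-
    stats::rlnorm(n_als, clin$months_meanlog, clin$months_sdlog)
  als$months_onset_to_last_visit <-
    als$months_onset_to_baseline + clin$followup_months
  rate <- progression_rate(als$alsfrs_baseline, als$months_onset_to_baseline)
  decline <- stats::rpois(n_als, lambda = rate * clin$followup_months)
  als$alsfrs_followup <- pmax(0L, als$alsfrs_baseline - decline)

  ctrl$onset_site <- "none"
  ctrl$alsfrs_baseline <- NA_integer_
  ctrl$alsfrs_followup <- NA_integer_
  ctrl$months_onset_to_baseline <- NA_real_
  ctrl$months_onset_to_last_visit <- NA_real_

  out <- bind_rows(ctrl, als)
  out$subject_id <- sprintf("S%03d", seq_len(nrow(out)))
  dplyr::relocate(out, "subject_id")
}

#' ALS disease progression rate in ALSFRS-r points per month
#'
#' Defined as (48 - ALSFRS-r score) divided by disease duration in months.
#'
#' @param alsfrs Integer ALSFRS-r score(s), 0-48.
#' @param months Disease duration(s) in months, > 0.
#' @return Non-negative progression rate(s), points/month.
#' @export
#' @examples
#' progression_rate(34, 17)
progression_rate <- function(alsfrs, months) {
  if (any(alsfrs < 0 | alsfrs > 48, na.rm = TRUE)) {
    abort("ALSFRS-r scores must lie in [0, 48]", class = "nfstoich_domain_error")
  }
  if (any(months <= 0, na.rm = TRUE)) {
    abort("disease duration must be positive", class = "nfstoich_domain_error")
  }
  (48 - alsfrs) / months
}

#' Categorize a progression rate as slow, intermediate or fast
#'
#' Slow below 0.5 points/month, intermediate for 0.5-1.0 inclusive, fast
#' above 1.0.
#'
#' @param rate Non-negative progression rate(s) in points/month.
#' @return Character vector of `"slow"`, `"intermediate"`, `"fast"`.
#' @export
progression_category <- function(rate) {
  if (any(rate < 0, na.rm = TRUE)) {
    abort("progression rate cannot be negative", class = "nfstoich_domain_error")
  }
  dplyr::case_when(
    rate < 0.5 ~ "slow",
    rate <= 1.0 ~ "intermediate",
    TRUE ~ "fast"
  )
}

#' Disease stage from a baseline ALSFRS-r score
#'
#' Early for scores 40-48, intermediate for 25-39, late for 24 and below.
#'
#' @param alsfrs Integer ALSFRS-r score(s), 0-48.
#' @return Character vector of `"early"`, `"intermediate"`, `"late"`.
#' @export
disease_stage <- function(alsfrs) {
  if (any(alsfrs < 0 | alsfrs > 48, na.rm = TRUE)) {
    abort("ALSFRS-r scores must lie in [0, 48]", class = "nfstoich_domain_error")
  }
  dplyr::case_when(
    alsfrs >= 40 ~ "early",
    alsfrs >= 25 ~ "intermediate",
    TRUE ~ "late"
  )
}

#' Write / read a cohort as CSV
#'
#' Concentrations are written in g/L (scientific notation allowed).
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param path File path.
#' @return `write_cohort_csv()` returns `path` invisibly; `read_cohort_csv()`
#'   returns the cohort tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    subject_id = readr::col_character(),
                    group = readr::col_character(),
                    onset_site = readr::col_character(),
                    alsfrs_baseline = readr::col_integer(),
                    alsfrs_followup = readr::col_integer(),
                    .default = readr::col_double()
                  ))
}
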