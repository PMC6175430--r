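#' Convert a mass concentration to molarity
#'
#' Divides a concentration in g/L by the isoform molar mass (Da treated as
#' g/mol).
#'
#' @param conc Non-negative concentration(s), g/L.
#' @param molar_mass Molar mass in g/mol, or an assay name from
#'   [nf_isoforms()] (`"NfL"`, `"NfM"`, `"NfH_SMI35"`, `"NfH_SMI34"`).
#' @return Molarity in mol/L.
#' @export
#' @examples
#' to_molarity(6.8e-11, "NfL")
to_molarity <- function(conc, molar_mass) {
  if (is.character(molar_mass)) {
    spec <- nf_isoforms()
    i <- match(molar_mass, spec$assay)
    if (anyNA(i)) abort("unknown assay name", class = "nfstoich_domain_error")
    molar_mass <- spec$molar_mass[i]
  }
  if (any(conc < 0, na.rm = TRUE)) {
    abort("concentrations cannot be negative", class = "nfstoich_domain_error")
  }
  stopifnot(all(molar_mass > 0))
  conc / molar_mass
}

#' Convert molarity to a particle count per litre
#'
#' @param molarity Non-negative molarity, mol/L.
#' @return Particles per litre (molarity times Avogadro's number).
#' @export
to_particles <- function(molarity) {
  if (any(molarity < 0, na.rm = TRUE)) {
    abort("molarity cannot be negative", class = "nfstoich_domain_error")
  }
  molarity * nf_constants()$avogadro
}

#' Combine the two NfH phosphoform assays into one NfH channel
#'
#' @param smi35,smi34 Non-negative particle counts from the SMI35 and SMI34
#'   assays.
#' @param mode `"smi35_only"` (default), `"smi34_only"` or `"sum"`.
#' @return Combined NfH particle count(s).
#' @export
combine_nfh <- function(smi35, smi34, mode = c("smi35_only", "sum", "smi34_only")) {
  mode <- match.arg(mode)
  pick <- switch(mode,
    sum = smi35 + smi34,
    smi35_only = smi35,
    smi34_only = smi34
  )
  if (all(is.na(pick))) {
    abort("no NfH data available in the requested channel",
          class = "nfstoich_missing_data_error")
  }
  if (any(pick < 0, na.rm = TRUE)) {
    abort("particle counts cannot be negative", class = "nfstoich_domain_error")
  }
  pick
}

#' Per-subject particle profiles from a concentration cohort
#'
#' Converts each assay concentration to molarity and then to particles per
#' litre, and combines the two NfH assays into a single NfH channel.
#'
#' @param cohort Cohort tibble with columns `subject_id`, `group` and
#'   `conc_nfl`, `conc_nfm`, `conc_nfh_smi35`, `conc_nfh_smi34`.
#' @param nfh_mode NfH channel combination, see [combine_nfh()].
#' @param unit Input unit of the concentration columns; `"pg_per_ml"`
#'   applies the factor 1e-9 to reach g/L.
#' @return Tibble `subject_id`, `group`, `nfl`, `nfm`, `nfh` (particles/L),
#'   `calibrated = FALSE`.
#' @export
#' @examples
#' generate_cohort(cohort_config(seed = 1)) |> particle_profiles()
particle_profiles <- function(cohort,
                              nfh_mode = c("smi35_only", "sum", "smi34_only"),
                              unit = c("g_per_l", "pg_per_ml")) {
  nfh_mode <- match.arg(nfh_mode)
  unit <- match.arg(unit)
  u <- if (unit == "pg_per_ml") 1e-9 else 1
  tibble::tibble(
    subject_id = cohort$subject_id,
    group = cohort$group,
    nfl = to_particles(to_molarity(cohort$conc_nfl * u, "NfL")),
    nfm = to_particles(to_molarity(cohort$conc_nfm * u, "NfM")),
    nfh = combine_nfh(
      to_particles(to_molarity(cohort$conc_nfh_smi35 * u, "NfH_SMI35")),
      to_particles(to_molarity(cohort$conc_nfh_smi34 * u, "NfH_SMI34")),
      mode = nfh_mode
    ),
    calibrated = FALSE
  )
}

#' One-point stoichiometric calibration factors from control medians
#'
#' Computes the per-channel correction factors `x = 7 / median(NfL)`,
#' `y = 3 / median(NfM)`, `z = 2 / median(NfH)` from the control-group
#' particle-count medians, so that the calibrated control medians land
#' exactly on the physiological target stoichiometry. The sample median is
#' the standard one (mean of the two middle order statistics for even n).
#'
#' @param profiles Particle-profile tibble from [particle_profiles()]; rows
#'   with `group == control_group` are used.
#' @param targets Target stoichiometry, default physiological 7:3:2.
#' @param control_group Label of the control group.
#' @return An object of class `nf_calibration` with elements `factors`
#'   (named `x`, `y`, `z`), `control_medians` and `targets`.
#' @export
calibration_factors <- function(profiles, targets = nf_targets(),
                                control_group = "control") {
  ctrl <- dplyr::filter(profiles, .data$group == control_group)
  if (nrow(ctrl) < 3) {
    abort("need at least 3 control profiles", class = "nfstoich_domain_error")
  }
  med <- c(NfL = median(ctrl$nfl), NfM = median(ctrl$nfm), NfH = median(ctrl$nfh))
  if (any(med <= 0) || any(!is.finite(med))) {
    abort("control medians must be strictly positive and finite",
          class = "nfstoich_calibration_error")
  }
  structure(list(
    factors = c(x = unname(targets["NfL"] / med["NfL"]),
                y = unname(targets["NfM"] / med["NfM"]),
                z = unname(targets["NfH"] / med["NfH"])),
    control_medians = med,
    targets = targets
  ), class = "nf_calibration")
}

#' @export
print.nf_calibration <- function(x, ...) {
  cat("One-point stoichiometric calibration\n")
  cat(sprintf("  targets (NfL:NfM:NfH): %s\n",
              paste(signif(x$targets, 4), collapse = ":")))
  cat(sprintf("  factors x, y, z: %s\n",
              paste(signif(x$factors, 6), collapse = ", ")))
  invisible(x)
}

#' Apply calibration factors to particle profiles
#'
#' Multiplies the NfL, NfM and NfH channels componentwise by the factors
#' `x`, `y`, `z`; the resulting counts are dimensionless stoichiometric
#' shares. Refuses to calibrate twice.
#'
#' @param profiles Uncalibrated particle-profile tibble.
#' @param calibration An `nf_calibration` from [calibration_factors()], or a
#'   named numeric vector `c(x=, y=, z=)`.
#' @return The profile tibble with calibrated counts and `calibrated = TRUE`.
#' @export
apply_calibration <- function(profiles, calibration) {
  if (any(profiles$calibrated)) {
    abort("profiles are already calibrated", class = "nfstoich_state_error")
  }
  f <- if (inherits(calibration, "nf_calibration")) calibration$factors else calibration
  stopifnot(all(c("x", "y", "z") %in% names(f)))
  profiles %>%
    mutate(nfl = .data$nfl * f[["x"]],
           nfm = .data$nfm * f[["y"]],
           nfh = .data$nfh * f[["z"]],
           calibrated = TRUE)
}

#' Cohort stoichiometry: per-group medians of calibrated counts
#'
#' @param profiles Calibrated particle-profile tibble.
#' @return Tibble with one row per group and columns `group`, `nfl`, `nfm`,
#'   `nfh` holding the per-channel medians (no renormalization).
#' @export
cohort_stoichiometry <- function(profiles) {
  if (nrow(profiles) == 0) {
    abort("empty profile table", class = "nfstoich_domain_error")
  }
  if (!all(profiles$calibrated)) {
    abort("profiles must be calibrated first", class = "nfstoich_state_error")
  }
  profiles %>%
    group_by(.data$group) %>%
    summarise(across(c("nfl", "nfm", "nfh"), median), .groups = "drop")
}

#' Gaussian kernel density summary of a concentration or count sample
#'
#' @param values Numeric sample (length >= 2).
#' @param bandwidth Kernel bandwidth; `NULL` uses the default plug-in rule.
#' @return Tibble with columns `value` and `density`, evaluated on a regular
#'   grid spanning the data; the density integrates to ~1.
#' @export
density_summary <- function(values, bandwidth = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 2) {
    abort("need at least 2 finite values", class = "nfstoich_domain_error")
  }
  d <- if (is.null(bandwidth)) {
    stats::density(values, kernel = "gaussian")
  } else {
    stats::density(values, bw = bandwidth, kernel = "gaussian")
  }
  tibble::tibble(value = d$x, density = d$y)
}
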