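#' ATP cost of translating a particle profile
#'
#' Per isoform, the particle count is multiplied by the isoform's amino-acid
#' count and by the ATP cost per amino acid (default 5).
#'
#' @param profiles Particle-profile tibble with channels `nfl`, `nfm`, `nfh`
#'   (calibrated shares or raw counts; the cost is linear either way).
#' @param constants See [nf_constants()].
#' @param aa_counts Named amino-acid counts per channel.
#' @return The input tibble with columns `atp_nfl`, `atp_nfm`, `atp_nfh` and
#'   `atp_total` appended.
#' @export
#' @examples
#' profile_tbl(nfl = 7, nfm = 3, nfh = 2) |> atp_cost()
atp_cost <- function(profiles, constants = nf_constants(),
                     aa_counts = nf_aa_counts()) {
  .check_counts(profiles)
  profiles %>%
    mutate(
      atp_nfl = .data$nfl * aa_counts[["NfL"]] * constants$atp_per_aa,
      atp_nfm = .data$nfm * aa_counts[["NfM"]] * constants$atp_per_aa,
      atp_nfh = .data$nfh * aa_counts[["NfH"]] * constants$atp_per_aa,
      atp_total = .data$atp_nfl + .data$atp_nfm + .data$atp_nfh
    )
}

#' Translation time cost of a particle profile
#'
#' Per isoform, particle count times amino-acid count times the folding time
#' per amino acid (default 25 s per 100 amino acids).
#'
#' @inheritParams atp_cost
#' @return The input tibble with `time_s_nfl`, `time_s_nfm`, `time_s_nfh`,
#'   `time_s_total` and `time_h_total` (hours) appended.
#' @export
time_cost <- function(profiles, constants = nf_constants(),
                      aa_counts = nf_aa_counts()) {
  .check_counts(profiles)
  s_per_aa <- constants$seconds_per_100aa / 100
  profiles %>%
    mutate(
      time_s_nfl = .data$nfl * aa_counts[["NfL"]] * s_per_aa,
      time_s_nfm = .data$nfm * aa_counts[["NfM"]] * s_per_aa,
      time_s_nfh = .data$nfh * aa_counts[["NfH"]] * s_per_aa,
      time_s_total = .data$time_s_nfl + .data$time_s_nfm + .data$time_s_nfh,
      time_h_total = .data$time_s_total / 3600
    )
}

#' Build a one-row particle-profile tibble
#'
#' Convenience constructor for single profiles in examples and tests.
#'
#' @param nfl,nfm,nfh Channel counts.
#' @param subject_id,group,calibrated Metadata columns.
#' @return A one-row profile tibble.
#' @export
profile_tbl <- function(nfl, nfm, nfh, subject_id = "S001",
                        group = "ALS", calibrated = TRUE) {
  tibble::tibble(subject_id = subject_id, group = group,
                 nfl = nfl, nfm = nfm, nfh = nfh, calibrated = calibrated)
}

.check_counts <- function(profiles) {
  cols <- c("nfl", "nfm", "nfh")
  stopifnot(all(cols %in% names(profiles)))
  if (any(as.matrix(profiles[cols]) < 0, na.rm = TRUE)) {
    abort("particle counts cannot be negative", class = "nfstoich_domain_error")
  }
}

#' Luxury counterfactual: restore the physiological stoichiometry
#'
#' Returns, per subject, the unique profile proportional to the target
#' stoichiometry (7:3:2) in which no channel falls below its observed value:
#' with `anchor = "max"` (default) the scale is `s = max(nfl/7, nfm/3,
#' nfh/2)` and the output is `(7s, 3s, 2s)`. Maintaining the physiological
#' ratio is thus modelled as synthesizing more of the deficient subunits,
#' never discarding measured protein. Alternative anchors scale on NfL only
#' or preserve the total count.
#'
#' @param profiles Calibrated particle-profile tibble.
#' @param targets Target stoichiometry, default 7:3:2.
#' @param anchor `"max"` (componentwise dominance), `"nfl"` (match observed
#'   NfL) or `"total"` (match observed total count).
#' @return Profile tibble with channels replaced by the counterfactual.
#' @export
#' @examples
#' profile_tbl(nfl = 24, nfm = 2.4, nfh = 1.6) |> luxury_counterfactual()
luxury_counterfactual <- function(profiles, targets = nf_targets(),
                                  anchor = c("max", "nfl", "total")) {
  anchor <- match.arg(anchor)
  .check_counts(profiles)
  if (!all(profiles$calibrated)) {
    abort("luxury counterfactual is defined on calibrated profiles",
          class = "nfstoich_state_error")
  }
  t_l <- targets[["NfL"]]; t_m <- targets[["NfM"]]; t_h <- targets[["NfH"]]
  s <- switch(anchor,
    max = pmax(profiles$nfl / t_l, profiles$nfm / t_m, profiles$nfh / t_h),
    nfl = profiles$nfl / t_l,
    total = (profiles$nfl + profiles$nfm + profiles$nfh) / (t_l + t_m + t_h)
  )
  profiles %>%
    mutate(nfl = t_l * s, nfm = t_m * s, nfh = t_h * s)
}

#' Cohort translation-cost table across stoichiometry scenarios
#'
#' Summarizes total ATP and translation time per subject for the three
#' scenarios of interest: controls as observed, ALS as observed ("adaptive")
#' and ALS under the luxury 7:3:2 counterfactual (computed per subject, then
#' aggregated).
#'
#' @param profiles Calibrated particle-profile tibble containing both groups.
#' @param constants See [nf_constants()].
#' @param anchor Luxury anchoring rule, see [luxury_counterfactual()].
#' @param control_group,als_group Group labels.
#' @return Tibble with columns `scenario`, `group`, `n`, `atp_mean`,
#'   `atp_sd`, `time_h_mean`, `time_h_sd`.
#' @export
cohort_cost_table <- function(profiles, constants = nf_constants(),
                              anchor = "max",
                              control_group = "control", als_group = "ALS") {
  ctrl <- dplyr::filter(profiles, .data$group == control_group)
  als <- dplyr::filter(profiles, .data$group == als_group)
  if (nrow(ctrl) == 0 || nrow(als) == 0) {
    abort("cohort must contain both groups", class = "nfstoich_domain_error")
  }
  scen <- list(
    `control-adaptive` = ctrl,
    `ALS-adaptive` = als,
    `ALS-luxury` = luxury_counterfactual(als, anchor = anchor)
  )
  purrr::imap(scen, function(p, name) {
    costs <- p %>% atp_cost(constants) %>% time_cost(constants)
    tibble::tibble(
      scenario = name,
      group = if (name == "control-adaptive") control_group else als_group,
      n = nrow(costs),
      atp_mean = mean(costs$atp_total), atp_sd = sd(costs$atp_total),
      time_h_mean = mean(costs$time_h_total), time_h_sd = sd(costs$time_h_total)
    )
  }) %>% bind_rows()
}

#' Per-subject costs for all scenarios, long format
#'
#' Helper behind [cohort_cost_table()] exposed for statistics on per-subject
#' totals (e.g. scenario GLMs).
#'
#' @inheritParams cohort_cost_table
#' @return Tibble `subject_id`, `group`, `scenario`, `atp_total`,
#'   `time_h_total`.
#' @export
scenario_costs <- function(profiles, constants = nf_constants(),
                           anchor = "max",
                           control_group = "control", als_group = "ALS") {
  ctrl <- dplyr::filter(profiles, .data$group == control_group)
  als <- dplyr::filter(profiles, .data$group == als_group)
  scen <- list(
    `control-adaptive` = ctrl,
    `ALS-adaptive` = als,
    `ALS-luxury` = luxury_counterfactual(als, anchor = anchor)
  )
  purrr::imap(scen, function(p, name) {
    p %>% atp_cost(constants) %>% time_cost(constants) %>%
      mutate(scenario = name) %>%
      select("subject_id", "group", "scenario", "atp_total", "time_h_total")
  }) %>% bind_rows()
}
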