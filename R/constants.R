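#' Physical constants of the neurofilament isoforms
#'
#' Per-isoform molar masses, full-protein amino-acid counts and the
#' physiological stoichiometric target shares used throughout the package.
#' NfH is measured by two phosphoform-specific immunoassays (SMI35, SMI34)
#' with slightly different calibrator masses; both carry the same
#' amino-acid count because they detect the same gene product.
#'
#' @return A tibble with columns `assay`, `isoform`, `molar_mass` (g/mol),
#'   `aa_count` (amino acids) and `target_share` (physiological
#'   NfL:NfM:NfH = 7:3:2; `NA` for the individual NfH assay rows, which
#'   are combined into one NfH channel before calibration).
#' @export
#' @examples
#' nf_isoforms()
nf_isoforms <- function() {
  tibble::tibble(
    assay        = c("NfL", "NfM", "NfH_SMI35", "NfH_SMI34"),
    isoform      = c("NfL", "NfM", "NfH", "NfH"),
    molar_mass   = c(68000, 150000, 200000, 210000),
    aa_count     = c(543L, 916L, 1020L, 1020L),
    target_share = c(7, 3, 2, 2)
  )
}

#' Stoichiometric target shares per combined isoform channel
#'
#' @param adaptive If `TRUE`, return the adaptive (disease) stoichiometry
#'   24:2.4:1.6 instead of the physiological 7:3:2.
#' @return Named numeric vector `c(NfL=, NfM=, NfH=)`.
#' @export
nf_targets <- function(adaptive = FALSE) {
  if (adaptive) c(NfL = 24, NfM = 2.4, NfH = 1.6) else c(NfL = 7, NfM = 3, NfH = 2)
}

#' Model constants for particle conversion and translation costs
#'
#' @return Named list: `avogadro` (1/mol), `atp_per_aa` (ATP per amino acid
#'   incorporated during translation), `seconds_per_100aa` (seconds to fold
#'   a 100-amino-acid protein).
#' @export
nf_constants <- function() {
  list(
    avogadro          = 6.0221415e23,
    atp_per_aa        = 5,
    seconds_per_100aa = 25
  )
}

# per-isoform aa counts on the combined (NfL, NfM, NfH) channels
nf_aa_counts <- function() c(NfL = 543, NfM = 916, NfH = 1020)

#' Derive a reproducible stage-specific seed from a global seed
#'
#' Combines a global integer seed with a stage label by a fixed polynomial
#' string hash, so adding or reordering pipeline stages never perturbs the
#' random stream of another stage.
#'
#' @param seed Global integer seed.
#' @param stage Character stage label.
#' @return An integer in `[0, 2^31 - 1)` usable with [set.seed()].
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  m <- 2147483647
  h <- seed %% m
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% m
  as.integer(h)
}
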