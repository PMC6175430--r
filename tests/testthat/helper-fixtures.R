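library(dplyr, warn.conflicts = FALSE)

# small in-code fixtures shared across test files

# control profiles whose per-channel medians are exactly (nfl, nfm, nfh):
# three subjects at 0.5x, 1x and 2x the median profile
control_profiles_with_medians <- function(nfl, nfm, nfh) {
  tibble::tibble(
    subject_id = c("C1", "C2", "C3"),
    group = "control",
    nfl = nfl * c(0.5, 1, 2),
    nfm = nfm * c(0.5, 1, 2),
    nfh = nfh * c(0.5, 1, 2),
    calibrated = FALSE
  )
}

# brute-force Mann-Whitney U: discordant pair count with half ties
brute_force_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  u
}

# textbook one-way ANOVA F from scratch (between/within mean squares)
brute_force_anova_f <- function(groups) {
  all <- unlist(groups)
  k <- length(groups); n <- length(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - mean(all))^2, 1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  (ssb / (k - 1)) / (ssw / (n - k))
}

# minimal three-bead-per-arm specs for fast brush builds
tiny_specs <- function(n_beads = 3L, charge = 0) {
  sp <- lapply(c(NfL = "NfL", NfM = "NfM", NfH = "NfH"), function(s) {
    list(n_beads = as.integer(n_beads), charge = rep(charge, n_beads),
         phospho_sites = integer(0))
  })
  attr(sp, "phospho_charge") <- -2
  sp
}
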