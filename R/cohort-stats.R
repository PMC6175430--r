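#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise level in (0, 1).
#' @param m Number of comparisons (>= 1).
#' @return `alpha / m`, at full precision.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 6)
bonferroni_threshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1)
  if (m < 1) abort("m must be a positive integer", class = "nfstoich_domain_error")
  alpha / m
}

#' Two-group comparison: Welch t or Mann-Whitney U
#'
#' With `gaussian = NULL` each sample is screened with Shapiro-Wilk at
#' alpha = 0.05; the Welch t test is used when both pass, the two-tailed
#' Mann-Whitney U test otherwise.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @param gaussian Force the parametric (`TRUE`) or nonparametric (`FALSE`)
#'   branch, or `NULL` to screen.
#' @return One-row tibble: `test_name`, `statistic`, `df`, `p_value`.
#' @export
two_group_test <- function(x, y, gaussian = NULL) {
  if (length(x) < 2 || length(y) < 2) {
    abort("each sample needs at least 2 observations",
          class = "nfstoich_domain_error")
  }
  if (is.null(gaussian)) {
    sw <- function(v) {
      if (length(unique(v)) == 1) return(FALSE)
      stats::shapiro.test(v)$p.value > 0.05
    }
    gaussian <- sw(x) && sw(y)
  }
  if (gaussian) {
    tt <- stats::t.test(x, y)
    tibble::tibble(test_name = "Welch t", statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p_value = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    tibble::tibble(test_name = "Mann-Whitney U",
                   statistic = unname(wt$statistic),
                   df = NA_real_, p_value = wt$p.value)
  }
}

#' Multi-group comparison: one-way GLM plus Kruskal-Wallis
#'
#' Fits a one-way fixed-effects ANOVA (the "GLM" of the analysis pipeline;
#' F with k-1 and N-k degrees of freedom) and a Kruskal-Wallis test. Post
#' hoc pairwise Welch t tests are run only when the omnibus ANOVA reaches
#' `alpha` (overall significance gates the pairwise stage).
#'
#' @param values Numeric response.
#' @param labels Group labels (>= 2 groups, each n >= 2).
#' @param alpha Omnibus significance level gating the post hoc stage.
#' @param posthoc_m Number of comparisons used for the Bonferroni-corrected
#'   post hoc threshold; defaults to the number of group pairs.
#' @return List of class `multi_group_glm`: `omnibus` tibble (ANOVA and
#'   Kruskal-Wallis rows) and `posthoc` tibble (`contrast`, `statistic`,
#'   `p_value`, `alpha_corrected`, `significant`; empty when not qualified).
#' @export
multi_group_glm <- function(values, labels, alpha = 0.05, posthoc_m = NULL) {
  labels <- as.factor(as.character(labels))
  if (nlevels(labels) < 2) {
    abort("need at least 2 groups", class = "nfstoich_domain_error")
  }
  if (any(table(labels) < 2)) {
    abort("every group needs at least 2 observations",
          class = "nfstoich_domain_error")
  }
  dat <- data.frame(v = values, g = labels)
  an <- stats::anova(stats::aov(v ~ g, data = dat))
  kw <- stats::kruskal.test(values, labels)
  omnibus <- tibble::tibble(
    test_name = c("one-way GLM (ANOVA)", "Kruskal-Wallis"),
    statistic = c(an$`F value`[1], unname(kw$statistic)),
    df1 = c(an$Df[1], unname(kw$parameter)),
    df2 = c(an$Df[2], NA),
    p_value = c(an$`Pr(>F)`[1], kw$p.value)
  )
  posthoc <- tibble::tibble()
  p_omni <- omnibus$p_value[1]
  if (is.finite(p_omni) && p_omni < alpha) {
    combs <- utils::combn(levels(labels), 2, simplify = FALSE)
    if (is.null(posthoc_m)) posthoc_m <- length(combs)
    thr <- bonferroni_threshold(alpha, posthoc_m)
    posthoc <- purrr::map(combs, function(pr) {
      tt <- stats::t.test(values[labels == pr[1]], values[labels == pr[2]])
      tibble::tibble(contrast = paste(pr, collapse = " vs "),
                     statistic = unname(tt$statistic),
                     p_value = tt$p.value,
                     alpha_corrected = thr,
                     significant = tt$p.value < thr)
    }) %>% bind_rows()
  }
  structure(list(omnibus = omnibus, posthoc = posthoc), class = "multi_group_glm")
}

#' @export
print.multi_group_glm <- function(x, ...) {
  print(x$omnibus)
  if (nrow(x$posthoc)) print(x$posthoc)
  invisible(x)
}

#' Association of calibrated isoform levels with progression category
#'
#' For each isoform channel, runs [multi_group_glm()] of the calibrated
#' counts across the slow / intermediate / fast progression categories of
#' the ALS group, with Bonferroni-corrected post hoc contrasts (m = 3).
#'
#' @param profiles Calibrated particle-profile tibble.
#' @param cohort Cohort tibble supplying `alsfrs_baseline` and
#'   `months_onset_to_baseline` (joined on `subject_id`).
#' @param als_group ALS group label.
#' @return Tibble with one omnibus row per isoform (`isoform`, `test_name`,
#'   `statistic`, `df1`, `df2`, `p_value`) and the post hoc tables in the
#'   `posthoc` list-column.
#' @export
progression_association <- function(profiles, cohort, als_group = "ALS") {
  dat <- profiles %>%
    dplyr::filter(.data$group == als_group) %>%
    left_join(select(cohort, "subject_id", "alsfrs_baseline",
                     "months_onset_to_baseline"),
              by = "subject_id") %>%
    mutate(category = progression_category(
      progression_rate(.data$alsfrs_baseline, .data$months_onset_to_baseline)))
  present <- unique(dat$category)
  if (length(present) < 2) {
    abort("need at least two progression categories",
          class = "nfstoich_domain_error")
  }
  if (length(present) < 3) {
    warn(sprintf("progression categories missing: %s",
                 paste(setdiff(c("slow", "intermediate", "fast"), present),
                       collapse = ", ")))
  }
  purrr::map(c(NfL = "nfl", NfM = "nfm", NfH = "nfh"), function(col) {
    multi_group_glm(dat[[col]], dat$category, posthoc_m = 3)
  }) %>%
    purrr::imap(function(res, iso) {
      res$omnibus %>%
        dplyr::filter(.data$test_name == "one-way GLM (ANOVA)") %>%
        mutate(isoform = iso, .before = 1) %>%
        mutate(posthoc = list(res$posthoc))
    }) %>%
    bind_rows()
}
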