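#' Kernel density plot of per-channel particle counts
#'
#' One curve per isoform channel, on the convention red = NfL, blue = NfM,
#' green = NfH. Calibrated profiles give the stoichiometric-share densities;
#' raw profiles show the assay-scale distortion.
#'
#' @param profiles Particle-profile tibble.
#' @param group Optional group label to subset on.
#' @return A ggplot object.
#' @export
plot_stoichiometry <- function(profiles, group = NULL) {
  if (!is.null(group)) profiles <- profiles[profiles$group == group, ]
  long <- tidyr::pivot_longer(profiles, c("nfl", "nfm", "nfh"),
                              names_to = "channel", values_to = "count")
  long$channel <- factor(toupper(sub("nf", "Nf", long$channel)),
                         levels = c("NfL", "NfM", "NfH"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$count, colour = .data$channel)) +
    ggplot2::geom_density() +
    ggplot2::scale_colour_manual(values = c(NfL = "#d62728", NfM = "#1f77b4",
                                            NfH = "#2ca02c")) +
    ggplot2::labs(x = if (all(profiles$calibrated)) "calibrated particle share"
                      else "particles / L",
                  y = "density", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a brush simulation summary
#'
#' Mean radius of gyration per species with standard-deviation error bars.
#'
#' @param object A `brush_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.brush_result <- function(object, ...) {
  s <- object$summary
  s$species <- factor(s$species, levels = c("NfL", "NfM", "NfH"))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$species, y = .data$mean_rg)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_rg - .data$sd_rg,
                                        ymax = .data$mean_rg + .data$sd_rg),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "radius of gyration (nm)") +
    ggplot2::theme_minimal()
}

#' Bar plot of the cohort translation-cost table
#'
#' @param cost_table Output of [cohort_cost_table()].
#' @param what `"atp"` or `"time"`.
#' @return A ggplot object.
#' @export
plot_cost_table <- function(cost_table, what = c("atp", "time")) {
  what <- match.arg(what)
  m <- if (what == "atp") "atp_mean" else "time_h_mean"
  s <- if (what == "atp") "atp_sd" else "time_h_sd"
  ggplot2::ggplot(cost_table,
                  ggplot2::aes(x = .data$scenario, y = .data[[m]])) +
    ggplot2::geom_col(fill = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data[[m]] - .data[[s]],
                                        ymax = .data[[m]] + .data[[s]]),
                           width = 0.2) +
    ggplot2::labs(x = NULL,
                  y = if (what == "atp") "total ATP (molecules)"
                      else "translation time (h)") +
    ggplot2::theme_minimal()
}
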