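#' Tidy a one-point calibration object
#'
#' @param x An `nf_calibration` from [calibration_factors()].
#' @param ... Unused.
#' @return Tibble with one row per isoform channel: `isoform`, `factor`,
#'   `control_median`, `target`.
#' @export
tidy.nf_calibration <- function(x, ...) {
  tibble::tibble(
    isoform = names(x$control_medians),
    factor = unname(x$factors),
    control_median = unname(x$control_medians),
    target = unname(x$targets[names(x$control_medians)])
  )
}

#' @rdname tidy.nf_calibration
#' @return `glance()` returns a one-row tibble with the factor range and the
#'   number of channels.
#' @export
glance.nf_calibration <- function(x, ...) {
  tibble::tibble(n_channels = length(x$factors),
                 min_factor = min(x$factors), max_factor = max(x$factors))
}

#' Tidy multi-group test results
#'
#' @param x A `multi_group_glm` from [multi_group_glm()].
#' @param which `"omnibus"` (default) or `"posthoc"`.
#' @param ... Unused.
#' @return The requested component as a tibble.
#' @export
tidy.multi_group_glm <- function(x, which = c("omnibus", "posthoc"), ...) {
  which <- match.arg(which)
  x[[which]]
}

#' @rdname tidy.multi_group_glm
#' @export
glance.multi_group_glm <- function(x, ...) {
  o <- x$omnibus[x$omnibus$test_name == "one-way GLM (ANOVA)", ]
  tibble::tibble(statistic = o$statistic, df1 = o$df1, df2 = o$df2,
                 p_value = o$p_value, n_posthoc = nrow(x$posthoc))
}

#' Tidy brush simulation results
#'
#' @param x A `brush_result` from [run_brush_simulation()].
#' @param ... Unused.
#' @return The per-species radius-of-gyration summary tibble.
#' @export
tidy.brush_result <- function(x, ...) x$summary

#' @rdname tidy.brush_result
#' @export
glance.brush_result <- function(x, ...) {
  tibble::tibble(
    n_arms = nrow(x$state$arms),
    n_beads = nrow(x$state$coords),
    n_backbones = x$config$n_backbones,
    sweeps_prod = x$config$sweeps_prod,
    energy = x$state$energy,
    phosphorylated = x$config$phosphorylated
  )
}

#' Tidy gyration contrast tables
#'
#' @param x A `gyration_contrasts` object.
#' @param which `"posthoc"` (default) or `"omnibus"`.
#' @param ... Unused.
#' @return The requested tibble.
#' @export
tidy.gyration_contrasts <- function(x, which = c("posthoc", "omnibus"), ...) {
  which <- match.arg(which)
  x[[which]]
}

#' @rdname tidy.gyration_contrasts
#' @export
glance.gyration_contrasts <- function(x, ...) x$omnibus
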