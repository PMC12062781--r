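#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a phylogenetic mixed-model fit
#'
#' @param x A `pglmm_fit`.
#' @param effects `"fixed"` (default) or `"ran_pars"` for the variance
#'   components.
#' @param ... Unused.
#' @return A tibble with one row per term: `estimate`, `std_error`,
#'   `conf_low`, `conf_high`, `pd` (fixed) or `variance`, `sd` and
#'   interval columns (ran_pars).
#' @method tidy pglmm_fit
#' @export
tidy.pglmm_fit <- function(x, effects = c("fixed", "ran_pars"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") x$coefficients else x$varcomp
}

#' One-row summary of a phylogenetic mixed-model fit
#'
#' @param x A `pglmm_fit`.
#' @param ... Unused.
#' @return A tibble with `nobs`, `n_species`, `sigma`, `logLik`,
#'   `partial_r2`, `n_dropped`, `reml`.
#' @method glance pglmm_fit
#' @export
glance.pglmm_fit <- function(x, ...) {
  tibble::tibble(
    nobs = length(x$y),
    n_species = length(x$design$species),
    sigma = sqrt(x$sigma2),
    logLik = x$loglik,
    partial_r2 = partial_r2(x),
    n_dropped = x$design$n_dropped,
    reml = x$reml
  )
}

#' Coefficient (forest) plot of a fit
#'
#' Point estimates with 95% intervals per fixed effect, intercept omitted,
#' colored by whether the interval excludes zero.
#'
#' @param object A `pglmm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pglmm_fit
#' @export
autoplot.pglmm_fit <- function(object, ...) {
  d <- object$coefficients
  d <- d[d$term != "(Intercept)", , drop = FALSE]
  d$term <- factor(d$term, levels = rev(d$term))
  d$significant <- d$conf_low > 0 | d$conf_high < 0
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term,
                                  color = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high)) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "firebrick", `FALSE` = "steelblue"),
                                guide = "none") +
    ggplot2::labs(x = "standardized effect on the response", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a spline correlogram
#'
#' @param object A `spline_correlogram`.
#' @param ... Unused.
#' @return A ggplot object: smoothed residual correlation against
#'   great-circle distance with the bootstrap envelope.
#' @method autoplot spline_correlogram
#' @export
autoplot.spline_correlogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$distance_km, y = .data$correlation)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "distance (km)", y = "residual correlation") +
    ggplot2::theme_minimal()
}

#' Plot a posterior predictive check
#'
#' Observed summary statistics against their simulated 95% envelopes.
#'
#' @param object A `ppc_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ppc_summary
#' @export
autoplot.ppc_summary <- function(object, ...) {
  d <- tibble::tibble(stat = factor(names(object$observed),
                                    levels = names(object$observed)),
                      observed = unname(object$observed),
                      lower = unname(object$lower),
                      upper = unname(object$upper))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                           width = 0.3, color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), color = "firebrick") +
    ggplot2::labs(x = NULL, y = "response summary",
                  title = "observed vs. simulated envelopes") +
    ggplot2::theme_minimal()
}
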