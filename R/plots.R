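#' Plot a simulated lifetime
#'
#' Four stacked panels over age: dry-matter intake (basal and total),
#' allocation coefficients, body masses, and milk yield.  The intake
#' panel shows the characteristic basal curve rising asymptotically with
#' lactation humps superimposed at each parturition and absent during dry
#' periods.
#'
#' @param object A `cow_life` object with a recorded trajectory.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cow_life
#' @export
autoplot.cow_life <- function(object, ...) {
  tr <- tidy.cow_life(object)
  long <- dplyr::bind_rows(
    tr %>% dplyr::select("day", basal = "acq_b", total = "acq_t") %>%
      tidyr::pivot_longer(-"day") %>%
      mutate(panel = "intake (kg DM/d)"),
    tr %>% dplyr::select("day", growth = "alloc_g", survival = "alloc_s",
                         gestation = "alloc_pf", lactation = "alloc_pc") %>%
      tidyr::pivot_longer(-"day") %>%
      mutate(panel = "allocation coefficient"),
    tr %>% dplyr::select("day", structural = "structural_mass",
                         labile = "labile_mass") %>%
      tidyr::pivot_longer(-"day") %>%
      mutate(panel = "body mass (kg)"),
    tr %>% dplyr::select("day", milk = "milk_yield") %>%
      tidyr::pivot_longer(-"day") %>%
      mutate(panel = "milk yield (kg/d)")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day / 365, y = .data$value,
                                     colour = .data$name)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "age (years)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot marginal means of a factorial response
#'
#' @param results An `fe_experiment` tibble from [run_design()].
#' @param response Summary column to plot, e.g. `"fe_lac2"`.
#' @return A ggplot object: marginal mean with \eqn{\pm} 1 standard error
#'   per factor level.
#' @export
plot_marginals <- function(results, response = "fe_life") {
  mm <- marginal_means(results, response)
  ggplot2::ggplot(mm, ggplot2::aes(x = .data$level, y = .data$mean,
                                   group = .data$factor)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se)) +
    ggplot2::facet_wrap(~factor, nrow = 1) +
    ggplot2::labs(x = "trait level", y = response) +
    ggplot2::theme_minimal()
}

#' Plot sensitivity indices
#'
#' @param object An `fe_sensitivity` object.
#' @param ... Unused.
#' @return A ggplot bar chart of per-term variance shares.
#' @method autoplot fe_sensitivity
#' @export
autoplot.fe_sensitivity <- function(object, ...) {
  idx <- tidy.fe_sensitivity(object) %>%
    arrange(.data$index) %>%
    mutate(term = factor(.data$term, levels = .data$term))
  ggplot2::ggplot(idx, ggplot2::aes(x = .data$index, y = .data$term)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "share of output variance", y = NULL,
                  title = object$response) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
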