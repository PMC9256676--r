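#' Plot group-level posterior distributions
#'
#' Density of the group-level posterior mean draws per parameter, split by
#' age group and condition.
#'
#' @param object An `stddm_fit`.
#' @param parameters Parameters to show (default: all).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stddm_fit <- function(object, parameters = NULL, ...) {
  pars <- parameters %||% object$par_names
  df <- purrr::map_dfr(1:4, function(g) {
    purrr::map_dfr(match(pars, object$par_names), function(j) {
      tibble::tibble(
        age_group = object$cells$age_group[g],
        condition = object$cells$condition[g],
        parameter = object$par_names[j],
        value = object$draws$mu[, g, j]
      )
    })
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, fill = .data$condition,
                                   linetype = .data$age_group)) +
    ggplot2::geom_density(alpha = 0.35) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "group-level posterior mean", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot EV-sensitivity slopes by age group and condition
#'
#' @param slopes Output of [ev_slopes()].
#' @return A ggplot object.
#' @export
plot_ev_sensitivity <- function(slopes) {
  ggplot2::ggplot(slopes, ggplot2::aes(x = .data$condition, y = .data$slope,
                                       fill = .data$condition)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5, size = 1) +
    ggplot2::facet_wrap(~age_group) +
    ggplot2::labs(y = "logistic slope per EV point (EV sensitivity)") +
    ggplot2::theme_minimal()
}

#' Plot a model-comparison table
#'
#' @param object An `stddm_comparison`.
#' @param ... Unused.
#' @return A ggplot object of per-cell DIC by model.
#' @export
autoplot.stddm_comparison <- function(object, ...) {
  df <- object$table |>
    dplyr::filter(.data$age_group != "all")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model_id, y = .data$dic,
                                   fill = .data$model_id)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(age_group ~ condition, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "DIC (smaller is better)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
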