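# ggplot2 views of trajectories and fits, and broom-style accessors.

#' Plot a cage trajectory
#'
#' Shows the DsRed carrier fraction and the three para allele frequencies
#' against generation, the quantities plotted for laboratory cages.
#'
#' @param object A `cage_trajectory` from [run_deterministic()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cage_trajectory
#' @export
autoplot.cage_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("dsred", "freq_L", "freq_F", "freq_R"),
    names_to = "series", values_to = "frequency"
  ) |>
    dplyr::mutate(series = factor(
      .data$series, levels = c("dsred", "freq_L", "freq_F", "freq_R"),
      labels = c("DsRed+ carriers", "1014L", "1014F", "NHEJ")
    ))
  ggplot2::ggplot(long, ggplot2::aes(.data$generation, .data$frequency,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Generation", y = "Frequency", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot replicate stochastic trajectories
#'
#' Spaghetti plot of replicate cages for one summary quantity, optionally
#' with the deterministic trajectory overlaid.
#'
#' @param sims Tibble from [run_stochastic()] (columns `rep`, `generation`,
#'   and the summary columns).
#' @param quantity One of `"dsred"`, `"freq_L"`, `"freq_F"`, `"freq_R"`.
#' @param deterministic Optional `cage_trajectory` to overlay in black.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(sims, quantity = c("dsred", "freq_L", "freq_F",
                                                 "freq_R"),
                              deterministic = NULL) {
  quantity <- match.arg(quantity)
  p <- ggplot2::ggplot(sims, ggplot2::aes(.data$generation,
                                          .data[[quantity]],
                                          group = .data$rep)) +
    ggplot2::geom_line(alpha = 0.25, colour = "grey40") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Generation", y = quantity) +
    ggplot2::theme_minimal()
  if (!is.null(deterministic)) {
    p <- p + ggplot2::geom_line(
      data = dplyr::mutate(tibble::as_tibble(deterministic), rep = 0L),
      colour = "black", linewidth = 0.9
    )
  }
  p
}

#' Trace plot of an MCMC fit
#'
#' @param object An `edrive_fit` from [run_mcmc()].
#' @param ... Unused.
#' @return A ggplot object with one facet per fitted parameter.
#' @method autoplot edrive_fit
#' @export
autoplot.edrive_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$draws, cols = -c("iteration", "log_posterior"),
    names_to = "term", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$iteration, .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = object$settings$burn_in,
                        linetype = "dashed", colour = "red") +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "Iteration", y = "Parameter value") +
    ggplot2::theme_minimal()
}

#' Tidy posterior summaries of a fit
#'
#' @param x An `edrive_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` (posterior median), `conf.low`,
#'   `conf.high` (central 95% credible interval).
#' @method tidy edrive_fit
#' @export
tidy.edrive_fit <- function(x, ...) {
  posterior_summary(x) |>
    dplyr::transmute(
      term = .data$term, estimate = .data$median,
      conf.low = .data$q2.5, conf.high = .data$q97.5
    )
}

#' One-row fit summary
#'
#' @param x An `edrive_fit`.
#' @param ... Unused.
#' @return Tibble with chain dimensions, acceptance rate, and the maximum
#'   log-posterior seen in the kept draws.
#' @method glance edrive_fit
#' @export
glance.edrive_fit <- function(x, ...) {
  tibble::tibble(
    iterations = x$settings$iterations,
    burn_in = x$settings$burn_in,
    thin = x$settings$thin,
    n_kept = nrow(x$draws),
    n_parameters = length(x$settings$parameters_to_fit),
    acceptance_rate = x$acceptance_rate,
    max_log_posterior = max(x$draws$log_posterior)
  )
}
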