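# Random-walk Metropolis-Hastings on logit-transformed drive parameters with
# Uniform(0,1) priors ("no prior information"). Hand-rolled sampler: the
# posterior is low-dimensional and the likelihood is the package's own exact
# recursion, so an all-at-once Gaussian random walk with modest step sizes
# mixes adequately.

#' MCMC sampler settings
#'
#' @param iterations Total Metropolis-Hastings iterations.
#' @param burn_in Iterations discarded before summarising (must be smaller
#'   than `iterations`).
#' @param thin Keep every `thin`-th iteration in the stored chain.
#' @param proposal_scale Standard deviation of the Gaussian random-walk
#'   proposal on the logit scale; a single value or a named per-parameter
#'   vector. The default 0.15 gives 20-40% acceptance on cage datasets of the
#'   standard size.
#' @param seed Integer seed for the sampler (initial point and proposals).
#' @param parameters_to_fit Character vector naming the [drive_params()]
#'   fields to sample; the rest stay at their `base_params` values.
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(iterations = 50000L, burn_in = iterations %/% 5L,
                          thin = 10L, proposal_scale = 0.15, seed = 1L,
                          parameters_to_fit = c("c", "l", "m", "s_drive_self",
                                                "s_drive_hover", "s_Fhom")) {
  stopifnot(
    iterations >= 10, burn_in >= 0, burn_in < iterations, thin >= 1,
    all(proposal_scale > 0), length(parameters_to_fit) >= 1,
    all(parameters_to_fit %in% c("c", "l", "m", "s_drive_self",
                                 "s_drive_hover", "s_Fhom",
                                 "s_Fcarrier_f", "s_Fcarrier_m"))
  )
  k <- length(parameters_to_fit)
  scales <- if (length(proposal_scale) == 1L) {
    stats::setNames(rep(proposal_scale, k), parameters_to_fit)
  } else {
    if (!all(parameters_to_fit %in% names(proposal_scale))) {
      stop("per-parameter `proposal_scale` must name every fitted parameter",
           call. = FALSE)
    }
    proposal_scale[parameters_to_fit]
  }
  structure(
    list(iterations = as.integer(iterations), burn_in = as.integer(burn_in),
         thin = as.integer(thin), proposal_scale = scales,
         seed = as.integer(seed), parameters_to_fit = parameters_to_fit),
    class = "mcmc_settings"
  )
}

# log posterior on the probability scale; uniform priors mean the only prior
# content is the support constraint (and the c + l <= 1 coupling)
.log_post <- function(values, base_params, datasets, prior_only, read_ess,
                      drift_adjust) {
  p <- .params_update(base_params, values)
  if (p$c + p$l > 1) return(-Inf)
  if (prior_only) return(0)
  sum(vapply(datasets,
             function(ds) .loglik_dataset(p, ds, read_ess, drift_adjust),
             numeric(1)))
}

#' Fit drive parameters by Metropolis-Hastings MCMC
#'
#' Samples the posterior of the selected drive parameters given one or more
#' cage observation datasets, under independent Uniform(0,1) priors. The
#' random walk operates on logit-transformed parameters (with the Jacobian
#' term included), so proposals always respect the probability bounds. The
#' initial point is drawn from the prior and re-drawn (up to 100 times) while
#' the posterior is non-finite. Datasets of different designs enter one joint
#' likelihood, which is how the two mode-specific mating costs are fitted
#' simultaneously.
#'
#' @param data A `cage_dataset`, a list of them, or `NULL` together with
#'   `prior_only = TRUE`.
#' @param settings An [mcmc_settings()] object.
#' @param base_params [drive_params()] values for the parameters not being
#'   fitted.
#' @param prior_only If `TRUE` the likelihood is identically zero and the
#'   chain samples the prior (used for sampler validation).
#' @param read_ess Optional effective sample size for the read counts,
#'   passed to the likelihood (see [log_likelihood()]); `1.5 * ngs_flies`
#'   matches the information content of the pooled-fly design.
#' @param drift_adjust If `TRUE`, use the quasi-likelihood weights of
#'   [log_likelihood()] that also account for finite-census drift around the
#'   deterministic mean; recommended for credible intervals with honest
#'   frequentist coverage at laboratory census sizes.
#' @return An object of class `edrive_fit`: list with `draws` (tibble of
#'   thinned iterations, one column per fitted parameter, plus
#'   `log_posterior`), `acceptance_rate`, `settings`, `base_params`, and the
#'   dataset designs. Use [posterior_summary()], [generics::tidy()],
#'   [generics::glance()] or [autoplot()] on it.
#' @examples
#' ds <- generate_cage_dataset("hover_1to3", n_cages = 1, seed = 1)
#' fit <- run_mcmc(ds, mcmc_settings(iterations = 2000, burn_in = 500,
#'                                   parameters_to_fit = c("c", "l")))
#' posterior_summary(fit)
#' @export
run_mcmc <- function(data, settings = mcmc_settings(),
                     base_params = drive_params(), prior_only = FALSE,
                     read_ess = NULL, drift_adjust = FALSE) {
  stopifnot(inherits(settings, "mcmc_settings"))
  datasets <- if (is.null(data)) {
    if (!prior_only) stop("`data` is required unless prior_only = TRUE",
                          call. = FALSE)
    list()
  } else {
    .as_dataset_list(data)
  }
  validate_drive_params(base_params)
  pars <- settings$parameters_to_fit
  k <- length(pars)
  scales <- settings$proposal_scale

  set.seed(settings$seed)

  # initial point from the prior, re-drawn while the posterior is non-finite
  lp <- -Inf
  for (try in seq_len(100L)) {
    values <- stats::setNames(stats::runif(k), pars)
    lp <- .log_post(values, base_params, datasets, prior_only, read_ess,
                    drift_adjust)
    if (is.finite(lp)) break
  }
  if (!is.finite(lp)) {
    stop("could not find a starting point with finite posterior", call. = FALSE)
  }

  theta <- stats::qlogis(values)
  # Jacobian of the logit transform: log p + log(1 - p) per parameter
  ljac <- function(v) sum(log(v) + log1p(-v))
  post <- lp + ljac(values)

  n_keep <- settings$iterations %/% settings$thin
  draws <- matrix(NA_real_, n_keep, k, dimnames = list(NULL, pars))
  lp_trace <- numeric(n_keep)
  it_kept <- integer(n_keep)
  accepted <- 0L
  row <- 0L

  for (it in seq_len(settings$iterations)) {
    prop_theta <- theta + stats::rnorm(k, 0, scales)
    prop_values <- stats::setNames(stats::plogis(prop_theta), pars)
    prop_lp <- .log_post(prop_values, base_params, datasets, prior_only,
                         read_ess, drift_adjust)
    prop_post <- if (is.finite(prop_lp)) prop_lp + ljac(prop_values) else -Inf
    if (log(stats::runif(1L)) < prop_post - post) {
      theta <- prop_theta
      values <- prop_values
      post <- prop_post
      accepted <- accepted + 1L
    }
    if (it %% settings$thin == 0L) {
      row <- row + 1L
      draws[row, ] <- values
      lp_trace[row] <- post
      it_kept[row] <- it
    }
  }

  structure(
    list(
      draws = dplyr::bind_cols(
        tibble::tibble(iteration = it_kept),
        tibble::as_tibble(draws),
        tibble::tibble(log_posterior = lp_trace)
      ),
      acceptance_rate = accepted / settings$iterations,
      settings = settings,
      base_params = base_params,
      designs = lapply(datasets, function(ds) {
        list(config = ds$config, mode = ds$mode, cas9_active = ds$cas9_active)
      }),
      prior_only = prior_only,
      read_ess = read_ess,
      drift_adjust = drift_adjust
    ),
    class = "edrive_fit"
  )
}

# post-burn-in draws as a plain tibble of parameter columns
.posterior_draws <- function(fit) {
  stopifnot(inherits(fit, "edrive_fit"))
  d <- dplyr::filter(fit$draws, .data$iteration > fit$settings$burn_in)
  if (nrow(d) == 0L) stop("no post-burn-in draws in chain", call. = FALSE)
  dplyr::select(d, -"iteration", -"log_posterior")
}

#' Posterior summaries of a fitted chain
#'
#' Empirical medians, means and central 95% credible intervals (2.5% and
#' 97.5% chain quantiles) of the post-burn-in draws.
#'
#' @param fit An `edrive_fit` from [run_mcmc()].
#' @return Tibble with columns `term`, `median`, `mean`, `q2.5`, `q97.5`.
#' @export
posterior_summary <- function(fit) {
  d <- .posterior_draws(fit)
  purrr::map_dfr(names(d), function(nm) {
    v <- d[[nm]]
    q <- stats::quantile(v, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
    tibble::tibble(term = nm, median = q[2L], mean = mean(v),
                   q2.5 = q[1L], q97.5 = q[3L])
  })
}

#' @export
print.edrive_fit <- function(x, ...) {
  cat("<edrive_fit>", nrow(x$draws), "kept draws,",
      length(x$designs), "dataset(s), acceptance rate",
      sprintf("%.2f", x$acceptance_rate), "\n")
  print(posterior_summary(x))
  invisible(x)
}

#' Posterior predictive cage trajectories
#'
#' Draws parameter vectors from the post-burn-in chain and runs one
#' stochastic cage simulation per draw, giving the trajectory band to overlay
#' on observed data.
#'
#' @param fit An `edrive_fit`.
#' @param config A [cage_config()]; defaults to the first fitted dataset's
#'   design.
#' @param n_draws Number of posterior draws (0 gives an empty tibble).
#' @param seed Integer seed.
#' @return Tibble with columns `draw`, `generation`, `dsred`, `freq_L`,
#'   `freq_F`, `freq_R`.
#' @export
posterior_predictive <- function(fit, config = NULL, n_draws = 100L,
                                 seed = 1L) {
  stopifnot(inherits(fit, "edrive_fit"), n_draws >= 0)
  if (n_draws == 0L) {
    return(tibble::tibble(
      draw = integer(), generation = integer(), dsred = numeric(),
      freq_L = numeric(), freq_F = numeric(), freq_R = numeric()
    ))
  }
  design <- if (!is.null(config)) {
    list(config = config, mode = config$mode,
         cas9_active = fit$base_params$cas9_active)
  } else {
    if (length(fit$designs) == 0L) {
      stop("supply `config`: the fit has no attached dataset design",
           call. = FALSE)
    }
    fit$designs[[1L]]
  }
  d <- .posterior_draws(fit)
  set.seed(seed)
  idx <- sample.int(nrow(d), n_draws, replace = TRUE)
  purrr::map_dfr(seq_len(n_draws), function(i) {
    p <- .params_update(fit$base_params, as.list(d[idx[i], ]))
    p$mode <- design$mode
    p$cas9_active <- design$cas9_active
    tr <- .run_stoch_counts(design$config, p)
    s <- .counts_summary(tr$fc, tr$mc)
    tibble::tibble(
      draw = i, generation = 0:design$config$generations,
      dsred = s[, 1L], freq_L = s[, 2L], freq_F = s[, 3L], freq_R = s[, 4L]
    )
  })
}
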