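# Likelihood construction and the Metropolis-Hastings sampler.

# a dataset whose observations sit exactly at the deterministic expectations
# (rounded), for likelihood-shape checks
exact_dataset <- function(preset = "self_elim_1to3", params = drive_params()) {
  pre <- cage_preset(preset)
  pred <- edriver:::.predicted_summaries(pre$config, params)
  depth <- pre$config$read_depth
  obs <- purrr::map_dfr(0:pre$config$generations, function(g) {
    p <- pred[g + 1, ]
    reads <- round(depth * p[2:4])
    reads[1] <- reads[1] + depth - sum(reads)
    tibble::tibble(
      cage = 1L, generation = g,
      dsred_positive = as.integer(round(60 * p[1])), dsred_scored = 60L,
      reads_L = as.integer(reads[1]), reads_F = as.integer(reads[2]),
      reads_R = as.integer(reads[3])
    )
  })
  structure(
    list(observations = obs, truth = NULL, config = pre$config,
         params = params, mode = pre$config$mode,
         cas9_active = params$cas9_active),
    class = "cage_dataset"
  )
}

test_that("the likelihood peaks at the generating parameters on exact data", {
  truth <- drive_params()
  ds <- exact_dataset(params = truth)
  ll0 <- log_likelihood(truth, ds)
  expect_true(is.finite(ll0))
  for (nm in c("c", "l", "m", "s_drive_self", "s_Fhom")) {
    for (delta in c(-0.2, 0.2)) {
      v <- truth[[nm]] + delta
      if (v < 0 || v > 1) next
      pert <- truth
      pert[[nm]] <- v
      class(pert) <- "drive_params"
      if (pert$c + pert$l > 1) next
      expect_lt(log_likelihood(pert, ds), ll0)
    }
  }
})

test_that("generations without scored flies or reads contribute nothing", {
  pre <- cage_preset("self_elim_1to3")
  empty <- structure(
    list(
      observations = tibble::tibble(
        cage = 1L, generation = 3L, dsred_positive = 0L, dsred_scored = 0L,
        reads_L = 0L, reads_F = 0L, reads_R = 0L
      ),
      config = pre$config, params = pre$params,
      mode = pre$config$mode, cas9_active = TRUE
    ),
    class = "cage_dataset"
  )
  expect_identical(log_likelihood(drive_params(), empty), 0)
})

test_that("an observed count with zero predicted frequency gives -Inf", {
  # a no-drive seeding predicts carrier frequency 0 everywhere
  seeding <- tibble::tibble(
    sex = c("female", "male"), genotype = c("Y+/Y+;L/F", "Y+;L"),
    count = c(60, 60)
  )
  config <- cage_config(seeding, generations = 2)
  ds <- structure(
    list(
      observations = tibble::tibble(
        cage = 1L, generation = 1L, dsred_positive = 3L, dsred_scored = 60L,
        reads_L = 0L, reads_F = 0L, reads_R = 0L
      ),
      config = config, params = drive_params(), mode = "self_eliminating",
      cas9_active = TRUE
    ),
    class = "cage_dataset"
  )
  expect_identical(log_likelihood(drive_params(), ds), -Inf)
})

test_that("the likelihood is invariant to cage and generation order", {
  ds <- generate_cage_dataset("hover_1to3", n_cages = 2, seed = 21)
  ll <- log_likelihood(drive_params(), ds)
  shuffled <- ds
  set.seed(1)
  shuffled$observations <- shuffled$observations[
    sample(nrow(shuffled$observations)),
  ]
  expect_equal(log_likelihood(drive_params(), shuffled), ll)
  # and to dataset order in a list
  ds2 <- generate_cage_dataset("self_elim_1to3", n_cages = 1, seed = 22)
  expect_equal(log_likelihood(drive_params(), list(ds, ds2)),
               log_likelihood(drive_params(), list(ds2, ds)))
})

test_that("read-term tempering only rescales the multinomial component", {
  ds <- generate_cage_dataset("hover_1to3", n_cages = 1, seed = 23)
  full <- log_likelihood(drive_params(), ds)
  tempered <- log_likelihood(drive_params(), ds, read_ess = 37.5)
  expect_true(is.finite(tempered))
  expect_gt(tempered, full) # read terms are large negative numbers
})

test_that("identical seeds give identical chains", {
  ds <- generate_cage_dataset("hover_1to3", n_cages = 1, seed = 30)
  st <- mcmc_settings(iterations = 500, burn_in = 100, thin = 5, seed = 9,
                      parameters_to_fit = c("c", "l"))
  f1 <- run_mcmc(ds, st, read_ess = 37.5)
  f2 <- run_mcmc(ds, st, read_ess = 37.5)
  expect_identical(f1$draws, f2$draws)
  expect_true(all(f1$draws$c >= 0 & f1$draws$c <= 1))
  expect_gt(f1$acceptance_rate, 0)
  expect_lt(f1$acceptance_rate, 1)
})

test_that("a boundary-true parameter is recovered near the boundary", {
  truth <- drive_params(c = 0, mode = "hover")
  ds <- generate_cage_dataset("hover_1to3", n_cages = 2, seed = 31,
                              params = truth)
  fit <- run_mcmc(ds, mcmc_settings(iterations = 3000, burn_in = 1000,
                                    seed = 2, parameters_to_fit = "c"),
                  base_params = truth, read_ess = 37.5)
  s <- posterior_summary(fit)
  expect_lt(s$median, 0.25)
  expect_lt(s$q2.5, 0.05)
})

test_that("prior-only sampling reproduces Uniform(0,1) marginals", {
  fit <- run_mcmc(NULL,
                  mcmc_settings(iterations = 200000, burn_in = 0, thin = 20,
                                proposal_scale = 2.5, seed = 17,
                                parameters_to_fit = c("m", "s_Fhom")),
                  prior_only = TRUE)
  d <- edriver:::.posterior_draws(fit)
  expect_equal(nrow(d), 10000)
  for (nm in names(d)) {
    ks <- suppressWarnings(stats::ks.test(d[[nm]], "punif"))
    expect_gt(ks$p.value, 0.01)
  }

  # the joint support constraint truncates correctly: with l fixed at 0.32,
  # the prior for c is uniform on (0, 0.68)
  fit <- run_mcmc(NULL,
                  mcmc_settings(iterations = 50000, burn_in = 0, thin = 10,
                                proposal_scale = 2.5, seed = 19,
                                parameters_to_fit = "c"),
                  prior_only = TRUE)
  cc <- edriver:::.posterior_draws(fit)$c
  expect_lte(max(cc), 0.68)
  ks <- suppressWarnings(stats::ks.test(cc, "punif", 0, 0.68))
  expect_gt(ks$p.value, 0.01)
})

test_that("posterior summaries are the empirical chain quantiles", {
  fake <- function(v) {
    structure(
      list(
        draws = tibble::tibble(iteration = seq_along(v), c = v,
                               log_posterior = 0),
        settings = list(burn_in = 0L)
      ),
      class = "edrive_fit"
    )
  }
  s <- posterior_summary(fake(rep(0.3, 50)))
  expect_equal(s$median, 0.3)
  expect_equal(s$q2.5, 0.3)
  expect_equal(s$q97.5, 0.3)

  set.seed(8)
  s <- posterior_summary(fake(stats::runif(1e5)))
  expect_lt(abs(s$q2.5 - 0.025), 0.005)
  expect_lt(abs(s$q97.5 - 0.975), 0.005)
  expect_lt(abs(s$median - 0.5), 0.01)

  empty <- fake(numeric(0))
  expect_error(posterior_summary(empty), "draws")
})

test_that("posterior predictive bands have the requested shape", {
  ds <- generate_cage_dataset("hover_1to3", n_cages = 1, seed = 33)
  fit <- run_mcmc(ds, mcmc_settings(iterations = 400, burn_in = 100,
                                    thin = 5, seed = 3,
                                    parameters_to_fit = c("c", "l")),
                  read_ess = 37.5)
  expect_equal(nrow(posterior_predictive(fit, n_draws = 0)), 0)
  pp <- posterior_predictive(fit, n_draws = 5, seed = 4)
  expect_equal(dplyr::n_distinct(pp$draw), 5)
  expect_equal(nrow(pp), 5 * 10)
  expect_true(all(pp$freq_L >= 0 & pp$freq_L <= 1, na.rm = TRUE))
})

test_that("tidy, glance and the trace plot expose the chain", {
  ds <- generate_cage_dataset("hover_1to3", n_cages = 1, seed = 34)
  fit <- run_mcmc(ds, mcmc_settings(iterations = 400, burn_in = 100,
                                    thin = 5, seed = 5,
                                    parameters_to_fit = c("c", "l")),
                  read_ess = 37.5)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "conf.low", "conf.high"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$n_parameters, 2)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("settings validation rejects inconsistent chains", {
  expect_error(mcmc_settings(iterations = 100, burn_in = 100), "burn_in")
  expect_error(mcmc_settings(proposal_scale = 0), "proposal_scale")
  expect_error(mcmc_settings(parameters_to_fit = "bogus"))
  expect_error(run_mcmc(NULL, mcmc_settings()), "prior_only")
})
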