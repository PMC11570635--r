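# Likelihood of cage observations under the deterministic mean model.
#
# The deterministic recursion plays the role of the mean process (one curve
# per design, as fitted to the replicate cages); each cage enters as an
# independent observation around it. Per generation the DsRed tally is
# binomial in the predicted carrier frequency and the read counts are
# multinomial in the predicted population allele frequencies.

# predicted per-generation summaries for a design under candidate parameters
.predicted_summaries <- function(config, params) {
  eng <- .build_engine(params)
  f <- config$seed_f / sum(config$seed_f)
  m <- config$seed_m / sum(config$seed_m)
  G <- config$generations
  out <- matrix(NA_real_, G + 1L, 4L)
  out[1L, ] <- .state_summary(f, m)
  for (g in seq_len(G)) {
    st <- .step_engine(f, m, eng)
    if (st$extinct) break
    f <- st$f; m <- st$m
    out[g + 1L, ] <- .state_summary(f, m)
  }
  out # columns: dsred, freq_L, freq_F, freq_R; NA rows after extinction
}

.as_dataset_list <- function(data) {
  if (inherits(data, "cage_dataset")) return(list(data))
  if (is.list(data) && all(vapply(data, inherits, logical(1), "cage_dataset"))) {
    return(data)
  }
  stop("`data` must be a cage_dataset or a list of cage_dataset objects",
       call. = FALSE)
}

# candidate parameters adjusted to a dataset's design (mode, cassette type)
.design_params <- function(params, ds) {
  params$mode <- ds$mode
  params$cas9_active <- ds$cas9_active
  params
}

.loglik_dataset <- function(params, ds, read_ess = NULL,
                            drift_adjust = FALSE) {
  pred <- .predicted_summaries(ds$config, .design_params(params, ds))
  obs <- ds$observations
  gen <- obs$generation
  scored <- obs$dsred_scored
  pos_n <- obs$dsred_positive
  xs <- cbind(obs$reads_L, obs$reads_F, obs$reads_R)
  census <- ds$config$census_adults
  n_alleles <- 1.5 * ds$config$ngs_flies # X chromosomes in the pooled sample
  ll <- 0
  for (i in seq_along(gen)) {
    t <- gen[i]
    p <- pred[t + 1L, ]
    if (anyNA(p)) return(-Inf) # model extinct where data exist
    if (scored[i] > 0L) {
      term <- stats::dbinom(pos_n[i], scored[i],
                            min(max(p[1L], 0), 1), log = TRUE)
      if (drift_adjust) {
        # quasi-likelihood weight: cumulative drift variance ~ t p(1-p)/N
        # adds to the sampling variance p(1-p)/n, shrinking the effective
        # sample size to 1 / (1/n + t/N)
        term <- term * (1 / scored[i]) / (1 / scored[i] + t / census)
      }
      ll <- ll + term
    }
    x <- xs[i, ]
    n <- sum(x)
    if (n > 0L) {
      q <- pmin(pmax(p[2:4], 0), 1)
      if (any(x > 0 & q <= 0)) return(-Inf)
      pos <- x > 0
      term <- lgamma(n + 1) - sum(lgamma(x + 1)) + sum(x[pos] * log(q[pos]))
      # temper the read term to its effective information content when the
      # two-stage sampling (few flies, many reads) inflates the variance
      if (drift_adjust) {
        # allele pool: 1.5 census X chromosomes; fly sampling + read noise
        ess <- 1 / (1 / n_alleles + 1 / n + t / (1.5 * census))
        term <- term * min(1, ess / n)
      } else if (!is.null(read_ess)) {
        term <- term * min(1, read_ess / n)
      }
      ll <- ll + term
    }
    if (!is.finite(ll)) return(-Inf)
  }
  ll
}

#' Log-likelihood of cage observations
#'
#' Sums, over datasets, cages, and generations, the binomial log-probability
#' of the DsRed+ tally given the deterministic model's carrier frequency and
#' the multinomial log-probability of the L/F/R read counts given the model's
#' population allele frequencies. A generation with no scored flies
#' contributes nothing to the DsRed term; a predicted frequency of zero with
#' a positive observed count yields `-Inf`. Each dataset is evaluated under
#' its own design (deployment mode and Cas9 activity), so one parameter set
#' with both mating costs can be scored jointly against self-eliminating and
#' hover cages.
#'
#' The optional `read_ess` argument tempers each generation's multinomial
#' read term by `read_ess / read_depth`, reducing its weight to an effective
#' sample size. This is the overdispersion correction for the two-stage
#' sampling design: 5000 reads are drawn from only `ngs_flies` pooled flies,
#' so the reads carry at most about `1.5 * ngs_flies` independent X
#' chromosomes' worth of information (two per female, one per male), not
#' 5000. The default (`NULL`) is the plain multinomial.
#'
#' @param params A [drive_params()] candidate.
#' @param data A `cage_dataset` (see [generate_cage_dataset()]) or a list of
#'   them.
#' @param read_ess Optional effective sample size for the read counts (see
#'   Details); `NULL` for the unweighted multinomial.
#' @param drift_adjust If `TRUE`, weight every generation's terms by
#'   quasi-likelihood factors that add the cumulative finite-census drift
#'   variance (of order `t / census` by generation `t`) to the sampling
#'   variance, so the posterior reflects process noise as well as
#'   observation noise. Supersedes `read_ess` (the fly-pool correction is
#'   included). All constants come from the cage design, none are free.
#' @return A single finite number or `-Inf`.
#' @export
log_likelihood <- function(params, data, read_ess = NULL,
                           drift_adjust = FALSE) {
  validate_drive_params(params)
  sum(vapply(.as_dataset_list(data),
             function(ds) .loglik_dataset(params, ds, read_ess, drift_adjust),
             numeric(1)))
}
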