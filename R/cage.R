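# Multi-generation cage dynamics: deterministic genotype-frequency recursion,
# finite-population stochastic simulation, and the cage observation scheme
# (half-population DsRed scoring; pooled-fly amplicon sequencing).

#' Cage experiment configuration
#'
#' @param seeding Tibble with columns `sex`, `genotype`, `count` describing
#'   the founding adults (see [cage_preset()] for the standard designs).
#' @param census_adults Constant number of adults per generation (default 120,
#'   the number of seeded adults).
#' @param generations Number of generations to simulate beyond generation 0.
#' @param mode Deployment mode, `"self_eliminating"` or `"hover"`; selects
#'   which male mating cost applies.
#' @param dsred_scored_fraction Fraction of each generation scored for the
#'   dominant DsRed marker (default 0.5: half the progeny pool).
#' @param ngs_flies Number of randomly sampled flies pooled for amplicon
#'   sequencing each generation (default 25).
#' @param read_depth Number of sequencing reads per generation sample
#'   (default 5000).
#' @return An object of class `cage_config`.
#' @export
cage_config <- function(seeding, census_adults = 120L, generations = 9L,
                        mode = c("self_eliminating", "hover"),
                        dsred_scored_fraction = 0.5,
                        ngs_flies = 25L, read_depth = 5000L) {
  mode <- match.arg(mode)
  stopifnot(
    is.data.frame(seeding),
    all(c("sex", "genotype", "count") %in% names(seeding)),
    nrow(seeding) > 0,
    all(seeding$count > 0),
    census_adults >= 2, generations >= 1,
    dsred_scored_fraction > 0, dsred_scored_fraction <= 1,
    ngs_flies >= 1, read_depth >= 1
  )
  parsed <- parse_genotype(seeding$genotype)
  if (!identical(parsed$sex, seeding$sex)) {
    stop("seeding `sex` column disagrees with the genotype strings",
         call. = FALSE)
  }
  v <- .vectors_from_tbl(seeding, "count")
  structure(
    list(
      seeding = tibble::as_tibble(seeding[c("sex", "genotype", "count")]),
      seed_f = v$f, seed_m = v$m,
      census_adults = as.integer(census_adults),
      generations = as.integer(generations),
      mode = mode,
      dsred_scored_fraction = dsred_scored_fraction,
      ngs_flies = as.integer(ngs_flies),
      read_depth = as.integer(read_depth)
    ),
    class = "cage_config"
  )
}

#' Standard cage designs
#'
#' Bundles the seeding tables of the laboratory cage experiments with the
#' fitted parameter set. Drive founders are homo-/hemizygous cassette with the
#' wild-type L allele; the target population carries the resistant F allele in
#' a y+ background (self-eliminating mode) or y- background (hover mode).
#' `"self_elim_1to3"`: 15 males + 15 females E;L against 45 + 45 Y+;F.
#' `"hover_1to3"`: the same counts with Y-;F targets. `"self_elim_1to1"` /
#' `"hover_1to1"`: 30 + 30 of each. `"control_noCas9_1to1"`: the Cas9-less
#' control cassette (E0) seeded 1:1 against y+ targets, Cas9 inactive.
#'
#' @param name Preset name.
#' @param generations Number of generations (default 9).
#' @return List with elements `config` ([cage_config()]) and `params`
#'   ([drive_params()] at the fitted point estimates, mode matched).
#' @examples
#' cage_preset("self_elim_1to3")$config$seeding
#' @export
cage_preset <- function(name = c("self_elim_1to3", "hover_1to3",
                                 "self_elim_1to1", "hover_1to1",
                                 "control_noCas9_1to1"),
                        generations = 9L) {
  name <- match.arg(name)
  seed_tbl <- function(drive_n, target_n, target_y, drive_y = "E") {
    tibble::tibble(
      sex = c("male", "female", "male", "female"),
      genotype = c(
        paste0(drive_y, ";L"), paste0(drive_y, "/", drive_y, ";L/L"),
        paste0(target_y, ";F"), paste0(target_y, "/", target_y, ";F/F")
      ),
      count = c(drive_n, drive_n, target_n, target_n)
    )
  }
  spec <- switch(name,
    self_elim_1to3 = list(seed_tbl(15, 45, "Y+"), "self_eliminating", TRUE),
    hover_1to3 = list(seed_tbl(15, 45, "Y-"), "hover", TRUE),
    self_elim_1to1 = list(seed_tbl(30, 30, "Y+"), "self_eliminating", TRUE),
    hover_1to1 = list(seed_tbl(30, 30, "Y-"), "hover", TRUE),
    control_noCas9_1to1 = list(seed_tbl(30, 30, "Y+", drive_y = "E0"),
                               "self_eliminating", FALSE)
  )
  config <- cage_config(spec[[1]], census_adults = sum(spec[[1]]$count),
                        generations = generations, mode = spec[[2]])
  params <- drive_params(mode = spec[[2]], cas9_active = spec[[3]])
  list(config = config, params = params)
}

#' Founding population of a cage
#'
#' @param config A [cage_config()] object.
#' @return Tibble with columns `sex`, `genotype`, `count` (generation 0).
#' @export
seed_population <- function(config) {
  stopifnot(inherits(config, "cage_config"))
  config$seeding
}

# internal state vectors ------------------------------------------------------

.vectors_from_tbl <- function(tbl, col) {
  f <- rep(0, .N_FEM)
  m <- rep(0, .N_MALE)
  for (i in seq_len(nrow(tbl))) {
    gi <- .genotype_index(tbl$genotype[i])
    if (gi$sex == "female") f[gi$idx] <- f[gi$idx] + tbl[[col]][i]
    else m[gi$idx] <- m[gi$idx] + tbl[[col]][i]
  }
  list(f = f, m = m)
}

.state_tbl <- function(f, m, col) {
  out <- dplyr::bind_rows(
    tibble::tibble(sex = "female", genotype = .FEM$label, value = f),
    tibble::tibble(sex = "male", genotype = .MALE$label, value = m)
  ) |>
    dplyr::filter(.data$value > 0)
  names(out)[names(out) == "value"] <- col
  out
}

#' One deterministic generation
#'
#' Advances per-sex genotype frequencies by one generation: mothers contribute
#' in proportion to frequency times fecundity, fathers in proportion to
#' frequency times mating weight (lottery polygyny), offspring follow the
#' exact zygote law with viability filtering, and the result is renormalized
#' within each sex.
#'
#' @param state Tibble with columns `sex`, `genotype`, `freq` (frequencies
#'   normalized within each sex).
#' @param params A [drive_params()] object.
#' @return State tibble of the next generation; attribute `extinct` is `TRUE`
#'   when one sex has no viable parents (all-zero state, not an error).
#' @export
step_deterministic <- function(state, params = drive_params()) {
  v <- .vectors_from_tbl(state, "freq")
  st <- .step_engine(v$f / max(sum(v$f), 1e-300),
                     v$m / max(sum(v$m), 1e-300),
                     .build_engine(params))
  out <- .state_tbl(st$f, st$m, "freq")
  attr(out, "extinct") <- st$extinct
  out
}

#' Deterministic cage trajectory
#'
#' Iterates [step_deterministic()] from the seeded population and summarises
#' each generation by the DsRed carrier fraction and the population L/F/R
#' allele frequencies (X-chromosome pool: two alleles per female, one per
#' male, equal sex ratio).
#'
#' @param config A [cage_config()] object.
#' @param params A [drive_params()] object.
#' @return A `cage_trajectory` tibble with columns `generation`, `dsred`,
#'   `freq_L`, `freq_F`, `freq_R`. Attribute `states` holds the per-genotype
#'   frequencies of every generation; attribute `extinct` flags loss of all
#'   viable parents.
#' @examples
#' pre <- cage_preset("self_elim_1to3")
#' run_deterministic(pre$config, pre$params)
#' @export
run_deterministic <- function(config, params = drive_params()) {
  stopifnot(inherits(config, "cage_config"))
  eng <- .build_engine(params)
  f <- config$seed_f / sum(config$seed_f)
  m <- config$seed_m / sum(config$seed_m)
  G <- config$generations
  summ <- matrix(NA_real_, G + 1L, 4L)
  states <- vector("list", G + 1L)
  summ[1L, ] <- .state_summary(f, m)
  states[[1L]] <- .state_tbl(f, m, "freq")
  extinct <- FALSE
  for (g in seq_len(G)) {
    st <- .step_engine(f, m, eng)
    f <- st$f; m <- st$m
    if (st$extinct) extinct <- TRUE
    summ[g + 1L, ] <- if (extinct) rep(NA_real_, 4L) else .state_summary(f, m)
    states[[g + 1L]] <- .state_tbl(f, m, "freq")
  }
  out <- tibble::tibble(
    generation = 0:G,
    dsred = summ[, 1L], freq_L = summ[, 2L],
    freq_F = summ[, 3L], freq_R = summ[, 4L]
  )
  attr(out, "states") <- dplyr::bind_rows(
    purrr::imap(states, ~ dplyr::mutate(.x, generation = .y - 1L,
                                        .before = 1L))
  )
  attr(out, "extinct") <- extinct
  class(out) <- c("cage_trajectory", class(out))
  out
}

# deterministic next-generation distribution from count (or freq) vectors
.next_gen_dist <- function(f, m, eng) {
  .step_engine(f / sum(f), m / sum(m), eng)
}

#' One stochastic (finite-census) generation
#'
#' Computes the exact next-generation genotype distribution from the current
#' counts and samples the next adult census from it: `census_adults / 2`
#' females and males drawn i.i.d. (multinomial).
#'
#' @param state Tibble with columns `sex`, `genotype`, `count`.
#' @param params A [drive_params()] object.
#' @param config A [cage_config()] object (supplies the census).
#' @param seed Optional integer seed for reproducibility.
#' @return Count state tibble of the next generation; attribute `extinct` is
#'   set when no viable parents of one sex remain (all-zero state).
#' @export
step_stochastic <- function(state, params, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- .vectors_from_tbl(state, "count")
  res <- .step_stoch_vec(v$f, v$m, .build_engine(params),
                         config$census_adults)
  out <- .state_tbl(res$f, res$m, "count")
  attr(out, "extinct") <- res$extinct
  out
}

.step_stoch_vec <- function(fc, mc, eng, census) {
  if (sum(fc) <= 0 || sum(mc) <= 0) {
    return(list(f = rep(0, .N_FEM), m = rep(0, .N_MALE), extinct = TRUE))
  }
  st <- .next_gen_dist(fc, mc, eng)
  if (st$extinct) {
    return(list(f = rep(0, .N_FEM), m = rep(0, .N_MALE), extinct = TRUE))
  }
  nf <- floor(census / 2)
  nm <- census - nf
  list(
    f = as.numeric(stats::rmultinom(1L, nf, st$f)),
    m = as.numeric(stats::rmultinom(1L, nm, st$m)),
    extinct = FALSE
  )
}

# full stochastic trajectory on count vectors; uses the current RNG stream
.run_stoch_counts <- function(config, params, eng = .build_engine(params)) {
  G <- config$generations
  fc <- matrix(0, .N_FEM, G + 1L)
  mc <- matrix(0, .N_MALE, G + 1L)
  fc[, 1L] <- config$seed_f
  mc[, 1L] <- config$seed_m
  for (g in seq_len(G)) {
    res <- .step_stoch_vec(fc[, g], mc[, g], eng, config$census_adults)
    fc[, g + 1L] <- res$f
    mc[, g + 1L] <- res$m
  }
  list(fc = fc, mc = mc)
}

.counts_summary <- function(fc, mc) {
  t(vapply(seq_len(ncol(fc)), function(g) {
    sf <- sum(fc[, g]); sm <- sum(mc[, g])
    if (sf + sm <= 0) return(rep(NA_real_, 4L))
    .state_summary(fc[, g] / max(sf, 1), mc[, g] / max(sm, 1))
  }, numeric(4L)))
}

#' Stochastic cage trajectories
#'
#' Runs replicate finite-census simulations of a cage design. Replicates are
#' drawn sequentially from one RNG stream seeded once with `seed`, so a given
#' `(config, params, reps, seed)` call is fully reproducible.
#'
#' @param config A [cage_config()] object.
#' @param params A [drive_params()] object.
#' @param reps Number of replicate cages.
#' @param seed Integer master seed.
#' @return Tibble with columns `rep`, `generation`, `dsred`, `freq_L`,
#'   `freq_F`, `freq_R` (`NA` rows after extinction of all viable parents).
#' @examples
#' pre <- cage_preset("hover_1to3")
#' run_stochastic(pre$config, pre$params, reps = 3, seed = 1)
#' @export
run_stochastic <- function(config, params = drive_params(), reps = 1L,
                           seed = 1L) {
  stopifnot(inherits(config, "cage_config"), reps >= 1)
  set.seed(seed)
  eng <- .build_engine(params)
  purrr::map_dfr(seq_len(reps), function(r) {
    tr <- .run_stoch_counts(config, params, eng)
    s <- .counts_summary(tr$fc, tr$mc)
    tibble::tibble(
      rep = r, generation = 0:config$generations,
      dsred = s[, 1L], freq_L = s[, 2L], freq_F = s[, 3L], freq_R = s[, 4L]
    )
  })
}

# observation model -----------------------------------------------------------

.observe_counts <- function(fc, mc, config) {
  N <- sum(fc) + sum(mc)
  if (N <= 0) {
    return(tibble::tibble(
      dsred_positive = 0L, dsred_scored = 0L,
      reads_L = 0L, reads_F = 0L, reads_R = 0L
    ))
  }
  K <- sum(fc * .FEM$cassette) + sum(mc * .MALE$cassette)
  n_scored <- min(N, round(config$dsred_scored_fraction * N))
  pos <- stats::rhyper(1L, K, N - K, n_scored)

  # two-stage allele sampling: flies first, then reads
  n_flies <- min(config$ngs_flies, N)
  pool <- c(rep(seq_len(.N_FEM), fc), rep(.N_FEM + seq_len(.N_MALE), mc))
  picked <- sample(pool, n_flies, replace = FALSE)
  alleles <- numeric(3L)
  for (id in picked) {
    if (id <= .N_FEM) alleles <- alleles + .FEM$pcount[id, ]
    else alleles[.MALE$p[id - .N_FEM]] <- alleles[.MALE$p[id - .N_FEM]] + 1
  }
  reads <- as.numeric(stats::rmultinom(1L, config$read_depth,
                                       alleles / sum(alleles)))
  tibble::tibble(
    dsred_positive = as.integer(pos), dsred_scored = as.integer(n_scored),
    reads_L = as.integer(reads[1L]), reads_F = as.integer(reads[2L]),
    reads_R = as.integer(reads[3L])
  )
}

#' Observe a cage generation
#'
#' Applies the laboratory scoring scheme to a count state: the DsRed+ tally is
#' a hypergeometric draw of the scored fraction of individuals, and allele
#' read counts come from a two-stage draw (sample `ngs_flies` flies without
#' replacement, pool their X alleles - one per male, two per female - then
#' draw `read_depth` reads multinomially from the pooled proportions).
#'
#' @param state Tibble with columns `sex`, `genotype`, `count`.
#' @param config A [cage_config()] object.
#' @param seed Optional integer seed.
#' @return One-row tibble with columns `dsred_positive`, `dsred_scored`,
#'   `reads_L`, `reads_F`, `reads_R`.
#' @export
observe <- function(state, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- .vectors_from_tbl(state, "count")
  .observe_counts(v$f, v$m, config)
}
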