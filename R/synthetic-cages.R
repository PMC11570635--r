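# Synthetic cage observation datasets: stochastic cage replicates pushed
# through the observation model, packaged with the hidden ground truth.

#' Generate a synthetic cage observation dataset
#'
#' Runs `n_cages` independent finite-census stochastic cages under a standard
#' design and applies the observation scheme to every generation: the
#' generation-0 record is the (known) seeded composition, later generations
#' get the hypergeometric DsRed tally and the two-stage 25-fly / read-depth
#' allele counts. The hidden truth (noise-free per-generation summaries of
#' each simulated cage) travels with the observations so recovery tests never
#' re-derive it.
#'
#' @param preset Name of a [cage_preset()] design (ignored when `config` and
#'   `params` are both supplied).
#' @param n_cages Number of replicate cages.
#' @param seed Integer master seed; all replicates and observations derive
#'   from it.
#' @param generations Number of generations.
#' @param config,params Optional explicit [cage_config()] / [drive_params()]
#'   overriding the preset bundle.
#' @return An object of class `cage_dataset`: a list with `observations`
#'   (tibble: `cage`, `generation`, `dsred_positive`, `dsred_scored`,
#'   `reads_L`, `reads_F`, `reads_R`), `truth` (tibble of per-cage noise-free
#'   summaries), `config`, `params` (the generating parameters), `mode` and
#'   `cas9_active` (design-level flags used by the likelihood).
#' @examples
#' ds <- generate_cage_dataset("self_elim_1to3", n_cages = 2, seed = 7)
#' ds$observations
#' @export
generate_cage_dataset <- function(preset = "self_elim_1to3", n_cages = 2L,
                                  seed = 1L, generations = 9L,
                                  config = NULL, params = NULL) {
  if (is.null(config) || is.null(params)) {
    pre <- cage_preset(preset, generations = generations)
    if (is.null(config)) config <- pre$config
    if (is.null(params)) params <- pre$params
  }
  stopifnot(inherits(config, "cage_config"), n_cages >= 1)
  validate_drive_params(params)
  set.seed(seed)
  eng <- .build_engine(params)
  G <- config$generations

  v0 <- .vectors_from_tbl(config$seeding, "count")
  obs0 <- .exact_observation(v0$f, v0$m, config)

  obs <- vector("list", n_cages)
  truth <- vector("list", n_cages)
  for (k in seq_len(n_cages)) {
    tr <- .run_stoch_counts(config, params, eng)
    rows <- vector("list", G + 1L)
    rows[[1L]] <- obs0
    for (g in seq_len(G)) {
      rows[[g + 1L]] <- .observe_counts(tr$fc[, g + 1L], tr$mc[, g + 1L],
                                        config)
    }
    obs[[k]] <- dplyr::bind_rows(rows) |>
      dplyr::mutate(cage = k, generation = 0:G, .before = 1L)
    s <- .counts_summary(tr$fc, tr$mc)
    truth[[k]] <- tibble::tibble(
      cage = k, generation = 0:G,
      dsred = s[, 1L], freq_L = s[, 2L], freq_F = s[, 3L], freq_R = s[, 4L]
    )
  }
  structure(
    list(
      observations = dplyr::bind_rows(obs),
      truth = dplyr::bind_rows(truth),
      config = config, params = params,
      mode = config$mode, cas9_active = params$cas9_active
    ),
    class = "cage_dataset"
  )
}

# exact (noise-free) observation of a known composition, used at generation 0
.exact_observation <- function(fc, mc, config) {
  N <- sum(fc) + sum(mc)
  K <- sum(fc * .FEM$cassette) + sum(mc * .MALE$cassette)
  n_scored <- min(N, round(config$dsred_scored_fraction * N))
  alleles <- drop(crossprod(.FEM$pcount, fc)) +
    vapply(1:3, function(a) sum(mc[.MALE$p == a]), numeric(1))
  reads <- floor(config$read_depth * alleles / sum(alleles))
  reads[1L] <- reads[1L] + (config$read_depth - sum(reads))
  tibble::tibble(
    dsred_positive = as.integer(round(n_scored * K / N)),
    dsred_scored = as.integer(n_scored),
    reads_L = as.integer(reads[1L]), reads_F = as.integer(reads[2L]),
    reads_R = as.integer(reads[3L])
  )
}

#' @export
print.cage_dataset <- function(x, ...) {
  cat("<cage_dataset>", x$mode, "mode,",
      dplyr::n_distinct(x$observations$cage), "cage(s),",
      x$config$generations, "generations",
      if (!x$cas9_active) "(Cas9 inactive)", "\n")
  print(x$observations, n = 4)
  invisible(x)
}
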