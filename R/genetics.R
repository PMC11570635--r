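# Single-genotype operations: gamete distributions, maternal carryover,
# viability and fitness weights, and the exact offspring law of a mated pair.

#' Germline para gamete distribution of a female
#'
#' Computes the distribution of the para allele transmitted through the female
#' germline. In a drive-bearing (E) female heterozygous L/F with active Cas9,
#' the cleavable F allele is converted to L with probability `c` (homology
#' directed repair off the L template) or destroyed to the loss-of-function R
#' allele with probability `l` (NHEJ), giving transmission probabilities
#' L: 0.5 + 0.5 c, F: 0.5 (1 - c - l), R: 0.5 l. All other contexts are
#' Mendelian.
#'
#' @param para_pair Character vector of two para alleles, e.g. `c("L", "F")`.
#' @param carries_E Logical; does the female carry the Cas9-bearing cassette?
#' @param params A [drive_params()] object.
#' @return Tibble with columns `allele` and `prob` (non-zero entries only;
#'   probabilities sum to 1).
#' @examples
#' germline_para_gametes(c("L", "F"), carries_E = TRUE, drive_params())
#' @export
germline_para_gametes <- function(para_pair, carries_E, params = drive_params()) {
  stopifnot(length(para_pair) == 2L, is.logical(carries_E))
  validate_drive_params(params)
  pi <- .parse_allele(para_pair, PARA_ALLELES, "para")
  dist <- numeric(3L)
  if (isTRUE(carries_E) && params$cas9_active && setequal(pi, c(1L, 2L))) {
    dist <- .drive_gamete_dist(params$c, params$l)
  } else {
    dist[pi[1L]] <- dist[pi[1L]] + 0.5
    dist[pi[2L]] <- dist[pi[2L]] + 0.5
  }
  tibble::tibble(allele = PARA_ALLELES, prob = dist) |>
    dplyr::filter(.data$prob > 0)
}

#' Maternal Cas9 carryover acting on one inherited para allele
#'
#' Cas9/gRNA ribonucleoprotein deposited into the egg by a drive-bearing
#' mother cleaves an inherited F allele with probability `m`; without an
#' assured repair template in the zygote the cut is modelled as mutagenic,
#' F -> R. L and R alleles, and all alleles in progeny of non-drive mothers,
#' pass unchanged.
#'
#' @param para_allele Single para allele label (`"L"`, `"F"` or `"R"`).
#' @param mother_is_E Logical; does the mother carry the Cas9 cassette?
#' @param params A [drive_params()] object.
#' @return Tibble with columns `allele`, `prob`.
#' @export
apply_maternal_deposition <- function(para_allele, mother_is_E,
                                      params = drive_params()) {
  stopifnot(length(para_allele) == 1L)
  validate_drive_params(params)
  pi <- .parse_allele(para_allele, PARA_ALLELES, "para")
  dist <- numeric(3L)
  dist[pi] <- 1
  if (isTRUE(mother_is_E) && params$cas9_active && pi == 2L) {
    dist[2L] <- 1 - params$m
    dist[3L] <- params$m
  }
  tibble::tibble(allele = PARA_ALLELES, prob = dist) |>
    dplyr::filter(.data$prob > 0)
}

#' Genotype viability
#'
#' Implements the lethal-mosaicism and loss-of-function viability rules:
#' males whose single para allele is R die (para is essential); males carrying
#' both the Cas9 cassette (E) and the cleavable F allele die (no repair
#' template); females that combine E with an F/F or R/F para pair die for the
#' same reason; and (switchable via `r_female_lethal`) R/F and R/R females are
#' inviable regardless of drive. With `cas9_active = FALSE` only the
#' template-independent R lethality applies.
#'
#' @param genotype Character vector of genotype strings (see
#'   [parse_genotype()]).
#' @param params A [drive_params()] object.
#' @return Integer vector of 0 (inviable) / 1 (viable).
#' @examples
#' viability(c("E;F", "Y+;F", "E/Y+;F/F"), drive_params())
#' @export
viability <- function(genotype, params = drive_params()) {
  eng <- .build_engine(params)
  vapply(genotype, function(g) {
    gi <- .genotype_index(g)
    as.integer(if (gi$sex == "male") eng$mviab[gi$idx] else eng$fviab[gi$idx])
  }, integer(1), USE.NAMES = FALSE)
}

#' Male mating-competitiveness weight
#'
#' Cassette-bearing males (E or E0 - the cost is the yellow- cassette
#' phenotype, not Cas9) have weight `1 - s_drive`, with the cost selected by
#' deployment mode (0.84 default against y+ competitors in self-eliminating
#' mode; 0.26 residual in hover mode), multiplied by the optional per-copy F
#' carrier cost. All other males have weight 1.
#'
#' @param genotype Character vector of male genotype strings.
#' @param params A [drive_params()] object.
#' @return Numeric vector of non-negative weights.
#' @export
mating_weight <- function(genotype, params = drive_params()) {
  eng <- .build_engine(params)
  vapply(genotype, function(g) {
    gi <- .genotype_index(g)
    if (gi$sex != "male") stop("mating_weight() applies to male genotypes",
                               call. = FALSE)
    eng$mate[gi$idx]
  }, numeric(1), USE.NAMES = FALSE)
}

#' Female fecundity weight
#'
#' F/F homozygous females have fecundity `1 - s_Fhom` (0.44 at the fitted
#' estimate); the cost is recessive, so L/F heterozygotes have weight 1 unless
#' the optional per-copy carrier cost is enabled.
#'
#' @param genotype Character vector of female genotype strings.
#' @param params A [drive_params()] object.
#' @return Numeric vector of non-negative weights.
#' @export
fecundity <- function(genotype, params = drive_params()) {
  eng <- .build_engine(params)
  vapply(genotype, function(g) {
    gi <- .genotype_index(g)
    if (gi$sex != "female") stop("fecundity() applies to female genotypes",
                                 call. = FALSE)
    eng$fec[gi$idx]
  }, numeric(1), USE.NAMES = FALSE)
}

#' Exact offspring distribution of a mated pair
#'
#' Enumerates all zygotes of a cross at a 50/50 sex ratio, applies germline
#' drive conversion in the maternal germline, maternal Cas9 carryover to every
#' inherited F allele of a drive mother's zygote, and the viability rules,
#' then renormalizes among viable offspring. The computation is exact (no
#' sampling). Parental fitness weights do not enter: this is the offspring law
#' conditional on the mating.
#'
#' @param mother,father Genotype strings (female / male).
#' @param params A [drive_params()] object.
#' @return Tibble with columns `sex`, `genotype`, `prob`, where `prob` is the
#'   viable-offspring distribution conditional on sex (sums to 1 within each
#'   sex). The attribute `survival` holds the pre-normalization surviving
#'   zygote fraction as `c(female = , male = , overall = )`.
#' @examples
#' offspring_distribution("E/Y+;L/F", "Y-;L", drive_params())
#' @export
offspring_distribution <- function(mother, father, params = drive_params()) {
  gm <- .genotype_index(mother)
  gf <- .genotype_index(father)
  if (gm$sex != "female" || gf$sex != "male") {
    stop("offspring_distribution() expects a female mother and male father",
         call. = FALSE)
  }
  eng <- .build_engine(params)
  f <- rep(0, .N_FEM); f[gm$idx] <- 1
  m <- rep(0, .N_MALE); m[gf$idx] <- 1
  st <- .step_engine(f, m, eng, weighted = FALSE)
  out <- dplyr::bind_rows(
    tibble::tibble(sex = "female", genotype = .FEM$label, prob = st$f),
    tibble::tibble(sex = "male", genotype = .MALE$label, prob = st$m)
  ) |>
    dplyr::filter(.data$prob > 0)
  attr(out, "survival") <- c(
    female = st$surv_f, male = st$surv_m,
    overall = 0.5 * (st$surv_f + st$surv_m)
  )
  out
}
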