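# Internal exact transmission engine.
#
# One generation is computed from per-sex genotype frequency vectors by
# aggregating egg and sperm haplotype distributions. Because both loci are
# X-linked, sons receive their X entirely from the mother; daughters combine a
# maternal egg with the father's single X. Mothers are split into drive (E)
# and non-drive classes because maternal Cas9 carryover applies to both the
# maternally and the paternally inherited F allele of a drive mother's
# zygote, which couples egg and sperm distributions through the mother class.

# germline para gamete distribution for an L/F female with active drive
.drive_gamete_dist <- function(c, l) {
  c(0.5 + 0.5 * c, 0.5 * (1 - c - l), 0.5 * l) # (L, F, R)
}

.build_engine <- function(params) {
  validate_drive_params(params)
  cas9 <- params$cas9_active
  sdr <- .s_drive(params)

  # egg para distribution per female genotype: germline drive conversion in
  # E-bearing L/F females, then maternal deposition of the transmitted allele
  pG <- .FEM$pmendel
  drv <- .FEM$carries_E & cas9 & .FEM$is_LF
  if (any(drv)) {
    d <- .drive_gamete_dist(params$c, params$l)
    pG[drv, 1L] <- d[1L]; pG[drv, 2L] <- d[2L]; pG[drv, 3L] <- d[3L]
  }
  dep <- .FEM$carries_E & cas9
  if (any(dep) && params$m > 0) {
    pG[dep, 3L] <- pG[dep, 3L] + params$m * pG[dep, 2L]
    pG[dep, 2L] <- pG[dep, 2L] * (1 - params$m)
  }

  EGG <- matrix(0, .N_FEM, 12L)
  for (y in 1:4) for (p in 1:3) {
    EGG[, (y - 1L) * 3L + p] <- .FEM$ymendel[, y] * pG[, p]
  }

  # sperm haplotype class distributions; SPE applies to zygotes of E mothers
  # (paternal F allele exposed to maternal Cas9 carryover)
  SP0 <- matrix(0, 12L, 12L)
  SPE <- matrix(0, 12L, 12L)
  for (j in 1:12) {
    SP0[j, j] <- 1
    if (cas9 && .MALE$p[j] == 2L) {
      SPE[j, j] <- 1 - params$m
      SPE[j, j + 1L] <- params$m # (y, F) -> (y, R)
    } else {
      SPE[j, j] <- 1
    }
  }

  # fitness weights
  fec <- ifelse(.FEM$is_FF, 1 - params$s_Fhom, 1) *
    (1 - params$s_Fcarrier_f)^.FEM$n_F
  mate <- ifelse(.MALE$cassette, 1 - sdr, 1) *
    ifelse(.MALE$p == 2L, 1 - params$s_Fcarrier_m, 1)

  # viability
  mviab <- as.numeric(!(.MALE$p == 3L |
                          (cas9 & .MALE$y == 1L & .MALE$p == 2L)))
  fdead <- (cas9 & .FEM$carries_E & (.FEM$is_FF | .FEM$is_RF)) |
    (params$r_female_lethal & (.FEM$is_RR | .FEM$is_RF))
  fviab <- as.numeric(!fdead)

  list(
    EGG = EGG, SP0 = SP0, SPE = SPE,
    fec = fec, mate = mate, fviab = fviab, mviab = mviab,
    isE = as.numeric(.FEM$carries_E)
  )
}

# one exact generation step on frequency vectors.
# f: length-60 female genotype frequencies; m: length-12 male frequencies.
# weighted = FALSE skips parental fitness weighting (per-pair offspring law).
.step_engine <- function(f, m, eng, weighted = TRUE) {
  wf <- if (weighted) f * eng$fec else f
  wm <- if (weighted) m * eng$mate else m
  sf <- sum(wf); sm <- sum(wm)
  if (sf <= 0 || sm <= 0) {
    return(list(f = rep(0, .N_FEM), m = rep(0, .N_MALE),
                surv_f = 0, surv_m = 0, extinct = TRUE))
  }
  wf <- wf / sf
  wm <- wm / sm
  wfE <- wf * eng$isE
  ME <- drop(crossprod(eng$EGG, wfE))
  M0 <- drop(crossprod(eng$EGG, wf - wfE))
  FE <- drop(crossprod(eng$SPE, wm))
  F0 <- drop(crossprod(eng$SP0, wm))

  sons <- (ME + M0) * eng$mviab
  dvec <- as.vector(outer(ME, FE)) + as.vector(outer(M0, F0))
  daughters <- drop(.AGG %*% dvec) * eng$fviab

  surv_m <- sum(sons)
  surv_f <- sum(daughters)
  list(
    f = if (surv_f > 0) daughters / surv_f else rep(0, .N_FEM),
    m = if (surv_m > 0) sons / surv_m else rep(0, .N_MALE),
    surv_f = surv_f, surv_m = surv_m,
    extinct = surv_f <= 0 || surv_m <= 0
  )
}

# summaries of a frequency state ---------------------------------------------

.state_summary <- function(f, m) {
  carrier <- 0.5 * sum(f * .FEM$cassette) + 0.5 * sum(m * .MALE$cassette)
  # X allele pool: 2 per female, 1 per male, equal sex ratio
  fem_alleles <- drop(crossprod(.FEM$pcount, f)) # counts weighted, sums to 2
  male_alleles <- vapply(1:3, function(a) sum(m[.MALE$p == a]), numeric(1))
  tot <- 0.5 * fem_alleles + 0.5 * male_alleles
  s <- sum(tot)
  freq <- if (s > 0) tot / s else rep(NA_real_, 3)
  c(dsred = carrier, freq_L = freq[1], freq_F = freq[2], freq_R = freq[3])
}
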