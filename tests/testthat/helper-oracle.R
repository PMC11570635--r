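# Independent brute-force oracle for the offspring law: enumerates every
# atomic event (maternal gamete x paternal gamete x deposition outcome x sex)
# with plain string bookkeeping, deliberately sharing no code with the
# package's matrix engine.

oracle_offspring <- function(mother, father, params) {
  gm <- parse_genotype(mother)
  gf <- parse_genotype(father)
  stopifnot(gm$sex == "female", gf$sex == "male")
  my <- c(gm$y1, gm$y2)
  mp <- c(gm$para1, gm$para2)
  carries_E <- "E" %in% my

  # maternal para gamete distribution (the yellow gamete is my[i], 0.5 each)
  pg <- c(L = 0, F = 0, R = 0)
  if (carries_E && params$cas9_active && setequal(mp, c("L", "F"))) {
    pg["L"] <- 0.5 + 0.5 * params$c
    pg["F"] <- 0.5 * (1 - params$c - params$l)
    pg["R"] <- 0.5 * params$l
  } else {
    pg[mp[1]] <- pg[mp[1]] + 0.5
    pg[mp[2]] <- pg[mp[2]] + 0.5
  }

  dep <- function(a) {
    if (carries_E && params$cas9_active && a == "F" && params$m > 0) {
      c(F = 1 - params$m, R = params$m)
    } else {
      stats::setNames(1, a)
    }
  }
  male_ok <- function(y, p) {
    if (p == "R") return(FALSE)
    !(params$cas9_active && y == "E" && p == "F")
  }
  female_ok <- function(ys, ps) {
    pp <- paste(sort(ps), collapse = "/")
    if (params$cas9_active && "E" %in% ys && pp %in% c("F/F", "F/R")) {
      return(FALSE)
    }
    !(params$r_female_lethal && pp %in% c("F/R", "R/R"))
  }
  canon <- function(alleles, levels) {
    paste(levels[sort(match(alleles, levels))], collapse = "/")
  }

  sons <- c()
  daughters <- c()
  add <- function(tab, key, pr) {
    tab[key] <- (if (key %in% names(tab)) tab[[key]] else 0) + pr
    tab
  }
  for (i in 1:2) for (pa in names(pg)) {
    base <- 0.5 * pg[[pa]]
    if (base == 0) next
    for (pa2 in names(dep(pa))) {
      pr <- base * dep(pa)[[pa2]]
      # son: X entirely maternal
      if (male_ok(my[i], pa2)) {
        sons <- add(sons, paste0(my[i], ";", pa2), 0.5 * pr)
      }
      # daughter: plus the father's X, his F allele also exposed to carryover
      for (pf2 in names(dep(gf$para1))) {
        prd <- 0.5 * pr * dep(gf$para1)[[pf2]]
        ys <- c(my[i], gf$y1)
        ps <- c(pa2, pf2)
        if (female_ok(ys, ps)) {
          key <- paste0(canon(ys, Y_ALLELES), ";", canon(ps, PARA_ALLELES))
          daughters <- add(daughters, key, prd)
        }
      }
    }
  }
  surv_m <- sum(sons) / 0.5
  surv_f <- sum(daughters) / 0.5
  list(
    male = if (length(sons)) sons / sum(sons) else sons,
    female = if (length(daughters)) daughters / sum(daughters) else daughters,
    surv_m = surv_m, surv_f = surv_f
  )
}

# offspring allele marginal (fraction of L/F/R in the offspring X pool) from
# an offspring_distribution() tibble
offspring_allele_marginal <- function(od) {
  alleles <- c(L = 0, F = 0, R = 0)
  for (i in seq_len(nrow(od))) {
    g <- parse_genotype(od$genotype[i])
    w <- od$prob[i] * attr(od, "survival")[[od$sex[i]]]
    for (a in stats::na.omit(c(g$para1, g$para2))) {
      alleles[a] <- alleles[a] + w
    }
  }
  alleles / sum(alleles)
}
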