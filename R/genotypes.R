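# Allele and genotype space for the two X-linked loci.
#
# yellow locus alleles: E  = full drive cassette (vasa-Cas9 + gRNA-F + DsRed, y-)
#                       E0 = control cassette without Cas9 (DsRed, y-)
#                       Y+ = wild-type yellow
#                       Y- = yellow mutant (no cassette)
# para (vgsc) alleles:  L = wild-type 1014L (not cleavable)
#                       F = resistant kdr 1014F (the only cleavable allele)
#                       R = NHEJ loss-of-function allele (target site destroyed)
#
# Males are hemizygous (one allele per locus); females carry unordered pairs.
# The two loci are ~50 cM apart, so inheritance is treated as independent and
# no cis/trans phase is tracked within females.

#' Allele labels at the yellow locus
#' @format Character vector of the four recognised yellow-locus alleles.
#' @export
Y_ALLELES <- c("E", "E0", "Y+", "Y-")

#' Allele labels at the para (vgsc) locus
#' @format Character vector of the three recognised para alleles.
#' @export
PARA_ALLELES <- c("L", "F", "R")

# unordered pair enumerations ------------------------------------------------

.pairs_of <- function(n) {
  out <- matrix(0L, nrow = n * (n + 1L) / 2L, ncol = 2L)
  k <- 0L
  for (a in seq_len(n)) for (b in a:n) {
    k <- k + 1L
    out[k, ] <- c(a, b)
  }
  out
}

.YPAIRS <- .pairs_of(4L) # 10 unordered yellow pairs
.PPAIRS <- .pairs_of(3L) # 6 unordered para pairs

.pair_lookup <- function(pairs, n) {
  lk <- matrix(0L, n, n)
  for (k in seq_len(nrow(pairs))) {
    lk[pairs[k, 1L], pairs[k, 2L]] <- k
    lk[pairs[k, 2L], pairs[k, 1L]] <- k
  }
  lk
}

.YPAIR_IDX <- .pair_lookup(.YPAIRS, 4L)
.PPAIR_IDX <- .pair_lookup(.PPAIRS, 3L)

.N_FEM <- nrow(.YPAIRS) * nrow(.PPAIRS) # 60
.N_MALE <- 4L * 3L # 12

# male genotype index: (y - 1) * 3 + p
.MALE <- local({
  y <- rep(1:4, each = 3L)
  p <- rep(1:3, times = 4L)
  list(
    y = y, p = p,
    cassette = y <= 2L, # E or E0 -> DsRed+, yellow-
    label = paste0(Y_ALLELES[y], ";", PARA_ALLELES[p])
  )
})

# female genotype index: (ypair - 1) * 6 + ppair
.FEM <- local({
  iy <- rep(seq_len(nrow(.YPAIRS)), each = nrow(.PPAIRS))
  ip <- rep(seq_len(nrow(.PPAIRS)), times = nrow(.YPAIRS))
  y1 <- .YPAIRS[iy, 1L]; y2 <- .YPAIRS[iy, 2L]
  p1 <- .PPAIRS[ip, 1L]; p2 <- .PPAIRS[ip, 2L]
  ymendel <- matrix(0, .N_FEM, 4L)
  pmendel <- matrix(0, .N_FEM, 3L)
  for (i in seq_len(.N_FEM)) {
    ymendel[i, y1[i]] <- ymendel[i, y1[i]] + 0.5
    ymendel[i, y2[i]] <- ymendel[i, y2[i]] + 0.5
    pmendel[i, p1[i]] <- pmendel[i, p1[i]] + 0.5
    pmendel[i, p2[i]] <- pmendel[i, p2[i]] + 0.5
  }
  n_F <- (p1 == 2L) + (p2 == 2L)
  list(
    y1 = y1, y2 = y2, p1 = p1, p2 = p2,
    carries_E = y1 == 1L | y2 == 1L,
    cassette = y1 <= 2L | y2 <= 2L,
    is_LF = (p1 == 1L & p2 == 2L),
    is_FF = (p1 == 2L & p2 == 2L),
    is_RF = (p1 == 2L & p2 == 3L),
    is_RR = (p1 == 3L & p2 == 3L),
    n_F = n_F,
    # para allele counts per female genotype (columns L, F, R)
    pcount = pmendel * 2,
    ymendel = ymendel,
    pmendel = pmendel,
    label = paste0(
      Y_ALLELES[y1], "/", Y_ALLELES[y2], ";",
      PARA_ALLELES[p1], "/", PARA_ALLELES[p2]
    )
  )
})

# daughter aggregation: egg class (12) x sperm class (12) -> female index,
# laid out so that as.vector(outer(egg, sperm)) matches (egg fastest).
.DMAP <- local({
  map <- integer(144L)
  k <- 0L
  for (s in seq_len(12L)) for (e in seq_len(12L)) {
    k <- k + 1L
    ye <- (e - 1L) %/% 3L + 1L; pe <- (e - 1L) %% 3L + 1L
    ys <- (s - 1L) %/% 3L + 1L; ps <- (s - 1L) %% 3L + 1L
    map[k] <- (.YPAIR_IDX[ye, ys] - 1L) * 6L + .PPAIR_IDX[pe, ps]
  }
  map
})

.AGG <- local({
  m <- matrix(0, .N_FEM, 144L)
  for (k in seq_len(144L)) m[.DMAP[k], k] <- 1
  m
})

# parsing / formatting --------------------------------------------------------

.parse_allele <- function(x, levels, what) {
  i <- match(x, levels)
  if (anyNA(i)) {
    stop("unknown ", what, " allele: ", paste(x[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  i
}

#' Parse a compact genotype string
#'
#' Genotypes are serialized as `"<yellow>;<para>"` for hemizygous males
#' (e.g. `"E;F"`) and `"<y1>/<y2>;<p1>/<p2>"` for females
#' (e.g. `"E/Y+;L/F"`). Allele order within a female is irrelevant; the
#' parsed form is canonical.
#'
#' @param x Character vector of genotype strings.
#' @return A tibble with columns `genotype` (canonical label), `sex`, and the
#'   allele columns `y1`, `y2`, `para1`, `para2` (`y2`/`para2` are `NA` for
#'   males).
#' @examples
#' parse_genotype(c("E;F", "Y+/E;F/L"))
#' @export
parse_genotype <- function(x) {
  stopifnot(is.character(x), length(x) > 0)
  parts <- strsplit(x, ";", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed genotype string: ", x[bad][1], call. = FALSE)
  purrr::map_dfr(parts, function(pp) {
    ys <- strsplit(pp[1], "/", fixed = TRUE)[[1]]
    ps <- strsplit(pp[2], "/", fixed = TRUE)[[1]]
    if (length(ys) != length(ps) || !length(ys) %in% 1:2) {
      stop("genotype must have 1 (male) or 2 (female) alleles at each locus: ",
           paste(pp, collapse = ";"), call. = FALSE)
    }
    yi <- sort(.parse_allele(ys, Y_ALLELES, "yellow"))
    pi <- sort(.parse_allele(ps, PARA_ALLELES, "para"))
    if (length(yi) == 1L) {
      tibble::tibble(
        genotype = .MALE$label[(yi - 1L) * 3L + pi], sex = "male",
        y1 = Y_ALLELES[yi], y2 = NA_character_,
        para1 = PARA_ALLELES[pi], para2 = NA_character_
      )
    } else {
      fi <- (.YPAIR_IDX[yi[1], yi[2]] - 1L) * 6L + .PPAIR_IDX[pi[1], pi[2]]
      tibble::tibble(
        genotype = .FEM$label[fi], sex = "female",
        y1 = Y_ALLELES[yi[1]], y2 = Y_ALLELES[yi[2]],
        para1 = PARA_ALLELES[pi[1]], para2 = PARA_ALLELES[pi[2]]
      )
    }
  })
}

# internal: genotype string -> (sex, index)
.genotype_index <- function(x) {
  stopifnot(length(x) == 1L)
  g <- parse_genotype(x)
  if (g$sex == "male") {
    list(sex = "male",
         idx = (match(g$y1, Y_ALLELES) - 1L) * 3L + match(g$para1, PARA_ALLELES))
  } else {
    yi <- match(c(g$y1, g$y2), Y_ALLELES)
    pi <- match(c(g$para1, g$para2), PARA_ALLELES)
    list(sex = "female",
         idx = (.YPAIR_IDX[yi[1], yi[2]] - 1L) * 6L + .PPAIR_IDX[pi[1], pi[2]])
  }
}

#' Enumerate the full genotype space
#'
#' Lists all 12 hemizygous male and 60 diploid female genotype classes at the
#' yellow x para locus pair, with a viability flag under the supplied
#' parameters.
#'
#' @param params A [drive_params()] object.
#' @return Tibble with columns `sex`, `genotype`, `viable`.
#' @export
genotype_space <- function(params = drive_params()) {
  eng <- .build_engine(params)
  dplyr::bind_rows(
    tibble::tibble(sex = "female", genotype = .FEM$label, viable = eng$fviab == 1),
    tibble::tibble(sex = "male", genotype = .MALE$label, viable = eng$mviab == 1)
  )
}
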