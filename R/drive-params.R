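#' Drive model parameters
#'
#' Bundles all rates and fitness parameters of the e-Drive model. The default
#' values are the fitted point estimates from the multi-generational cage
#' analysis: germline conversion of the cleavable resistant allele F to
#' wild-type L (`c` = 0.27), germline mutagenic repair F -> R (`l` = 0.32),
#' maternal Cas9 carryover cleaving an inherited F allele in the zygote
#' (`m` = 0.47), mating-competitiveness reduction of cassette-bearing males
#' (0.84 in self-eliminating mode, i.e. against y+ competitors; residual 0.26
#' in hover mode), and fecundity reduction of F/F homozygous females
#' (`s_Fhom` = 0.56).
#'
#' @param c Probability of germline conversion F -> L in drive-bearing L/F
#'   females (requires `c + l <= 1`).
#' @param l Probability of germline NHEJ mutagenesis F -> R in the same
#'   context.
#' @param m Probability that maternal Cas9 carryover from a drive-bearing
#'   mother cleaves an inherited F allele at zygote formation (modelled as
#'   mutagenic, F -> R).
#' @param s_drive_self Mating-competitiveness reduction of cassette-bearing
#'   (y-) males in self-eliminating mode (y+ competitors).
#' @param s_drive_hover Residual mating-competitiveness reduction of
#'   cassette-bearing males in hover mode (y- competitors).
#' @param s_Fhom Fecundity reduction of F/F homozygous females (recessive:
#'   L/F heterozygotes pay nothing by default).
#' @param s_Fcarrier_f,s_Fcarrier_m Optional per-copy fitness cost of the F
#'   allele in females / males; off (0) by default.
#' @param cas9_active Logical; `FALSE` models the no-Cas9 control cassette
#'   (no cleavage, no drive-context lethality).
#' @param mode `"self_eliminating"` (cassette released into a y+ background)
#'   or `"hover"` (y- background); selects which mating cost applies.
#' @param r_female_lethal Logical; whether R/F and R/R females are inviable
#'   even without the drive (R is a loss-of-function allele of an essential
#'   channel). Default `TRUE`.
#' @return An object of class `drive_params` (a validated named list).
#' @examples
#' drive_params() # fitted point estimates, self-eliminating mode
#' drive_params(mode = "hover")
#' neutral_params() # all drive action and costs switched off
#' @export
drive_params <- function(c = 0.27, l = 0.32, m = 0.47,
                         s_drive_self = 0.84, s_drive_hover = 0.26,
                         s_Fhom = 0.56,
                         s_Fcarrier_f = 0, s_Fcarrier_m = 0,
                         cas9_active = TRUE,
                         mode = c("self_eliminating", "hover"),
                         r_female_lethal = TRUE) {
  mode <- match.arg(mode)
  p <- list(
    c = c, l = l, m = m,
    s_drive_self = s_drive_self, s_drive_hover = s_drive_hover,
    s_Fhom = s_Fhom, s_Fcarrier_f = s_Fcarrier_f, s_Fcarrier_m = s_Fcarrier_m,
    cas9_active = isTRUE(cas9_active), mode = mode,
    r_female_lethal = isTRUE(r_female_lethal)
  )
  validate_drive_params(p)
  structure(p, class = "drive_params")
}

#' @rdname drive_params
#' @export
neutral_params <- function(mode = c("self_eliminating", "hover")) {
  drive_params(
    c = 0, l = 0, m = 0, s_drive_self = 0, s_drive_hover = 0,
    s_Fhom = 0, cas9_active = FALSE, mode = mode
  )
}

validate_drive_params <- function(p) {
  num <- c("c", "l", "m", "s_drive_self", "s_drive_hover", "s_Fhom",
           "s_Fcarrier_f", "s_Fcarrier_m")
  for (nm in num) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("drive parameter '", nm, "' must be a probability in [0, 1]",
           call. = FALSE)
    }
  }
  if (p$c + p$l > 1 + 1e-12) {
    stop("conversion probabilities must satisfy c + l <= 1", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.drive_params <- function(x, ...) {
  cat("<drive_params> mode =", x$mode,
      if (!x$cas9_active) "(Cas9 inactive)", "\n")
  cat(sprintf(
    "  c = %.3f  l = %.3f  m = %.3f\n  s_drive(self) = %.3f  s_drive(hover) = %.3f  s_Fhom = %.3f\n",
    x$c, x$l, x$m, x$s_drive_self, x$s_drive_hover, x$s_Fhom
  ))
  if (x$s_Fcarrier_f > 0 || x$s_Fcarrier_m > 0) {
    cat(sprintf("  s_Fcarrier_f = %.3f  s_Fcarrier_m = %.3f\n",
                x$s_Fcarrier_f, x$s_Fcarrier_m))
  }
  invisible(x)
}

# mating cost that applies under the current deployment mode
.s_drive <- function(params) {
  if (params$mode == "hover") params$s_drive_hover else params$s_drive_self
}

# replace a named subset of parameters (used by the MCMC)
.params_update <- function(params, values) {
  for (nm in names(values)) params[[nm]] <- unname(values[[nm]])
  class(params) <- "drive_params"
  params
}
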