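# Cross-based empirical estimators: the receiver-conversion formula for F2
# females, the x2 receiver-chromosome correction, and the donor:receiver
# transmission-bias test.

#' Receiver allelic conversion rate from F2 female reads
#'
#' In F2 females inheriting one receiver chromosome, half of all sequenced
#' reads come from the reference paternal X, so the conversion rate on the
#' receiver chromosome is `2 * (Y - 0.5)` where `Y` is the observed fraction
#' of wild-type L reads. Values are clamped to `[-1, 1]`; negative values are
#' returned as-is (a useful diagnostic of sampling noise or reference
#' mis-assignment), not hidden.
#'
#' @param Y Numeric vector of L read fractions in `[0, 1]`.
#' @return Numeric vector of conversion rates.
#' @examples
#' female_conversion_rate(c(0.5, 0.64, 1))
#' @export
female_conversion_rate <- function(Y) {
  if (!is.numeric(Y) || any(is.na(Y)) || any(Y < 0 | Y > 1)) {
    stop("`Y` must be a read fraction in [0, 1]", call. = FALSE)
  }
  pmin(pmax(2 * (Y - 0.5), -1), 1)
}

#' Receiver-chromosome allele frequencies from raw F2 female read fractions
#'
#' Converts raw per-allele read fractions measured in F2 females (where half
#' the reads are the paternal reference L allele) into receiver-chromosome
#' frequencies: `L_receiver = 2 (L_raw - 0.5)`, `F_receiver = 2 F_raw`,
#' `NHEJ_receiver = 2 NHEJ_raw`. When the inputs sum to 1 the outputs do too
#' (exact closed form); a `renormalized` flag marks the numerically
#' impossible case.
#'
#' @param raw Numeric vector of length 3 (optionally named `L`, `F`, `NHEJ`)
#'   of raw read fractions summing to 1.
#' @return Tibble with columns `allele`, `raw`, `receiver`; attribute
#'   `renormalized` is `TRUE` if the outputs had to be rescaled (deviation
#'   from unit sum beyond 1e-9).
#' @examples
#' receiver_class_frequencies(c(L = 0.64, F = 0.24, NHEJ = 0.12))
#' @export
receiver_class_frequencies <- function(raw) {
  if (!is.numeric(raw) || length(raw) != 3L || any(is.na(raw))) {
    stop("`raw` must be three numeric read fractions (L, F, NHEJ)",
         call. = FALSE)
  }
  if (abs(sum(raw) - 1) > 1e-8) {
    stop("raw read fractions must sum to 1", call. = FALSE)
  }
  rec <- c(2 * (raw[[1L]] - 0.5), 2 * raw[[2L]], 2 * raw[[3L]])
  renorm <- abs(sum(rec) - 1) > 1e-9
  if (renorm && sum(rec) > 0) rec <- rec / sum(rec)
  out <- tibble::tibble(
    allele = c("L", "F", "NHEJ"),
    raw = as.numeric(raw),
    receiver = rec
  )
  attr(out, "renormalized") <- renorm
  out
}

#' Donor versus receiver chromosome transmission bias
#'
#' Ratio of recovered donor (mini-white marked) to receiver (w-) chromosomes
#' among F2 progeny, with a two-sided exact binomial test against Mendelian
#' 50:50 transmission.
#'
#' @param n_donor,n_receiver Non-negative integer counts (not both zero).
#' @return One-row tibble with columns `n_donor`, `n_receiver`, `ratio`
#'   (`Inf` when no receivers were recovered) and `p_value`.
#' @examples
#' transmission_ratio(100, 50)
#' @export
transmission_ratio <- function(n_donor, n_receiver) {
  stopifnot(
    length(n_donor) == 1L, length(n_receiver) == 1L,
    n_donor >= 0, n_receiver >= 0
  )
  if (n_donor + n_receiver == 0) {
    stop("at least one chromosome must have been recovered", call. = FALSE)
  }
  test <- stats::binom.test(n_donor, n_donor + n_receiver, p = 0.5,
                            alternative = "two.sided")
  tibble::tibble(
    n_donor = as.integer(n_donor),
    n_receiver = as.integer(n_receiver),
    ratio = if (n_receiver == 0) Inf else n_donor / n_receiver,
    p_value = test$p.value
  )
}
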