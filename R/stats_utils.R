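#' Exact upper binomial tail P(X >= k)
#'
#' Direct log-space summation of the binomial mass from `k` to `n`,
#' numerically stable for the tiny tail probabilities (around 1e-6)
#' used when arguing that mapping artifacts cannot explain a handful of
#' outlier windows among a few hundred tested.
#'
#' @param n number of trials.
#' @param p per-trial success probability.
#' @param k threshold count.
#' @return `P(X >= k)` for `X ~ Binomial(n, p)`.
#' @export
binomial_tail_at_least <- function(n, p, k) {
  if (!is.numeric(n) || n < 0 || n != round(n)) stopf("invalid n")
  check_prob(p, "p")
  if (!is.numeric(k) || k < 0 || k > n || k != round(k))
    stopf("k must be an integer in [0, n]")
  if (k == 0) return(1)
  if (p == 0) return(0)
  if (p == 1) return(1)
  kk <- k:n
  sum(exp(lchoose(n, kk) + kk * log(p) + (n - kk) * log1p(-p)))
}

#' Probability that k independent events all occur
#'
#' `rate^k`: e.g. the chance that four windows, each a false positive
#' with probability equal to the FDR of 0.2, are all false positives is
#' `0.2^4 = 0.0016`.
#'
#' @param rate per-event probability in `[0, 1]`.
#' @param k number of independent events (non-negative integer).
#' @return `rate^k`.
#' @export
independent_product <- function(rate, k) {
  check_prob(rate, "rate")
  if (!is.numeric(k) || k < 0 || k != round(k)) stopf("invalid k")
  rate^k
}

#' Conversion between physical and population-scaled distance
#'
#' One rho unit is `4 Ne r`; under the working convention of 1 cM/Mb
#' male recombination near the SDR and 0.01 cM per rho unit, one rho
#' corresponds to 10 kb, so 0.6 Mb is 60 rho and 4.6 Mb is 460 rho.
#' (Note that plugging Ne = 1e5 and r per 10 kb into `4 Ne r` directly
#' gives a different number; the cM-per-rho constant is exposed
#' explicitly so the convention is an auditable choice, not a hidden
#' assumption.)
#'
#' @param cm_per_mb local recombination map density (cM per Mb).
#' @param cm_per_rho map length corresponding to one rho unit.
#' @return list of class `rho_scaling` with the derived `bp_per_rho`.
#' @export
rho_scaling <- function(cm_per_mb = 1.0, cm_per_rho = 0.01) {
  check_positive(cm_per_mb, "cm_per_mb")
  check_positive(cm_per_rho, "cm_per_rho")
  structure(list(cm_per_mb = cm_per_mb, cm_per_rho = cm_per_rho,
                 bp_per_rho = cm_per_rho / cm_per_mb * 1e6),
            class = "rho_scaling")
}

#' @rdname rho_scaling
#' @param distance_bp physical distance in bp (>= 0).
#' @param scaling a [rho_scaling()].
#' @export
physical_to_rho <- function(distance_bp, scaling = rho_scaling()) {
  if (any(distance_bp < 0)) stopf("distance must be >= 0")
  distance_bp / scaling$bp_per_rho
}

#' @rdname rho_scaling
#' @param rho distance in rho units (>= 0).
#' @export
rho_to_physical <- function(rho, scaling = rho_scaling()) {
  if (any(rho < 0)) stopf("distance must be >= 0")
  rho * scaling$bp_per_rho
}
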