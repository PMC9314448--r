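# Conversion of lambda_s to heterozygous selection coefficients under
# strong selection and mutation-selection balance. At equilibrium a
# deleterious allele segregates at frequency ~ mu / s_het, so the expected
# number of polymorphic sites among M sites observed in 2N chromosomes
# matches the depletion model when
#   s_het ~ (2 N mu / Pbar) / (1 - lambda_s) = (2 N / c) / (1 - lambda_s),
# with c = Pbar / mu.

#' Parameters of the mutation-selection balance conversion
#'
#' @param N Number of diploid individuals in the panel (default 71702).
#' @param mu Per-site, per-generation mutation rate (default 1.2e-8).
#' @param P_bar Mean per-site rate of rare-variant occurrence under
#'   neutrality (default 0.162; recompute from your own neutral sites where
#'   available).
#' @return A `selection_params` list with the derived constant
#'   `c = P_bar / mu`.
#' @examples
#' selection_params()$c # 1.35e7
#' @export
selection_params <- function(N = 71702, mu = 1.2e-8, P_bar = 0.162) {
  stopifnot(N > 0, mu > 0, P_bar > 0)
  structure(list(N = N, mu = mu, P_bar = P_bar, c = P_bar / mu),
            class = "selection_params")
}

#' @export
print.selection_params <- function(x, ...) {
  cat(sprintf("N = %d diploids, mu = %.3g, Pbar = %.4g, c = Pbar/mu = %.4g\n",
              x$N, x$mu, x$P_bar, x$c))
  invisible(x)
}

#' Heterozygous selection coefficient implied by lambda_s
#'
#' `s_het ~ (2N/c) / (1 - lambda_s)` under mutation-selection balance.
#' The approximation is only trustworthy when selection is strong; a
#' warning is emitted for `lambda_s < 0.45`, below which the implied
#' coefficients are too small for the equilibrium assumption to pin them
#' down reliably.
#'
#' @param lambda_s Depletion estimate(s), each `< 1`.
#' @param params A [selection_params()] object.
#' @return Implied `s_het` value(s); strictly increasing in `lambda_s`.
#' @examples
#' shet_from_lambda(0.45) # ~0.02
#' @export
shet_from_lambda <- function(lambda_s, params = selection_params()) {
  stopifnot(inherits(params, "selection_params"))
  if (any(lambda_s >= 1)) stop("lambda_s must be < 1")
  if (any(lambda_s < 0.45)) {
    warning("lambda_s < 0.45: implied s_het is outside the regime where ",
            "the mutation-selection balance approximation is reliable")
  }
  (2 * params$N / params$c) / (1 - lambda_s)
}

#' Background-adjusted harmonic-mean selection coefficient
#'
#' When a fraction `1 - rho` of the target sites is effectively neutral,
#' the depletion signal is diluted; given an external estimate of `rho`
#' (the fraction of sites under any selection), the harmonic mean of
#' `s_het` over the selected sites is `(2N/c) * rho / (rho - lambda_s)`.
#' With `rho = 1` this reduces to [shet_from_lambda()].
#'
#' @param lambda_s Depletion estimate.
#' @param rho Fraction of sites under selection, in (0, 1], strictly
#'   greater than `lambda_s`.
#' @param params A [selection_params()] object.
#' @return Adjusted harmonic-mean `s_het`.
#' @export
shet_adjusted <- function(lambda_s, rho, params = selection_params()) {
  stopifnot(inherits(params, "selection_params"))
  if (any(rho <= 0 | rho > 1)) stop("rho must lie in (0, 1]")
  if (any(rho <= lambda_s)) {
    stop("rho must exceed lambda_s (otherwise the harmonic mean is ",
         "undefined or negative)")
  }
  (2 * params$N / params$c) * rho / (rho - lambda_s)
}

#' Harmonic mean of selection coefficients
#'
#' `H[s] = M / sum(1/s_i)`; by the AM-HM inequality it never exceeds the
#' arithmetic mean, which is why depletion-based estimates under variable
#' selection bound the arithmetic mean from below.
#'
#' @param s_values Positive selection coefficients.
#' @return The harmonic mean.
#' @export
harmonic_mean_s <- function(s_values) {
  if (length(s_values) == 0L) stop("empty vector")
  if (any(s_values <= 0)) stop("all selection coefficients must be positive")
  length(s_values) / sum(1 / s_values)
}
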