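# Maximum-likelihood estimation of lambda_s, the fractional depletion of
# rare variants relative to the neutral mutation model.
#
# The generative model is Y_i^(j) ~ Bernoulli((1 - lambda_s) P_i^(j)) over
# retained sites i and alternative alleles j in {1,2,3}. The closed-form
# (bias-corrected) estimator is lambda_hat = 1 - R' / (M * Pbar), with
#   R'   = sum of Y over all (site, allele) pairs,
#   M    = number of retained sites,
#   Pbar = mean over sites of the per-site sum of P (= 3 * mean of all P),
# and variance
#   Var(lambda_hat) = (1 - l) / (M Pbar) - (1 - l)^2 T / (M Pbar)^2,
# where T = sum of P^2. The likelihood-ratio test compares the exact
# likelihood at its (numerically located) maximum with lambda_s = 0.

lambda_suffstats <- function(tab) {
  keep <- !tab$excluded
  p <- tab$P[keep]
  y <- tab$Y[keep]
  if (length(p) == 0L) stop("no retained sites (M = 0)")
  if (anyNA(p)) stop("P has not been filled for all retained rows")
  if (any(p <= 0 | p >= 1)) stop("every retained P must lie in (0,1)")
  M <- length(p) / 3
  if (M != floor(M)) stop("site table must carry 3 allele rows per site")
  list(y = y, p = p, M = M, R_prime = sum(y), P_bar = sum(p) / M,
       T = sum(p^2))
}

#' Estimate the depletion of rare variants (lambda_s)
#'
#' Fits the rare-variant depletion model to a site table whose `P` column
#' has been filled by a mutation model. Returns the closed-form
#' bias-corrected maximum-likelihood estimate of `lambda_s`, its standard
#' error from the Bernoulli sampling variance of the rare-variant count,
#' the exact log-likelihood at the (numerically maximised) estimate and at
#' the null `lambda_s = 0`, and a likelihood-ratio p-value against the
#' null. `lambda_s` may be negative (rare variants in excess of the neutral
#' expectation) and is never clamped.
#'
#' @param tab A `site_table` with `P` filled for retained rows.
#' @param max_sites Optional cap on the number of sites used; when fewer
#'   sites than `M` are requested a seeded simple random sample of sites is
#'   taken. Default `NULL` uses all sites.
#' @param seed Seed for the optional subsample.
#' @return A `lambda_fit` object with components `lambda_s`, `stderr`,
#'   `R_prime`, `M`, `P_bar`, `Q_bar`, `T`, `loglik_alt`, `loglik_null`,
#'   `p_value` and `lambda_mle` (the exact-likelihood maximiser used for
#'   the test). Supports `print`, `summary`, `coef`, `vcov`, `confint`,
#'   `logLik` and `simulate` methods.
#' @examples
#' tab <- toy_site_table(p = rep(0.05, 300), y = rep(c(1, 0), c(10, 290)))
#' fit <- estimate_lambda(tab)
#' coef(fit)
#' @export
estimate_lambda <- function(tab, max_sites = NULL, seed = NULL) {
  if (!is.null(max_sites)) {
    keep <- !tab$excluded
    sites <- unique(paste(tab$chrom, tab$pos0)[keep])
    if (length(sites) > max_sites) {
      local_seed(seed)
      take <- sample(sites, max_sites)
      tab <- tab[paste(tab$chrom, tab$pos0) %in% take, , drop = FALSE]
    }
  }
  ss <- lambda_suffstats(tab)
  MP <- ss$M * ss$P_bar
  if (MP <= 0) stop("expected number of rare variants (M * Pbar) is zero")
  lambda_hat <- 1 - ss$R_prime / MP

  v <- (1 - lambda_hat) / MP - (1 - lambda_hat)^2 * ss$T / MP^2
  boundary <- FALSE
  if (v < 0) {
    warning("estimated variance negative; clamped to 0")
    v <- 0
  }
  if (lambda_hat >= 1) {
    boundary <- TRUE
    warning("lambda_s at the boundary 1 (no rare variants observed); ",
            "the standard error is not asymptotically regular there")
  }

  ll <- function(l) loglik_bernoulli(ss$y, ss$p, l)
  lo <- 1 - 1 / max(ss$p) + 1e-9
  opt <- stats::optimize(ll, c(lo, 1), maximum = TRUE, tol = 1e-9)
  lambda_mle <- opt$maximum
  loglik_alt <- opt$objective
  # never report a maximum below the closed-form start
  if (lambda_hat < 1 && lambda_hat > lo && ll(lambda_hat) > loglik_alt) {
    lambda_mle <- lambda_hat
    loglik_alt <- ll(lambda_hat)
  }
  if (ss$R_prime == 0 && ll(1) >= loglik_alt) {
    lambda_mle <- 1
    loglik_alt <- ll(1)
  }
  loglik_null <- ll(0)
  stat <- max(0, 2 * (loglik_alt - loglik_null))
  p_value <- stats::pchisq(stat, df = 1, lower.tail = FALSE)

  structure(list(lambda_s = lambda_hat, stderr = sqrt(v),
                 R_prime = ss$R_prime, M = ss$M, P_bar = ss$P_bar,
                 Q_bar = ss$P_bar / 3, T = ss$T,
                 loglik_alt = loglik_alt, loglik_null = loglik_null,
                 p_value = p_value, lambda_mle = lambda_mle,
                 boundary = boundary, P = ss$p,
                 call = match.call()),
            class = "lambda_fit")
}

loglik_bernoulli <- function(y, p, lambda_s) {
  if (lambda_s == 1) {
    # every Bernoulli parameter is 0: impossible if a rare variant was seen
    return(if (sum(y) > 0) -Inf else 0)
  }
  q <- (1 - lambda_s) * p
  if (any(q < 0) || any(q >= 1)) {
    stop("lambda_s = ", lambda_s,
         " puts a Bernoulli parameter outside [0,1)")
  }
  sum(y * log(q) + (1 - y) * log1p(-q))
}

#' Exact log-likelihood of lambda_s for a site table
#'
#' The log of the full allele-specific Bernoulli likelihood over retained
#' (site, allele) pairs.
#'
#' @param tab A `site_table` with `P` filled.
#' @param lambda_s Scalar depletion parameter; must keep every Bernoulli
#'   parameter `(1 - lambda_s) * P` in `[0, 1)` (the boundary value 1 is
#'   allowed and yields `-Inf` if any rare variant is present).
#' @return The log-likelihood.
#' @export
loglikelihood <- function(tab, lambda_s) {
  ss <- lambda_suffstats(tab)
  loglik_bernoulli(ss$y, ss$p, lambda_s)
}

#' Likelihood-ratio p-value for lambda_s != 0
#'
#' @param tab A `site_table` with `P` filled.
#' @return Upper-tail chi-squared (1 df) p-value of twice the log-likelihood
#'   ratio between the maximised alternative and the null `lambda_s = 0`.
#' @export
lrt_pvalue <- function(tab) {
  estimate_lambda(tab)$p_value
}

#' Site-level (simple) depletion estimator
#'
#' The single-indicator-per-site variant: `1 - R / (M * mean_P)`. Identical
#' to the full allele-specific estimator when no site carries more than one
#' rare variant.
#'
#' @param n_rare Number of sites with a rare variant (R).
#' @param n_sites Number of retained sites (M).
#' @param mean_P Mean per-site probability of carrying a rare variant.
#' @return The estimate of lambda_s.
#' @export
estimate_lambda_simple <- function(n_rare, n_sites, mean_P) {
  if (n_sites <= 0) stop("n_sites must be positive")
  if (mean_P <= 0) stop("mean_P must be positive")
  if (n_rare > n_sites) {
    stop("n_rare exceeds n_sites: at most one rare-variant flag per site ",
         "in the site-level estimator")
  }
  1 - n_rare / (n_sites * mean_P)
}

# ---- methods ----------------------------------------------------------

#' @export
print.lambda_fit <- function(x, ...) {
  cat(sprintf("lambda_s = %.4g (SE %.3g), LRT p = %.3g\n",
              x$lambda_s, x$stderr, x$p_value))
  cat(sprintf("R' = %d rare variants over M = %d sites (Pbar = %.4g)\n",
              x$R_prime, as.integer(x$M), x$P_bar))
  if (x$lambda_s > 0.45 && x$lambda_s < 1) {
    cat(sprintf("implied s_het (mutation-selection balance) ~ %.3g\n",
                shet_from_lambda(x$lambda_s)))
  }
  invisible(x)
}

#' @export
summary.lambda_fit <- function(object, ...) {
  out <- c(lambda_s = object$lambda_s, stderr = object$stderr,
           R_prime = object$R_prime, M = object$M, P_bar = object$P_bar,
           Q_bar = object$Q_bar, T = object$T,
           loglik_alt = object$loglik_alt, loglik_null = object$loglik_null,
           p_value = object$p_value)
  class(out) <- "summary.lambda_fit"
  out
}

#' @export
print.summary.lambda_fit <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}

#' @export
coef.lambda_fit <- function(object, ...) {
  c(lambda_s = object$lambda_s)
}

#' @export
vcov.lambda_fit <- function(object, ...) {
  matrix(object$stderr^2, 1, 1, dimnames = list("lambda_s", "lambda_s"))
}

#' @export
logLik.lambda_fit <- function(object, ...) {
  structure(object$loglik_alt, df = 1L, nobs = 3L * object$M,
            class = "logLik")
}

#' @export
confint.lambda_fit <- function(object, parm = "lambda_s", level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- matrix(object$lambda_s + c(-1, 1) * z * object$stderr, 1, 2,
                dimnames = list("lambda_s",
                                sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                           1 - (1 - level) / 2))))
  out
}

#' @export
simulate.lambda_fit <- function(object, nsim = 1, seed = NULL, ...) {
  local_seed(seed)
  p <- (1 - object$lambda_s) * object$P
  p <- pmin(pmax(p, 0), 1 - 1e-12)
  out <- as.data.frame(matrix(stats::rbinom(length(p) * nsim, 1L,
                                            rep(p, nsim)),
                              ncol = nsim))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Build a minimal in-memory site table for simulation and testing
#'
#' Wraps per-(site, allele) probabilities (and optionally indicators) in a
#' valid `site_table` on a synthetic contig, three alleles per site.
#'
#' @param p Numeric vector of per-(site, allele) probabilities; its length
#'   must be a multiple of 3.
#' @param y Optional 0/1 vector of rare-variant indicators (default all 0).
#' @param chrom Chromosome name for the synthetic rows.
#' @return A `site_table`.
#' @export
toy_site_table <- function(p, y = NULL, chrom = "sim") {
  n <- length(p)
  if (n %% 3L != 0L) stop("length(p) must be a multiple of 3")
  if (is.null(y)) y <- rep(0L, n)
  stopifnot(length(y) == n)
  m <- n / 3L
  as_site_table(data.frame(
    chrom = rep(chrom, n), pos0 = rep(seq_len(m) - 1L, each = 3L),
    ref = rep("A", n), alt = rep(c("C", "G", "T"), m),
    context7 = rep("AAAAAAA", n), Y = as.integer(y),
    common = rep(0L, n), coverage = rep(30, n), gc_frac = rep(0.5, n),
    cpg_island = rep(FALSE, n), excluded = rep(FALSE, n),
    reason = rep("", n), P = p, stringsAsFactors = FALSE))
}
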