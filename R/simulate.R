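# Simulators: (a) the exact Bernoulli depletion model with known lambda_s,
# (b) mutation-selection balance with site-wise s_het drawn from a DFE
# (point mass at zero + Gamma), via the equilibrium Poisson sampler,
# and (c) a synthetic genome generator for end-to-end fixtures.

#' Distribution of fitness effects (point mass + Gamma)
#'
#' A mixture of a point mass at `s_het = 0` (weight `pi0`) and a Gamma
#' distribution with shape `shape` and scale `scale` on the `s_het` scale.
#' The defaults are a published coding-region DFE re-scaled to
#' heterozygous-selection units.
#'
#' @param pi0 Weight of the point mass at zero, in \[0, 1\].
#' @param shape,scale Gamma shape and scale (both positive).
#' @return A `dfe` object.
#' @export
dfe <- function(pi0 = 0.031, shape = 0.1930, scale = 0.0168) {
  if (pi0 < 0 || pi0 > 1) stop("pi0 must lie in [0,1]")
  if (shape <= 0 || scale <= 0) stop("Gamma shape and scale must be positive")
  structure(list(pi0 = pi0, shape = shape, scale = scale), class = "dfe")
}

#' @export
print.dfe <- function(x, ...) {
  cat(sprintf("DFE: point mass %.3g at 0 + Gamma(shape %.4g, scale %.4g); mean s_het %.4g\n",
              x$pi0, x$shape, x$scale, dfe_mean(x)))
  invisible(x)
}

#' @rdname dfe
#' @param n Number of draws.
#' @param d A `dfe`.
#' @export
rdfe <- function(n, d) {
  stopifnot(inherits(d, "dfe"))
  s <- stats::rgamma(n, shape = d$shape, scale = d$scale)
  s[stats::runif(n) < d$pi0] <- 0
  s
}

dfe_mean <- function(d) (1 - d$pi0) * d$shape * d$scale

# probability mass of the DFE per bin of a histogram over s >= 0
dfe_bin_mass <- function(d, breaks) {
  m <- diff(stats::pgamma(breaks, shape = d$shape, scale = d$scale)) *
    (1 - d$pi0)
  if (breaks[1] <= 0) m[1] <- m[1] + d$pi0
  m
}

#' Simulate rare-variant indicators under the exact depletion model
#'
#' Draws `Y ~ Bernoulli((1 - lambda_s) P)` independently for every
#' (site, allele) pair.
#'
#' @param p Per-(site, allele) probabilities: a numeric vector or a
#'   `site_table` with `P` filled (retained rows are used and the returned
#'   table carries the simulated `Y`).
#' @param lambda_s True depletion parameter; `(1 - lambda_s) * p` must lie
#'   in `[0, 1)`.
#' @param seed Integer seed.
#' @return A `sim_result` list: `Y` (simulated indicators), `table` (the
#'   site table with `Y` replaced, when a table was supplied), and `truth`
#'   (`lambda_s`, `seed`, expected `R'`).
#' @export
bernoulli_simulate <- function(p, lambda_s, seed = NULL) {
  tab <- NULL
  if (inherits(p, "site_table")) {
    tab <- p
    keep <- !tab$excluded
    p <- tab$P[keep]
    if (anyNA(p)) stop("P has not been filled in the supplied site table")
  }
  q <- (1 - lambda_s) * p
  if (any(q < 0 | q >= 1)) {
    stop("(1 - lambda_s) * p must lie in [0, 1)")
  }
  local_seed(seed)
  y <- stats::rbinom(length(q), 1L, q)
  if (!is.null(tab)) {
    tab$Y[!tab$excluded] <- y
    tab$common[!tab$excluded] <- 0L
  }
  structure(list(Y = y, table = tab,
                 truth = list(lambda_s = lambda_s, seed = seed,
                              expected_R = sum(q))),
            class = "sim_result")
}

#' Simulate sites under mutation-selection balance
#'
#' Draws a selection coefficient per site from the DFE. Sites under strong
#' selection (`s_het >= s_min`) receive an allele count Poisson-distributed
#' with mean `2 N mu / s_het` -- the equilibrium frequency in a sample of
#' `2N` chromosomes. Below `s_min` (including the point mass at zero) the
#' equilibrium mean would exceed the neutral expectation, so those sites
#' instead carry a rare variant with the empirical neutral probability
#' `neutral_P`. Sites whose allele count reaches the common-variant
#' threshold `floor(rare_max_af * 2N)` copies are flagged common and
#' excluded, matching the estimator's filter.
#'
#' @param n_sites Number of independent sites.
#' @param d A [dfe()].
#' @param N Diploid sample size (default 71702).
#' @param mu Mutation rate per site per generation (default 1.2e-8).
#' @param neutral_P Neutral per-site rare-variant probability
#'   (default 0.162).
#' @param rare_max_af Frequency threshold for "rare" (default 0.001).
#' @param s_min Strong-selection threshold on `s_het` (default 0.001);
#'   draws within 10% of it are flagged in the result.
#' @param seed Integer seed.
#' @return An `msb_sim` list: `s_het`, `count`, `rare`, `common`,
#'   `neutral_regime`, and the parameters.
#' @export
msb_simulate <- function(n_sites, d, N = 71702, mu = 1.2e-8,
                         neutral_P = 0.162, rare_max_af = 0.001,
                         s_min = 0.001, seed = NULL) {
  stopifnot(inherits(d, "dfe"), n_sites >= 1, N > 0, mu > 0, neutral_P > 0)
  local_seed(seed)
  s <- rdfe(n_sites, d)
  strong <- s >= s_min
  count <- integer(n_sites)
  count[strong] <- stats::rpois(sum(strong), 2 * N * mu / s[strong])
  count[!strong] <- stats::rbinom(sum(!strong), 1L, neutral_P)
  thresh <- max(1L, floor(rare_max_af * 2 * N))
  common <- strong & count >= thresh
  rare <- count >= 1L & !common
  near <- strong & s < 1.1 * s_min
  structure(list(s_het = s, count = count, rare = rare, common = common,
                 neutral_regime = !strong, near_threshold = near,
                 params = list(N = N, mu = mu, neutral_P = neutral_P,
                               rare_max_af = rare_max_af, s_min = s_min,
                               seed = seed, dfe = d)),
            class = "msb_sim")
}

#' @export
print.msb_sim <- function(x, ...) {
  cat(sprintf(paste0("Mutation-selection balance simulation: %d sites, ",
                     "%d rare variants, %d common (excluded), ",
                     "%d neutral-regime sites\n"),
              length(x$s_het), sum(x$rare), sum(x$common),
              sum(x$neutral_regime)))
  invisible(x)
}

#' Depletion estimate from a mutation-selection balance simulation
#'
#' Applies the site-level estimator to the simulated rare-variant flags,
#' with `mean_P` equal to the neutral rate used in the simulation and
#' common sites excluded.
#'
#' @param sim An `msb_sim`.
#' @return List with `lambda_s`, `stderr` (site-level Bernoulli standard
#'   error), `R`, `M`, `mean_P`, and the implied `s_het` from
#'   [shet_from_lambda()] computed with the simulation's own `N`, `mu` and
#'   `neutral_P` (`NA` with a warning suppressed when `lambda_s < 0.45`).
#' @export
lambda_from_msb <- function(sim) {
  stopifnot(inherits(sim, "msb_sim"))
  keep <- !sim$common
  M <- sum(keep)
  R <- sum(sim$rare[keep])
  pbar <- sim$params$neutral_P
  lam <- estimate_lambda_simple(R, M, pbar)
  MP <- M * pbar
  v <- max(0, (1 - lam) / MP - (1 - lam)^2 * (M * pbar^2) / MP^2)
  pars <- selection_params(N = sim$params$N, mu = sim$params$mu,
                           P_bar = pbar)
  s_het <- if (lam < 1) {
    suppressWarnings(shet_from_lambda(lam, pars))
  } else NA_real_
  list(lambda_s = lam, stderr = sqrt(v), R = R, M = M, mean_P = pbar,
       s_het = s_het)
}

#' Decompose the DFE of "missing" rare variants
#'
#' If the DFE of new mutations is `f(x)` and the surviving rare variants
#' trace the density `g(x)`, then under the depletion model `f` is a
#' mixture of `g` with weight `1 - lambda_s` and the missing-variant
#' density `h` with weight `lambda_s`, so
#' `h(x) = (f(x) - (1 - lambda_s) g(x)) / lambda_s`. Computed over
#' histogram bins; negative bin masses (a diagnostic of inconsistency
#' between `f`, `g` and `lambda_s`) are clamped to zero and the total
#' clamped mass reported.
#'
#' @param f A [dfe()] for new mutations.
#' @param g Selection coefficients among surviving rare variants: a numeric
#'   vector of draws, an `msb_sim` (its `s_het[rare]` values are used), or
#'   -- with `g_is_mass = TRUE` -- per-bin masses matching `breaks`.
#' @param lambda_s Depletion, in (0, 1].
#' @param breaks Histogram breakpoints over `s_het >= 0`; default 50 equal
#'   bins spanning the data and the upper 0.999 quantile of `f`.
#' @param g_is_mass Interpret `g` as per-bin masses.
#' @return Data frame with `lower`, `upper`, `f_mass`, `g_mass`, `h_mass`
#'   (summing to 1), with attribute `clamped_mass`.
#' @export
decompose_missing_dfe <- function(f, g, lambda_s, breaks = NULL,
                                  g_is_mass = FALSE) {
  stopifnot(inherits(f, "dfe"))
  if (lambda_s <= 0 || lambda_s > 1) stop("lambda_s must lie in (0, 1]")
  if (inherits(g, "msb_sim")) g <- g$s_het[g$rare]
  if (is.null(breaks)) {
    hi <- max(stats::qgamma(0.999, shape = f$shape, scale = f$scale),
              if (!g_is_mass && length(g)) max(g) else 0)
    breaks <- seq(0, hi * 1.001, length.out = 51L)
  }
  f_mass <- dfe_bin_mass(f, breaks)
  if (g_is_mass) {
    if (length(g) != length(breaks) - 1L) {
      stop("g masses must have one entry per bin")
    }
    g_mass <- g / sum(g)
  } else {
    g_mass <- hist_mass(g, breaks)
  }
  h <- (f_mass - (1 - lambda_s) * g_mass) / lambda_s
  clamped <- -sum(h[h < 0])
  h[h < 0] <- 0
  if (sum(h) > 0) h <- h / sum(h)
  out <- data.frame(lower = breaks[-length(breaks)], upper = breaks[-1],
                    f_mass = f_mass, g_mass = g_mass, h_mass = h)
  attr(out, "clamped_mass") <- clamped
  out
}

hist_mass <- function(x, breaks) {
  if (length(x) == 0L) return(rep(0, length(breaks) - 1L))
  if (any(x < breaks[1] | x > breaks[length(breaks)])) {
    stop("values of g outside the histogram breaks")
  }
  h <- graphics::hist(x, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  h$counts / length(x)
}

#' Generate a synthetic genome with covariate tracks
#'
#' Writes an i.i.d. random DNA sequence at the requested G+C content, a
#' putatively-neutral region BED covering the contig, a handful of CpG
#' island intervals, and a per-site mean-coverage TSV (window-level means
#' around `coverage_mean` plus site-level jitter). Deterministic given the
#' seed.
#'
#' @param n_bp Sequence length (at least 1000).
#' @param seed Integer seed.
#' @param gc Target G+C fraction, in (0, 1) (default 0.41).
#' @param dir Output directory (created if needed).
#' @param chrom Contig name.
#' @param coverage_mean Mean sequencing coverage (default 30).
#' @return List with paths `fasta`, `neutral_bed`, `cpg_bed`, `coverage`,
#'   plus `chrom` and `n_bp`.
#' @export
synthetic_genome <- function(n_bp, seed, gc = 0.41, dir = tempfile("synth"),
                             chrom = "chrS", coverage_mean = 30) {
  if (n_bp < 1000) stop("n_bp must be at least 1000")
  if (gc <= 0 || gc >= 1) stop("gc must lie in (0, 1)")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  local_seed(seed)

  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq_chr <- paste(sample(names(probs), n_bp, replace = TRUE, prob = probs),
                   collapse = "")
  fasta <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(seq_chr, chrom)), fasta)

  neutral_bed <- file.path(dir, "neutral.bed")
  writeLines(sprintf("%s\t0\t%d", chrom, n_bp), neutral_bed)

  n_isl <- max(1L, n_bp %/% 50000L)
  isl_start <- sort(sample.int(max(1L, n_bp - 1000L), n_isl))
  cpg_bed <- file.path(dir, "cpg_islands.bed")
  writeLines(sprintf("%s\t%d\t%d", chrom, isl_start,
                     pmin(isl_start + 1000L, n_bp)), cpg_bed)

  win <- 1000L
  wmeans <- pmax(1, stats::rnorm(ceiling(n_bp / win), coverage_mean,
                                 coverage_mean / 10))
  cov <- pmax(0.1, rep(wmeans, each = win, length.out = n_bp) +
                stats::rnorm(n_bp, 0, 1))
  coverage <- file.path(dir, "coverage.tsv")
  utils::write.table(data.frame(chrom = chrom, pos0 = seq_len(n_bp) - 1L,
                                coverage = round(cov, 2)),
                     coverage, sep = "\t", quote = FALSE, row.names = FALSE)

  list(fasta = fasta, neutral_bed = neutral_bed, cpg_bed = cpg_bed,
       coverage = coverage, chrom = chrom, n_bp = n_bp)
}
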