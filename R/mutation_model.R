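# Neutral mutation model: heptamer-context relative rates, a linear-logistic
# covariate adjustment, and regional rescaling of the logit by sliding-window
# intercepts.

local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  # restore the caller's RNG stream when the calling function exits
  expr <- if (has_old) {
    bquote(assign(".Random.seed", .(get(".Random.seed", envir = globalenv())),
                  envir = globalenv()))
  } else {
    quote(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = env)
  set.seed(seed)
  invisible(NULL)
}

#' Fit heptamer-context relative mutation rates
#'
#' For every 7-mer context observed among retained neutral sites, computes
#' the relative frequency of each of the four outcomes: the three possible
#' alternative alleles (a rare variant of that allele is present) and "no
#' mutation". A pseudocount is added to each outcome before normalisation so
#' the four outcome frequencies sum to one per context and no outcome has
#' probability zero. 3-mer (one flank each side) and central-base marginal
#' aggregates are also stored, for fallback at contexts unseen in training.
#' Strands are not collapsed: rates for a context and its reverse complement
#' are estimated independently.
#'
#' @param neutral A `site_table` of putatively neutral sites (excluded sites
#'   are ignored).
#' @param pseudocount Count added to each of the four outcomes per context
#'   (default 0.5).
#' @return A `context_rates` object.
#' @export
fit_context_rates <- function(neutral, pseudocount = 0.5) {
  keep <- !neutral$excluded
  if (!any(keep)) stop("no retained neutral sites to fit context rates")
  tab <- neutral[keep, , drop = FALSE]

  level <- function(ctx) {
    # sites per context: each site contributes 3 rows
    n_sites <- tapply(rep(1L, nrow(tab)), ctx, length) / 3
    y <- tapply(tab$Y, paste(ctx, tab$alt), sum)
    list(n_sites = n_sites, y = y)
  }
  k7 <- level(tab$context7)
  ctx3 <- substring(tab$context7, 3L, 5L)
  k3 <- level(ctx3)
  k1 <- level(tab$ref)

  structure(list(k7 = k7, k3 = k3, k1 = k1, pseudocount = pseudocount),
            class = "context_rates")
}

# relative frequency of outcome `alt` given context, with pseudocount
rate_from_level <- function(level, ctx, alt, pc) {
  n <- level$n_sites[ctx]
  y <- level$y[paste(ctx, alt)]
  y[is.na(y) & !is.na(n)] <- 0
  (y + pc) / (n + 4 * pc)
}

#' Look up context-conditional rates with fallback
#'
#' Returns the relative frequency of a rare variant of allele `alt` given
#' the heptamer context; contexts unseen in training fall back to the 3-mer
#' rate for the same substitution, then to the central-base marginal.
#'
#' @param rates A `context_rates` object.
#' @param context Character vector of 7-mer contexts.
#' @param alt Character vector of alternative alleles.
#' @param fallback If `FALSE`, unseen contexts raise an error instead.
#' @return Numeric vector of rates in (0,1).
#' @export
context_rate <- function(rates, context, alt, fallback = TRUE) {
  stopifnot(inherits(rates, "context_rates"))
  pc <- rates$pseudocount
  r <- rate_from_level(rates$k7, context, alt, pc)
  miss <- is.na(r)
  if (any(miss)) {
    if (!fallback) {
      stop("contexts unseen in training: ",
           paste(utils::head(unique(context[miss]), 5L), collapse = ", "))
    }
    r[miss] <- rate_from_level(rates$k3, substring(context[miss], 3L, 5L),
                               alt[miss], pc)
    miss2 <- is.na(r)
    r[miss2] <- rate_from_level(rates$k1, substring(context[miss2], 4L, 4L),
                                alt[miss2], pc)
  }
  if (anyNA(r)) stop("central base unseen in training; cannot assign a rate")
  as.vector(r)
}

# leave-one-out rate for rows of the training table itself: the site's own
# observation is removed from its context's counts so the covariate is not
# contaminated by the response (material when contexts hold few sites)
context_rate_loo <- function(rates, context, alt, y_self) {
  pc <- rates$pseudocount
  loo_level <- function(level, ctx) {
    n <- level$n_sites[ctx]
    yy <- level$y[paste(ctx, alt)]
    yy[is.na(yy) & !is.na(n)] <- 0
    r <- (yy - y_self + pc) / (n - 1 + 4 * pc)
    r[!is.na(n) & n <= 1] <- NA # nothing left after removing the site
    r
  }
  r <- loo_level(rates$k7, context)
  miss <- is.na(r)
  if (any(miss)) {
    r3 <- loo_level(rates$k3, substring(context, 3L, 5L))
    r[miss] <- r3[miss]
  }
  miss <- is.na(r)
  if (any(miss)) {
    r1 <- loo_level(rates$k1, substring(context, 4L, 4L))
    r[miss] <- r1[miss]
  }
  r[is.na(r)] <- pc / (4 * pc)
  as.vector(pmin(pmax(r, 1e-12), 1 - 1e-12))
}

#' @export
print.context_rates <- function(x, ...) {
  cat(sprintf(paste0("Heptamer context rates: %d contexts observed",
                     " (pseudocount %.2g)\n"),
              length(x$k7$n_sites), x$pseudocount))
  invisible(x)
}

#' Fit the covariate adjustment of context rates
#'
#' Binomial-logistic regression of per-(site, allele) rare-variant presence
#' on four covariates: the logit of the raw context rate, log mean
#' sequencing coverage (natural log of coverage + 1), fractional G+C in a
#' 200 bp window, and the CpG-island indicator. A site-level simple random
#' sample of `sample_fraction` of the neutral sites is used, for parity with
#' genome-scale fits where using every site is unnecessary.
#'
#' @param neutral A `site_table` of neutral sites.
#' @param raw A `context_rates` object fit on the same (or comparable) data.
#' @param sample_fraction Fraction of sites sampled for the fit (default
#'   0.01).
#' @param seed Integer seed controlling the site sample (required for
#'   reproducibility).
#' @return A `covariate_model` with named coefficients, the training
#'   log-likelihood and fit metadata.
#' @export
fit_covariate_model <- function(neutral, raw, sample_fraction = 0.01, seed) {
  stopifnot(sample_fraction > 0, sample_fraction <= 1)
  if (missing(seed)) stop("a seed is required for the site sample")
  keep <- !neutral$excluded
  tab <- neutral[keep, , drop = FALSE]
  need <- c("coverage", "gc_frac", "cpg_island")
  bad <- need[vapply(need, function(cc) anyNA(tab[[cc]]), TRUE)]
  if (length(bad)) stop("missing covariate values: ",
                        paste(bad, collapse = ", "))

  sites <- unique(paste(tab$chrom, tab$pos0))
  local_seed(seed)
  n_take <- max(1L, round(length(sites) * sample_fraction))
  take <- sample(sites, n_take)
  tab <- tab[paste(tab$chrom, tab$pos0) %in% take, , drop = FALSE]

  df <- data.frame(y = tab$Y,
                   logit_raw = stats::qlogis(
                     context_rate_loo(raw, tab$context7, tab$alt, tab$Y)),
                   log_coverage = log(tab$coverage + 1),
                   gc_frac = tab$gc_frac,
                   cpg_island = as.numeric(tab$cpg_island))
  const <- vapply(df[-1], function(v) stats::var(v) == 0, TRUE)
  form <- stats::reformulate(names(df)[-1][!const], response = "y")
  fit <- stats::glm(form, family = stats::binomial(), data = df)
  if (!fit$converged) stop("covariate model failed to converge")
  coefs <- stats::setNames(numeric(4L),
                           c("logit_raw", "log_coverage", "gc_frac",
                             "cpg_island"))
  est <- stats::coef(fit)
  if (any(!is.finite(est))) {
    stop("non-finite coefficient (separation?) for: ",
         paste(names(est)[!is.finite(est)], collapse = ", "))
  }
  coefs[intersect(names(est), names(coefs))] <-
    est[intersect(names(est), names(coefs))]
  structure(list(intercept = unname(est["(Intercept)"]),
                 coefficients = coefs,
                 loglik = as.numeric(stats::logLik(fit)),
                 n_obs = nrow(df), seed = seed,
                 sample_fraction = sample_fraction),
            class = "covariate_model")
}

#' @export
print.covariate_model <- function(x, ...) {
  cat("Covariate model (binomial-logistic), coefficients:\n")
  print(round(c("(Intercept)" = x$intercept, x$coefficients), 4))
  cat(sprintf("Training log-likelihood %.2f on %d (site, allele) obs\n",
              x$loglik, x$n_obs))
  invisible(x)
}

covariate_logit <- function(cov, tab, raw) {
  b <- cov$coefficients
  cov$intercept +
    b["logit_raw"] * stats::qlogis(context_rate(raw, tab$context7, tab$alt)) +
    b["log_coverage"] * log(tab$coverage + 1) +
    b["gc_frac"] * tab$gc_frac +
    b["cpg_island"] * as.numeric(tab$cpg_island)
}

#' Fit regional rescaling intercepts
#'
#' Slides a window (default 150 kb, step 50 kb) along each chromosome and
#' fits, to the neutral sites in each window, a logistic regression with the
#' covariate-adjusted logit as an offset (coefficient fixed at one) and a
#' free intercept -- a local mutation-rate scaling factor on the logit
#' scale. Windows with fewer than `min_sites` neutral sites inherit the
#' chromosome-wide intercept.
#'
#' @param neutral A `site_table` of neutral sites.
#' @param adjusted_logits Numeric vector, one per row of `neutral`
#'   (excluded rows may be `NA`): the covariate-adjusted logit of the rate.
#' @param window Window length in bp (default 150000).
#' @param step Step between window starts in bp (default 50000).
#' @param min_sites Minimum neutral sites per window (default 100).
#' @return A `regional_scaler`.
#' @export
fit_regional_scalers <- function(neutral, adjusted_logits, window = 150000,
                                 step = 50000, min_sites = 100) {
  if (window <= 0 || step <= 0) stop("window and step must be positive")
  keep <- !neutral$excluded
  tab <- neutral[keep, , drop = FALSE]
  eta <- adjusted_logits[keep]
  if (anyNA(eta)) stop("adjusted logits missing for retained neutral sites")

  fit_intercept <- function(y, off) {
    fit <- stats::glm(y ~ 1 + offset(off), family = stats::binomial())
    unname(stats::coef(fit)[1])
  }

  res <- lapply(split(seq_len(nrow(tab)), tab$chrom), function(ii) {
    chrom <- tab$chrom[ii[1]]
    chrom_int <- fit_intercept(tab$Y[ii], eta[ii])
    len <- max(tab$pos0[ii]) + 1L
    starts <- window_starts(len, window, step)
    wins <- data.frame(chrom = chrom, win_start = starts,
                       win_end = pmin(starts + window, len),
                       intercept = NA_real_, n_sites = NA_integer_)
    for (w in seq_len(nrow(wins))) {
      inw <- ii[tab$pos0[ii] >= wins$win_start[w] &
                  tab$pos0[ii] < wins$win_end[w]]
      wins$n_sites[w] <- length(unique(tab$pos0[inw]))
      wins$intercept[w] <- if (wins$n_sites[w] < min_sites) chrom_int else
        fit_intercept(tab$Y[inw], eta[inw])
    }
    list(wins = wins, chrom_int = stats::setNames(chrom_int, chrom))
  })
  structure(list(windows = do.call(rbind, lapply(res, `[[`, "wins")),
                 chrom_intercepts = unlist(lapply(res, `[[`, "chrom_int")),
                 window = window, step = step, min_sites = min_sites),
            class = "regional_scaler")
}

window_starts <- function(len, window, step) {
  if (len <= window) return(0L)
  starts <- seq.int(0L, len - window, by = step)
  # clipped final window when the tail is not covered
  if (max(starts) + window < len) starts <- c(starts, max(starts) + step)
  starts
}

#' Regional intercept for genomic positions
#'
#' The intercept applied to a site is the arithmetic mean of the intercepts
#' of all fitted windows overlapping it; positions on chromosomes or in
#' stretches not covered by any window fall back to the chromosome-wide
#' intercept (zero for chromosomes absent from training).
#'
#' @param scaler A `regional_scaler`.
#' @param chrom,pos0 Vectors of chromosome names and 0-based positions.
#' @return Numeric vector of intercepts on the logit scale.
#' @export
regional_intercept <- function(scaler, chrom, pos0) {
  stopifnot(inherits(scaler, "regional_scaler"))
  w <- scaler$windows
  out <- numeric(length(chrom))
  for (ch in unique(chrom)) {
    ii <- which(chrom == ch)
    ww <- w[w$chrom == ch, , drop = FALSE]
    fallback <- unname(scaler$chrom_intercepts[ch])
    if (is.na(fallback)) fallback <- 0
    if (nrow(ww) == 0L) { out[ii] <- fallback; next }
    p <- pos0[ii]
    tot <- numeric(length(p))
    cnt <- integer(length(p))
    for (k in seq_len(nrow(ww))) {
      inw <- p >= ww$win_start[k] & p < ww$win_end[k]
      tot[inw] <- tot[inw] + ww$intercept[k]
      cnt[inw] <- cnt[inw] + 1L
    }
    out[ii] <- ifelse(cnt > 0L, tot / pmax(cnt, 1L), fallback)
  }
  out
}

#' @export
print.regional_scaler <- function(x, ...) {
  cat(sprintf("Regional scaler: %d windows (%g kb / %g kb) on %d chromosome(s)\n",
              nrow(x$windows), x$window / 1000, x$step / 1000,
              length(x$chrom_intercepts)))
  invisible(x)
}

#' Predict per-site, per-allele rare-variant probabilities
#'
#' Composes the three model stages: the raw heptamer-context rate is mapped
#' through the covariate-adjusted logistic model, the regional intercept is
#' added on the logit scale, and the inverse logit gives `P`. Every retained
#' (site, allele) row gets a `P` in (0,1); if the three allele probabilities
#' at a site sum to 1 or more they are rescaled with a warning.
#'
#' @param tab A `site_table`.
#' @param rates A `context_rates` object.
#' @param cov A `covariate_model`, or `NULL` to use the raw rates directly.
#' @param scaler A `regional_scaler`, or `NULL` for no regional rescaling.
#' @param fallback Passed to [context_rate()].
#' @return The site table with `P` filled for retained rows.
#' @export
predict_rates <- function(tab, rates, cov = NULL, scaler = NULL,
                          fallback = TRUE) {
  keep <- !tab$excluded
  sub <- tab[keep, , drop = FALSE]
  eta <- if (is.null(cov)) {
    stats::qlogis(context_rate(rates, sub$context7, sub$alt,
                               fallback = fallback))
  } else {
    covariate_logit(cov, sub, rates)
  }
  if (!is.null(scaler)) {
    eta <- eta + regional_intercept(scaler, sub$chrom, sub$pos0)
  }
  p <- stats::plogis(eta)
  psum <- stats::ave(p, paste(sub$chrom, sub$pos0), FUN = sum)
  if (any(psum >= 1)) {
    warning("per-site allele probabilities summed to >= 1 at ",
            sum(psum >= 1) / 3, " site(s); rescaled")
    p[psum >= 1] <- p[psum >= 1] / psum[psum >= 1] * 0.999
  }
  tab$P[keep] <- p
  tab
}

#' Full three-stage mutation-model fit
#'
#' Convenience wrapper fitting [fit_context_rates()],
#' [fit_covariate_model()] and (optionally) [fit_regional_scalers()] on a
#' neutral site table.
#'
#' @param neutral A `site_table` of neutral training sites.
#' @param sample_fraction,seed Passed to [fit_covariate_model()].
#' @param window,step,min_sites Passed to [fit_regional_scalers()].
#' @param pseudocount Passed to [fit_context_rates()].
#' @param regional If `FALSE`, skip the regional stage.
#' @return A `mutation_model` with elements `rates`, `covariates`, `scaler`,
#'   and `meta`; use `predict(model, table)` to fill `P`.
#' @export
fit_mutation_model <- function(neutral, sample_fraction = 0.01, seed,
                               window = 150000, step = 50000,
                               min_sites = 100, pseudocount = 0.5,
                               regional = TRUE) {
  rates <- fit_context_rates(neutral, pseudocount = pseudocount)
  cov <- fit_covariate_model(neutral, rates,
                             sample_fraction = sample_fraction, seed = seed)
  scaler <- NULL
  if (regional) {
    eta <- rep(NA_real_, nrow(neutral))
    keep <- !neutral$excluded
    eta[keep] <- covariate_logit(cov, neutral[keep, , drop = FALSE], rates)
    scaler <- fit_regional_scalers(neutral, eta, window = window,
                                   step = step, min_sites = min_sites)
  }
  structure(list(rates = rates, covariates = cov, scaler = scaler,
                 meta = list(seed = seed, sample_fraction = sample_fraction,
                             window = window, step = step,
                             pseudocount = pseudocount,
                             n_neutral_sites = n_retained_sites(neutral))),
            class = "mutation_model")
}

#' @export
print.mutation_model <- function(x, ...) {
  cat("Neutral mutation model\n")
  print(x$rates)
  print(x$covariates)
  if (!is.null(x$scaler)) print(x$scaler) else cat("No regional rescaling\n")
  invisible(x)
}

#' @param object A `mutation_model`.
#' @param newdata A `site_table` whose `P` column should be filled.
#' @param ... Unused.
#' @rdname fit_mutation_model
#' @export
predict.mutation_model <- function(object, newdata, ...) {
  predict_rates(newdata, object$rates, object$covariates, object$scaler)
}

#' Calibration of predicted rates against observed rare-variant fractions
#'
#' Bins retained (site, allele) observations by predicted `P` (quantile
#' bins) and compares the mean prediction with the observed fraction of
#' rare variants per bin.
#'
#' @param tab A `site_table` with `P` filled.
#' @param bins Number of bins (default 10; 1 gives the overall fraction).
#' @return Data frame with columns `bin`, `mean_P`, `obs_frac`, `n`.
#' @export
calibration_report <- function(tab, bins = 10) {
  keep <- !tab$excluded
  p <- tab$P[keep]
  y <- tab$Y[keep]
  if (anyNA(p)) stop("P has not been filled; run predict_rates() first")
  if (bins == 1L) {
    return(data.frame(bin = 1L, mean_P = mean(p), obs_frac = mean(y),
                      n = length(p)))
  }
  br <- unique(stats::quantile(p, probs = seq(0, 1, length.out = bins + 1)))
  grp <- cut(p, breaks = br, include.lowest = TRUE, labels = FALSE)
  out <- data.frame(bin = sort(unique(grp)),
                    mean_P = as.numeric(tapply(p, grp, mean)),
                    obs_frac = as.numeric(tapply(y, grp, mean)),
                    n = as.integer(table(grp)))
  rownames(out) <- NULL
  out
}
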