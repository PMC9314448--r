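---
title: "Measuring ultraselection from the depletion of rare variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring ultraselection from the depletion of rare variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ultrasel)
```

## The problem

In a panel of tens of thousands of sequenced genomes, almost every site
compatible with life is polymorphic *somewhere* — unless selection against
heterozygous carriers is strong enough to remove new mutations within a few
generations. Classical constraint measures built on cross-species
conservation, or on common variation, cannot see this regime. The signal
that can is the *depletion of rare variants*: at a site where any mutation
is strongly deleterious, even alleles at frequency below 10^-3^ are
missing. We call selection in this regime *ultraselection* and quantify its
prevalence in a target set of sites by `lambda_s`, the fractional reduction
in the rate at which rare single-nucleotide variants occur relative to a
neutral mutational expectation.

Everything hinges on that expectation: relative rates of rare variants are
exquisitely sensitive to mutation-rate variation, so `lambda_s` is only as
good as the neutral model behind it.

## The neutral mutation model

The model is fit to putatively neutral sites (supplied by the caller as a
BED file; in human applications these are unduplicated, non-repetitive,
reliably mappable regions away from annotated function) after three
filters, applied per site:

* **CpG sites are removed entirely** (reference C followed by G, or G
  preceded by C — both strands of the dinucleotide), because
  methylation-driven hypermutation makes them qualitatively different.
* **Sites with mean sequencing coverage below 20** are removed: apparent
  "missing" variants there reflect call-rate, not selection.
* **Sites carrying any common variant** (frequency at or above 10^-3^, or
  at or above 1 − 10^-3^ on the reference allele) are removed whole, since
  the likelihood below conditions on the absence of common variation.

Three stages then predict, for every retained site `i` and each of the
three possible alternative alleles `j`, the probability `P_i^(j)` that a
rare variant segregates:

1. **Heptamer context rates.** For every 7-mer centred on the site, the
   relative frequency of each outcome (three alternative alleles plus "no
   mutation") among neutral sites. All 4^8^ context-outcome cells are kept
   distinct — no strand collapsing, preserving real strand asymmetries. A
   pseudocount (default 0.5 per outcome) avoids zero rates; contexts never
   seen in training fall back to the central 3-mer, then to the
   central-base marginal.
2. **Covariate adjustment.** A binomial-logistic regression of the
   per-(site, allele) rare-variant indicator on the logit of the raw
   context rate, log(coverage + 1), fractional G+C in a 200 bp window, and
   a CpG-island indicator. The natural log of coverage + 1 tolerates zero
   coverage; the CpG-island track is a caller-supplied BED. At genome
   scale a 1% site sample suffices (`sample_fraction`), and the sample is
   seeded so fits are reproducible.
3. **Regional rescaling.** A 150 kb window slides along each chromosome in
   50 kb steps; within each window a logistic regression with the adjusted
   logit as a fixed-coefficient-one offset fits a free intercept — a local
   mutation-rate scaling. A site falls in up to three windows and takes
   the arithmetic mean of their intercepts (the smooth, symmetric choice;
   how overlaps combine is otherwise arbitrary). Windows with fewer than
   `min_sites` (default 100) neutral sites inherit the chromosome-wide
   intercept, as does any position outside all windows.

Two numerical details matter at small training sizes. First, during stage
2 the raw-rate covariate for each training row is computed *leaving that
site's own observation out* of its context's counts: when a context holds
few sites, the site's own indicator otherwise contaminates the covariate
and inflates the fitted slope (we observed a slope of ~1.8 instead of
~1 on small simulated genomes). Prediction always uses the full-sample
rates. Second, windows are clipped at chromosome ends so the final window
never extends past the sequence; a chromosome shorter than one window gets
a single window.

## The depletion estimator

With `P_i^(j)` fixed, presence of a rare variant is modelled as
independent Bernoulli draws thinned by selection:

$$Y_i^{(j)} \sim \mathrm{Bernoulli}\big((1-\lambda_s)\,P_i^{(j)}\big).$$

Writing $R' = \sum_{i,j} Y_i^{(j)}$, $M$ for the number of retained sites,
$\bar P$ for the mean per-site sum of the three allele probabilities and
$T=\sum_{i,j} (P_i^{(j)})^2$, the bias-corrected closed-form estimator and
its variance are

$$\hat\lambda_s = 1-\frac{R'}{M\bar P},\qquad
\mathrm{Var}(\hat\lambda_s)=\frac{1-\hat\lambda_s}{M\bar P}
-\frac{(1-\hat\lambda_s)^2\,T}{(M\bar P)^2}.$$

`estimate_lambda()` returns this estimate in a classed object with the
usual `print`, `summary`, `coef`, `vcov`, `confint`, `logLik` and
`simulate` methods. Several properties are worth knowing:

* **Negative estimates are meaningful and never clamped** — an excess of
  rare variants, as seen empirically near transcription start sites,
  yields `lambda_s < 0`, a diagnostic of local model misspecification.
* **The estimator only needs the rates to be unbiased.** Mean-preserving
  noise in `P` leaves both the estimate and its standard error nearly
  unchanged (the `T` term is second order); the test suite verifies a
  ±50% multiplicative perturbation moves the sampling spread by < 10%.
* **The likelihood-ratio test** compares the *exact* Bernoulli
  log-likelihood, maximised numerically over
  $(1 - 1/\max P,\, 1]$, against `lambda_s = 0`; twice the ratio is
  referred to a chi-squared distribution with 1 df. The numerical maximum
  is floored at the closed-form value's likelihood so the statistic is
  never negative. At the boundary $\hat\lambda_s = 1$ (no rare variants at
  all) the variance formula degenerates to zero and a warning flags the
  non-regularity.
* **Closed form vs exact maximiser.** For allele-homogeneous `P` the
  bias-corrected closed form solves the exact score equation exactly. With
  heterogeneous `P` the two differ per realisation by a fluctuation of
  order $\mathrm{sd}(P)/(M\bar P)$ that only vanishes in expectation; at
  50-site instances with widely spread rates the gap can reach a few
  times 10^-2^, while at thousands of sites it falls below 10^-3^. The
  test suite checks both regimes at the tolerances that actually hold.
* Sites flagged excluded contribute to neither $R'$ nor $M$. A site-level
  variant (`estimate_lambda_simple()`) using one indicator per site is
  identical to the allele-level estimator whenever no site carries more
  than one rare variant.

## From depletion to selection coefficients

Under mutation–selection balance with strong heterozygous selection, a
deleterious allele segregates at frequency ~`mu/s_het`, so the expected
number of polymorphic sites among `M` sites in `2N` chromosomes matches
the depletion model when

$$s_{\mathrm{het}} \approx \frac{2N/c}{1-\lambda_s},\qquad c=\bar P/\mu.$$

Defaults follow the data regime the method is designed for: `N = 71702`
diploids, `mu = 1.2e-8`, `P_bar = 0.162` (recompute it from your own
neutral sites when available), giving `c = 1.35e7`:

```{r}
selection_params()
shet_from_lambda(0.45)
```

The conversion is only trustworthy when depletion is strong —
`lambda_s` above roughly 0.45, i.e. `s_het` of roughly 0.02 and up — and
a warning is emitted below that. Two refinements:

* With **variable selection across sites** the conversion estimates the
  *harmonic* mean `H[s] = M / sum(1/s_i)`, which by the AM–HM inequality
  under-estimates the arithmetic mean; treat it as a lower bound.
* If a known fraction `1 - rho` of target sites is effectively neutral,
  `shet_adjusted(lambda_s, rho)` returns
  `(2N/c) * rho / (rho - lambda_s)`, the harmonic mean over the selected
  fraction. The common-variant correction to the balance equation is
  omitted: only ~3% of variants are common in this regime and the
  relationship is approximate anyway.

## Simulators, and what they do and do not show

`bernoulli_simulate()` draws data from the exact estimation model — the
right tool for checking unbiasedness, standard errors and test size.

`msb_simulate()` draws a selection coefficient per site from a DFE (point
mass at zero plus a Gamma on the `s_het` scale) and, for sites under
strong selection, an allele count from the Poisson equilibrium with mean
`2*N*mu/s_het`; counts reaching `floor(rare_max_af * 2N)` copies (143 at
the defaults) are flagged common and excluded, mirroring the estimator's
filter. **Below the strong-selection threshold** (`s_min = 0.001`) the
equilibrium mean would exceed the neutral polymorphism rate, so those
sites (including the point mass at zero) instead carry a rare variant
with the empirical neutral probability `neutral_P`. This equilibrium
sampler deliberately replaces a forward demographic simulation: it is
fast, demography-free, and accurate exactly where the `s_het` conversion
itself is valid. Its limits are the conversion's limits:

* Constant-`s_het` recovery through `shet_from_lambda()` is accurate to
  within ~3% down to `s_het = 0.03` and remains within ~35% at 0.02.
* For weak selection (`s_het` near or below `s_min`) the sampler is *not*
  a substitute for demographic simulation; DFEs dominated by weak effects
  (e.g. a Gamma with most mass below 10^-3^) produce depletion values that
  should not be compared against forward-simulation results.
* The harmonic-mean property is demonstrated with an exponential DFE
  shifted into the sampler's validity domain (`s >= 0.01`): over all
  draws of an unrestricted exponential, `E[1/s]` diverges and the
  harmonic mean is not even well defined, while near the threshold the
  saturation of `1 - exp(-2Nmu/s)` breaks the linearised identity.
  Within the domain, the recovered coefficient tracks `H[s]` to within a
  few percent and sits far below the arithmetic mean.

`decompose_missing_dfe()` inverts the mixture
`f(x) = (1-lambda_s) g(x) + lambda_s h(x)` on histogram bins to recover
the DFE `h` of the variants selection removed, given the DFE `f` of new
mutations and the surviving variants' coefficients `g`. Negative bin
masses are clamped to zero and reported — a nonzero clamped mass is a
diagnostic that `f`, `g` and `lambda_s` are mutually inconsistent, not
noise to be hidden.

`synthetic_genome()` writes an i.i.d. random sequence (default 41% G+C,
matching the human genome-wide average), a neutral-region BED, a few 1 kb
CpG-island intervals and a smoothly varying coverage track. It emulates
the *inputs* of a real analysis, not their biology: there is no true CpG
hypermutation, no repeat structure, no regional rate variation unless the
test injects one. End-to-end tests built on it (fit on a neutral segment,
estimate on a held-out target with depletion injected at the
(site, allele) level) therefore demonstrate the statistical pipeline —
filters, model fit, calibration, estimation — and nothing about
mutational biology.

## Genome-wide accounting

`build_accounting()` turns per-category `(lambda_s, n_sites)` rows into a
budget of ultraselection: the background category's `lambda_s` (default:
nonconserved introns, 0.009 in the bundled `genome_partition()` table) is
subtracted from every category — a conservative correction for residual
model misspecification — with negative adjusted values floored at zero;
expected ultraselected sites, proportions and fold enrichments follow, and
multiplying expected sites by `2 * mu` gives expected de novo strongly
deleterious mutations per potential zygote. Using the nonconserved
*intergenic* background (0.003) instead is the less conservative variant —
a different `background_name`, not different code. Totals are computed
from unrounded values; rounding happens only in `print()`. Propagated
errors combine category and background standard errors in quadrature;
floored categories are pinned at zero by construction and carry no error.

```{r}
acct <- build_accounting(genome_partition(), "nonconserved intron")
round(acct$totals$exp_sdel, 2)
```

## Problem sizes and reproducibility

The shipped tests exercise the full stack at sizes a laptop handles
comfortably: Monte-Carlo calibration at 10,000 sites and 500 replicates
per depletion level, equilibrium simulations at 10^5^–10^6^ sites, and an
end-to-end pipeline on a 230 kb synthetic genome (~180,000 neutral
training sites, ~28,000 target sites) — large enough that the 2-standard-
error recovery checks are meaningful, small enough to run in minutes.
Every stochastic step takes an explicit seed: the covariate-model site
sample, the optional estimation subsample, and all simulators; identical
seeds give identical results. Model bundles serialize to plain text
(TSV + JSON) and reload to identical predictions.

## Known limitations

* The neutral model carries no overdispersion term; genuinely
  overdispersed mutation rates are tolerated by the estimator only insofar
  as they are unbiased within the target set.
* Local misspecification (e.g. promoter-proximal hypermutation,
  transcription-factor binding) shows up as negative `lambda_s` rather
  than being corrected; treat such estimates as diagnostics.
* The `s_het` conversion assumes mutation–selection balance and strong
  selection; below `lambda_s` of about 0.45 it is reported with a warning
  and should not be over-read.
* Coordinates are 0-based half-open internally; BED and VCF conversion
  happen only at the I/O boundary. Multi-allelic VCF records must be
  pre-split; indels are rejected.
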