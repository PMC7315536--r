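---
title: "Models and methods behind methclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methclock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methclock)
```

methclock implements a targeted epigenetic-age workflow end to end:
screening age-associated CpG sites across several methylation studies,
multivariable linear clocks on a transformed age scale, Poisson
quantification of methylation from duplex droplet digital PCR (ddPCR),
and — the centerpiece — a maximum-likelihood age estimate for every
individual bisulfite amplicon sequencing read. This vignette explains
each model, its assumptions, the tunable parameters, and the choices we
made where the design was genuinely open. Every number shown here is
computed by the code in this document or asserted by the package's test
suite; nothing is quoted from external data.

## Screening age-associated CpGs across studies

Blood methylomes measured on bead arrays differ between datasets in
offsets and dynamic range, so a correlation that holds in a pooled
matrix may be driven by a single cohort. `select_candidates()` therefore
requires each criterion to hold in **every** study of a
`StudyCollection` individually. Three criteria are available, and a CpG
can be selected by any of them:

* `pearson_age` — Pearson correlation of beta value with age,
* `spearman_age` — Spearman rank correlation with age,
* `pearson_log_age` — Pearson correlation with `ln(age + 1)`, which
  linearizes the fast methylation changes of childhood.

The default threshold is `|r| >= 0.5` in every study. We use the
inclusive comparison so the boundary case is testable and deterministic;
`SelectionCriteria(strict = TRUE)` switches to the strict inequality.
Beyond the threshold we also require the **sign** of the correlation to
agree across studies: a site that gains methylation with age in six
cohorts and loses it in the seventh is not a usable monotone age marker,
whatever its absolute correlations. Missing betas are dropped pairwise
and a CpG needs at least 3 complete pairs per study to be evaluable; a
zero-variance vector yields a missing correlation, never a number.

Before screening, `apply_exclusion_masks()` removes user-supplied
probe lists (SNP-associated, cross-reactive, smoking-associated,
sex-chromosomal, platform-restricted), and `subset_variance_filter()`
flags CpGs whose methylation varies strongly across purified
hematopoietic cell subsets — such sites track blood composition rather
than age. The filter uses the population variance (divisor *n*) across
the subset columns with a default cutoff of 0.02; with only six subset
columns the choice of divisor matters, and we treat the cutoff as
referring to the population variance of the small fixed panel rather
than an estimate for a larger population.

```{r selection}
coll <- simulate_study_collection(n_studies = 3, n_samples = 60,
                                  n_cpgs = 200, seed = 1)
sel <- select_candidates(coll, SelectionCriteria(r_cutoff = 0.5))
sel
```

## The age transformation and linear clocks

Methylation changes fastest in early life. Clocks therefore regress a
transformed age with a logarithmic child branch and a linear adult
branch, joined continuously at `adult_age` (default 20 years):

$$F(a) = \ln(a+1) - \ln(A+1) \;\; (a \le A), \qquad
  F(a) = \frac{a-A}{A+1} \;\; (a > A).$$

Predictions invert this map exactly:
$(1+A)e^{y}-1$ for $y<0$ and $(1+A)y+A$ for $y\ge 0$. The natural
logarithm is used throughout, and the round trip is exact to numerical
precision over the whole human age range (asserted to `1e-9` in the
tests). `fit_linear_clock()` is plain ordinary least squares of
(transformed) age on the listed CpG betas — deliberately so: penalized
model training is out of scope here, and transcribed coefficient tables
from published clocks can be loaded directly via `read_clock()`.

Evaluation reports the squared Pearson correlation of predicted versus
chronological age and the median absolute error in years — the two
numbers conventionally annotated on clock scatterplots. Note that this
$r^2$ is a correlation, not a refit regression $R^2$: it is invariant
to shifts and even to sign, which the tests document explicitly.
Missing betas cause a sample to be dropped (in fitting) or predicted as
missing (in prediction) — targeted assays are small, and silent
imputation would bias exactly the CpGs the clock depends on. Negative
predictions are not clipped by default because raw predictions are what
the scatterplots show; `clip_negative = TRUE` is available.

## ddPCR Poisson quantification

A duplex ddPCR reaction partitions template over ~20,000 droplets and
reads each droplet as positive or negative for a methylated-sequence
probe and an unmethylated-sequence probe. Because a positive droplet
may hold several copies, the positive fraction understates the
concentration; occupancy is Poisson, so the mean copies per droplet is
$\lambda = -\ln(1 - p_{pos})$ per channel, with double-positive
droplets counted as positive in **both** channels (the standard duplex
convention; our simulator validates that this accounting recovers the
truth). The methylation fraction is the rate ratio
$\lambda_m / (\lambda_m + \lambda_u)$; per-droplet volume factors
cancel.

```{r ddpcr}
d <- simulate_droplets(true_fraction = 0.3, total_copies = 10000,
                       n_droplets = 20000, seed = 7)
quantify_droplets(d)
```

The simulator splits the copy number deterministically
(`round(fraction * copies)`) and randomizes only the droplet
assignment, so recovery error measures the occupancy correction itself
rather than binomial noise in the input material. The naive
positive-ratio estimator is biased toward 0.5 at high template load;
the tests demonstrate the bias and its removal. Saturated channels
(no negative droplets) have no finite rate and raise an error advising
dilution. Confidence intervals are available as a seeded bootstrap over
droplet classifications (`methylation_fraction_ci()`); vendor CI models
are proprietary and are not reproduced.

## The single-read age predictor

Targeted amplicons carry many CpGs per read, and each sequenced strand
is one molecule's binary methylation pattern. The predictor treats
epigenetic aging as stochastic drift at each site independently:

1. **Site models.** For each site $i$ of amplicon $X$, the training
   samples' per-sample site frequencies (multiplicity-weighted means
   over reads) are regressed on age by OLS, giving linear functions
   $F_{X,i}(a)$. `site_probability()` clips them to $[0,1]$, yielding
   $p_{X,i}(a)$, the probability that site $i$ is methylated on a
   strand from a donor of age $a$.
2. **Pattern likelihood.** For a pattern $P$,
   $\Pr(P,a) = \prod_i q_i$ with $q_i = p_{X,i}(a)$ where $P$ is
   methylated and $1 - p_{X,i}(a)$ otherwise.
3. **Per-read age.** $a_P$ is the age maximizing $\Pr(P,a)$ over a
   grid of 0–200 years in 1-year steps; if the maximum is attained at
   several ages, $a_P$ is their average (so a clipped-probability
   plateau contributes its midpoint, which can be non-integer).
4. **Donor age.** The donor estimate is the mean of the $a_P$ over
   reads, counting each pattern once per occurrence.

Numerical choices worth knowing:

* The product is computed in log space — with 36 sites a linear-space
  product underflows; `log(0) = -Inf` propagates exact impossibility
  correctly through the column sums.
* Ties are detected with a relative tolerance of $10^{-12}$ on the
  likelihood, because exact float equality after `exp(log(...))` is
  fragile.
* A pattern impossible at **every** grid age (maximum likelihood 0,
  which happens when clipping drives some $p_i$ to exactly 0 or 1)
  gets an undefined $a_P$ and is excluded from the donor mean, with
  counts reported. A probability floor could avoid such exclusions, but
  silently converting an impossible read into a weak vote changes the
  estimator, so the default excludes and reports.
* Missing calls (`.`) have two policies: `"drop"` (default) discards
  the read; `"marginalize"` skips that site's factor. Per-read calls
  from an aligner occasionally lack a site, and the drop default is the
  conservative choice for an estimator whose unit is the whole pattern.
* The maximizer is exhaustive over the grid by design — the estimator
  is defined on the grid, and the tests pin it to an independent
  brute-force scan, tie handling included.

The read-level filter `filter_rare_patterns()` retains patterns seen at
least 10 times (inclusive), applied per sample and amplicon; it exists
to suppress sequencing-error haplotypes in deep amplicon data. For
**simulated** reads the filter is disabled in our recovery analyses:
with 36 independent sites nearly every simulated pattern is unique, and
there are no error reads to remove.

```{r single-read}
models <- random_site_models(12, seed = 11)
reads <- simulate_reads(models, c(donor_a = 35, donor_b = 70),
                        reads_per_donor = 500, seed = 3)
predict_sample_age(models, reads$donor_a)
predict_sample_age(models, reads$donor_b)
```

## What the simulators emulate — and what they do not

`simulate_reads()` draws each site of each read independently from the
clipped linear frequency — exactly the generative model the predictor
assumes. `simulate_study_collection()` builds multi-study beta
matrices: planted CpGs linear in age (default 0.005 beta/year, a strong
age-marker effect size; baselines spread over 0.1–0.5), decoys at
age-independent levels, per-(study, CpG) offsets (sd 0.05) emulating
between-dataset shifts, Gaussian measurement noise (sd 0.02 beta
units), betas clipped to $[0,1]$, ages uniform on 20–80 years by
default with a log-uniform pediatric-skew option. One root seed derives
per-donor and per-study substreams by a stable string hash, so any
subset of donors reproduces identically.

Passing recovery tests on these simulations shows the estimators invert
their own generative models at realistic sizes. It does **not** show
robustness to what the simulators omit: sequencing error, bisulfite
conversion failure, PCR amplification bias, correlated methylation of
neighboring sites on the same strand, or cell-composition shifts. The
between-site correlation tools (`pairwise_site_correlation()`) exist
precisely to quantify, on real data, the neighbor coupling that the
independence model ignores.

## Windowed enrichment around CpG sets

`cpg_windows()` extends each CpG by 250 bp in both directions in
0-based half-open coordinates: a site at position $p$ becomes
$[p-250, p+251)$, a 501-base window that includes the site base itself
(the alternative 500-base reading excludes it; we document and test the
inclusive choice). Coverage values summarized over such windows are
quantile normalized across samples (rank to mean-of-sorted-reference,
ties averaged — `limma::normalizeQuantiles`), then a target CpG set is
compared with a seeded random background set by the two-sided
Mann-Whitney rank test, per sample and pooled. Sidedness is a flag; the
default is two-sided because directionality is a hypothesis, not a
given.

## Problem sizes and determinism

The simulation studies in the tests and the acceptance script use 50
donors at 1,000 reads each over 36 CpGs for the single-read round trip,
seven studies of 100 samples by 2,000 CpGs for the screening pipeline,
and 20,000 droplets per ddPCR replicate — sizes at which Monte-Carlo
error is far below the decision thresholds while a complete run stays
in the tens of seconds on one core. Every stochastic path takes an
explicit seed; the command-line tool is byte-reproducible given
`--seed`, and each run writes a provenance JSON (inputs, parameters,
seed, package version) beside its output, because targeted age assays
are used in settings where auditability matters.

## Known limitations

* The single-read estimator inherits the independence assumption; on
  amplicons with strongly coupled neighboring CpGs its per-read ages
  compress toward the extremes of the grid.
* OLS site models can produce slopes so shallow that clipping never
  binds within 0–200 years yet the likelihood surface is nearly flat;
  the tie-averaging rule then pulls $a_P$ toward the grid midpoint.
  Wide read-age distributions (`read_age_distribution()`) flag this.
* The screening pipeline evaluates only CpGs present in every study;
  probes missing from one platform are ineligible rather than imputed.
* No preprocessing or normalization of array data is included — inputs
  are assumed to be finished beta values.
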