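---
title: "Quantifying stochastic and deterministic community assembly with beta-diversity null models"
author: "betadev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stochastic and deterministic community assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betadev)
```

## The question and the model

Replicated community experiments — for instance triplicate bioreactors
run for weeks under different disturbance-frequency regimes — pose a
deceptively simple question: when equally handled replicates diverge in
composition, is that the footprint of stochastic assembly (drift,
priority effects), and when they converge, of deterministic species
sorting? Observed β-diversity alone cannot say, because β moves
whenever α or γ move, even under purely random assembly.

`betadev` separates the two by comparison with an individual-based null
model. Diversity is expressed in Hill numbers, the effective number of
equally abundant OTUs at order $q$:

$$ {}^qD = \Big(\sum_i p_i^q\Big)^{1/(1-q)},
   \qquad q \in \{0, 1, 2\}, $$

with $^0D$ the OTU richness, $^1D = \exp(-\sum_i p_i \ln p_i)$ the
exponential Shannon entropy (the $q \to 1$ limit, with
$0 \ln 0 \equiv 0$), and $^2D = 1/\sum_i p_i^2$ the inverse Simpson
concentration. Lower orders weight rare OTUs more. For a treatment with
$n$ replicates the multiplicative partition

$$ \beta \;=\; 1 - \bar{\alpha} / \gamma $$

takes $\bar\alpha$ as the unweighted mean of the replicate Hill numbers
and $\gamma$ as the Hill number of the pooled counts. $\beta = 0$ when
all replicates share one composition; for $q = 0$ it approaches
$1 - 1/n$ when replicates are compositionally disjoint. Pooling raw
counts for $\gamma$ equals depth-weighted pooling and coincides with
the simple mean of proportions at equal (rarefied) depths; the
unweighted $\bar\alpha$ is the natural companion under that design.

### The null model

Each read of a treatment block is treated as an individual. The null
model relocates every individual uniformly at random among the
treatment's replicates while holding fixed (i) each replicate's read
total, (ii) each OTU's total abundance, and therefore (iii) the pooled
γ-diversity. The induced distribution on OTU-by-replicate tables is the
multivariate hypergeometric (Fisher) distribution on fixed-margin
contingency tables. Repeating the randomization (10,000 iterations by
default) yields the null mean $\overline{\beta_{\mathrm{exp}}}$ and
standard deviation $\sigma_{\mathrm{exp}}$, from which

$$ \mathrm{SES} = \frac{\beta_{\mathrm{obs}} -
  \overline{\beta_{\mathrm{exp}}}}{\sigma_{\mathrm{exp}}},
  \qquad
  \mathrm{SI} = \frac{\beta_{\mathrm{obs}} -
  \overline{\beta_{\mathrm{exp}}}}{\beta_{\mathrm{obs}}}. $$

SES near zero reads as assembly indistinguishable from random
placement of individuals (stochasticity dominant); strongly negative
SES as replicates *more similar* than chance (convergent deterministic
sorting); positive as excess divergence. SI is the same deviation
normalized by the observed β, and is undefined (reported as `NA`,
never coerced to 0) when $\beta_{\mathrm{obs}} = 0$; SES is likewise
`NA` when $\sigma_{\mathrm{exp}} = 0$, since 0 would wrongly claim
"exactly at expectation".

### Sampler and oracle

Permuting every read label literally is infeasible at millions of reads
per iteration. The sampler instead allocates each replicate column in
turn by a sequential conditional hypergeometric draw from the remaining
OTU totals (compiled; equivalent to Patefield's fixed-margin algorithm
and exactly equal in distribution to label permutation).
`enumerateNullExact()` provides the independent oracle: for small
blocks it enumerates every fixed-margin table with its hypergeometric
mass and returns the exact distribution of β. The canonical margins
(2,2)/(2,2) admit three tables and give β (q = 0) equal to 0 with
probability 2/3 and 0.5 with probability 1/3 — mean 1/6, population sd
0.23570 — so an observed disjoint block scores SES $+1.414$ and SI
$2/3$, and an observed identical block SES $-0.707$ with SI undefined.
The test suite holds the Monte-Carlo sampler to these values (and to
base R's `r2dtable` cell frequencies) within three Monte-Carlo
standard errors. Note one convention: the Monte-Carlo `null_sd` is the
*sample* standard deviation over iterations, while the oracle's is the
population value of the exact distribution; tests compare like with
like.

## The synthetic generator

`generateExperiment()` emulates a replicated disturbance experiment
endpoint (a single sampling day, labelled day 35, plus an optional
day-0 inoculum): a lognormal metacommunity of `nOtus` genera with
niche traits uniform on $[0,1]$; per-treatment expected profiles by
Gaussian niche filtering
$p_i \propto p_{\mathrm{pool},i}\, w_i^F$ with
$w_i = \exp(-(t_i - e)^2 / 2\sigma_\nu^2)$ (computed in log space so
strong filters do not underflow); and per-replicate sampling at
dispersion $\phi$:

* $\phi = 1$ — one multinomial draw per replicate;
* $\phi > 1$ — Dirichlet-multinomial with concentration
  $c = \mathrm{depth}/(\phi - 1)$, giving variance $\approx \phi$
  times multinomial at large depth (drift-like divergence);
* $0 \le \phi < 1$ — largest-remainder rounding of
  $(1-\phi)\,\mathrm{depth}\cdot p + \phi\,m$ with $m$ one multinomial
  draw: a monotone variance knob that is exactly deterministic at
  $\phi = 0$ while conserving the read total exactly (remainder ties
  break to the lowest OTU index).

Every sample draws from an RNG substream hashed from the master seed
and the (treatment, replicate) indices, so output is identical
regardless of generation order.

### Default parameterization

The `idhPreset()` constants encode the qualitative disturbance-gradient
expectation — extremes niche-dominated and convergent, intermediates
drift-dominated — with evenly spaced environments, filter strengths
$(4, 2, 1, 0.5, 0.5, 1, 2, 4)$, dispersions
$(0.2, 0.8, 1, 1, 1, 1, 0.8, 0.2)$, 300 OTUs, lognormal $\sigma = 1.5$
(a typical steep microbial rank-abundance curve), niche width 0.25 (a
quarter of the trait axis: filters select broad guilds, not single
OTUs) and 50,000 reads per sample (large enough that multinomial noise
does not mask the regimes, small enough for desk-scale runs). These
are illustrative generator defaults, chosen once; they are **not**
estimates of any real bioreactor system. The optional
ecosystem-function readout is
$f = \mathrm{slope}\cdot {}^2D(\text{profile}) + N(0, \text{sd})$ with
preset slope 1 and sd 2 — a strong but noisy diversity–function link
for exercising the correlation stage.

What the generator deliberately omits: temporal dynamics (a single
endpoint is generated because the null model is applied per time
point), species interactions, mechanistic growth/toxicant chemistry,
and any taxonomy. Passing tests on synthetic data therefore demonstrate
the statistical machinery — margin conservation, calibration under the
null, monotone response to the dispersion knob — not fidelity to any
particular real community.

### A note on filtering and evenness

Increasing filter strength does *not* universally decrease $^2D$: when
the pool's dominant OTU sits far from the environmental optimum, weak
filtering suppresses it and transiently *raises* evenness. Monotone
decline is guaranteed (and property-tested) when pool abundance and
niche fitness are concordant; the limits are exact in all cases
($F = 0$ returns the pool; $F \to \infty$ concentrates on the
best-matching OTU).

## Other numerical choices

* **Rarefaction** is without replacement (multivariate hypergeometric
  per sample), matching read-subsampling semantics; samples below the
  requested depth abort the run rather than being dropped silently.
* **Hill orders** are restricted to $\{0, 1, 2\}$; presence for
  $q = 0$ means count ≥ 1.
* **Bray–Curtis** is computed on relative abundances (optionally
  square-root transformed, the default) via `vegan::vegdist`, making
  unequal depths safe; within-treatment dispersion is summarized as the
  mean/sd of replicate pairs, with sd defined as 0 for a single pair.
* **Spearman** uses average ranks for ties; the two-sided p-value is
  the full permutation distribution for $n \le 9$ and the
  t-approximation otherwise (experiment-level n here is ≤ 24+, where
  the approximation is adequate).
* **FDR** control is Benjamini–Hochberg step-up at rate 0.10, applied
  once per correlation family.
* **Normalization tolerance** is $10^{-12}$ for probability vectors at
  rest and $10^{-8}$ on user-supplied profiles.
* All OTUs enter the null model; no most-abundant-genera truncation is
  applied (such truncation belongs to regression-model diagnostics,
  not to the randomization).

## Pipeline and problem sizes

`runPipeline()` orchestrates simulate/load → optional rarefaction →
Hill profiles → β-partition → null model → Bray–Curtis + dispersion →
diversity–function correlations → a JSON report with config echo, file
manifest and a per-treatment summary joining Hill means ± sd,
$\beta_{\mathrm{obs}}$, SES, SI and dispersion. The stages are equally
usable as standalone exported functions — that is the package's
"command line". Failure policy is abort-on-error with a stage-named
message, since later stages consume earlier outputs; a fixed
configuration and seed give byte-identical stage tables.

The shipped checks run at deliberately desk-friendly sizes chosen to
make Monte-Carlo error small relative to the asserted tolerances: the
oracle block at 10,000 iterations; margin conservation over $10^5$
sampled tables; null self-consistency over 200 seeded experiments (50
OTUs × 3 replicates × 5,000 reads, 1,000 iterations); regime recovery
at $\phi \in \{0.2, 1, 4\}$ over 50 experiments each; 20 preset runs
for the interior-diversity-peak check; and one full 500-OTU × 24-sample
× 50,000-read pipeline at 10,000 iterations.

## Known limitations

* SES magnitudes grow with read depth (more individuals make the null
  tighter), so SES is comparable across treatments within one design,
  not across studies with different depths — rarefy first.
* The under-dispersed regime ($\phi < 1$) is a pragmatic blend, not a
  mechanistic model of convergent dynamics; only its monotonicity and
  limits are meaningful.
* The exact enumerator is intentionally guarded (total ≤ 20 reads or
  ≤ $10^5$ tables); it is an oracle, not a production path.
* Whether randomization should run on rarefied or raw counts is left
  to the user (`rarefactionDepth`); defaults analyze the table as
  given.
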