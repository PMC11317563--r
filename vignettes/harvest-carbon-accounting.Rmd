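---
title: "Estimating harvests from heaped recall surveys, and what they replace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating harvests from heaped recall surveys, and what they replace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harvestcarbon)
```

## The problem

Subsistence harvest surveys in Arctic communities rely on recall: a
harvester is asked, months after the fact, how many geese or whitefish or
caribou they took. Because harvesters rarely count their catch, recalled
quantities cluster on round numbers — multiples of 5, 10, or 50 — and the
rounding is coarser for larger catches. This *heaping* is a multiplicative
measurement error. On top of it, a share of records loses its count to
data-entry error and must be imputed, and the survey records only
*successful* harvests, so the trips that burned fuel and returned nothing
are invisible.

`harvestcarbon` estimates the latent true harvest behind every report,
converts the posterior into edible weight, the retail cost of replacing
that food with market substitutes, the greenhouse-gas emissions those
substitutes would incur under four transport scenarios, and the gasoline
(litres, dollars, and CO2e) of producing the harvest locally — including
the inferred unsuccessful trips. All uncertainty is carried as posterior
draws from end to end; no stage collapses to a point estimate.

## The deheaping model

Let $y_i$ be the reported count of record $i$ and $T_i$ the latent true
harvest. The observation model is lognormal with median $T_i$:

$$\log y_i \sim \mathrm{Normal}(\log T_i,\; \sigma_{\mathrm{obs}}),
\qquad \sigma_{\mathrm{obs}} = 0.15 .$$

The scaling factor $\sigma_{\mathrm{obs}}$ is *fixed*, not estimated: it is
chosen so that the implied error scales with the size of the estimate the
way heaping does. A lognormal with median $m$ and log-scale SD $\sigma$
has standard deviation

$$\mathrm{SD} = m\, e^{\sigma^2/2}\sqrt{e^{\sigma^2}-1},$$

so at $\sigma = 0.15$ a report of 10 animals carries an SD of about 1.5
animals (`lognormal_sd(10, 0.15)` = `r round(lognormal_sd(10, 0.15), 2)`).
The factor is exposed in `deheap_config()` for sensitivity analysis but
0.15 is the default throughout.

The prior on each latent pools information within a *species type* — a
group of species that are ecologically similar and harvested with similar
techniques (all geese together, all caribou subspecies together), so that
a report of 45 geese in a community where goose harvests centre on 10 is
treated with more skepticism than one of 12:

$$\log T_i \sim \mathrm{Normal}(\hat\mu_{g(i)},\; \hat s_{g(i)}),$$

where $\hat\mu_g$ and $\hat s_g$ are the *plug-in empirical* mean and SD
of the logged observed (non-missing) reports of group $g$
(`species_type_moments()`). This is deliberately not a hierarchical
hyperprior: the group distribution is estimated once from the data and
held fixed, which keeps the latent updates conditionally independent and
the model transparent. Groups with a single report or zero variance get a
floor SD of 0.5 on the log scale — wide enough to be weakly informative,
and avoiding degenerate zero-variance priors.

Flagged-missing records have no likelihood contribution; their latents
are drawn from the species-type distribution inside the same sampler, so
imputation uncertainty propagates like any other posterior uncertainty.
In the alternative `no_pooling` mode the species-type distribution
constrains *only* these imputations; observed reports get a flat prior
and their posterior is simply $\mathrm{Normal}(\log y_i,
\sigma_{\mathrm{obs}})$ on the log scale.

Latent harvests are continuous positive reals and stay fractional
downstream — no integer rounding anywhere — which absorbs some real
variation in animal size and usable portion.

### Sampling and diagnostics

Because the latents are conditionally independent given the plug-in
moments, `fit_deheap()` updates all of them simultaneously with a
vectorised random-walk Metropolis step on the log scale, with per-latent
proposal scales set to 2.4 times the closed-form conditional SD (the
normal–normal conjugate posterior, which also serves as the independent
oracle in the test suite). Missing-record latents are drawn exactly from
their full conditional (the group prior). Defaults are 3 chains of 4,000
iterations; the first half of each chain is warmup, and kept draws are
thinned to a working set of `n_keep` (default 100) draws per latent that
all downstream propagation uses. Convergence is checked with split
R-hat per latent against a 1.01 threshold; a fit that misses it returns a
result flagged `converged = FALSE` with a warning, never a silent
success. Chains are seeded explicitly and identical seed + configuration
reproduces draws bit-for-bit.

## The trip model

Fuel inputs are calibrated on an instrumented trip dataset (132 trips in
the default study conditions). Three components share one joint
posterior (`fit_trip_model()`):

* **Success**: each trip succeeds with probability $\theta$,
  $\;\mathrm{success}_j \sim \mathrm{Bernoulli}(\theta)$, flat
  $\mathrm{Beta}(1,1)$ prior. The sampler moves on the logit scale; the
  Beta conjugate posterior is the oracle the tests compare against.
* **Fuel of successful trips**: a log-log regression
  $\log f_j \sim \mathrm{Normal}(a + b \log w_j,\; \sigma)$ of fuel
  $f_j$ (L) on edible weight $w_j$ (kg), one pooled regression across
  transport modes.
* **Fuel of failed trips**:
  $\log f_j \sim \mathrm{Normal}(\mu_f, \sigma_f)$.

Priors are mildly regulating: standard normal on $a$, $b$, $\mu_f$ (all
log-scale quantities), half-normal(1) on $\sigma$ and $\sigma_f$. The
sampler Gibbs-samples $(a, b)$ and $\mu_f$ from their conjugate normal
conditionals and takes Metropolis steps on $\log\sigma$, $\log\sigma_f$,
and $\mathrm{logit}\,\theta$. Records with nonpositive fuel are excluded
with a message; tables with no failures (or no successes) are rejected
with a pointer to the `pseudo_counts` option rather than fitting a
degenerate $\theta$.

Because interviewees report individual expenses but often group harvests,
`divide_group_harvests()` divides snowmobile and ATV harvests by the
participant count (as if each participant ran their own machine) and
keeps boat harvests whole (one boat, several people) before fitting.

### Unobserved failures

Every harvest report is treated as one successful trip — a simplification
that biases fuel slightly high, accepted knowingly. The failures
accompanying $n$ observed successes under a Bernoulli process are
negative-binomial, with expectation $n(1-\theta)/\theta$
(`expected_failures()`). `simulate_failures()` draws, per posterior draw,
a failure count from that distribution and total failed-trip fuel as a
sum of lognormal $(\mu_f, \sigma_f)$ draws, so failure-count and
fuel-per-failure uncertainty both propagate. Failed-trip fuel is
attributed at the regional level, not per community.

## Propagation, valuation, emissions

Per-draw edible kilograms are latent count times the per-species edible
weight (per species, *not* pooled by species type). Value and emissions
are linear maps of kilograms:

* **Substitution value**: kg x the community's price of the record's
  replacement category (poultry, fish mix, or beef/pork mix) x a CPI
  factor (default 0.989) aligning the pricing-study year with the survey
  year. Category blends (50/50 beef–pork; even chicken leg/breast; 70/30
  whitefish/salmonid for fish) live in the configuration, not in code.
* **Replacement emissions**: kg x [production factor of the category +
  sum over the community's route legs of distance x per-kg-per-km factor
  of the leg's mode]. Four scenarios are materialised from one config
  file: road-to-barge and road-to-air ("food mail") routes, each at a low
  and a high emission-factor endpoint. The endpoints are how uncertainty
  in transport emissions is carried — there is deliberately no error
  model on prices, edible weights, or emission factors themselves.
* **Gasoline emissions**: litres x [combustion factor 2.319 kg CO2e/L +
  density 0.749 kg/L x the shipping term for moving the gasoline itself
  along a region-level rail-then-barge route]. The gasoline route is one
  region-level route rather than per community because failed-trip fuel
  is only defined regionally.

Totals are reported per taxon class (birds, fish, mammals) plus a grand
total, and class draws sum *exactly* to the total draw by draw.

### HPDI convention

Summaries report the mean, SD, and 90% highest-posterior-density
interval. With $n$ sorted draws and mass $p$, `hpdi()` returns the
shortest window spanning $\lceil pn \rceil$ inter-draw gaps (i.e.
$\lceil pn \rceil + 1$ draws), ties broken at the lowest start index; for
$\{1, \dots, 100\}$ at $p = 0.9$ this is $[1, 91]$. Whether such an
interval should span $\lceil pn \rceil$ or $\lfloor pn \rfloor$ draws is
a genuine convention choice; this one is fixed, documented, and tested
against an exhaustive brute-force search.

## What the synthetic data emulates — and what it does not

`simulate_harvest_reports()` draws true counts lognormally per species
type, heaps them with `heap()`, and blanks a completely-at-random share
(default 64 of 2,388, emulating the scale of data-entry loss in a
regional survey year). The heaping rule — exact below 5, nearest 5 below
100, nearest 10 below 250, nearest 50 above — matches the qualitative
pattern of recalled counts (round multiples of 5/10/50, coarser for
larger catches), but the *real* reporting mechanism is unobservable, so
the rule is a parameter (`heap_rule()`) and ground truth is serialized
with every dataset; no claim rests on the rule being literally true.
Missingness is MCAR on the argument that ID/field confusion in data entry
is plausibly unrelated to harvest size.

`simulate_trips()` applies the Bernoulli/regression/lognormal process
directly, with defaults $\theta = 0.75$, $a = 2$, $b = 0.5$,
$\sigma = 0.5$, $\mu_f = 3$, $\sigma_f = 0.4$ — numbers chosen so a
typical 30 kg trip burns ~50 L and a failed trip ~22 L, realistic for
snowmobile and boat travel. Machine trips with several participants
carry the group total in `edible_kg` (fuel stays individual), so the
group-division step recovers the generating individual harvest exactly.

Passing recovery tests on these data shows the estimators invert the
generating process they assume. It does *not* show the model is right
about real recall error: real heaping may be asymmetric, correlated with
species memorability, or truncation rather than rounding, and real
missingness may not be MCAR.

## A known calibration limitation

Deterministic rounding is not lognormal noise. Two consequences, both
visible in the package's own calibration harness: the expected heaped
count sits up to ~1% below the true count for species whose catches fall
just above a rounding-grain boundary, and the actual log-scale dispersion
of heaping (roughly 0.11–0.23 depending on the count regime) differs
from the fixed 0.15. Each report's posterior is therefore centred a
fraction of a percent off its truth in a direction the model cannot see.
For a single report this is negligible against its ~15% posterior SD; for
a *sum over thousands of reports* the posterior SD shrinks toward ~0.6%
while the offset does not shrink at all, so at survey scale the 90%
interval of the total edible weight covers the generating truth
substantially less often than 90%. This is a structural property of any
grid-free multiplicative-error treatment of deterministic heaping, not a
sampler defect — the same fits pass their conjugate-oracle and
parameter-recovery checks — and modelling the heaping grid explicitly is
out of scope by design. Totals at survey scale should be read as
estimates with a sub-percent systematic uncertainty in addition to their
posterior SD.

## Problem sizes used in the test suite

The shipped tests exercise the samplers at sizes chosen to make
Monte-Carlo error small relative to the tolerances they assert:
single-report oracle checks at 3 chains x 4,000 iterations (100 random
cases); trip-model recovery on 50 replicate datasets of 132 trips at 2
chains x 4,000 iterations; interval calibration on 50 survey-scale
datasets (2,388 reports) at 2 chains x 600 iterations with 150 kept
draws, a deliberately thinned working size for which the
highest-density-interval machinery is still well behaved. The full suite
runs in a couple of minutes on one core.

## Limitations

* Participation-rate extrapolation from reported to *true total* harvest
  is out of scope; all outputs describe the reported harvest only.
* One pooled fuel regression across transport modes; no per-mode fits.
* No embodied carbon of vehicles or equipment; direct emissions only.
* Prices, edible weights and emission factors enter as fixed
  configuration; scenario endpoints are the only uncertainty carried for
  transport emissions.
* The bundled species weights, prices, emission factors and distances
  are synthetic, order-of-magnitude-realistic stand-ins
  (`inst/extdata/*_synthetic.*`); analyses of real regions must supply
  their own configuration tables.
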