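---
title: "Concentration-index uncertainty for aggregated register data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concentration-index uncertainty for aggregated register data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concsim)
```

## The measurement problem

Administrative registers record health events — here, deaths from causes
amenable to health care — for an entire population, together with a
socioeconomic indicator such as equivalized family income grouped into
ordered classes. Inequality in such data is summarized by the
concentration index $C$, computed from an aggregated table of deaths
$d_{ig}$ and person-years $p_{ig}$ by age group $i$ and socioeconomic
group $g$.

Because the register covers the total population, there is no sampling
error, and interval methods developed for surveys answer the wrong
question. Uncertainty instead stems from the stochastic nature of deaths
and from registration error: causes of death are occasionally miscoded,
and the recorded income class need not reflect a person's real economic
position. This package's simulation intervals model exactly that: the
outcome counts (or derived quantities) are treated as random, while the
population structure — group person-year shares, ranks, age structure and
standard weights — is held fixed, since person-years and ages in registers
are effectively exact and the income *grouping* is by fixed proportions.

## Estimators

Per group, rates are directly age-standardized to a weight vector $w_i$
normalized to $\sum_i w_i = 100{,}000$:
$y_g = \sum_i (d_{ig}/p_{ig})\, w_i$, in events per 100,000 person-years.
With person-year shares $f_g$, midpoint ranks
$R_g = \sum_{\gamma<g} f_\gamma + 0.5 f_g$ and weighted mean
$\bar y = \sum_g f_g y_g$,

$$C \;=\; \frac{2}{\bar y}\sum_{g=1}^G y_g f_g R_g \; - \; 1 .$$

The identical value arises as the slope $\beta_1$ of the weighted least
squares model
$2\sigma_R^2 (y_g/\bar y)\sqrt{p_g} = \beta_0\sqrt{p_g} +
\beta_1 R_g\sqrt{p_g} + e_g$, where
$\sigma_R^2 = \sum_g f_g (R_g - 0.5)^2$. We solve the normal equations on
the $\sqrt{p_g}$-premultiplied design as written — no reparameterization —
because the REG interval consumes that fit's conventional slope standard
error. The equivalence $|C_{\text{formula}} - \beta_1| < 10^{-10}$ is
enforced by a property test over random tables.

Two conventions worth making explicit:

* **Ordering is caller-declared.** The group order (least → most
  advantaged) is an explicit attribute / a required `seg_order` CSV
  column, never inferred from labels: a silently reversed order flips the
  sign of $C$.
* **$\bar y$ uses person-year shares** $f_g$, not event shares.
* A table with no events anywhere has an undefined index and raises an
  error; it is never reported as 0 or NaN.

## Interval procedures

**REG** — $C \pm q\, \widehat{se}(\beta_1)$ with $q$ a Student-$t$
quantile on $G-2$ degrees of freedom (configurable to normal). This is
what standard software reports, and its error model — independent
homoskedastic residuals around the regression line — does not describe
register data: residual scatter mixes stochastic noise with the systematic
curvature of the rate–rank relationship, so the interval is generally too
wide (though it can also be too narrow when the points happen to fall on a
line).

**KWV** — the grouped-data variance estimator that corrects the slope
standard error for the serial correlation of the cumulative rank,
$\widehat{var}(C) = \frac{1}{n}\big[\sum_g f_g a_g^2 - (1+C)^2\big]$ with
$a_g = \frac{y_g}{\bar y}(2R_g - 1 - C) + 2 - q_{g-1} - q_g$ and $q_g$ the
concentration-curve ordinate. The estimator is defined for samples of $n$
observations; registers have no such $n$. We default to $n = G$ (each
group summary counted once), which yields widths of the same order as REG;
any other choice simply rescales the width by $1/\sqrt{n}$, so `n_obs` is
an explicit argument and the default is flagged in the documentation as a
convention, not an estimate.

**Simulation intervals.** All five methods draw $N$ (default 10,000)
replicate datasets, recompute the index each time with shares, ranks,
$\sigma_R^2$, person-years and weights fixed, and report the empirical
2.5/97.5 percentiles. The point estimate attached to the interval is
always the observed-data $C$.

* **MC** perturbs the regression outcome:
  $2\sigma_R^2 y_g/\bar y \sim N(\mu_g, \sigma_g^2)$ with $\mu_g$ the
  observed value and $\sigma_g = \mu_g/\sqrt{n_g}$, $n_g$ the group's
  event count. Refitting the regression is a linear functional of the
  draws, so replicates are a single matrix product.
* **MC-rate** perturbs the standardized rates,
  $y_g^* \sim N(y_g,\ y_g^2/n_g)$, and recomputes $\bar y^*$ from the
  draws. Recomputing the mean makes the formula and WLS estimators
  coincide replicate by replicate; the alternative (freezing $\bar y$)
  would break that equivalence, which is why we recompute.
* **BIN** redraws each cell $d_{ig}^* \sim B(D_i, \rho_{ig})$,
  $\rho_{ig} = d_{ig}/D_i$, independently across groups within an age
  band. The draws share the age-band total $D_i$ as the binomial index but
  are uncoupled, so the simulated total event count varies — the
  intended representation of false-positive/false-negative coding error.
* **POIS** uses $d_{ig}^* \sim Pois(d_{ig})$. Small-mean cells make the
  replicate distribution right-skewed, so POIS is the one method expected
  to produce visibly asymmetric intervals.
* **MN** holds each $D_i$ exactly fixed and redistributes it,
  $(X_{i1},\dots,X_{iG}) \sim \textrm{Multinomial}(D_i, \rho_i)$ —
  appropriate when the event total is trusted and only its socioeconomic
  attribution is uncertain.

If larger errors are plausible (e.g. systematic miscoding), the MC and
MC-rate variances can be inflated by overriding the divisor $n_g$
(`variance_divisor`): a smaller divisor means "as if fewer events", wider
intervals, unchanged median. Alternatively `rate_variances` replaces
$y_g^2/n_g$ wholesale, e.g. with empirical cross-year variances of the
group rates (`empirical_rate_variance()`, sample variance with the $n-1$
denominator over a window of adjacent years).

### Numerical choices

* Percentiles use order statistics with linear interpolation (R's
  `quantile` type 7); the replicate set for a fixed seed is bit-identical
  across runs.
* Normal draws (MC, MC-rate) are **not** truncated at zero. Truncation
  would destroy the symmetry and the median-equals-observed-$C$ property
  that make the normal methods interpretable; negative draws are counted
  (`n_negative_draws`) rather than censored. At register scale they are
  vanishingly rare.
* Zero probabilities are explicitly allowed in the binomial/multinomial
  samplers (a cell or group with no observed events never receives
  simulated ones), and a group with observed rate 0 is degenerate at 0 in
  the normal methods.
* Replicates with a non-positive simulated mean rate leave the index
  undefined; they are excluded, counted in `n_failed`, and a run aborts if
  they exceed 1% of $N$ (configurable). This is our convention; at
  register scale the situation does not arise.
* In `run_compare()` every method draws from an independent substream
  derived from the master seed and the method's position in the canonical
  method list, so adding or removing a method never changes the others'
  results.

## The synthetic register

Real cause-of-death registers are confidential, so the package carries a
generator whose defaults are a fixed "stated world", not tuning knobs:
20 income groups of equal person-year share; ages 1–74 in a 1–4 band plus
5-year bands; a stable age pyramid; an exponential-in-age baseline hazard;
and a log-linear income gradient,
$E[d_{ig}] = p_{ig}\, b_i\, e^{\text{gradient}\,(R_g - 0.5)}$, with
Poisson counts. The `finland-1996-men` preset was calibrated once, before
the test suite was written, against three targets typical of a mid-1990s
male amenable-mortality register: overall standardized rate 102 per
100,000, roughly 2,000–2,300 deaths per year at 2.3 million person-years,
and true (expected-rate) $C = -0.27$ (gradient $-1.701015$, solved by
`uniroot`). The standard weights are an illustrative European-standard
style vector (truncated at age 1 and normalized); they are user-replaceable
input, not a claim about any specific published standard.

What the generator emulates: the scale, age structure, gradient shape and
Poisson event noise of register counts, with fixed group proportions. What
it does not: income misclassification with structure (errors are captured
only through the resampling models), cause-of-death coding drift over
time, migration, unequal group shares, or overdispersion beyond Poisson.
A green test on synthetic data therefore establishes internal consistency
of the estimators and interval procedures at realistic scale — not that
any particular error model is the right description of a given country's
register.

On this stated world the package's test suite verifies, among others:
that the five simulated intervals agree pairwise within 20% in length;
that MC/MC-rate/BIN/MN are symmetric with replicate medians on the
observed $C$; that REG and KWV are at least 1.3× wider than MC; that 95%
BIN intervals cover the true $C$ in 90–99% of 500 regenerations; and that
the estimated $C$ is unbiased for the expected-rate $C$ (mean bias
< 0.01 over 200 regenerations).

## Amenable-mortality classification

The cause list is shipped as a plain CSV
(`inst/extdata/amenable_rules.csv`): one row per cause, with place of
intervention (primary vs specialized care), timing (primary prevention,
early detection and treatment, improved treatment and medical care), an
inclusive age window, ICD-10 patterns and optional exclusions. Matching
uses conventional prefix-interval semantics on the dot-stripped code:
`A00–09` covers any `A0x` code including decimal children; `A48.1` covers
that subcode and its children only; ranges never cross a letter unless
written with two letters. Design choices where the printed list is silent:
the childhood "all respiratory diseases (excl. pneumonia/influenza)" row
carries an explicit `J09–18` exclusion so influenza/pneumonia codes can
never enter through `J00–09`/`J20–99`; maternal death ("all ages") is
encoded as 0–120; compound rows (e.g. diphtheria/tetanus/polio/varicella)
are kept as single rules; and overlapping rules all match — the classifier
reports matches, it does not rank them, since the downstream analysis only
needs amenable yes/no.

## Known limitations

* The KWV `n_obs = G` default is a documented convention; the width of
  that interval is only meaningful relative to a stated $n$.
* The index here is for non-binary rate outcomes; binary-outcome
  normalizations of $C$ are out of scope, as are survey designs,
  individual-level estimation, and the relative/slope indices of
  inequality (the simulation machinery would extend to them).
* Interval methods assume the age-band × group table is dense with
  positive person-years; sparse strata must be merged upstream.
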