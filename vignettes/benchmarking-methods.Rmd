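---
title: "Noninferiority benchmarking of knee replacement constructs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noninferiority benchmarking of knee replacement constructs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

National joint registries record every primary total knee replacement
(TKR) and every subsequent revision. A *construct* — the unit of
comparison here — is a brand combined with fixation (cemented or
uncemented), bearing mobility (fixed or mobile) and constraint (cruciate
retaining or posterior stabilised). Annual reports usually summarise
performance as a prosthesis time incidence rate (revisions per 100
component-years), which ranks constructs in absolute terms but offers no
head-to-head statement. `kneebench` implements a dynamic internal
benchmarking analysis instead: every construct used in sufficient numbers
is compared with the best-performing contemporary construct in the same
registry, and classified against noninferiority margins.

## The model

### Net failure by 1-Kaplan-Meier

For one construct, let \(d_i\) be the number of first revisions at the
distinct revision time \(t_i\) and \(n_i\) the number still at risk just
before \(t_i\). The cumulative all-cause revision probability ("net
failure") at time \(t\) is estimated as

\[
\hat F(t) \;=\; 1 - \prod_{t_i \le t}\Bigl(1 - \frac{d_i}{n_i}\Bigr),
\qquad
\widehat{\mathrm{Var}}[\hat F(t)] \;=\; \hat S(t)^2
\sum_{t_i \le t} \frac{d_i}{n_i\,(n_i - d_i)} ,
\]

the second expression being the classical Greenwood estimator. Deaths are
treated as independent censoring, so \(\hat F\) targets the *marginal*
probability of revision — the quantity a patient would face were death
not to intervene — rather than the cumulative incidence in the presence
of the competing risk of death. This is a deliberate modelling choice,
not an approximation error; competing-risk estimators (Aalen–Johansen)
are out of scope here. Under independent censoring the estimand is
unaffected by the death rate, a property the test-suite verifies by
simulation.

Conventions: tied events precede censorings at the same time (the
standard product-limit convention); revisions at exactly \(t\) count
toward \(\hat F(t)\); "at risk at \(t\)" means follow-up of at least
\(t\) with no earlier revision, mirroring the "remaining at risk" counts
of registry reports. If the risk set is ever exhausted by events the
Greenwood sum has an infinite term; the estimate is then flagged
degenerate (failure 1, variance undefined) and excluded from
comparisons.

### Confidence intervals

Intervals on the failure scale are plain symmetric normal intervals,
\(\hat F \pm z_{1-\alpha/2}\sqrt{\widehat{\mathrm{Var}}}\), clipped to
\([0,1]\). Registry benchmarking reports print symmetric intervals for
their reference constructs, and the downstream Wald comparison works on
the same scale, so the symmetric form is the coherent default. A
log(−log) transform is *not* applied; this is recorded as an assumption
rather than a registry fact.

### Reference selection and margins

At each evaluation time (3, 5, 7 and 10 years by default) the *reference*
is the construct with the lowest estimated net failure among those with
at least `ref_min = 1000` procedures still at risk; ties break toward the
larger risk set, then lexicographically, so reports are reproducible.
Every other construct with at least `comp_min = 500` at risk is an
eligible comparator.

The at-risk floors are design quantities, not arbitrary cut-offs: with
roughly 5% cumulative failure, ~1000 at risk gives a 95% CI of full width
about 3 percentage points, and ~500 at risk about 5 points.
`ci_width_study()` reproduces exactly this calculation, and the
acceptance script reports it.

Noninferiority margins are *relative-risk* margins converted to absolute
failure differences using the reference's point estimate:
\(m_{20} = 0.20\,\hat F_{\mathrm{ref}}(t)\) and
\(m_{100} = 1.00\,\hat F_{\mathrm{ref}}(t)\). A comparator sitting at the
100% margin has exactly double the reference's cumulative failure
probability. The point estimate (not a CI bound) defines the margins,
consistent with drawing fixed margin lines on a difference plot.

### Comparison and classification

For comparator \(c\) versus reference \(r\),

\[
\hat\Delta = \hat F_c - \hat F_r,\qquad
\mathrm{SE}(\hat\Delta) = \sqrt{\widehat{\mathrm{Var}}_c +
\widehat{\mathrm{Var}}_r},
\]

with a symmetric normal CI on \(\hat\Delta\) and a two-sided Wald
p-value. The p-value is descriptive only; classification uses the CI
limits, evaluated against the margins in a fixed order, first match wins:

1. lower limit above \(m_{100}\): **inferior at the 100% margin**;
2. lower limit above \(m_{20}\): **inferior at the 20% margin**;
3. upper limit below \(m_{20}\): **noninferior at the 20% margin**;
4. upper limit below \(m_{100}\): **noninferior at the 100% margin**;
5. otherwise **inconclusive**.

The rule sentences overlap for a narrow interval lying wholly between the
two margins (lower limit above \(m_{20}\), upper below \(m_{100}\));
evaluating inferiority before noninferiority resolves this, and such an
interval is called inferior at the 20% margin — the construct's excess
failure is established, merely bounded below doubling. Comparisons are
strict, so exact equality with a margin (measure zero) falls through to
the weaker category. No multiple-testing correction is applied and no
superiority analysis is run.

Gender stratification, when requested, recomputes reference, margins and
eligibility within each stratum; records of unknown gender are excluded
from stratified runs with a logged count.

## The synthetic registry generator

No public registry extract exists at procedure level, so the generator is
a first-class part of the package: it emulates the statistical structure
the analysis assumes, and all statistical guarantees are demonstrated on
it.

Each construct scenario draws, per procedure, an enrolment offset
\(u \sim \mathrm{Uniform}\) over a window measured in years *before* the
data-lock date (so \(u\) is also the administrative censoring time), a
revision time \(T_r\) and a death time \(T_d\) from independent constant
hazards. Observed follow-up is \(\min(T_r, T_d, u)\) with the matching
status. Choices and their reasons:

- **Exponential revision times** (default) give the closed-form truth
  \(F(t) = 1 - e^{-\lambda_r t}\) used by parameter-recovery and coverage
  tests. A Weibull shape parameter is available for robustness
  experiments but is not used in the shipped checks.
- **Uniform staggered enrolment** over the window reproduces the steady
  depletion of at-risk counts with horizon that registry figures show.
  Real enrolment rates trend over calendar time; uniformity is an
  explicit simplification.
- **Death hazard 0.02/yr** in the demo scenario is a realistic
  all-cause mortality for a TKR population (median age near 70).
- **Per-scenario substreams** are derived deterministically from the
  master seed, so adding a scenario leaves existing constructs'
  records untouched and registries are bit-reproducible.

`nzjr_like_scenario()` is a canned 25-construct configuration shaped like
a national registry's 3-year analysis: one reference-grade construct
(true 3-year failure 1.2%, comfortably over 1000 at risk), a spread of
comparators between 1.05× and 2.2× the reference failure with cohort
sizes from ~800 to 9000 over a 21-year enrolment window, and one
construct with triple the reference hazard. A generated registry yields
one qualifying reference and ~24 eligible comparators at 3 years, with
several classification bands populated.

What the generator does *not* emulate: case-mix (age/comorbidity) effects
on revision, informative censoring, clustering by surgeon or hospital,
and calendar trends in implant use. Passing tests therefore demonstrate
the estimator and classifier are correct under the stated sampling
assumptions, not that real registry differences are causally
attributable to the implant.

## Problem sizes and verification

The shipped checks run at desk scale: 200 replicate cohorts for the
CI-width design quantities, 1000 replicates for CI coverage (binomial
regime, \(n = 1000\), ~5% failure, observed coverage must lie in
[93%, 97%]), 1000 null-calibration and 500 power replicates of the full
two-arm pipeline at 10 years (null inferior-classification rate at most
\(\alpha/2\) plus Monte-Carlo slack; power above 80% against a tripled
failure probability), and 1000 random small datasets compared with the
`survival` package's product-limit implementation to \(10^{-12}\) as an
independent oracle.

## Known limitations

- Net failure is not a cumulative incidence; with heavy mortality the two
  diverge, and users wanting the competing-risk quantity need a different
  estimator.
- Margins derive from the reference *point estimate*; uncertainty in the
  reference is carried by the pooled SE of the difference, but the margin
  lines themselves are treated as fixed.
- The symmetric failure-scale CI can clip at 0 for very low failure
  probabilities with small risk sets; eligibility floors largely prevent
  this regime from being compared.
- Bilateral procedures are treated as independent, as the per-procedure
  schema implies.
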