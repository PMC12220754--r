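---
title: "Disproportionality screening of spontaneous reports: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality screening of spontaneous reports: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The screening problem

Spontaneous-report databases have no exposure denominator, so the only
available comparison is internal: does event *y* make up a larger share of
the reports naming drug *x* than of the reports naming other drugs? Each
drug–event pair is summarized by the 2×2 table (a, b, c, d) where the target
row is defined by the **primary-suspect (PS) role** — reports carrying the
drug only as secondary suspect, concomitant or interacting medication stay
in the comparator rows, because the screening question is about the drug
judged responsible. N = a+b+c+d is the whole deduplicated universe and is
the same for every pair; this is asserted as an invariant.

Counting is per *report*: a case that lists the same PT twice contributes
once, and at SOC level a case with several PTs of one SOC contributes once
to that SOC's cell. The alternative (counting report–PT pairs at SOC level)
is defensible; we chose report-level counting because the 2×2 cells are
defined as report counts, and the choice is isolated in `build_all_tables()`
should anyone want to switch it.

## The four statistics

`compute_ror()`, `compute_prr()`, `compute_bcpnn()` and `compute_ebgm()`
implement the standard closed forms (see the README for the formulas). Some
numerical decisions worth making explicit:

* **Zero cells.** ROR and the EBGM interval are undefined with any zero
  cell, PRR with c = 0; these return `NA` with a `defined` flag, and an
  undefined statistic *fails* its signal criterion. No continuity
  correction is applied by default — the criteria already demand a ≥ 3, and
  silent +0.5 corrections change the estimand. A Haldane–Anscombe
  correction is available behind `haldane = TRUE`, and a Yates-corrected χ²
  behind `yates = TRUE`, both default off.
* **b = 0** is not degenerate for PRR: the SE term 1/a − 1/(a+b) vanishes
  and the interval is finite. This is tested against the high-precision
  referee.
* **BCPNN priors.** The conjugate priors are α₁ = β₁ = 1, α = β = 2,
  γ₁₁ = 1 with γ = γ₁₁(N+α)(N+β)/((a+b+α₁)(a+c+β₁)). They regularize zero
  cells, so E(IC), V(IC) and IC−2SD are finite whenever N > 0. As all cells
  scale up, E(IC) → IC and V(IC) → 0 (tested as a monotone-convergence
  property). Signal tiers on IC−2SD: none ≤ 0 < weak ≤ 1.5 < medium ≤ 3
  < strong.
* **EBGM as implemented is unshrunk.** The formula aN/((a+c)(a+b)) is the
  plain observed-to-expected ratio and satisfies EBGM = 2^IC exactly (an
  identity the tests assert at machine precision). Published MGPS values
  are usually produced by a gamma-mixture empirical-Bayes fit whose
  shrinkage this ratio does not reproduce; fitting that five-parameter
  mixture is out of scope here, and a shrinkage backend could be added
  behind the same interface. Likewise we interpret the "IC(IC025)" columns
  of published report tables as E(IC) and IC−2SD, the only lower bound the
  method defines in closed form.
* **Report rounding** is half-up to 2 decimals (`round_half_up()`), the
  convention of published signal tables; internal values keep full
  precision, and the exported full signal list carries 10 decimals.

The four-way verdict is the conjunction of the per-method criteria, so its
specificity is bounded below by every individual method; there is no other
multiple-testing control, which matches screening practice (the verdict
flags pairs for clinical review, it does not estimate causal effects).

## Cleaning model

Deduplication keeps, per case, the highest `caseversion`, breaking ties by
latest receipt date and then by largest primary id — a total order, hence
deterministic, idempotent and insensitive to input row order (all tested).
Drug-name normalization is dictionary-based, case- and
whitespace-insensitive, keeping unmapped names verbatim; PTs missing from
the PT→SOC vocabulary are routed to a sentinel `UNMAPPED` SOC rather than
dropped, so the universe size N is never silently reduced. Every cleaning
step logs a counter. Age bins are resolved as [0,18), [18,45), [45,65),
[65,75), [75,∞), with missing or implausible ages (outside 0–120) treated
as unspecified. MedDRA itself is licensed; the shipped vocabulary is a
small synthetic stand-in (56 PTs, 9 SOCs) sufficient to exercise the
mapping machinery.

## What the generator emulates — and what it does not

`generate_reports()` draws, per report: independent Bernoulli drug
exposures (probability 0.3 per drug by default; an empty draw is assigned
one drug uniformly, as a report must name a drug); one PS drug uniform
among the report's drugs, the rest labelled SS/C/I; independent per-PT
Bernoulli events at baseline probability 0.02; and demographics from
categorical mixes. The default demographic mix is the printed margin
profile of a large montelukast cohort (53.01% male, 31.01% under 18, 52.1%
US, hospitalization 20.31%, consumers 39.24%), and the default year
distribution is a discretized normal centred on 2013 — the published series
gives only the 2013 peak and the 2004–2023 span, so a smooth unimodal shape
with the correct argmax is the minimal realistic choice. Reports whose
event draws all fail receive a designated background PT ("Drug
ineffective", the most common filler term in real spontaneous data).

**Planted signals** multiply the baseline probability (capped at 1) for a
(drug, PT) pair *when that drug is the report's primary suspect*. We apply
the multiplier through the PS role rather than through mere carriage
deliberately: the screening universe is PS-defined, and under PS-application
the planted pair's true 2×2 odds ratio has the closed form
odds(min(1, p·m))/odds(p) (`planted_odds_ratio()`), so calibration claims
are exact. Under carriage-based application the non-PS carriers would
contaminate the comparator rows and the implied odds ratio would depend on
the whole exposure configuration, leaving nothing exact to test against.

Duplicate injection re-emits ⌊rate·n⌋ deterministically selected cases with
an incremented version, a later receipt date and occasionally perturbed
demographics, recording ground truth in a `latest` flag — exactly what
deduplication must recover, and the round-trip tests require recovery to be
*exact*.

The generator deliberately omits known features of real spontaneous data:
reporting delays and backlog, the Weber and notoriety effects (time-varying
reporting rates per drug), correlated events (syndromes), drug–drug
interaction signals, dose and indication fields, and country-specific
coding habits. Passing calibration tests on this model therefore shows the
*pipeline arithmetic and plumbing* are right — not that the four criteria
have any particular sensitivity or specificity on real FAERS data, where
confounding by indication and reporting biases dominate.

## Validation design and problem sizes

The test suite validates at three levels, all seeded and deterministic:

* **Arithmetic:** every statistic on 1,000 random tables with cells in
  [1, 10⁴] against an independent mpmath evaluation of the closed forms at
  50 significant digits (relative error < 10⁻¹⁰), plus frozen
  high-precision values for reference tables and the exact identities
  EBGM = 2^IC and χ² = 0 ⇔ ad = bc.
* **Statistical calibration:** a null universe of 10⁵ reports × 56 PTs
  must yield a four-way signal rate below 1% (observed: 0); with a planted
  odds ratio of 4 (baseline 0.02, exposure 0.3, 6,000 reports per
  replicate) the 95% ROR CI covers the truth in 93–97% of 200 replicates
  (observed: 95.5% at the default seed); under binomial null simulation
  the ROR CI excludes 1 in 5% ± 2% of 1,000 runs.
* **Plumbing:** generator → "$"-delimited writer → reader → deduplication
  reproduces the ground-truth latest versions exactly, and identical
  config + seed gives byte-identical pipeline outputs.

These sizes (10⁵-report null universe, 200 calibration replicates at 6,000
reports) were chosen as the smallest at which the binomial tolerances quoted
above are meaningful.

## Known limitations

* EBGM carries no genuine empirical-Bayes shrinkage (above); on small
  counts it is as noisy as the ROR it mirrors.
* The CIs are Wald intervals on the log scale; their finite-sample
  coverage is only approximately nominal for very small cells, which is
  one reason the a ≥ 3 floor is part of the criteria.
* The PS-role universe definition means a drug's non-PS reports dilute the
  comparator; that matches the screening convention being emulated but is
  a modelling choice, not a law.
* Stratified (age/sex/year) tables and interaction screening are out of
  scope.
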