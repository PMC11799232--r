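---
title: "Disproportionality signal mining with pvmine: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal mining with pvmine: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvmine)
```

## The problem

Spontaneous-reporting databases (FAERS and its international
counterparts) accumulate case reports in which reporters associate drugs
with coded adverse events. Reporting is voluntary and unnormalized: there
is no denominator of exposed patients, events are heavily skewed toward a
few common terms, demographics are often missing, and the same case can
be resubmitted in several versions. Disproportionality analysis
sidesteps the missing denominator by comparing, within the database
itself, how often an event is reported with a target drug versus with
everything else. `pvmine` implements this analysis for report-level
extracts with one row per report × drug × event, the layout produced by
FAERS front ends such as OpenVigil.

## Counting model

All statistics are computed at the *case* level. A case enters the
analysis once, after deduplication keeps only the rows of its highest
report version (the convention for FAERS case versioning; the pipeline
exposes deduplication as a switchable step because some front ends
pre-deduplicate). For a target drug and target event, a case contributes
to cell `a` when the drug appears with role PS (primary suspect) *and*
the event appears at least once; multiplicity within a case is ignored.
The comparator — cells `c` and `d` — is every case of the supplied
extract in which the target drug is not PS; a drug occurring only as
secondary suspect or concomitant therefore counts as background, matching
the PS-based extraction contract. The background is whatever extract the
user supplies: against a whole-database extract the statistics estimate
database-wide disproportionality, against a narrower query they estimate
disproportionality within that query.

SOC-level tables reuse the same operation with the event defined as "the
case carries at least one preferred term whose primary SOC is the
target". Counting is primary-SOC-only, so per-drug SOC percentages sum to
100; multi-axial secondary assignments are not used.

## Statistics and signal criteria

With the 2×2 table `(a, b, c, d)`:

* `ROR = ad/bc`, 95% CI `exp(ln ROR ± 1.96·√(1/a + 1/b + 1/c + 1/d))`;
* `PRR = [a/(a+b)]/[c/(c+d)]`, 95% CI
  `exp(ln PRR ± 1.96·√(1/a − 1/(a+b) + 1/c − 1/(c+d)))`;
* χ² in two variants, Pearson `N(ad−bc)²/((a+b)(c+d)(a+c)(b+d))` and
  Yates (numerator `N(|ad−bc|−N/2)²`, floored at zero). Published signal
  tables rarely state which variant they print, so both are exposed and
  neither is asserted as "the" value.

The multiplier is the literal 1.96, not `qnorm(0.975)`, matching how
these intervals are printed in the field. A pair is a signal when
simultaneously `a ≥ 3` (inclusive), ROR CI lower bound `> 1` (strict) and
`PRR > 2` (strict); the strict/inclusive readings follow the usual
wording of the criteria. All three thresholds are configurable.

Zero cells make the estimates undefined; such pairs are flagged and
excluded from signals rather than silently corrected, because an
automatic +0.5 would change the signal count invisibly. An explicit
Haldane mode adds 0.5 to every cell *of zero-containing tables only*,
leaving well-populated tables untouched.

Two algebraic facts are used as cross-cutting invariants. First, for any
all-positive table, `ROR > PRR ⟺ ROR > 1` (and `ROR = PRR ⟺ ROR = 1`):
the ratio `ROR/PRR = d(a+b)/(b(c+d))` sits on the same side of 1 as ROR.
Second, a lognormal CI has geometric mean equal to its point estimate, to
machine precision. Both are enforced by property tests over thousands of
random tables, and both double as sanity checks on *published* rows.

## Inverting published summaries

A published signal row `(a, PRR, ROR, ROR CI)` determines the hidden
cells exactly. Writing `p = a/(a+b)` and `q = c/(c+d)`, the definitions
give `PRR = p/q` and `ROR = [p/(1−p)]/[q/(1−q)]`, which combine to

```
p = (ROR − PRR)/(ROR − 1),   q = p/PRR,
```

and the CI half-width yields `S² = [ln(hi/lo)/(2·1.96)]² = 1/a + 1/b +
1/c + 1/d`, from which `b = a(1−p)/p`, `c = 1/(R(1−q))`, `d = 1/(Rq)`
with `R = S² − 1/a − 1/b`. The implementation uses this closed form
directly — a multi-start numerical root finder was considered and
rejected, since the exact solution is available, is faster, and turns
every infeasibility into a *named* diagnosis: `p ∉ (0,1)` is the
PRR/ROR-ordering violation, a CI geometric mean away from the ROR breaks
the lognormal-CI precondition (tolerance 0.005 relative, generous for
3-decimal print rounding), and `R ≤ 0` means the printed CI is too narrow
for any positive `c, d`. `ROR = 1` leaves the system underdetermined and
is rejected explicitly. Note the pleasant forensic property: inverting a
row of a published top-20 table recovers not just the drug's margin but
the size of the whole background database.

The inversion is exquisitely sensitive for rows with `ROR ≈ PRR` (there
`R` is a difference of nearly equal rounded quantities), which is the
expected behaviour: those rows pin down an enormous background whose size
print rounding can no longer resolve. Residuals of the recomputed
statistics are always reported so the user sees the conditioning.

## Demographics

Demographics count distinct PS cases per drug. Age bins are `<18`,
`18–44`, `45–64`, `≥65` with missing ages in an explicit `unknown` bin,
and ages arriving in non-year units (decades, months, weeks, days, hours)
are converted by the reader; unconvertible or absurd values (≥150 years)
become missing with a warning rather than killing the row. Percentages
are shares of the drug's distinct-case total, rounded to 2 decimals. The
country ranking covers *known* countries only (ties alphabetical), with
the missing-country mass reported separately: published demographic
tables list named top-5 countries, and folding the (often large) missing
mass into the ranking would displace them.

## The synthetic generator

`sim_scenario()`/`generate_reports()` emulate the statistical structure a
FAERS-like extract presents to this pipeline:

* **Event frequencies** follow a Zipf law (`q_j ∝ rank^−1.5` by default,
  exponent configurable) over a catalog that starts with the real
  preferred terms of published triazole signal tables — spontaneous
  databases have exactly this heavy-tailed shape.
* **Events per report**: one guaranteed "index" event drawn from `q` plus
  independent per-PT Bernoulli extras with `p_j = (mean_events − 1)·q_j`
  (default `mean_events = 3`), so every report has ≥1 event and the
  marginal inclusion probability of PT `j` is the closed-form
  `B_j = 1 − (1 − q_j)(1 − p_j)`.
* **Planting** a (drug, pt, ρ) association rescales, for reports whose PS
  drug is the target, the event's inclusion odds: `odds(B′) = ρ·odds(B)`,
  realized through the Bernoulli component. Because the comparator arm is
  untouched, the *expected table's ROR is exactly ρ* (`expected_table()`
  returns the closed-form cells); PRR converges to ρ only for rare
  events. Targets implying probabilities outside [0, 1) are rejected at
  scenario construction with a suggestion to lower ρ.
* **Roles and drugs**: one PS drug per report from catalog weights
  (defaults make the three triazoles minority drugs against a realistic
  co-medication background), plus Poisson-many concomitant drugs with
  roles SS/C/I.
* **Demographics** mirror the published marginals coarsely: ~50% male,
  ~30% missing age, US-dominated countries with a 21% missing mass.
* **Case versioning**: a configurable fraction of cases (default 5%) is
  emitted twice with incremented version, exercising deduplication.

Everything is driven by the mandatory scenario seed; generation saves and
restores the caller's RNG state. What the generator does *not* emulate —
temporal reporting dynamics, drug–drug interaction reporting, correlated
event clusters (syndromes), differential reporting by country or year, or
duplicate cases with *conflicting* content — bounds what green tests
mean: they validate the statistical machinery under the stated sampling
model, not robustness to every pathology of real spontaneous data.

## Calibration experiments and problem sizes

The test suite and `scripts/acceptance.R` run the same experiments at the
same sizes:

* identity suite on 1,000 random all-positive tables (cells 1–500);
* contingency construction vs an independent brute-force double-loop
  counter on 100 random extracts of ≤200 reports;
* inversion round-trips on 100 random tables plus the published worked
  rows;
* CI coverage of a planted ROR = 5 across 500 replicates of 20,000
  reports (the published-criteria scale at which `a` is a few hundred),
  expected in the 93–97% band;
* null calibration on one 50,000-report extract with nothing planted:
  across all (drug, PT) pairs with `a ≥ 3`, the fraction whose 95% ROR CI
  excludes 1 should sit near the nominal 5% (the CI-coverage reading of
  "false positive rate"; the one-sided exceedance `ci_low > 1` runs near
  2.5% and is reported alongside, as is the joint-criteria signal rate,
  which is strictly smaller).

Replicate seeds for the coverage experiment are drawn from the
master-seeded RNG stream rather than from an arithmetic progression:
structured seed sequences are a known way to manufacture correlated
Mersenne–Twister streams, and decorrelated replicate seeds are the
standard practice for Monte Carlo calibration.

## Limitations

The package computes association, not causation: no adjustment for
confounding by indication, co-medication, or reporting fashion is
attempted, and no multiple-testing correction is applied (the
conventional joint criteria play that role crudely). Bayesian shrinkage
methods (BCPNN, EBGM/MGPS) are out of scope. Headline signal *counts*
from published studies are not reproducible from desk-scale extracts —
they depend on the full database background — which is exactly why the
validation strategy here rests on in-table arithmetic, algebraic
identities, oracle equivalence and simulation recovery instead.
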