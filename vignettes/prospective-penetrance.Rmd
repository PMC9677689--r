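---
title: "Methods: prospective penetrance estimation on an integer age grid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prospective penetrance estimation on an integer age grid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lynchcohort)
```

## The estimation problem

Carriers of pathogenic variants in the mismatch-repair genes (MLH1, MSH2,
MSH6, PMS2) face gene-, gender- and organ-specific cancer risks. Reliable
risk figures for counselling must come from prospectively accrued
observation time: a carrier contributes at-risk time only from the age at
which prospective follow-up begins (left truncation), until last
observation, death or a qualifying diagnosis (right censoring). Cancers
diagnosed before inclusion are *prevalent* history: they are kept as
carrier attributes, and a query-time policy decides whether such carriers
enter a given denominator at all.

The unit of observation is the carrier — exactly one row, never
duplicated, never split, with one follow-up window and any number of
cancer events. `validate_cohort()` enforces this structure (uniqueness,
referential integrity, window ordering, death bookkeeping, vocabulary
membership, whole-year ages in [0, 110]) and reports *every* violation
rather than stopping at the first, because in registry practice the data
call is iterated with the contributing centres.

## Person-time on the integer age grid

Registry data of this kind record ages as whole years, so every interval
convention must be stated explicitly:

* All intervals are half-open. A window from inclusion age $s$ to last
  observation $b$ covers the year-cells $[s, s+1), \dots, [b-1, b)$ and
  contributes exactly $b - s$ person-years ($0$ when $s = b$; such
  carriers still appear in the head-count output).
* A diagnosis at integer age $e$ occurred at an unknown moment inside
  $[e, e+1)$. The package counts the whole diagnosis year as at-risk
  time: under event censoring the window ends at $e + 1$, not $e$. This
  keeps every annual rate at or below 1 event per person-year, keeps each
  counted event inside at-risk time even when the diagnosis year is the
  final year of observation, and matches person-time attribution in
  registry practice. It is a convention — with data at year resolution
  some choice is forced — and it is applied uniformly by
  `risk_window()`, `incidence_table()` and `km_export()`, which all share
  one selection routine so the outputs cannot disagree about who
  qualifies.
* Three censoring policies are provided because published analyses do not
  always state theirs: `first_target_event` (default; organ-specific
  incidence), `first_any_cancer` (any first cancer ends at-risk time) and
  `admin_only` (administrative censoring only). Under `admin_only` an
  event in the very last observed year (age $e$ with $e$ = last
  observation) is not counted, since the window $[s, b)$ contains no
  at-risk time at age $b$; under the default policy it is counted and the
  year is at risk. Only the first qualifying target-organ event per
  carrier is ever counted in $d$.
* Three prevalent-case policies: exclude carriers with pre-inclusion
  target-organ cancer (default), exclude any pre-inclusion cancer, or
  include everyone. Prevalent events themselves are never counted as
  incident events under any policy.

For a selection, bin $i$ accumulates events $d_i$, person-years $y_i$ and
the annual rate $r_i = d_i / y_i$ ($r_i$ is undefined, not $0/0$, when
$y_i = 0$). The defaults — ages $[25, 75)$ in 5-year bins — reflect the
usual reporting range for carrier risks; both are free parameters of
`query_spec()`.

## Exact intervals and cumulative incidence

Rare-cancer strata routinely have $d_i \in \{0, 1, 2\}$, where normal
approximations fail, so interval estimation uses the exact (Garwood)
chi-square form:
$$\left[\tfrac{1}{2y}\chi^2_{\alpha/2,\,2d},\;
        \tfrac{1}{2y}\chi^2_{1-\alpha/2,\,2d+2}\right],$$
with lower limit 0 at $d = 0$. The test suite cross-checks this against
the independent exact-Poisson routine in `stats::poisson.test()`.

Cumulative incidence from a start age $c$ is the discrete product over
one-year steps,
$$Q(a) = 1 - \prod_{t=c}^{a-1}\bigl(1 - r(t)\bigr),$$
with $r(t)$ read from the bin covering year $t$. On the integer-age
person-time model each at-risk carrier-year is a Bernoulli trial, so the
per-year rate is a probability and the product form is the natural
accumulator; it also makes the age-conditioning identity
$Q_c(a) = (Q_0(a) - Q_0(c))/(1 - Q_0(c))$ hold exactly, which is how
"risk from any current age" is validated. Numerical conventions:

* rates above 1 (possible with tiny denominators) are clamped to 1 inside
  the product, with a warning — $Q$ must remain a probability;
* a year whose bin has $y = 0$ inherits the most recent earlier rate
  (carry-forward, with a warning); a year covered by no bin, or with no
  earlier rate to inherit, is a coverage error naming the first such age;
* start ages below 25 are allowed with a warning: published carrier risks
  are conventionally reported from age 25 onwards and younger strata are
  usually too thin.

Uncertainty in the curve is propagated by a parametric bootstrap:
$d_i^* \sim \text{Poisson}(d_i)$ per bin with $y_i$ fixed, pointwise
percentile bands (default 2000 replicates, level 0.95). The seed is a
required, recorded argument, so every band is reproducible. An internal
coverage experiment (500 simulated tables from known rates) checks that
the 95% band covers the true end-of-curve risk at close to nominal
frequency.

## Survival after cancer

`km_export()` produces one row per carrier whose first index-organ
diagnosis is incident and inside the query's age range: time from
diagnosis to exit in whole years, death from any cause as the event.
Zero-length rows (diagnosed at last observation, alive) are retained and
flagged rather than dropped, so the export's row count always equals the
tabulated event total under the default censoring policy — an identity
the tests assert. The bundled `km_estimate()` is a reference
product-limit estimator (deaths precede censorings at tied times, the
standard convention) checked to 1e-12 against `survival::survfit`; for
real analyses the exported rows can go to any survival package.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates registries with known truth: carriers drawn
from categorical gene/gender/region/status distributions; an inclusion
age from a discretised distribution (default: ages 25–60 weighted by a
Normal(35, 10) density, mimicking predictive testing in early adulthood);
administrative censoring after a drawn number of follow-up years (default
uniform 3–22); per-organ cancer onset as independent per-year Bernoulli
draws with $p = 1 - \exp(-h)$ from piecewise-constant annual hazards; and
an annual death probability from the first incident diagnosis onwards
(default 0.04). Events are walked from birth, so later inclusion
mechanically produces more prevalent history — a property the tests
assert. The default size of 2,000 carriers is the order of magnitude at
which a first pooled, gender-unstratified analysis of this kind becomes
feasible.

The Bernoulli convention $p = 1 - \exp(-h)$ makes the discrete product
$1 - \prod(1-p)$ equal the continuous-time form $1 - e^{-h k}$ *exactly*,
so estimator checks against truth carry no discretisation error. Gaps in
a hazard specification are treated as hazard 0 (so bands always
effectively tile ages 0–110); overlapping bands are a configuration
error. The default hazard table (`default_hazards()`) uses illustrative
Lynch-like magnitudes — male-dominant colorectal risk for MLH1, high
gynaecological hazards for MSH2/MSH6, low hazards for PMS2, zero outside
ages 25–75 — chosen once to exercise the engine across realistic
regimes; it is deliberately *not* calibrated to any published risk table.

The simulator draws at most one event per organ per carrier, organs
evolve independently, death hazard starts only at an incident (not
prevalent) diagnosis, and non-pathogenic carriers get zero tumour hazard.
Real registries differ in all four respects (second primaries in the same
organ, correlated organ risks, background mortality, phenocopies in
non-carriers), so passing tests demonstrate correctness of the
*computation* under the stated model, not realism of any particular risk
figure.

## Design choices that were genuinely open

* **Same-organ, same-age duplicate events** are legal data: nothing in
  the carrier-centric model forbids two recorded primaries of one organ
  at one age, so validation does not reject them; tabulation counts only
  the first qualifying event regardless.
* **Gene and organ vocabularies are configurable enumerations** (defaults:
  the four MMR genes; ten Lynch-spectrum organ codes). EPCAM or
  additional organs can be admitted per cohort without code changes.
* **Non-pathogenic records** (`non_carrier`, `unknown`) are importable
  and appear in the head-count output, but incidence queries default to
  `statuses = "pathogenic"`; other statuses must be selected explicitly.
* **CSV as the interchange contract** (RFC 4180, header required, booleans
  as 0/1, missing as empty, 6 significant digits for rates, canonical row
  order for byte-stable writes) replaces database connectivity; the
  column dialect is documented in `read_cohort()`.
* **Ties in the index diagnosis** (two target organs at the same age):
  the export keeps one row per carrier — the carrier is the unit — and
  labels it with the alphabetically first organ.

## Problem sizes used by the test suite

The suite validates the engine with: 200 random cohorts (up to 50
carriers) against a per-carrier-per-year brute-force enumeration, exact
equality; 500 constant-hazard cohorts of 2,000 carriers for Garwood
coverage of a known rate; 500 bootstrap-band replicates for curve
coverage; 100 random row sets against `survival::survfit`; and 100
random round-trip cohorts. These sizes give exact checks where exactness
is claimed and Monte-Carlo bands of a few tenths of a percent where
coverage is claimed, while keeping a full run under a minute on one CPU.

## Known limitations

* Thin tails are noisy: a late bin with, say, $y = 3$ and one event has
  $r = 1/3$, and five compounded years of it move $Q$ drastically. The
  engine reports what the data say; restricting the reporting range to
  well-populated ages (or widening bins) is the analyst's decision.
* No competing-risk adjustment: $Q$ is risk in the absence of competing
  mortality, and the K-M endpoint is death from any cause. Aalen-Johansen
  or cause-specific extensions are out of scope.
* One-axis Lexis only: person-time is split by age, not calendar period.
* Whole-year resolution throughout; sub-year timing is not represented.
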