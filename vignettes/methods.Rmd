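---
title: "Methods: age-based dose/time reallocation and its risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age-based dose/time reallocation and its risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agedose)
```

## The procedure

`agedose` models a session-level reallocation of FDG activity and PET scan
time. Within each daily session the patients are ordered by age, ties
broken by roster order (a stable sort, so the input file is the
tie-breaker of record). The `k` youngest patients receive

- activity′ = ⌊activity × (1 − f)⌋,
- scan time′ = ⌊scan time × (1 + f)⌋,

the `k` oldest the mirror image, and the remainder are untouched. Defaults
are f = 0.20 and k = 3. Because a patient's counting statistic is roughly
proportional to activity × time, a modified patient's pre-truncation
counting statistic scales by (1 − f)(1 + f) = 1 − f² = 0.96 at the default
fraction: the rule is approximately, not exactly, count-preserving, and the
package asserts the 0.96 factor as a documented property rather than
claiming a conservation law.

A session with fewer than 2k + 1 patients cannot support disjoint young
and old groups plus at least one unmodified patient; `k` is then shrunk to
⌊(n − 1)/2⌋ with a warning (or, in strict mode, the session is rejected).
The degenerate n = 1 session therefore leaves its only patient unmodified.

### Truncation policy

Fractional MBq and seconds are floored, not rounded: the bundled
worked-example session fixes this (289.6 → 289, 214.4 → 214, 242.4 → 242,
296.4 → 296, 1335.6 → 1335, 950.4 → 950, 1070.4 → 1070 are all floors).
One printed cell in that session — the 19-year-old's modified scan time,
1465 s — is inconsistent with every other row's ×1.2 arithmetic
(1211 × 1.2 = 1453.2); the package treats it as a typo in the source
table, computes 1453, and excludes that single cell from its oracles.
Floating point makes naive flooring hazardous: 1165 × 1.2 is
1397.999… in binary, so `apply_algo()` floors after adding a 10⁻⁷
guard, which is far below the half-unit that could change a correct
answer.

## Dose model

Effective dose is linear in administered activity, ED = A·c. The default
coefficient c = 0.016 mSv/MBq is *derived*, not assumed: every printed ED
in the bundled worked session equals activity × 0.016 with zero residual,
and `derive_ed_coefficient()` recovers exactly that with a 10⁻³ relative
consistency check across pairs. The ICRP nominal adult FDG coefficient
(≈ 0.019 mSv·MBq⁻¹) is selectable but is not the default precisely because
it does not reproduce the bundled data; the `dose_coefficient` object
carries a provenance string so reports can keep this distinction visible.
The dose modelled is the PET component only — CT acquisition parameters
are held fixed by the procedure and CT dose is out of scope.

## Risk model

Additional cancer risk is linear in effective dose with an age- and
sex-specific slope: ACR = r(age, sex) × ED. Linearity is the
low-dose assumption underpinning BEIR VII-style risk estimation, and it
has a structural consequence the package leans on everywhere: for a
patient whose activity changes by a ratio ρ, ACR changes by exactly ρ.

Two sources for r are provided:

1. **The calibrated table (default).** Ten nodes back-calculated from the
   worked-example session (r = ACR/ED per patient). They decrease
   strictly with age within each sex and are higher for females at
   comparable ages — e.g. the female node at 67 exceeds the male node
   at 63. The underlying lifetable quantity (incidence vs mortality LAR,
   transport weighting) is undisclosed in the source; the back-calculated
   ratios are the only authoritative anchor, which is why they are the
   default and why their provenance is labelled.
2. **The lifetable engine (opt-in).** A generic BEIR VII-style LAR:
   LAR(D, e) = Σₐ (β_sex·D/DDREF)·exp(γe*)·(a/60)^η · S(a)/S(e), with
   e* = (min(e, 30) − 30)/10, summed over tabulated attained ages a with
   a > e, a ≥ e + latency and a ≤ max\_age. The bound convention is fixed
   by the requirement that, with latency 0, exposure at an age contributes
   nothing at that same age (risk accrues strictly afterwards). All
   parameters are user-supplied configuration; in BEIR VII's preferred
   models γ ≈ −0.30 per decade, so that younger exposures carry more risk.
   Note the sign convention matters: with this e* (non-positive), a
   *positive* γ would make risk rise with exposure age below 30. Even with
   γ < 0, LAR need not be monotone in exposure age when η > 0 — the
   (a/60)^η weight grows with attained age, partially offsetting the
   shrinking horizon — so monotonicity is a property of specific
   parameter choices, not of the form.

Interpolation between table nodes is piecewise linear in age (the simplest
monotone-preserving choice); outside the tabulated range the end value is
clamped, since ages outside 18–90 are excluded by design (an error policy
is available). ACR is treated as a dimensionless risk on the calibration
scale of the table in use, without asserting whether that scale is percent
or per-person.

### Printed-value tolerances

The worked session's printed risks were evidently rounded from unrounded
internals: three cells (0.0549, 0.0106, 0.0088) differ by exactly one unit
in the fourth decimal from the dose-ratio arithmetic on the printed
inputs. All comparisons against printed risk values therefore use a
tolerance of one unit in the last printed decimal; internal computation is
never rounded.

## Evaluation

Strata are the whole cohort, each sex, and the inclusive age brackets
18–29, 30–60, 61–90. Per stratum the package reports n, mean and sample
(n − 1) SD of ACR under both protocols, the percent change
100 × (mean_ref − mean_algo)/mean_ref **of the stratum means** (a ratio of
means, deliberately not a mean of per-patient ratios — the two differ, and
only the former reproduces the published stratum arithmetic), and a paired
Student t-test on the per-patient differences. Zero-variance differences
(every patient changed by the same amount, or none changed) make the t
statistic undefined; the package signals a classed warning and returns NA
rather than a spurious number. Positive percent change means the modified
protocol reduced risk.

Session-level summaries recompute percent decreases from unrounded session
means; the bundled 43-session summary table's printed percentages cannot
be recovered from its own rounded mean columns (they derive from the
authors' unrounded internals), so exactness tests use self-generated data
and the bundled table serves as a structural fixture only.

For display, percent changes are truncated toward zero at one decimal
(`format_percent()`), matching the published convention for the oldest
bracket's entry (7.46 → 7.4); computation never truncates. No single
one-decimal display rule reproduces every published stratum entry from the
published rounded means (two entries require rounding rather than
truncation), which is documented here rather than patched over: the
comparisons in the test suite accept agreement at one-decimal precision
and apply the truncation rule where the published table demonstrably used
it.

## The synthetic-cohort generator

`generate_cohort()` emulates the study population's reported margins:
43 sessions of 7–13 patients (uniform), 57% male, age from a truncated
normal (64, 14) on [18, 90], weight from a truncated normal (72.3, 14.2)
on [40, 120] kg, activity = ⌊weight × N(3.95, 0.3)⌋ clipped to
[185, 399] MBq, scan time N(1191, 198) clipped to [600, 1800] s and
floored. Truncated normals are sampled by inverse-CDF mapping of uniforms,
so a seed fully determines the cohort. The per-kg SD (0.3 MBq/kg) and the
weight and scan-time truncation bounds are package choices — only means,
SDs and ranges are reported for the population — and are exposed as
configuration.

What the generator does *not* emulate, and what passing tests therefore do
not show about real data:

- **Age–session clustering.** Real sessions have structured age
  compositions; the generator draws ages i.i.d. within and across
  sessions.
- **The young tail.** A truncated normal (64, 14) puts well under 1% of
  patients in the 18–29 bracket, versus 4% in the study cohort, whose age
  distribution is left-heavier than any normal. Simulated 18–29 strata
  are tiny and occasionally empty; the qualitative checks treat the
  youngest-bracket ordering as conditional on the stratum being populated.
- **Age–sex–weight dependence.** All demographics are drawn independently.

## Numerical and design choices

- Floor truncation with a 10⁻⁷ guard (above); `round` available as an
  alternative policy.
- Age ties at group boundaries: stable roster order decides.
- Percent-change display truncates toward zero at one decimal; JSON and
  CSV outputs carry unrounded values except where the results-file
  contract states a precision (activities/times integer, ED 3 decimals,
  ACR and percent change 4 decimals), at which the CSV round-trips
  losslessly.
- The paired t-test is delegated to `stats::t.test(paired = TRUE)`; the
  test suite checks it against an independently coded difference formula.
- Problem sizes: the test suite and qualitative checks run on the bundled
  ten-patient session, small generated rosters, and five default-sized
  simulated cohorts (~420 patients each), which keeps the full suite in
  the tens of seconds on a single CPU while exercising every stratum.

## Known limitations

- The calibrated risk table has ten nodes from one session; between nodes
  it is a linear guess, and below 19/above 81 a clamp. It reproduces its
  source exactly but is not a population risk model.
- The lifetable engine is a skeleton of the BEIR VII preferred-model
  structure (no site-specific risks, no ERR/EAR transport averaging, no
  uncertainty), intended for transparent sensitivity analyses, not
  regulatory dosimetry.
- CT dose, image quality, counting-statistics noise and scanner effects
  are all out of scope; the 1 − f² counting-statistic factor is the only
  image-quality-adjacent quantity tracked.
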