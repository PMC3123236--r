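---
title: "Methods: plate calculations, IC50 estimation and the synthetic validator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plate calculations, IC50 estimation and the synthetic validator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(platewell)
```

`platewell` manages dose–response microplate assays end to end: plate
design, raw-data import, curation and analysis. This vignette explains the
statistical procedures, the choices behind them, and what the synthetic
validator does and does not demonstrate.

## The data model and its assumptions

Plates are built in steps so that each artefact is reusable: a *plate
type* (geometry only), a *plate layout* (well roles and formulas), a
*master plate* (substances and concentrations), and finally a barcoded
*plate* holding one raw measurement per well. The analysis layer assumes:

* one scalar measurement per well (no time series);
* raw signal is an increasing function of the quantity of interest
  (e.g. fluorescence from surviving cells), anchored by *blank* wells
  (no cells, background signal) and *control* wells (untreated, full
  signal);
* treatment wells carry geometric dilution series, so concentration is
  naturally analysed on a log10 axis;
* curation is binary: a well is either used or flagged as an outlier, and
  flagged wells leave *every* downstream computation (group aggregates, QC
  statistics, dose–response points).

## The formula language

Well and plate functions are written in a small Excel-like expression
language: numbers, `+ - * /`, unary minus, parentheses, the current
well's `value`, A1-style well references, aggregates
`avg | sd | cv | min | max | median | count(GROUP)` over a marker group's
non-outlier wells, and `plate(NAME)` references to named plate functions.
Identifiers are case-sensitive and whitespace is insignificant. There is
deliberately no cell-range syntax (`A1:B3`): marker groups *are* the
ranges, which keeps formulas meaningful when a layout is reused on a
different plate shape.

Semantics are split by failure type, because curation must not crash
reporting: *data-dependent* failures (a missing well, an empty group,
division by zero) evaluate to missing (`NA`) and propagate; *structural*
failures (an unknown group or plate function, a `value` token inside a
plate function, a cycle among plate functions) raise errors. Plate
functions are resolved by direct recursion with cycle detection — there is
no fixed-point iteration, so mutually recursive plate functions are a
reference error, not an infinite loop.

Throughout the package the *sample* standard deviation (n − 1) is used,
matching screening QC practice; consequently `sd` of a single well is
missing, and so is the CV% of a one-well group.

The survival-index formula shipped in examples and the simulator,

```
SI% = (value - avg(BLANK)) / (avg(CTRL) - avg(BLANK)) * 100
```

is the standard viability normalisation (blank-subtracted signal scaled
between blank = 0% and untreated control = 100%). Layouts can attach
different SI formulas to different well groups, so each plate region can
be normalised against its nearest control group.

## QC statistics

* **CV%** is `100 · sd/mean` over a control group's non-outlier wells,
  reported per group *and* pooled over the union of all control wells.
  The pooled value tracks between-group drift that per-group CVs hide. A
  zero mean or n < 2 yields a missing entry rather than an error.
* **Z-scores** over a chosen well set are `(x − mean)/sd` with the sample
  sd of that set; they are meaningful in primary screening (one
  concentration per substance), not within dilution series.

## IC50 estimation

Two procedures operate on the same per-substance curve: non-outlier
replicate wells are grouped by concentration, the evaluated SI per well is
averaged per concentration (with sd when n ≥ 2), and points are sorted by
ascending concentration. Replicates are averaged *before* either
estimator, so both see the same piecewise-linear curve "drawn with
straight lines between the points".

**Linear interpolation (default).** Adjacent point pairs whose responses
bracket the 50% level are candidates; the pair whose responses are jointly
closest to 50% (minimal `|r1 − 50| + |r2 − 50|`) is interpolated linearly
*in log10(concentration)* to the crossing. Choices worth stating:

* *Axis.* Dilution series are geometric, so dose–response plots are drawn
  on a log-dose axis; interpolating on log10(c) is the faithful reading of
  a straight line on such a plot. The linear axis remains available behind
  the `axis` argument of `ic50_linear()` / `response_at()`, and the test
  suite's dense-grid oracle uses the same axis convention, so the choice
  is isolated and self-consistent.
* *Bracketing only.* A nearest-but-not-bracketing pair would extrapolate;
  if no pair brackets 50% (curve entirely above or below), the result is
  undefined with a `no_crossing` reason code rather than a number.
* *Ties and exact hits.* A point at exactly 50% returns its concentration
  directly; among equally-close bracketing pairs the lower concentration
  wins. Non-monotone curves may cross 50% several times — the jointly
  closest pair rule picks one deterministically.

**Hill fit (optional).** The four-parameter logistic
`f(c) = bottom + (top − bottom)/(1 + (c/IC50)^h)` is fitted by non-linear
least squares (Levenberg–Marquardt via `minpack.lm::nlsLM`), parameterised
in log10(IC50). At least 4 points are required (4 free parameters).
Numerical scheme:

* initialisation: `top = max(r)`, `bottom = min(r)`, `|h| = 1` with the
  sign taken from the response-vs-log-dose trend (positive `h` for
  decreasing response in this parameterisation), and IC50 from the linear
  estimate when defined, else the geometric mean of the concentration
  range;
* bounds: `IC50 ∈ [c_min/100, c_max·100]` — two decades beyond the
  measured range, past which an IC50 claim from these data would be
  meaningless; top/bottom/slope are free;
* convergence: relative tolerance 1e-8, up to 200 iterations. If the LM
  path fails outright (which happens on exact-fit, zero-residual data,
  where its post-fit gradient factorisation is singular), a bounded
  L-BFGS-B pass on the residual sum of squares takes over and reports its
  own convergence status; if that fails too, the initial guess is returned
  with `converged = FALSE`. A fit whose RSS exceeds the RSS of its own
  starting point is never reported as converged.

Fixing `top`/`bottom` was considered and rejected as the default: free
asymptotes are the safer general choice for cell assays whose curves "vary
a lot", and a constrained variant can be layered on without changing the
interface.

**Comparing retrieved series.** `compare_series()` is a two-sided Welch
(unequal-variance) t-test, the safer default when replicate counts and
variances differ between plate batches. When both series are constant the
statistic is undefined; the result carries missing `t`/`p` and a reason
instead of an error or a fabricated zero.

## The auditing store

Every resource is one JSON document with an audit block (creator, UTC
creation time). Deletion is *soft*: the flag hides the resource from
default listings and blocks new references, but nothing is ever physically
removed, and only an administrator can undelete. Updates (data import,
outlier flags) never touch the original audit fields. Only creation and
deletion events are audited — a deliberate minimal contract; a
modification log could be added at the store layer without touching
callers. Doubles are serialized as 17-significant-digit strings so a
reopened store is bit-identical to the one closed, which the suite checks
with `identical()`.

## The synthetic validator

`simulate_plate()` generates plates from a known truth so every stage —
file parsing, barcode matching, formula evaluation, curation, both IC50
procedures — can be validated without any external data. The signal model
per well is

```
raw(w) = (blank + v(w) * (control - blank)) * drift(w) * edge(w) + e,
e ~ N(0, sd^2)
```

with viability `v` equal to the true Hill response at the well's
concentration, 1 for controls and 0 for blanks and unused wells.

Default conditions (chosen once, as a realistic cell-viability plate):

| parameter | default | rationale |
|---|---|---|
| geometry | 8 × 12 | the manual-throughput standard |
| outer ring | unused | edge wells are routinely excluded from measurement roles |
| controls | 2 flanking columns in different regions (+ pooled group; per-row groups in `regional` mode) | nearest-control practice against spatial drift |
| blanks | 1 row | background anchor |
| substances | 2 × 2 replicate rows | replicate/coverage trade-off on 60 usable wells |
| dilution | 8 half-log steps from 100 µM | spans ~3.5 decades around the true IC50s (1 and 10 µM) |
| signal | control 1000, blank 50 (RFU) | ~20:1 signal-to-background |
| noise sd | 2% of the control–blank span (= 2 SI points) | a clean but non-trivial assay |

Drift is multiplicative and linear in the row/column indices, and the edge
artifact is a single multiplier on the outer ring — the simplest
mechanisms that make spatial structure testable. These are emulation
devices, not mechanistic models: the simulator does not reproduce
incubation dynamics, meniscus optics, correlated (non-linear) drift
surfaces, or heavy-tailed outliers. Passing the synthetic suite therefore
demonstrates that the *pipeline machinery* is correct under its stated
noise model; it does not certify performance on pathological real-world
plates.

One experiment deserves its own note. To show the value of region-matched
controls under drift, the suite compares `regional` mode (each treatment
row normalised against the control wells in its own row) with `pooled`
mode (one SI formula against all controls) under 1%-per-row drift, scoring
the *linear-interpolation* IC50 against truth. Two findings shaped this
design: with a centred treatment block, symmetric linear drift leaves the
pooled control average nearly unbiased, so control placement must be
compared through level-sensitive statistics; and after replicate
averaging, linear row drift distorts SI affinely — which a free-asymptote
Hill fit absorbs exactly, making the 50%-crossing estimator the right
probe. The comparison runs one noiseless plate (pure bias, ~10× smaller
for nearest controls) and 40 noisy plates (medians) under fixed seeds.

## Problem sizes in the test suite

The suite validates the linear-IC50 routine against an independent
dense-grid crossing oracle on 1000 random monotone curves (20001-point
log grids), Hill recovery on 100 simulated noisy plates (median relative
IC50 error under 10%), the Welch test's type-I error on 1000 replications,
and the full simulate → write → import → report chain in both file
dialects. These sizes were chosen to give stable pass/fail behaviour under
fixed seeds while keeping a full run in well under a minute.

## Known limitations

* No cross-plate global fitting, combination-index analysis, or B-score
  style spatial normalisation beyond what well functions can express.
* The reader-log dialect is project-defined; real vendor exports need a
  new reader behind the same interface.
* The store is single-user-at-a-time by design (trusted local usernames,
  no locking); the audit contract, not concurrency, is the point.
* `count()` of an empty group is 0 rather than missing — it answers "how
  many usable wells", which is a well-defined question even when the
  answer is none.
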