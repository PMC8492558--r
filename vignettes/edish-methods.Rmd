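---
title: "Methods: eDISH screening statistics and their implementation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eDISH screening statistics and their implementation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The screening problem

Drug-induced liver injury (DILI) is the leading safety reason for drug
withdrawal, and the canonical early-warning analysis in clinical trials is
the eDISH display (evaluation of Drug-Induced Serious Hepatotoxicity): each
subject is reduced to the peak post-baseline alanine aminotransferase (ALT)
and the peak post-baseline total bilirubin (TB), both expressed as multiples
of the upper limit of normal (ULN), and plotted on log axes. The plane is
divided by two thresholds into four regions of clinical meaning:

* **possible Hy's Law** — ALT ≥ 3×ULN *and* TB ≥ 2×ULN. Hy's Law is the
  observation that hepatocellular injury severe enough to impair bilirubin
  excretion carries a high risk of fatal DILI.
* **Temple's Corollary** — marked ALT elevation without bilirubin elevation;
  a sensitive early indicator of hepatotoxic potential.
* **hyperbilirubinemia** — bilirubin elevation without marked ALT elevation
  (Gilbert-pattern, hemolysis, or cholestatic causes).
* **within range** — neither threshold crossed.

`edishr` computes these statistics from raw trial laboratory tables,
classifies subjects, and renders the interactive report a safety reviewer
or data monitoring committee works from.

## Derived statistics

All derivations start from one normalized record per (subject, analyte,
study day) with a result and its ULN.

**Fold-ULN.** `fold_uln(value, uln) = value / uln`. Dimensionless; every
downstream statistic is built from it, so the analysis is unaffected by the
units a study reports so long as value and ULN share them.

**Baseline and treatment-emergent peaks.** Study days follow the CDISC
convention (day 1 is first dose; there is no day 0). The baseline for an
analyte is the latest record at day ≤ 1, unless the mapping supplies an
explicit baseline flag, which wins. Peaks are computed over post-baseline
days (> 1) only — the screening question is about treatment-emergent
elevation — and ties are broken to the earliest day so that peak timing is
deterministic.

**R and nR ratios.** At a visit with a same-day ALP measurement,

* `R = (ALT fold-ULN) / (ALP fold-ULN)`
* `nR = max(ALT, AST fold-ULN) / (ALP fold-ULN)`

These locate the injury on the hepatocellular–cholestatic axis. The package
follows the CIOMS convention: ratio ≥ 5 hepatocellular, ≤ 2 cholestatic,
strictly between mixed; an undefined ratio (no same-day ALP) is
indeterminate. Both breakpoints are configurable.

The subject-level ratio used for the injury-pattern call has two bases,
because clinical practice computes R "at presentation" while a screening
table may prefer peaks:

* `ratio_basis = "visit"` (default): the same-day ratio at the visit of the
  subject's peak transaminase fold. This is the standard clinical
  definition and is what the default pipeline reports.
* `ratio_basis = "peak"`: the ratio of peak folds, which may come from
  different days.

Both are exposed; the choice is configuration, not a hidden constant.

**Peak-time separation.** `|day(peak ALT) − day(peak TB)|`. A Hy's-Law-like
pair of elevations is far more concerning when the two peaks are temporally
concordant; the `within_window` flag (default window 30 days) carries this.
Quadrant membership deliberately keeps the classic eDISH definition — peaks
possibly from different days — and temporal concordance is encoded as point
color in the figure, not as a change of quadrant.

**P_ALT.** An estimate of the percentage of hepatocytes lost, from a
released-enzyme mass balance:

```
P_ALT = 100 × (peak ALT − baseline ALT) × V_d / ALT_total ,  clipped to [0, 100]
```

where `V_d` is the distribution volume of circulating ALT (default 3 L,
adult plasma volume) and `ALT_total` the total ALT content of the intact
liver (default 30 000 U, chosen so that peak ALT near 10 000 U/L — the
range seen with massive necrosis — maps to near-total loss). Both constants
are calibration-dependent and live in configuration
(`p_alt_constants()`), not in code; the estimate ignores ALT elimination
during the rise and should be read as an order-of-magnitude triage aid, not
a measurement.

**Hysteresis path.** For the animation, the per-subject ALT-vs-TB trajectory
is the day-ordered sequence of (ALT fold, TB fold). Days where only one of
the two analytes was measured carry the other forward from its last
observation (LOCF); this keeps the path defined at every observation day
without inventing interpolated values (a configurable alternative would be
to drop incomplete days). The path starts at the first day both analytes
have been observed.

## Quadrant classification

With `x` the peak ALT fold (or the peak nR ratio in nR mode) and `y` the
peak TB fold, thresholds are **inclusive on the flagged side**: a subject
exactly at 3×ULN / 2×ULN is a possible Hy's Law case. Defaults are 3 (ALT),
2 (TB) and 5 (nR mode), all configurable — oncology programs, for example,
routinely run with relaxed ALT cut points. In `fold_baseline` axis mode the
*display* coordinates switch to fold-of-baseline, but quadrant membership
stays on fold-ULN peaks: the regulatory definitions are ULN-based, and
changing the classification silently with an axis toggle would be a trap.

## Ingest

SDTM-like tables (`USUBJID, LBTESTCD, LBSTRESN, LBSTNRHI, LBDY`) and
ADaM-like tables (`USUBJID, PARAMCD, AVAL, ANRHI|A1HI, ADY`) are recognized
automatically (case-insensitive); when both signatures are present the
analysis-ready ADaM mapping wins and the tie is logged. `ANRHI` is preferred
over `A1HI` by default and is configurable. Anything else needs a small
mapping file binding five columns and, optionally, an analyte-code
dictionary; the shipped dictionary covers the common `LBTESTCD`/`PARAMCD`
spellings (`SGPT`, `BILI`, `TBILI`, …).

Normalization policy, all surfaced in the validation report rather than
silently applied:

* duplicate (subject, analyte, day) records collapse to the **maximum**
  value by default — conservative for safety screening — with `first` and
  `mean` available;
* records with unmappable analyte codes, non-numeric results, or day 0 are
  excluded and counted by reason;
* a record without a usable ULN falls back to a configured study-level
  per-analyte ULN, else is excluded (fold-ULN is undefined without a
  reference);
* no unit conversion is attempted (folds are unit-free); a heuristic
  warning fires when a ULN varies more than 2-fold within one analyte,
  which usually means mixed units;
* a subject without post-baseline ALT *and* TB is retained but marked
  non-evaluable.

## Numerical choices

Dimensionless derived quantities (folds, and hence ratios) are quantized at
**7 significant digits**. Clinical assays carry about 3 significant digits,
so nothing scientifically meaningful is discarded, and in return derived
tables become exactly invariant under unit rescaling (multiplying every
value and its ULN by the same constant) and stable across numerics
libraries — raw double division leaves last-ulp differences under such
rescaling. Peak ties (which quantization can only make more frequent) are
broken to the earliest day, deterministically. Dialect writers print values
with 17 significant digits, which makes write→read round trips exact in
double precision and fixed-seed emissions byte-identical.

## The synthetic trial generator

The simulator exists so the whole pipeline is testable with no patient
data: every subject carries a designed phenotype whose defining
inequalities hold with **margin ≥ 1.2×** at zero noise, so the pipeline
must recover the design exactly when noise is off, and degrades gracefully
— and measurably — as noise grows.

| phenotype | ALT peak | AST peak | ALP peak | TB peak | pattern (R at ALT peak) | quadrant |
|---|---|---|---|---|---|---|
| normal | 0.6 | 0.6 | 0.6 | 0.6 | 1.0 → cholestatic | within range |
| hys_law | 6.0 (d15) | 5.0 | 0.6 | 3.0 (d22) | 10 → hepatocellular | possible Hy's Law |
| temples | 5.0 (d15) | 4.0 | 0.6 | 0.6 | 8.3 → hepatocellular | Temple's Corollary |
| hyperbili | 0.6 | 0.6 | 0.6 | 3.0 (d15) | 1.0 → cholestatic | hyperbilirubinemia |
| cholestatic | 1.2 (d15) | 0.6 | 3.0 (d15) | 1.4 | 0.4 → cholestatic | within range |
| mixed | 3.8 (d15) | 3.0 | 1.2 (d15) | 0.6 | 3.17 → mixed | Temple's Corollary |

(Entries are designed peak fold-ULN; a "pattern" of cholestatic for a
normal subject is simply what the step function returns at R = 1 — the
truth labels are generated through the same public rules the pipeline
applies, so consistency is by construction, not by annotation.)

Mechanics and defaults:

* visit schedule −7, 1, 8, 15, 22, 29, 43, 57 — screening, first dose, then
  weekly/biweekly, a typical phase-2 panel cadence;
* ULNs ALT 40 U/L, AST 40 U/L, ALP 120 U/L, TB 1.2 mg/dL — conventional
  reference values, configuration only;
* baselines drawn lognormally around 0.6×ULN; excursions rise log-linearly
  from onset to the designed peak and decay exponentially on the log-fold
  scale (half-life 10 days), a shape that resembles hepatocellular injury
  time courses and gives analytic control of the peak;
* noise is multiplicative lognormal with `noise_sd = 0.1` on the log scale
  (~10% CV), the order of short-term analytic plus biological variation of
  serum liver tests;
* the default phenotype mix (1.5% Hy's Law, 2.5% Temple's, 2.5%
  hyperbilirubinemia, 5% cholestatic, 5% mixed, 83.5% normal) emulates a
  trial with a modest hepatotoxic signal;
* each subject draws from an independent RNG substream derived from the
  master seed, so growing `n_subjects` never reshuffles earlier subjects.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: missed visits and dropout, assay batch
effects, mixed units across sites, covariate-dependent injury risk,
rechallenge, and any drug-specific pharmacology. The generator validates
the *derivation and classification machinery*, not clinical performance.

## The report

The exported document is a single HTML file with the figure data embedded
as JSON and a small SVG/JavaScript runtime inlined next to it. Writing the
runtime into the document (rather than linking a charting library) makes
self-containment trivial: the file contains no external script, style, font
or image references and renders with networking disabled. Behaviors: hover
tooltips, click-through participant profiles (four analyte series plus the
R-ratio series), a step/play hysteresis animation whose frame *k* shows the
length-*k* path prefix, and per-attribute filter controls. Filtering only
toggles visibility — it never changes a point's coordinates.

Axes are log-scaled by default (fold values span orders of magnitude);
point size, when enabled, is mapped affinely in *rank* of the chosen
measure so extreme values cannot dominate the display, and the mapping is
stated in the legend. Every number shown in a tooltip is string-formatted
(4 significant digits) from the same summary-table column the derived-table
export writes — one source of truth. Output is deterministic: rebuilding
from identical inputs is byte-identical, unless the optional timestamp
header is switched on.

## Verification approach and problem sizes

The test suite checks the derivation logic against brute-force full-scan
oracles (plain loops over raw records) on randomly structured studies of up
to 50 subjects, checks round trips through both CDISC-like dialects,
asserts exact boundary behavior at the thresholds and breakpoints, and runs
the zero-noise identifiability and noisy-recovery checks at 200 and 1000
subjects respectively — sizes chosen to be representative of a mid-size
phase-2/3 safety population while keeping the default suite quick to run.
The noisy-recovery rate at the default settings is computed by the suite
itself and asserted against a frozen regression value; the vignette makes
no empirical claim beyond what those tests compute.

## Known limitations

* P_ALT constants are placeholders pending site-specific calibration; the
  estimate ignores enzyme elimination kinetics.
* No causality scoring (RUCAM), no between-arm inference on quadrant
  proportions, no adjudication logic — the tool triages, it does not judge.
* Units are assumed consistent within (study, analyte); only a heuristic
  warning guards against violations.
* SAS transport ingest is an extension point, not implemented; input is
  delimited text.
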