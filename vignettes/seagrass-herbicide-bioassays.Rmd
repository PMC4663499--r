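---
title: "Concentration-response and mixture analysis for PSII herbicide bioassays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concentration-response and mixture analysis for PSII herbicide bioassays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seagrasstox)
library(dplyr)
```

## The assay and its endpoints

Photosystem II (PSII) herbicides block electron transport at the D1 protein,
so their most sensitive, fastest-responding effect in plants is a drop in the
effective quantum yield of PSII measured by pulse-amplitude-modulation (PAM)
fluorometry. The miniature leaf assay this package models exposes isolated
seagrass leaves (*Halophila ovalis*) in 12-well plates, nine replicate leaves
per concentration, with solvent controls, and reads fluorescence at 24 and
48 h. Two endpoints are computed from raw fluorescence:

* effective quantum yield, light-adapted: $\Delta F / F_m' = (F_m' - F) / F_m'$
* maximum quantum yield, dark-adapted: $F_v / F_m = (F_m - F_0) / F_m$

and the response variable for modelling is percent inhibition relative to the
solvent control, $I = 100\,(Y_c - Y_s)/Y_c$. Three quality-control rules
surround the endpoints:

* **Leaf screening.** Only leaves with $F_v/F_m$ *strictly greater* than 0.65
  enter an assay; exactly 0.65 is rejected. The strict inequality is the
  wording of the screening protocol, and `screen_leaves()` applies it as
  stated.
* **Control drift.** The assay is valid only while the mean control
  $F_v/F_m$ has declined less than 8.5% from the 0 h baseline at every later
  timepoint (`control_drift_qc()`).
* **Control aggregation.** Inhibition is computed against the *mean*
  solvent-control yield of the same plate and timepoint. The protocol states
  only "relative to solvent control"; the mean is chosen because the assay
  reports standard errors of dose means, and it is configurable via
  `control_by` in `plate_endpoints()`. Readings within ±1 h of the nominal
  0/24/48 h timepoints are binned to the nominal value.

Negative inhibition (stimulation above the control) is preserved, never
clipped: truncation at zero would bias the lower asymptote of the logistic
fit.

## The concentration-response model

`fit_4pl()` fits the four-parameter logistic

$$ I(x) = B + \frac{T - B}{1 + (\mathrm{IC}_{50}/x)^{h}} $$

by nonlinear least squares, parameterised internally in
$\lambda = \log_{10}\mathrm{IC}_{50}$ on the log dose scale. This makes the
optimiser's geometry near-quadratic and the delta-method interval symmetric in
log dose, which is how ICx intervals are conventionally reported. Controls
(dose 0) are excluded from the fit — inhibition is already normalised to them,
and zero has no position on a log-dose axis.

Numerical choices that matter:

* **Multi-start.** The optimiser (Levenberg–Marquardt) is started from a
  deterministic 3 × 3 grid: $\lambda$ at the dose grid's midpoint and ±1
  decade, hill slope in {0.5, 1, 2}. The best start by residual sum of squares
  wins; ties break toward the start nearest the grid midpoint, so fits are
  bit-reproducible.
* **Box constraints.** The search is bounded to the region the endpoint and
  design can identify: top in [0, 110] (percent inhibition of a yield cannot
  exceed 100; the margin absorbs noise), bottom in [−50, 50] (admitting
  stimulation), hill in [0.1, 10], and $\lambda$ within the tested dose range
  ±1.5 decades. On well-determined data the optimum is interior and the bounds
  are inactive. They exist because the 4PL has a flat likelihood ridge on
  narrow designs — top and IC50 can grow without bound at essentially
  unchanged SS — and an IC50 decades outside the tested range is not an
  estimate, it is an artefact. Override via the `bounds` argument.
* **Degenerate inputs.** Fewer than five distinct positive doses, or a
  response with zero variance, is a refused fit (classed error), not a
  warning. A response span under 40 points or a non-increasing dose-mean
  profile triggers a warning, since the asymptotes are then poorly determined.
* **Constrained mode.** `constrain = TRUE` pins $B = 0$, $T = 100$, matching
  the common fully-normalised convention; the default leaves all four
  parameters free, as the source assays were fitted.

### ICx and its uncertainty

`invert_icx()` inverts the fitted curve. The default *absolute* mode solves
$I(x) = f$, i.e. $x = \mathrm{IC}_{50}\left((f-B)/(T-f)\right)^{1/h}$; this is
the right definition when ICx values are compared against guideline
concentrations as absolute protection levels. The *relative* mode
($x = \mathrm{IC}_{50}(f/(100-f))^{1/h}$) is provided for comparison with
packages that define ECx as a fraction of the fitted span. A level outside
$(B, T)$ raises a classed "not reached" condition which the pipeline reports
as "> max dose tested".

Confidence intervals come from the delta method on $\log_{10} x$ using the
full parameter covariance (so uncertainty in $B$, $T$ and $h$ propagates into
IC10, not just the IC50's own standard error), back-transformed to dose units.
A nonparametric bootstrap (resampling replicates within dose, seeded,
default 1000 draws) is available via `ci_method = "bootstrap"`.

### Relative potency

ReP = IC50(reference)/IC50(test), with diuron the conventional reference.
`rep_table()` matches the reference IC50 by duration when available; when the
reference was only assayed at 24 h (as here), 48 h rows divide the 24 h
reference value, and the `reference_duration` column records that this
happened. This mirrors how the published 48 h relative potencies were formed.

### Comparing curves

`compare_ic50_ftest()` applies the extra-sum-of-squares F-test. Under the
default `shared_bth` scheme, bottom, top and hill are shared across all curves
in both nested models; the full model gives each curve its own
$\log_{10}\mathrm{IC}_{50}$, the reduced model forces one common value:

$$ F = \frac{(SS_{red} - SS_{full})/(df_{red} - df_{full})}{SS_{full}/df_{full}}. $$

The scheme is configurable (`separate_all` frees all four parameters per
curve) because the degrees of freedom printed in the source comparison could
not be reconstructed from its stated design; the choice is recorded in the
output. Post-hoc pairwise tests are reported uncorrected — matching the
letter-group convention of bioassay tables — with a Holm-adjusted column
alongside.

## Toxic Units and Concentration Addition

For mixtures of same-mode-of-action toxicants, the Concentration Addition
(CA) model predicts that toxicity depends only on the summed Toxic Units

$$ \mathrm{TU}_{sum} = \sum_i \frac{C_i}{\mathrm{IC}_{50,i}}, $$

so a mixture reaches 50% inhibition at $\mathrm{TU}_{sum} = 1$ regardless of
composition. The TU basis is the 24 h IC50 table by default — the basis used
to design the source experiments even though four herbicides act more slowly —
and every output records it. `design_mixture_series()` doses component $i$ at
$C_i = L\,p_i\,\mathrm{IC}_{50,i}$ for TU level $L$, where the proportions
$p_i$ are proportions of *TU contribution*, not of mass; recomputing
`tu_sum()` on any designed row group returns $L$ to machine precision. The
default dilution ladder is the assay design {0, 0.25, 0.5, 0.75, 1, 1.5, 2, 4}.

`classify_additivity()` implements the joint-action decision rule. Sham
reference mixtures (a compound "mixed" with itself, which by Loewe
self-consistency must behave exactly like the single compound on the TU
scale) anchor the additive response. The significance test dominates the
point estimate: the mixture is *additive* unless its IC50 differs
significantly from **every** supplied reference, then *synergistic* if
IC50 < 1 TU and *antagonistic* if > 1 TU. Requiring a consistent difference
against all references mirrors the source study's reading — a mixture that
differed from one sham but not the other was still held additive overall —
and keeps the familywise false-classification rate below the per-test level.
With no references the rule falls back to whether the IC50's confidence
interval contains 1 (flagged `ci_fallback` in the result).

## Guideline screening

`flag_protectiveness()` compares ICx estimates against ecotoxicity threshold
value (ETV) sets: an ETV is protective only when strictly below the ICx;
equality is non-protective. No published cell sits exactly on the boundary,
so the inclusive convention is fixed by documentation rather than by data.
The shipped guideline table uses 48 h IC values for the slow-acting
herbicides (ametryn, metribuzin, prometryn, hexazinone), as its source table
footnotes, and records the published protectiveness pattern verbatim so tests
can verify the reproduction cell by cell.

## The synthetic assay generator

No raw well data were deposited with the source study, so `assay_scenario()`
and the `simulate_*()` functions regenerate data with the study's design and
statistical structure:

* truth curves per herbicide from the shipped IC50 table, with bottom 0,
  top 100 and hill 1 by default;
* nine replicate leaves per concentration; a 7-point geometric dose ladder
  spanning IC50/30 to 30·IC50 plus a solvent control (the single-herbicide
  concentration series was not printed, so a ladder centred on the IC50 is
  used); the TU ladder above for mixtures;
* Gaussian replicate noise of sd 5 inhibition points, homoscedastic by
  default. No numeric replicate SD is printed anywhere in the source, so this
  default is a documented calibration: it reproduces the fitted $R^2$ of
  0.98–0.99 and dose-mean standard errors of ~1.7 points with n = 9,
  consistent with the small published error bars. An optional yield-scale
  noise mode (`noise_model = "yield"`, sd 0.03) induces the heteroscedasticity
  real data show, with clipping of yields to [0, 1] counted and reported;
* a solvent-control yield of 0.70 — a plausible healthy-leaf value above the
  0.65 screening floor, a configuration default rather than a measured one;
* `deviation_factor` scales the effective TU dose in mixture simulations
  (1 = exact CA; 2 means every nominal TU acts as 2 TU, a synergistic truth
  with IC50 at 0.5 TU).

`simulate_raw_plate()` additionally converts yields to raw fluorescence pairs
(arbitrary positive instrument scale) so the fluorometry stage can be
exercised end to end.

What the generator does *not* emulate: uptake kinetics between 12 and 48 h,
plate-position effects (randomised away in the protocol), between-leaf
heterogeneity in control yield, and any real-world deviation from the 4PL
shape. Passing tests therefore demonstrate that the estimators recover known
truths under the study's design and noise level — not that any particular
field sample obeys the model.

## What the tests establish, and at what scale

The simulation-based checks use 200 seeded replicates per condition: IC50
recovery and interval coverage for every herbicide truth in the endpoint
table (median absolute log10 error below 0.05; 95% CI coverage inside
[90%, 99%]), the CA null (mean fitted mixture IC50 within 1 ± 0.05 TU and
pairwise F-tests rejecting at roughly the nominal 5%), and synergy power
(`deviation_factor = 2` classified synergistic in ≥95% of seeds). Noiseless
fits are cross-checked against an independent grid-plus-bisection SS
minimiser that shares no code with `fit_4pl()`. These sizes were chosen to
estimate proportions to a few percent while keeping a full run to a few
minutes on one core.

## Known limitations

* The published IC50s themselves cannot be re-derived — raw well data were
  not deposited — so the shipped endpoint table is data, not a computed
  result, and simulation-based properties stand in for re-estimation.
* The absolute-mode ICx is undefined when the fitted bottom exceeds the
  requested level; on narrow TU designs the fitted bottom is weakly
  determined and IC10 estimates can be reported as not reached.
* Hormesis (stimulation at low dose followed by inhibition) is not modelled;
  stimulation appears only as noise around the bottom asymptote.
* The F-test assumes homoscedastic Gaussian residuals shared across curves;
  strong heteroscedasticity (as under yield-scale noise) makes it
  approximate.

## A worked run

```{r pipeline}
cfg <- pipeline_config(seed = 2026,
                       herbicides = c("diuron", "atrazine", "ametryn"),
                       mixtures = list(c("diuron", "atrazine")),
                       references = list(c("diuron", "diuron"),
                                         c("atrazine", "atrazine")))
res <- run_pipeline(cfg)
res$log
res$rep_table
res$mixture_report |> select(mixture_id, ic50_tu, classification)
```
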