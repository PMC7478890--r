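---
title: "Quantifying drug-drug synergy: dose-equivalent isobolograms and Bliss independence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying drug-drug synergy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isobliss)
```

## The problem

Whether two targeted inhibitors kill cancer cells better *together* than the
sum of their parts is a quantitative question with two classical, and
genuinely different, answers. **Loewe additivity** takes a drug mixed with
itself as the definition of "no interaction": a dose-equivalent mixture of
two similar drugs should behave exactly like either drug alone. **Bliss
independence** instead models the two drugs as independent probabilistic
events acting on the cell population. `isobliss` implements both analyses
end to end — from raw plate-reader luminescence to Combination Indices,
Bliss Indices, and excess-over-Bliss surfaces — together with a
dose-equivalent design generator and a plate simulator with known ground
truth.

The motivating experimental setting is viability screening of lung
adenocarcinoma spheroids treated with combinations of an EGFR tyrosine
kinase inhibitor and inhibitors of proximal RAS-pathway intermediates
(SOS1, SHP2), read out by a luminescent ATP assay. Nothing in the package
is specific to that system: any viability screen producing the long
well-level table described below can be analyzed.

## Data model and normalization

Input is a long CSV, one row per well: `plate_id`, `well`, up to three drug
slots (`drug_a`/`log_dose_a`, ...), a `ratio_label` naming the arm
(`"alone"`, `"untreated"`, a mixture label), `technical_rep`, `experiment`,
and raw `luminescence`. Doses are log10 molar throughout; an absent drug is
an empty cell, never −∞.

`normalize_viability()` divides every well by the **maximum** luminescence
among the untreated wells of its group. Grouping defaults to plate ×
experiment: the untreated reference is a property of one physical plate
read, and sharing it across experiments would leak scale differences
between runs. Whether the reference should instead be pooled per experiment
batch is not determined by the assay description; per-plate is this
package's choice and is configurable via `scope`. Viability is *not*
clipped at this stage — wells noisier than the reference keep viabilities
above 1 so that curve fitting sees undistorted data; clipping to the [0, 1]
effect scale happens only where Bliss arithmetic requires it.

## Dose-response model

All curves are the four-parameter logistic in log10 dose,

$$ v(x) = bottom + \frac{top - bottom}{1 + 10^{\,hill\,(x - \log EC_{50})}} , $$

with `hill > 0` meaning viability falls with dose; the curve passes through
$(\log EC_{50}, (top+bottom)/2)$ exactly. `fit_4pl()` fits all replicate
points jointly (unweighted) by Levenberg–Marquardt with box constraints —
`top` in [0.5, 1.5], `bottom` in [−0.1, 1.0], `hill` in [0.05, 20] — and
five starts for $\log EC_{50}$ spread across the dose range, keeping the
best residual sum of squares. The constraints and multi-start are
robustness measures for 10-point ladders, where a single bad start can park
the EC50 at a boundary. A fit is flagged `converged = FALSE` (never
silently dropped) when every optimizer start fails, when the EC50 lands
more than one log outside the tested range, or when the fitted maximal
effect `top − bottom` is below 0.1 — a near-flat curve has no identifiable
EC50, which is also how an inert drug in a combination design gets flagged
instead of contributing a meaningless Combination Index.

Linear (straight-isobole) isobologram analysis additionally assumes the two
curves are roughly parallel with similar maximal effects.
`parallelism_gate()` operationalizes this with three configurable numeric
gates, checked in order: each drug's maximal effect at least 0.5 (a drug
achieving at most a 50% viability reduction cannot support the analysis),
Hill-slope ratio within [1/2, 2], and maximal-effect gap at most 0.2. The
thresholds are this package's numerical commitments for a qualitative
criterion; `analyze_isobologram()` refuses ungated pairs and points the
user to Bliss analysis, which has no parallelism requirement, unless
`override_gate = TRUE`.

## Dose-equivalent design

`snap_to_grid()` moves a fitted log EC50 to the nearest point of the
1/3-log grid (integer multiples of 1/3, which contains all integer log
doses); ties break toward the lower dose, which keeps more of the curve top
represented. `build_ladder()` lays out 10 points with the anchor 8th from
the bottom (7 below, 2 above). The asymmetric placement ensures both
asymptotes appear on a 10-point ladder when the anchor approximates the
EC50; both counts are arguments for drugs whose curves sit differently.
Internally doses are exact grid multiples and are rendered to two decimals
only on output, so shifting a ladder by one step never accumulates drift.

`two_drug_mixture_plan()` builds the five-ratio mixing table. Fractions
follow the integer-microliter volumes of a 100 μL well — 80/20, 66/34,
50/50, 34/66, 20/80 — rather than exact thirds, because those are the
volumes a pipetting protocol actually delivers. At ladder rank *i* the
mixture delivers `fraction × full ladder dose` of each drug while the
nominal per-drug axes remain the full ladders.

`bliss_band_plan()` generates the three dose-equivalent bands used when a
full checkerboard is too expensive: drug B's ladder held constant, drug A
shifted by one grid step down (1:2), none (1:1), or up (2:1). Bliss designs
deliver **full** doses of both drugs — no volume reduction — because the
independence reference compares against each drug's own full-dose marginal
effect.

## Isobologram analysis and the Combination Index

For each mixture ratio, `analyze_isobologram()` fits one curve per drug's
nominal dose axis and multiplies the fitted EC50 by that drug's volume
fraction — the 4:1 mixture is only 80% drug A, so drug A's apparent EC50
overstates its contribution by 1/0.8. (Fitting on delivered dose instead
is mathematically identical; the nominal-axis-then-correct route is used
because it mirrors how mixture EC50 tables are reported.) The Combination
Index of a ratio is

$$ CI = \frac{EC_{50,A,mix}}{EC_{50,A,alone}} +
        \frac{EC_{50,B,mix}}{EC_{50,B,alone}} , $$

with the numerators fraction-corrected. CI < 0.8 is called synergy,
CI > 1.2 antagonism, the closed band between them additive. The pair
$(EC_{50,A,mix}/EC_{50,A,alone},\; EC_{50,B,mix}/EC_{50,B,alone})$ is one
isobole point; additivity is the line $x + y = 1$. Results report per-ratio
CI plus mean ± sd across ratios, and `by_experiment = TRUE` re-runs the
analysis per experiment to summarize CI variability across independent
experiments.

## Bliss independence

Viability converts to effect as $E = \mathrm{clip}(1 - v, 0, 1)$; the
expected effect of independent drugs is $E_A + E_B - E_A E_B$; the Bliss
Index is expected/observed and the excess over Bliss is
$100\,(observed - expected)$ percentage points. A zero observed effect
makes BI undefined; such cells carry an `NA` sentinel and are excluded from
summaries rather than raising errors. Replicates are averaged to a mean
viability per condition *before* effect conversion — BI is computed on
experiment-averaged effects, not averaged per-experiment BIs; the
alternative ordering is a defensible choice but is not what heatmap
presentations of pooled experiments usually encode. The synergy call
threshold defaults to BI < 0.85, the operational heatmap cutoff; BI < 1 is
nominal synergy and the threshold is an argument.

## Three-drug extension

`three_drug_design()` treats a 1:1 dose-equivalent pair as a single
pseudo-drug and combines the third drug with it at volume triples
33/33/34, 25/25/50, 17/17/66 per 100 μL (labels `(1+1):1`, `(1+1):2`,
`(1+1):4`). The pseudo-drug has no molar concentration of its own; its dose
axis is the nominal ladder of its first component, reported alongside both
component doses — any consistent axis cancels in the CI ratios.
`analyze_three_drug()` reports two CI families per mix: the CI of the third
drug against the pair (denominators: the 50:50 pair's EC50 on its axis and
the third drug's alone EC50) and the independent three-way CI. For the
independent CI all three denominators default to single-agent alone EC50s,
the reading consistent with treating each drug independently; a variant
using the 50:50 pair EC50 as the first denominator is available via
`independent_denominator = "pair_5050"`.

## The simulator and what passing tests mean

`simulate_single_agent()` and `simulate_combination()` generate plate
tables from known truth: 96-well plates using only the inner 60 wells
(outer wells are buffer in practice), untreated wells on every plate,
3 technical replicates within a plate and 3 independent experiments by
default, and luminescence
`untreated_mean × experiment_scale × true_viability × noise`.

* **Noise** is multiplicative lognormal with mean 1, parameterized by its
  CV (default 0.10): luminescence is positive and heteroscedastic, which a
  lognormal captures and additive Gaussian noise does not. A per-experiment
  lognormal scale factor (CV 0.05) emulates day-to-day assay drift.
* **Reference surfaces.** Bliss: survival fractions multiply,
  $v = \prod_i (1 - E_i)$ (inclusion–exclusion; the three-drug form is the
  standard extension, as isobolograms rather than Bliss are usually used
  for triples). Loewe: $v$ solves $\sum_i d_i / D_i(v) = 1$ with $D_i(v)$
  the iso-effective single-agent dose, found by bisection on $v$ to an
  interval tolerance of 1e−10; combinations whose effect falls outside the
  joint single-agent range take the nearer boundary viability with a
  warning.
* **Synergy injection** multiplies delivered doses by `1 + synergy_alpha`
  before surface evaluation, only in wells containing ≥ 2 drugs — the
  single-agent marginals the analyses compare against must stay at truth
  for the injected interaction to be purely a combination effect. An
  optional per-drug log-dose window restricts the boost to a dose region,
  giving a ground-truth synergy mask for detection tests. Dose potentiation
  is one of many possible synergy mechanisms; it was chosen because it is
  monotone and shifts CI and BI in the correct direction
  (a global boost by $1+\alpha$ moves the DEQ mixture CI to
  $1/(1+\alpha)$).

Everything is reproducible bit-for-bit from the configuration and seed.

Passing the simulator-based suites shows the estimators are *correct* —
they recover the generating model's additivity or injected synergy — not
that real spheroid data satisfy the model: real plates have edge effects,
spatial gradients, non-lognormal outliers, and drifting untreated
references that the generator deliberately omits.

## Numerical choices and degenerate inputs

* Problem sizes in the test suite: 10-point ladders, the full 10 × 10
  checkerboard, 500-replicate EC50-recovery simulations at 10% CV with 3
  technical replicates — the scale at which a single screening campaign
  operates.
* Fits on noiseless model data recover parameters to ≥ 6 significant
  digits; noiseless Loewe surfaces give CI within [0.95, 1.05] after
  round-tripping through fitting, and noiseless Bliss checkerboards give
  BI = 1 to 1e−9.
* Equidistant snap candidates go to the lower dose; CI class boundaries
  belong to the additive band; BI at zero observed effect is `NA`;
  untreated wells never carry doses; a group without untreated wells is an
  error naming the group.
* The Bliss-vs-Loewe relationship depends on curve steepness: for Hill
  slope 1 a dose-additive pair under-performs the Bliss expectation
  (BI > 1), while steep curves (hill ≈ 2) beat it below the EC50 (BI < 1).
  The cross-model test uses steep curves for that reason.

## Known limitations

* No Chou–Talalay median-effect Fa–CI curves, no curved isoboles for
  non-constant potency ratios, and no ZIP/HSA alternative scores.
* Mixture and single-agent curves are fit independently; no sharing of
  `top`/`bottom` across arms.
* No bootstrap confidence intervals on EC50s or CIs; uncertainty is
  summarized only as spread across ratios/experiments.
* The simulator models neither well-position geometry nor
  drug-penetration effects of 3D culture; it emulates the *statistical*
  structure of the assay, not its biology.
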