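---
title: "Converting carbon-ion rectum constraints across fractionations and RBE models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Converting carbon-ion rectum constraints across fractionations and RBE models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cirtconvert)
```

## The problem

Carbon-ion radiotherapy (CIRT) centres report RBE-weighted dose with
different radiobiological models: Japanese centres (NIRS) use the
microdosimetric kinetic model (MKM), while European centres (CNAO and
others) use the local effect model (LEM). The *same physical plan* yields
different Gy (RBE) numbers under the two models, so organ-at-risk
constraints published by one centre cannot be applied directly at
another. Independently, moving from a 16-fraction protocol to
hypofractionated 12-, 8- or 4-fraction protocols changes the biologically
tolerable total dose, which is conventionally handled with the
linear-quadratic (LQ) iso-effect model.

`cirtconvert` implements both conversions and the two orders in which
they can be composed, plus the dose-volume-histogram (DVH) machinery
needed to check patient plans against the resulting constraints.

## The two models

**LQ iso-effect.** Two schemes, `N1` fractions of `d1` Gy and `N2`
fractions of `d2` Gy, are iso-effective when their biologically effective
doses (BED) agree:

    N2 * d2 * (1 + d2/(a/b)) = N1 * d1 * (1 + d1/(a/b))

`isoeffect_dose()` solves this in closed form through the positive root
of the quadratic in `d2`; no iteration is involved, so results are exact
to machine precision and `bed()` is conserved to better than 1e-9
relative (a tested invariant). The default `alpha_beta` is 3.9 Gy, the
value used for rectum in the hypofractionated prostate CIRT literature;
it is an explicit argument everywhere because the engine itself is
organ-agnostic.

**RBE conversion.** The MKM-to-LEM dose mapping is an empirical, plan-
derived, strictly monotone curve. Treatment-planning-system generation of
that curve is out of scope here; `conversion_curve()` represents it as a
set of paired dose anchors with a shape-preserving interpolant, and the
package ships the anchors that are public for the 16-fraction rectum
curve: four forward pairs (28.80→43.14, 46.40→58.48, 56.00→65.11,
60.80→68.33 Gy (RBE)) merged with the three backward pairs from the CNAO
absolute-volume constraint adaptation (39.99→54.00, 49.84→61.00,
57.31→66.00). The seven pairs are jointly strictly monotone and form the
packaged `cirt_fixture_curve("16fx")`.

## The two strategy orderings

Starting from MKM constraints at 16 fractions:

* **MKM LQ** (`convert_mkm_lq()`): LQ conversion first, in MKM dose
  space, then MKM→LEM with the *target* scheme's curve.
* **LEM LQ** (`convert_lem_lq()`): MKM→LEM first with the 16-fraction
  curve, then LQ conversion in LEM dose space.

For LEM-native sources such as the CNAO absolute-volume set,
`convert_lem_source()` either applies LQ directly (LEM LQ) or first
inverts the 16-fraction curve, converts in MKM space, and re-converts
forward (MKM LQ). The two orderings do not commute because the
conversion factor between the models depends on dose per fraction; with
the packaged fixtures LEM LQ is systematically the higher (more
permissive) limit and the gap widens as the fraction number drops — a
tested invariant.

```{r}
tab <- build_constraint_table(cirt_fixture_constraints("cnao-16fx"),
                              schemes = c(12, 8, 4))
round(as.data.frame(tab)[, -(1:2)], 2)
```

## Interpolation and inversion choices

* **Monotone cubic by default.** The underlying curve is smooth and
  convex-ish in the published range; straight lines between the sparse
  forward anchors provably miss the published backward pairs (linear
  interpolation puts LEM 54.00 Gy (RBE) at MKM ≈ 41.26, far from the
  published 39.99). `stats::splinefun(method = "monoH.FC")`
  (Fritsch–Carlson) is anchor-exact, monotone for monotone data, and
  degrades gracefully to a straight line with only two anchors.
  `"piecewise-linear"` remains available by configuration.
* **Inverse by root finding.** `lem_to_mkm()` brackets the answer
  between anchors and calls `stats::uniroot()` at 1e-12 dose tolerance;
  doses exactly equal to an anchor value are snapped to the anchor so
  anchor-exactness holds at 1e-9 in both directions. Forward/inverse
  round trips are tested below 1e-6 across the domain.
* **Extrapolation.** Constraints near the prescription dose can sit
  slightly above the highest anchor, so the default policy extends the
  end chord linearly for up to 10 % of the anchor range with a warning;
  beyond that, and always under `extrapolation = "error"`, evaluation
  fails loudly.
* **Rounding.** All chains are computed at full floating precision;
  half-up rounding to 2 decimals (`round_half_up()`) happens only at
  render time, matching how published tables print doses. Golden tests
  compare at ±0.02 Gy (RBE) because the published inputs are themselves
  2-decimal roundings.

## Reconstructed hypofractionated curves

The 12-, 8- and 4-fraction conversion curves were generated per-protocol
in a planning system and are not published. The packaged
`cirt_fixture_curve("12fx-reconstructed")` (and 8/4-fx analogues) pair
LQ-converted MKM anchor doses with the published MKM-LQ-strategy outputs,
so they reproduce those outputs anchor-exactly *by construction*. They
are labelled synthetic, used for demonstrations and for the
property-based checks of the MKM LQ pipeline (ordering and widening gap),
and are never treated as evidence about the true unpublished curve
shapes. A plausibility generator, `generate_conversion_curve()`, encodes
the one robust published feature: the LEM/MKM ratio decays with dose
(≈1.50 at 28.8 Gy (RBE) down to ≈1.12 at 60.8 Gy (RBE) at 16 fractions).

## DVH conventions

Cumulative DVHs are (dose, relative volume) tables: the fraction of the
structure receiving at least each dose. `dose_at_relative_volume()` uses
linear interpolation and resolves flat segments to the *left-most*
crossing — the lowest dose achieving the volume level — which is the
conservative reading for organ-at-risk limits. `D0%` is implemented as
the v→0 crossing, i.e. the maximum dose received by any part of the
structure (if the curve never reaches the level, the highest recorded
dose is returned). Absolute-volume metrics are the ratio identity
`D_xcc = D_(x/V)%`; a requested volume exceeding the structure volume
makes the constraint vacuous and is reported as *not evaluable*, never as
a silent pass. Differential DVHs are rejected at read time with a hint
to convert upstream, keeping one unambiguous dialect.

## What the synthetic data emulates — and what it does not

`generate_dvh()` produces sigmoid (logistic) cumulative curves on a
0.1 Gy grid — the generic serial-organ rectal DVH shape — with optional
Gaussian volume noise repaired by isotonic regression.
`generate_dvh_with_metrics()` builds piecewise-linear curves through
prescribed (dose, volume) points so that requested `D_x%`/`D_xcc` values
are reproduced exactly (the grid is augmented with the exact control
doses). `generate_cohort()` composes these into cohorts with exactly
controlled exceedance counts: exceeder sets are nested head-sets, so
"8 of 38 over D20%, 4 of those over D10%" is a single count vector.
Volumes default to the published cohort range 34.59–75.29 cc; exceeding
metrics sit U(0, 2] Gy above the limit ("slight" exceedance), passing
metrics U(0.5, 5) Gy below. Where the literature gives only medians and
maxima, the dispersion choices here are free parameters chosen once.

A green cohort test therefore establishes that the *pipeline* recovers
construction truth exactly — not that real rectal DVHs look like these
curves. Real DVHs have plateaus, multimodal gradients and inter-patient
correlation that the generator does not attempt; per-patient published
data would be needed to calibrate that realism.

Seeding: patient `i` uses the derived stream `seed + i`, so enlarging a
cohort never reshuffles previously generated patients, and every
generator is bit-reproducible for a fixed seed.

## Degenerate inputs and numerical edges

* 0 Gy converts to 0 Gy under any scheme (forced by BED = 0).
* `n_from == n_to` returns the input dose bit-exactly.
* As `alpha_beta → ∞` the LQ conversion degenerates to equal total dose;
  tested at 1e9 Gy within 1e-4.
* Curve anchors are validated for joint strict monotonicity with the
  offending pair reported; identical schemes plus an identity curve give
  identity conversions.

## Known limitations

* The true 12/8/4-fraction conversion curves, and hence the MKM LQ
  cells, cannot be independently recomputed from public information;
  only the LEM LQ chain is fully reproducible at desk scale.
* The 10- vs 30-patient conversion-model uncertainty analysis requires
  patient plans and is out of scope.
* One published difference-percentage cell (4-fraction D1cc) cannot be
  reproduced within ±0.02 pp from the printed dose pairs alone — the
  printed value evidently derives from unrounded chains; the
  corresponding acceptance check is deliberately left failing rather
  than widened.
* No DICOM-RT parsing, no NTCP/toxicity modelling, no time-factor or
  LQ-L high-dose corrections.
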