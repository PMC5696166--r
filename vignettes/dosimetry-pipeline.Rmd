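---
title: "From biodistribution tables to absorbed doses: the mirdose pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From biodistribution tables to absorbed doses: the mirdose pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirdose)
```

## The problem

Before a radiolabeled antibody can move toward the clinic, two dosimetric
questions have to be answered from small-animal data: what absorbed dose
would a standard human receive per unit administered activity, organ by
organ, and what absorbed dose does the tumor itself receive from a
therapeutic administration. `mirdose` implements that chain for ex-vivo
biodistribution studies of the kind produced by gamma counting of dissected
tissues: per-organ, per-animal percent injected dose per gram (%ID/g) at a
handful of timepoints, for a diagnostic/therapeutic pair such as a
Cu-64-labeled imaging surrogate and a Lu-177-labeled therapeutic.

The stages are:

1. **Quantification** — %ID/g from counts and a counting standard,
   target-to-background ratios, blocking statistics, SUV, caliper tumor
   volume.
2. **Kinetics** — mono-exponential fits to organ mean time-activity curves,
   integrated into cumulated activities and residence times.
3. **Human extrapolation** — mouse %ID/g to human organ-total %ID by
   relative organ mass, then the same kinetic integration.
4. **MIRD organ doses** — residence times times S values; by default a
   self-dose (local electron deposition) engine, optionally a full
   user-supplied S-value matrix.
5. **Sphere tumor dose** — cumulated tumor activity converted by a
   unit-density sphere dose factor interpolated log-log in sphere mass.
6. **Synthetic studies** — a generator with per-animal log-normal noise and
   closed-form ground truth, so the whole chain is testable without animal
   data.

## Data model and conventions

Stored %ID/g values are **decay-corrected to injection time**, which is how
gamma-counter output is normally expressed; a study-level flag records this,
and every integration step reintroduces physical decay explicitly as
`exp(-lambda_phys * t)`. Keeping biological retention and physical decay
separate makes the decay handling auditable and lets one nuclide's
biodistribution be re-used for a dosimetric what-if with another physical
half-life.

Time is internally hours (files may declare hours or days). Summary tables
use the sample (n−1) SD, and display rounding is one decimal, half-up —
matching how biodistribution tables are conventionally printed.

Target-to-background ratios are reported both as the **mean of per-animal
ratios** (the default display, correct when each animal contributes both
tissues) and the **ratio of group means** (the only statistic computable
from a published mean table). Published tables do not always state which
convention they used, so both are carried and the choice is explicit in
every output.

## Kinetic fitting and integration

The default fit is ordinary least squares on log-transformed means — the
classic linearization, chosen because it is exactly reproducible and has no
starting-value sensitivity; a natural-scale Levenberg–Marquardt fit is
available by flag (`method = "nls"`). Curves are fitted on group means, not
per-animal curves, matching standard practice for dosimetry from serial
sacrifice designs (each animal contributes one timepoint, so per-animal
curves do not exist).

A single falling exponential cannot represent an organ that is still
accumulating — an antibody-avid tumor peaking a week after injection being
the canonical case. The pipeline therefore uses two integration schemes:

* **monoexp**: closed form `(a0/100)/lambda_eff`, used when the fitted
  biological rate is non-negative;
* **hybrid**: trapezoid integration of the decay-inclusive observed curve
  (starting from an empty tissue at injection; blood is instead
  back-extrapolated to its `t = 0` intercept, since tissues fill *from*
  blood), plus an analytic tail from the last timepoint.

The default tail assumes **physical decay only** — no further biological
clearance of whatever is still bound at the last sample. That is the
conservative (dose-overestimating) choice for a residualizing radiometal
antibody conjugate. The alternative `tail = "fitted"` uses the terminal
slope, floored at the physical rate. With `scheme = "auto"` the pipeline
picks hybrid exactly when the fitted biological rate is negative, and
records which scheme each organ received; when the experimenter *knows* a
curve is uptake-washout, `scheme = "hybrid"` should be forced, because a
long sampling window past the peak can hand the mono-exponential a net
negative slope and hide the accumulation phase.

When fitted rates are clamped (accumulating organs), the raw value is kept
in the fit diagnostics; the clamped effective rate can never fall below the
physical decay constant, so no residence time can exceed the
all-decays-in-place bound `T1/2 / ln 2`.

## Human extrapolation

The relative-organ-mass ("percent-kg/g") method scales each mouse
concentration to a human organ total:

`%ID_human(organ) = %IDg_mouse × BW_mouse(kg) × m_organ,human(g) / BW_human(kg)`

applied timepoint-wise, so human curves flow through the identical fitting
path. A `method = "direct"` flag (mouse organ %ID carried over unscaled)
exists for sensitivity analysis. The packaged phantom is a nominal 70-kg
adult with organ masses from the hermaphroditic adult mathematical phantom
used by organ-level dose codes; any user phantom file substitutes. The
default mouse body mass is 0.020 kg — typical for the 6-week athymic mice
used in xenograft work — and is overridable, since biodistribution reports
frequently omit it.

Remainder-of-body: the total-body residence bound minus the organ sum,
floored at zero. If the study has no whole-body retention curve, the
physical-decay bound `T1/2 / ln 2` is used (every injected atom decays
somewhere) with a logged warning; this overestimates the remainder when
excretion is substantial, and a whole-body curve should be supplied
whenever available.

## Dose engines

The default engine is **self-dose only**: each organ receives its own
non-penetrating (electron/beta) emissions, `S_self = Delta_np / m`, with
1 MBq·h = 3.6e9 decays. For a low-energy beta emitter like Lu-177
(mean electron energy ≈ 147.9 keV per decay, sub-millimetre range) this is
the dominant term; the photon cross-dose it omits is flagged in every
report header. Supplying an S-value file (`target, source, s_mGy_per_MBq_h`)
switches to full matrix dosimetry — phantom S-value tables are internal to
the established dose codes and are deliberately not redistributed with this
package. Consequently organ-level results from the self-dose engine anchor
*structure, units, linearity and ranking*, not agreement with a specific
dose code's output. Dose tables carry both mGy/MBq and rad/mCi
(= 3.7 × mGy/MBq) columns.

The tumor dose uses the **unit-density sphere model**: a grid of dose
factors over sphere masses (supported range 0.01–6000 g), interpolated by a
straight-line least-squares fit in (log mass, log factor) over the `k = 4`
nearest nodes. A *local* window rather than one global fit preserves
exactness on any power-law grid — which the default electron-only grid is
(`∝ 1/m`) — while still honouring the stated log-log least-squares method
if a user grid bends away from a power law at small masses. The default
electron absorbed fraction is `phi = 1` (complete local absorption,
photons escape), appropriate for Lu-177 betas in spheres of 0.1 g and
above; a user-supplied `phi(m)` curve hooks in for smaller spheres. With
`phi = 1` the computed dose is independent of the assumed sphere mass
(per-gram cumulated activity × mass × 1/mass cancels) — a model property,
asserted in the tests, that makes the result robust to the large
uncertainty typical of excised tumor masses.

## The synthetic generator

Synthetic studies exist so that every stage has a ground truth. Organ mean
curves are sums of exponentials: single washout, uptake-washout
`A(e^{-λ_out t} − e^{-λ_in t})`, or a general two-term mixture. The general
form is needed because real antibody curves have shapes the two named
special cases cannot reach — blood clears with a fast distribution phase
*and* a slow elimination phase, and a slowly accumulating tumor can be
non-zero within hours of injection while still peaking a week later. Noise
is multiplicative log-normal per sample with mean 1 (biodistribution data
are positive and right-skewed); `cv = 0` gives noiseless studies whose
pipeline results must match the closed-form `TruthRecord` integrals.
Generation is deterministic for a fixed seed: organs are processed in
sorted name order with a fixed draw order, and the blocking arm (which
scales the target organ's curve by a known multiplier) offsets the seed.

Two presets emulate the kinetic structure of an EGFR-targeted antibody in a
head-and-neck xenograft: `"cu64-paperlike"` (72-h horizon, tumor peaking
near 48 h at ~10 %ID/g, liver the highest normal organ) and
`"lu177-paperlike"` (14-d horizon, tumor plateauing around day 7 at ~19
%ID/g, spleen > lungs > liver held at every timepoint). Their mean-curve
parameters were fixed once against published group-mean tables for this
tracer class (each preset mean lies within 2 SD of the corresponding
printed cell), and the default animal CV of 0.15 was chosen once from the
printed SD-to-mean ratios (typically 0.1–0.3). What the generator does
*not* emulate: inter-animal correlation (each sample is independent),
weight-dependent kinetics, excretion routes, and assay-level artifacts such
as counting background — so passing recovery tests demonstrates the
estimator chain is correct, not that it is robust to every pathology of
real data.

## Numerical choices and degenerate inputs

* Non-positive curve values are excluded from log-domain fits with a
  warning; fewer than two positive points is a fit error.
* A fitted biological rate below zero is clamped to zero for integration;
  the raw value stays in diagnostics.
* Trapezoid integration assumes zero activity at injection for tissues and
  a back-extrapolated intercept for blood; the tail is analytic, so an
  all-zero curve integrates to exactly zero.
* Interpolation outside the sphere grid range is an error unless
  explicitly allowed.
* Negative specific binding in the cell-binding formula is reported as-is
  with a warning, never clamped — assay problems should stay visible.
* Duplicate (organ, animal, time) rows, missing schema columns and empty
  files are schema errors that name the offending row.

Problem sizes used in the shipped validation: parameter recovery runs 500
replicate single-organ studies (6 timepoints, n = 4, 10% CV); end-to-end
recovery uses a noiseless 4-organ study sampled every 6 h out to 50 days so
that trapezoid discretization, the only remaining error source, stays
below 0.5%.

## Worked example

```{r example, eval = FALSE}
study <- read_study(system.file("extdata",
                                "biodist_lu177_snu1066_means.tsv",
                                package = "mirdose"))
summarize_study(study)$peaks
#       organ time_h mean
#       blood      2 29.0
#      muscle     24  2.2
#       tumor    168 20.6

tumor <- organ_tac(study, "tumor")
tumor_absorbed_dose(tumor, injected = 12.95, tumor_mass_g = 0.15)
# <tumor_dose_result> lu177: 42.48 Gy for 12.95 MBq in a 0.15 g sphere
#   cumulated activity 74.7 MBq.h, dose factor 568.6 mGy/(MBq.h),
#   scheme hybrid (tail: physical)
```

The 42 Gy figure is the electrons-only, physical-tail estimate from the
printed group means; published sphere-model numbers for the same kind of
data can sit tens of percent higher because dose-code sphere factors
include photon self-dose and because the fit and tail conventions behind a
published number are rarely stated. Either way the conclusion such an
analysis supports — a tumor dose well above the tens-of-Gy threshold
associated with solid-tumor responses, delivered from a single
administration — is insensitive to that spread.

## Known limitations

* Self-dose engine only, unless the user supplies S values: no photon
  cross-organ dose, no marrow or bone sub-region modelling.
* Mono-exponential or trapezoid-plus-tail kinetics only: no compartmental
  or population PK modelling.
* The sphere model assumes unit density and complete electron absorption
  by default; sub-0.1-g spheres need a user absorbed-fraction curve.
* Extrapolation assumes mouse and human kinetics are equivalent after mass
  scaling — the standard, and strong, assumption of this study design.
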