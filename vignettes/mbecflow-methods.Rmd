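---
title: "Methods: quantifying phagocytosis and phagolysosomal oxidation with MBEC"
author: "mbecflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying phagocytosis and phagolysosomal oxidation with MBEC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbecflow)
```

## The measurement problem

Methylene blue–labeled, UV-killed *E. coli* (MBEC) turn a single
injected or cocultured particle into two readouts of phagocyte
function. First, because methylene blue (MB) is red-excited and
red-emitting, the MB a phagocyte accumulates is a flow-cytometric
measure of bacterial phagocytosis. Second, the oxidizing environment of
the maturing phagolysosome shifts MB emission toward the far red, so
the *shape* of the emission — not its brightness — reports
phagolysosomal oxidation, the NADPH-oxidase-dependent step that chronic
granulomatous disease (CGD) abolishes. This package implements the
analysis chain for both readouts and a synthetic data generator that
emulates the two experimental settings: ex vivo leukocyte–MBEC
cocultures, and in vivo intradermal injection sampled by paired venous
blood and dermal suction blisters.

## Two-state spectral model

MB emission inside cells is modeled as a convex mixture of two fixed
bases on a common 650–820 nm grid (1 nm steps):

$$S(\lambda;\rho) = (1-\rho)\,R(\lambda) + \rho\,O(\lambda), \qquad
\rho \in [0,1],$$

with $R$ peaking at the 696 nm primary emission peak (reduced,
unoxidized MB) and $O$ at the 760 nm shoulder (the oxidation-shifted
state). $\rho$ — the *oxidized fraction* — is this package's name for
the latent state behind the observed red shift; whether the shoulder
reflects a distinct chemical species or an environmental effect is not
resolved here, and the mixture is an operational model only.

Published spectra constrain only the two modal wavelengths and the
qualitative shape, so the bases are unimodal log-normal-shaped curves
in wavelength with modes pinned at 696 and 760 nm. The width parameters
(log-scale 0.35 for the reduced basis, 0.55 for the oxidized, about a
600 nm offset) were calibrated once so that **each basis puts at least
5% of its mass into each detector band** — this keeps all three
channels informative and makes the red-shift ratio strictly monotone in
$\rho$, which the test suite verifies on a 101-point grid. Both bases
are stored sum-normalized. The same two-state construction applied to
absorbance (reduced peak at MB's 665 nm absorbance maximum) represents
the peroxide-driven absorbance change; the hydrogen-peroxide link is a
saturating Hill-type curve (`peroxideOxidizedFraction()`, coefficient
1) of which only the direction is asserted — the dose–response was
never quantified.

Detector channels are band-pass windows rendered as trapezoidal
integrals times a multiplicative gain: AF647 (655–685 nm), AF700
(705–750 nm), APC-Cy7 (750–810 nm). Detector voltages are modeled as
pure gains; absolute voltage settings are metadata. Compensation is
deliberately out of scope: simulated data are spillover-free and no
`$SPILLOVER` keyword is written.

## The bespoke statistics

**Sum normalization.** Each point of an emission curve is divided by
the sum of all points, removing brightness differences between
conditions so spectra can be compared side by side. All unmixing
operates on sum-normalized spectra.

**Merged virtual MB channel.** The per-event *sum* of the three MB
channel intensities on the linear scale. The merging operation in the
original software is not algorithmically specified; summation is chosen
because it maximizes gathered light (the stated motivation for
merging) and gives the testable dominance property that the merged
value, and hence its geometric MFI, is at least each component's.

**Geometric MFI.** `exp(mean(log(pmax(v, 1))))`. The 1 a.u. floor
handles nonpositive values after background subtraction; whether the
original gating software excluded nonpositive events is unknown, so the
floor convention is documented and fixed. Events at the floor trigger a
warning, never silence.

**Red-shift ratio.** The APC-Cy7 : AF647 geometric-MFI ratio. The
noise-free closed form `predictRedshiftRatio()` is the ratio of the
mixture's band integrals and is strictly increasing in $\rho$; the
event-level `redshiftRatio()` must agree with it to 1e-6 for noise-free
rendered events, which is the end-to-end oracle in the tests. At the
**pipeline** level (per-sample summary rows) the ratio is additionally
*background-corrected*: each channel's MFI has the matched
fluorescence-minus-one control's MFI subtracted before the ratio is
formed. Additive autofluorescence loads the near-red channel
disproportionately when MB signal is low, which otherwise produces a
spurious upward ratio drift of 1–2% over a time series as the MB load
grows — enough to mimic a small oxidation signal. Background-corrected
(delta-MFI) ratios remove this artifact; the correction is undefined
(reported `NA`) until the MB signal clears the background.

**FMO gating.** The MB-low/MB-high cutoff is a percentile (default
99.5, configurable) of the control population's merged-channel values,
where the control saw only unlabeled *E. coli*. Controls under 200
events are rejected as unstable. Applying a gate back to its own
control leaves at most the complementary percentile MB-high, up to
binomial noise.

**Spectral unmixing.** Because both bases are sum-normalized, the
mixture is linear in $\rho$ and constrained least squares on the
normalized observed spectrum has the closed form
$\hat\rho = \mathrm{clamp}\!\left(\langle y - R,\, O - R\rangle /
\lVert O - R\rVert^2,\ 0,\ 1\right)$, with the residual norm reported.
Identical bases are rejected as unidentifiable. For binned
spectral-cytometry data the same solution is applied in bin space
(bases integrated over the same bins), avoiding interpolation bias. In
the pipeline, the population-mean binned spectrum has the matched
control's mean spectrum subtracted first (the autofluorescence
baseline), then is normalized and unmixed. Per-condition curves are
averaged *before* normalization — the mean spectrum of the gated
population is normalized, rather than normalizing per event — because
late blister samples hold only around a thousand cells and per-event
normalization would be dominated by dim-event noise.

## Synthetic data generator

The generator is a forward model of the assay, one cell at a time:

1. **Ingestion.** Counts are Poisson with mean
   $\lambda = \text{phagocytic rate} \times \text{MOI} \times f(t)$.
   For a coculture (single bacterial bolus at time zero) $f$ is the
   saturating transform $t/(t + 0.5\,\mathrm{h})$, reflecting sublinear
   uptake within the first hour; the exact kinetics are unpublished and
   the per-cell count distribution is an assumption. For blister
   neutrophils, cells arrive uniformly over the sampling interval and
   *encounter bacteria continuously*, so $f$ is linear in each cell's
   dwell time. The linear in-tissue form is deliberate: with uniform
   arrival it makes the total MB fluorescence intensity
   (MFI × MB-high count) rise through 24 h even though blister
   cellularity peaks at 9 h and falls to about a thousand cells by
   24 h — the clearance picture the in vivo data show — which no single
   saturating-bolus formula reproduces. Cytochalasin B multiplies
   $\lambda$ by 0.02; blood cells have no MBEC contact at all.
   Phagocytic rates are ordered neutrophil (2.0 /h/MOI) > macrophage
   (1.0) > monocyte (0.4) ≫ eosinophil (0.05) > T/B/NK (0).
2. **Oxidation.** Each cell's MB approaches full oxidation at first
   order, $\rho = 1 - e^{-k_{ox}\,\tau}$, over its phagolysosomal
   residence $\tau$ (ingestion uniform over the exposure window; only
   the marginal $\rho$ distribution matters downstream). Healthy
   neutrophil $k_{ox} = 0.8$/h; CGD-affected cells have $k_{ox} = 0$
   exactly; carriers split deterministically 50/50 (lyonization),
   keeping the intermediate phenotype sharp.
3. **Rendering.** Channel value = MB load × mixture band mass +
   autofluorescence, all times mean-one multiplicative log-normal noise
   (CV 25%, standard cytometer behavior). MB load is 300 a.u. per
   ingested bacterium at 1% labeling — placing a single bacterium an
   order of magnitude above red-channel autofluorescence, as observed
   for MBEC — scaled linearly by labeling concentration (1%, 0.5%,
   0.3%; linearity is an assumption) and reduced tenfold by membrane
   permeabilization. Spectral mode renders 5 nm wavelength bins
   (`MB_<lo>_<hi>nm`) instead of the three band channels.
4. **Markers and scatter.** Log-normal FSC/SSC place granulocytes
   SSC-high/FSC-high; Siglec8 flags eosinophils for exclusion. Surface
   markers shift with bacterial *contact* (CD11b/CD45/CD66b up, CD62L
   shed) identically for MBEC and unlabeled bacteria — the MB label
   itself never moves a marker — and are modulated per ingested
   bacterium (receptor internalization), with the same coefficients ex
   vivo and in vivo. That shared latent is what makes the MB–marker
   correlation structure agree between contexts, and it is asserted as
   a sign-agreement score, not as effect sizes. Blister cells carry a
   primed profile (CD66b/CD11b/CD45 up, CD62L down) whose magnitudes
   are free parameters with documented defaults.

**Packaged designs.** `exvivo` (0–60 min coculture series at MOI 10
plus an unlabeled FMO control), `moi` (titration at 1/3/10/30),
`cgd` (isolated neutrophils, 15–180 min, healthy/carrier/affected,
10,000 events per tube — the standard acquisition target that keeps
per-sample MFI-ratio noise well under a percent), and `invivo`:
19 volunteers contributing paired 3+5 h, 7+9 h, or two 24 h blisters
(38 blister points, 7–8 per time point), paired blood, one
unlabeled-coculture FMO control per volunteer, and a deterministic
exponentially clearing endotoxin column. Blister neutrophil counts
follow the observed cellularity (peak at 9 h, ~1,000 cells at 24 h);
two same-day blisters from one volunteer are distinguished by a site
annotation, which is also the key that duplicate detection in
`timecourse()` respects. Everything is seeded: per-sample seeds derive
deterministically from the study seed, and identical seeds give
byte-identical metadata and ground-truth tables.

**What the generator does not emulate.** Spillover between
fluorophores, doublets, time drift, dead cells and viability dyes,
spatial structure of the dermis, and real inter-donor variability.
Passing tests therefore demonstrate that the analysis chain measures
what the forward model encodes — monotone uptake, oxidation kinetics,
genotype contrasts, compartment differences — not that it is robust to
every instrument artifact of real acquisitions.

## File formats

Samples are written as FCS 3.1 (list mode, 32-bit little-endian
floats, no spillover keyword) with a minimal in-package reader and
writer; a tab-separated fallback (`writeEventsTSV()`/`readEvents()`)
is numerically equivalent up to single-precision rounding. Ground
truth (population, bacteria count, $\rho$, exposure) is exported only
to `truth.tsv`, never into FCS. Spectra serialize as two-column
delimited text.

## Numerical choices and degenerate inputs

- Peak finding breaks ties toward the shortest wavelength; flat
  spectra warn and return the grid start.
- All-zero spectra cannot be normalized or unmixed (explicit errors).
- Band windows that miss the grid integrate to zero with a warning;
  a zero AF647 integral makes the red-shift ratio undefined (error).
- The geometric-MFI floor is 1 a.u.; empty inputs error, all-floor
  inputs warn and return the floor.
- Negative intensities entering the merged channel are clipped to zero
  with a message reporting the count.
- `unmixOxidizedFraction()` resamples off-grid spectra by linear
  interpolation; binned pipeline data are unmixed in bin space
  instead.

## Problem sizes

Default studies run in seconds: the ex vivo design renders ~22,000
events across 6 samples, the in vivo design ~200,000 events across 76
samples, and the CGD design 150,000 events across 15 tubes. The test
suite and the acceptance script regenerate all of these from scratch
at fixed seeds.

## Known limitations

- The two-state mixture is operational; a continuum of oxidation
  states, pH effects, and MB photochemistry are not modeled.
- The Poisson ingestion law and the linear labeling-concentration
  scaling are assumptions flagged above.
- Population calls are scatter/Siglec8 rule-based, matched to the
  simulator's geometry; real panels would gate on the full marker set.
- Descriptive summaries only: hypothesis testing and multiple-testing
  procedures are intentionally out of scope, as are UMAP/heatmap
  workflows (gated tables are exported for external tools).
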