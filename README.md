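# mbecflow

Flow-cytometry analysis of bacterial phagocytosis and phagolysosomal
oxidation measured with methylene blue–labeled, UV-killed *Escherichia
coli* (MBEC).

MBEC is a dual-readout particle for human phagocyte function: the
amount of methylene blue (MB) a cell accumulates reports *phagocytosis*,
and the oxidation-driven **red shift** of MB emission inside the
phagolysosome reports *phagolysosomal oxidation* — the NADPH-oxidase
dependent killing step that is absent in chronic granulomatous disease
(CGD). This package implements the complete desk-side analysis for such
experiments, together with a synthetic event generator that emulates ex
vivo leukocyte–MBEC cocultures and in vivo blood/suction-blister
samples, so every stage can be exercised and validated without
instrument data.

## The model and statistics

MB emission is modeled as a two-state mixture on a 650–820 nm grid:

    S(λ; ρ) = (1 − ρ) · R(λ) + ρ · O(λ),    ρ ∈ [0, 1]

where `R` is the reduced-state basis peaking at the 696 nm primary
emission peak, `O` the oxidation-shifted basis peaking at the 760 nm
shoulder, and `ρ` the latent **oxidized fraction**. MB absorbance peaks
at 665 nm. Detector channels are band-pass windows — AF647 (655–685 nm),
AF700 (705–750 nm), APC-Cy7 (750–810 nm) — rendered as gained
trapezoidal integrals of `S`.

Core measurements:

- **Merged virtual MB channel** — the per-event linear sum
  AF647 + AF700 + APC-Cy7, widening detection to 655–810 nm.
- **Geometric MFI** — `exp(mean(log v))` with a 1 a.u. floor.
- **Red-shift ratio** — APC-Cy7 : AF647 geometric-MFI ratio, strictly
  increasing in `ρ`; its noise-free closed form is
  `predictRedshiftRatio()`.
- **FMO gating** — the MB-low/MB-high cutoff is the 99.5th percentile of
  a fluorescence-minus-one control (cells cocultured with *unlabeled*
  E. coli).
- **Spectral unmixing** — constrained least squares recovers `ρ` from a
  sum-normalized emission spectrum (`unmixOxidizedFraction()`).
- **Bench quantities** — OD420 standard curves for CFU,
  serial-dilution counts, bound-label mass
  (mass = concentration × volume), MOI, order-of-magnitude safety
  margins.

## Worked example

Generate a synthetic 60-minute coculture time series (five MBEC time
points plus an unlabeled-E. coli FMO control, written as FCS 3.1
files), then run the pipeline:

```r
library(mbecflow)

model <- defaultSpectralModel()
model
#> SpectralModel (two-state methylene blue)
#>   reduced peak:  696 nm
#>   oxidized peak: 760 nm
#>   absorbance peak: 665 nm
#>   channels: AF647[655-685] AF700[705-750] APCCy7[750-810]

predictRedshiftRatio(model, c(0, 0.5, 1))
#> [1] 0.683 1.991 5.904

dir <- file.path(tempdir(), "demo")
generateStudy("exvivo", dir, seed = 1)
res <- runStudy(dir, file.path(dir, "report"))
subset(res$summary, population == "neutrophil" & label == "MBEC",
       select = c(sample_id, time_h, mb_mfi, redshift_ratio,
                  mbhi_count, fold_change))
#>       sample_id time_h  mb_mfi redshift_ratio mbhi_count fold_change
#>  exvivo_t000min   0.00   47.47             NA          9       0.998
#>  exvivo_t015min   0.25 1432.90         0.8673       1998      30.128
#>  exvivo_t030min   0.50 2220.39         1.0188       1999      46.685
#>  exvivo_t045min   0.75 2654.69         1.1717       2004      55.816
#>  exvivo_t060min   1.00 2996.27         1.3764       2000      62.998
```

Reading the table: at time zero neutrophils sit at autofluorescence
(fold change ≈ 1, red-shift ratio undefined because there is no MB
signal above background). As coculture proceeds, the merged-channel MB
MFI rises ~60-fold as neutrophils phagocytose MBEC, essentially every
neutrophil becomes MB-high against the FMO gate, and the
background-corrected APC-Cy7:AF647 ratio climbs as internalized MB is
progressively oxidized in the phagolysosome.

Recovering the oxidized fraction from a spectrum is exact without
noise:

```r
u <- unmixOxidizedFraction(mixSpectra(model, 0.3), model)
u$rho        # 0.3
u$residual   # ~1e-17
```

A thin CLI wraps the same functions
(`inst/scripts/mbecflow generate|run|spectra|quantify`).

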