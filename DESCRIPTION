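Package: mbecflow
Title: Flow-Cytometry Analysis of Methylene Blue-Labeled E. coli
    Phagocytosis and Phagolysosomal Oxidation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying bacterial phagocytosis and
    phagolysosomal oxidation from flow-cytometry measurements of
    methylene blue-labeled, UV-killed E. coli (MBEC). Implements a
    two-state (reduced/oxidized) spectral model of methylene blue
    emission, detector band-pass rendering, the merged virtual MB
    channel, the APC-Cy7:AF647 red-shift ratio, fluorescence-minus-one
    gating, constrained spectral unmixing of the oxidized fraction, and
    per-sample/time-course summaries. Includes a synthetic
    spectral-cytometry event generator emulating ex vivo cocultures and
    in vivo blood/blister samples (FCS 3.1 output), plus bench-side
    quantification helpers (OD420 standard curves, serial-dilution CFU
    counts, bound-label mass, MOI).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
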