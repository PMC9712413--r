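Package: peakrama
Title: Backbone Dihedral-Angle Heterogeneity from Multidimensional
    Solid-State NMR Peak Shapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs and quantifies residue-specific backbone phi/psi
    conformational heterogeneity encoded in a single heterogeneously
    broadened cross-peak of a four-dimensional (H, N, CA, CB) solid-state
    NMR spectrum.  Two complementary reconstruction routes are provided: a
    prediction-based route that samples the peak on a regular chemical-shift
    grid, translates secondary-shift deviations onto neighbouring residues,
    and aggregates external-predictor Ramachandran probability maps weighted
    by peak intensity; and a database-matching route that selects
    chemical-shift/structure database entries inside the peak envelope and
    weights them by intensity over local entry density.  Both routes feed a
    common set of heterogeneity scores (circular variance, Shannon and
    excess entropy, flatness, and the helix/extended population ratio).  A
    synthetic-data module simulates 4D peaks from conformer mixtures, mock
    shift databases, and a mock shift-to-angle predictor for closed-loop
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
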