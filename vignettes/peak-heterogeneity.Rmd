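---
title: "Quantifying backbone dihedral-angle heterogeneity from a 4D solid-state NMR peak"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying backbone dihedral-angle heterogeneity from a 4D solid-state NMR peak}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakrama)
```

## The problem

In a rigid, conformationally heterogeneous protein sample — an amyloid,
a freeze-trapped folding intermediate, a lyophilized peptide glass —
every molecule is frozen in its own backbone conformation, and every
conformation resonates at its own chemical shifts.  A solid-state NMR
cross-peak of such a residue is therefore *heterogeneously broadened*:
its shape is a map of the underlying conformer distribution.  In a
four-dimensional (H, N, CA, CB) correlation each point of the peak
carries a correlated shift *quadruple* from (roughly) one slice of the
ensemble, and the well-known dependence of Cα/Cβ secondary shifts on
backbone dihedral angles — helix: Cα upfield-shifted high, Cβ low;
extended: the reverse, an anti-correlated pair — makes the peak shape
interpretable residue by residue, without selective labelling.

peakrama reconstructs the residue's distribution over the backbone
dihedral angles $(\phi, \psi)$ from one such resolved 4D peak region, by
two independent routes, and condenses either reconstruction into a small
set of heterogeneity scores.

## Route 1: prediction-based reconstruction

1. **Grid sampling** (`sample_grid()`).  The peak is probed on a regular
   chemical-shift lattice anchored at the intensity maximum, with
   per-nucleus spacings (defaults 0.4 / 1.5 / 1.0 / 1.5 ppm for
   H / N / CA / CB) fine enough to separate helical from extended shift
   regions.  Lattice points with multilinearly interpolated intensity
   below a fraction of the maximum (default 20%, a practical
   signal-to-noise floor) are discarded; the survivors are the grid
   points $i$ with intensities $I_i$.  Interpolated probing is the
   default; nearest-voxel probing is available
   (`method = "nearest"`), as the choice between the two is not
   observable from the result at realistic digital resolution.
2. **Neighbour translation** (`translate_to_neighbors()`).  Shift-based
   dihedral predictors use a window of consecutive residues, but in a
   heterogeneous sample the sub-peak elements of the neighbours cannot
   be paired with those of the residue of interest (ROI).  Instead, the
   ROI's secondary-shift deviation
   $r_i = \delta_i - \delta_{\mathrm{rc}}$ from its neighbour-corrected
   random-coil shift is *translated* onto the neighbours $j \pm 1$,
   $j \pm 2$: each receives its own random-coil shift plus $r_i$
   rescaled per residue type and nucleus.  The rescaling factor is the
   ratio of helix-minus-extended centre-of-gravity spans of the two
   types — the simplest measure of how strongly secondary structure
   modulates that nucleus in each type.  A single factor is used for
   both neighbour distances, and the chain is optionally padded by one
   terminal residue per side (glycine by default) so that window-based
   predictors see full windows.  The construction is affine in $r_i$
   and leaves the ROI's shifts untouched.
3. **Per-point maps and aggregation** (`parse_ann_output()`,
   `aggregate_maps()`).  Each grid point's shift table goes to an
   external predictor whose per-residue output is an 18 × 18
   probability grid over $(\phi, \psi)$ — only that grid is used, none
   of the predictor's derived outputs.  The whole-peak map is the
   intensity-weighted sum
   $D_k = \sum_i D_{ki}\, I_i$, normalized to unit mass.  Aggregation
   is linear, permutation-invariant, and invariant to uniform rescaling
   of the intensities.

The predictor runs out of process: `prepare_predictor_inputs()` writes
one TALOS-style shift table per grid point plus a manifest, and
`run_prediction_branch(predictor = "files")` reads the per-point grids
back.  For closed-loop validation, `mock_predictor()` substitutes the
external tool with an analytic posterior under the synthetic forward
model (below).

## Route 2: database-matching reconstruction

A per-residue table of a chemical-shift/structure database (PACSY-style:
shifts, $\phi/\psi$, STRIDE class, quality flag) is used directly:

1. entries from proteins failing shift quality control are dropped
   (`filter_quality()`);
2. STRIDE classes are simplified — H/G/I → helix, E → extended,
   T/B/b → other, C → coil — and coil entries are excluded: their
   shifts arise from fast conformational averaging in solution, which
   has no counterpart in a rigidified sample;
3. entries whose shift quadruple lies inside the peak envelope (same
   interpolated-intensity threshold as route 1) are kept
   (`select_in_envelope()`);
4. each kept entry is weighted $w_i = I_i / P_i$ — peak intensity over
   the local 4D entry density (`local_density()`, a product-Gaussian
   kernel estimate with bandwidths defaulting to the grid spacings of
   route 1).  The inverse-density factor removes the composition bias
   of the database: duplicating every entry $k$ times multiplies
   $P_i$ by exactly $k$ and leaves the normalized reconstruction
   unchanged, and a database that over-represents one class still
   reconstructs the peak's own class balance (both are tested);
5. the weighted entries are binned on the same 20° lattice as route 1
   (`entries_to_map()`).

By default $P_i$ is estimated from the entries inside the envelope; a
`density_scope = "all"` switch uses all quality-passing entries of the
residue type instead.  Selections smaller than `min_entries` (default
20) are flagged low-confidence rather than rejected — small selections
arise for shift combinations in sparsely populated database regions, and
their maps are dominated by a handful of entries.

## The folded map

Shift patterns cannot distinguish the sense of helix winding (for an
alanine between glycines, left- and right-handed helices are near
mirror images with near-identical shifts), so right-half map mass is
merged onto the left by point reflection about $(0, 0)$ —
"folding".  The unfolded lattice has bin centres at multiples of 20°
from −180° to +160° on both axes.  Under point reflection the columns
$\phi = 0$ and $\phi = -180$ map onto themselves, so the folded lattice
has exactly 10 φ-columns (−180° … 0°) by 18 ψ-rows — 180 bins — with
total mass conserved to machine precision.  This bin-centre convention
is what makes the 10-column folded lattice come out naturally; a grid
centred at −170° would fold 18 columns into 9 and need an ad-hoc
boundary column.

## Heterogeneity scores

All scores operate on the folded, normalized map (`score_all()`):

* **Circular variance** $V_\theta = 1 - |\bar v|$, the complement of the
  mean resultant length of the marginal distribution on each axis;
  0 for a single bin, 1 for a vanishing resultant.  After folding, φ
  spans only half the circle, so $V_\phi$ cannot reach 1 exactly under
  either convention: the default uses the raw bin angles; an
  angle-doubled variant for axial data (`phi_convention = "doubled"`)
  is provided, and the convention used is recorded in every output.
* **Shannon entropy** in nats over 180 (total), 10 (φ) or 18 (ψ) bins,
  with $0 \ln 0 := 0$: 0 for one populated state, up to
  $\ln 180 \approx 5.19$, $\ln 10 \approx 2.3$, $\ln 18 \approx 2.9$
  for uniform distributions.  **Excess entropy**
  $\Delta S = S - S^{\mathrm{conf.H}}$ subtracts the entropy of a
  confined-helix prediction, correcting for the ambiguity a shift-based
  predictor has even for a perfectly defined conformation.
* **Flatness.**  The relative abundance of the highest-probability bin,
  $\max_k D_k / \sum_k D_k$, measures confinement; its complement grows
  with heterogeneity.  Published tabulations of this family of scores
  are consistent with the complement convention, so `F` defaults to
  $1 - \max_k D_k$; both values are always reported
  (`F_peak_fraction` carries the raw maximum).
* **Helix/extended ratio** $R = \max(H, E) / \min(H, E) \ge 1$ over
  rectangular region masks (defaults: helix φ ∈ [−120°, −40°],
  ψ ∈ [−70°, 10°]; extended φ ∈ [−180°, −80°], ψ ∈ [100°, 180°];
  approximate, disjoint in ψ, fully configurable).  The dominant class
  is flagged, and a zero minor-class mass yields `Inf` — the signature
  of a clean single-class reconstruction rather than an error.

## The synthetic forward model

`forward_model()` fixes the study conditions for all closed-loop tests.
Helix and extended alanine-like classes sit at anti-correlated carbon
centroids (helix CA 55 / CB 18 ppm; extended CA 50 / CB 23 ppm) — the
5 ppm class separation that makes carbon shifts the informative
dimensions.  H/N centroids differ only mildly (0.2 / 2 ppm): amide
shifts report H-bonding and packing at least as much as backbone
angles, so in the simulation they act mainly as dispersion dimensions.
Within-class conformer scatter is 0.4 / 1.8 / 1.5 / 1.5 ppm
(H / N / CA / CB), and homogeneous linewidths of 0.5 / 0.3 / 0.5 ppm
FWHM (H / N / C) are convolved onto every conformer, the order expected
at moderate field and fast magic-angle spinning.  With these values a
two-class mixture spans roughly 7–8 ppm in the carbon dimensions at the
20% contour, matching the broadening regime the method targets.
Angular modes are placed at (−80°, −30°) for helix and (−130°, 140°)
for extended, inside the default region masks, with 15° wrapped-normal
spread.

`simulate_peak()` renders a conformer ensemble as a sum of separable 4D
Gaussians plus optional white noise; `generate_mock_database()` draws
database entries from the same model with configurable class
composition and quality-flag failure rate; `mock_predictor()` returns,
for one shift quadruple, the class-posterior mixture of angular kernels
(with a flat background class that takes over roughly three total
widths away from both centroids, flattening predictions for
implausible shift combinations).

What the generator deliberately does **not** emulate: continuum
conformer distributions between the class modes, turn/coil structure in
the peak itself, residue types other than a single ROI, shift
modulation by side-chain rotamers, ring currents or differential
H-bonding, and correlated (non-separable) lineshapes.  Closed-loop
results therefore validate the bookkeeping and the estimators, not the
shift physics.

## Numerical choices and scales

Problem sizes are chosen for interactive use: synthetic hypercubes are
24⁴ voxels (12⁴ in the oracle-equivalence checks), grids are a few
hundred points, mock databases hold a few thousand entries, and the
kernel density estimate is the exact O(n²) sum over the selection.  The
complete test suite and the acceptance script each run in well under a
minute.  Ties and degeneracies: negative intensities (processing
artefacts) are clipped at zero when a peak region is constructed, so
aggregation weights are non-negative; zero-intensity lattice points are
never selected; a single-entry selection gets a uniform density with a
warning; a zero-mass map refuses to normalize.

## A known, quantified limitation: threshold truncation bias

The relative-intensity threshold that defines both the grid selection
and the peak envelope truncates the *minor* conformer's intensity
distribution more severely than the major one's.  For a Gaussian class
with peak amplitude a fraction $a < 1$ of the global maximum, the
threshold $t$ keeps the region where the class's own profile exceeds
the relative level $\lambda = t / a$; in $d$ effective dimensions the
kept mass fraction is $P(\chi^2_d \le 2 \ln(1/\lambda))$.  The effect
is *scale-free* — independent of linewidths and scatter — and at
$t = 0.2$ it depresses the recovered minor-class population of a 30/70
two-class mixture by roughly a factor of two.  Both reconstruction
routes inherit the bias (the database route somewhat less, because the
inside-envelope density estimate under-weights envelope-edge density
and partially compensates).  Consequences, all visible in the
acceptance outputs: a balanced mixture is recovered essentially
exactly and the two routes agree closely on it; skewed mixtures are
recovered with the correct dominant class and correct ordering but
exaggerated dominance.  Ratios between residues analysed at the same
threshold remain comparable — the scores are designed for relative,
within-sample comparison — but absolute population ratios from
thresholded peaks should be read with this bias in mind, and lowering
the threshold (where signal-to-noise permits) reduces it roughly as
the $\chi^2$ expression predicts.

## Design choices that were genuinely open

* **Lattice anchor.**  The sampling lattice is anchored at the peak
  maximum, so the most intense point is always a grid point.
* **Probing interpolation.**  Multilinear interpolation rather than
  nearest-voxel, for smoothness of $I_i$; both are exposed.
* **Rescaling formula.**  The centre-of-gravity span ratio (see route
  1); a per-distance ($j\pm1$ vs $j\pm2$) differentiation was
  considered and rejected for lack of any calibration data.
* **$r_i$ dimensionality.**  The deviation vector covers the four
  observed nuclei; the table schema tolerates a C′ column so a
  five-nucleus variant needs no format change.
* **Density estimator.**  Product-Gaussian KDE with per-nucleus
  bandwidths tied to the grid spacings, so both routes resolve shift
  space at the same scale; the envelope-only scope is the default
  because the reconstruction is a property of the envelope.
* **Reference tables.**  The shipped random-coil and centre-of-gravity
  CSVs are approximate synthetic stand-ins (marked as such in their
  headers) sufficient for the closed-loop machinery; production use
  should substitute published tables via the documented schemas.

## Worked example

```{r example, eval = FALSE}
model <- forward_model()
ensemble <- list(class_conformer(model, "helix", 0.5),
                 class_conformer(model, "extended", 0.5))
peak <- simulate_peak(ensemble, model)
cfg <- run_config(seed = 1)
both <- run_both_branches(cfg, peak = peak,
                          entries = generate_mock_database(3000,
                                                           model = model,
                                                           seed = 2))
both$comparison
```
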