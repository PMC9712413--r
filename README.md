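# peakrama

Residue-specific backbone dihedral-angle heterogeneity from the shape of
a single 4D solid-state NMR cross-peak.

## What problem this solves

In rigid but conformationally heterogeneous samples — amyloids,
freeze-trapped folding intermediates, lyophilized peptide glasses —
every molecule is frozen in its own backbone conformation, and a
residue's cross-peak is *heterogeneously broadened*: its shape encodes
the distribution of conformers.  In a four-dimensional (H, N, Cα, Cβ)
correlation each point of the peak carries a correlated shift quadruple,
and the anti-correlated dependence of Cα/Cβ secondary shifts on backbone
dihedral angles makes that shape interpretable residue by residue,
without selective labelling.

peakrama reconstructs the residue's Ramachandran distribution — the
probability density D_k over binned (φ, ψ) combinations — from one
resolved 4D peak region, by two independent routes:

* **Prediction route.**  Sample the peak on a regular chemical-shift
  lattice (intensity ≥ 20 % of the maximum); translate each lattice
  point's secondary-shift deviation onto the neighbouring residues
  (rescaled per residue type and nucleus by the ratio of
  helix-minus-extended centre-of-gravity spans); obtain one 18 × 18
  (φ, ψ) probability grid per point from a shift-based dihedral
  predictor; aggregate them intensity-weighted, D_k = Σᵢ D_kᵢ Iᵢ.
* **Database route.**  Keep quality-passing entries of a
  chemical-shift/structure database whose shift quadruple lies inside
  the peak envelope, weight each by wᵢ = Iᵢ / Pᵢ (peak intensity over
  local 4D entry density, which cancels database composition bias), and
  bin their (φ, ψ) angles on the same lattice.

Both maps are "folded" (right-handed/left-handed helical regions merged
by point reflection about the origin, yielding a 10 × 18 lattice) and
scored with a common set of heterogeneity measures:

* circular variance V_φ, V_ψ = 1 − |mean resultant| of each marginal,
* Shannon entropies S_φ, S_ψ, S_total (nats; maxima ln 10 ≈ 2.3,
  ln 18 ≈ 2.9, ln 180 ≈ 5.19) and excess entropy ΔS over a
  confined-helix reference,
* flatness F (abundance of the top bin, and its complement),
* the helix/extended population ratio R = max(H, E)/min(H, E) over
  configurable Ramachandran region masks.

A synthetic module (forward model, 4D peak simulator, mock database,
mock predictor) provides closed-loop ground truth, so the whole pipeline
is testable without a spectrometer, an external predictor, or database
access.

## Worked example

```r
library(peakrama)

model <- forward_model()                      # alanine-like two-class model
ensemble <- list(class_conformer(model, "helix", 0.5),
                 class_conformer(model, "extended", 0.5))
peak <- simulate_peak(ensemble, model)        # 24^4 hypercube, (H,N,CA,CB)

cfg <- run_config(seed = 1)
both <- run_both_branches(cfg, peak = peak,
                          entries = generate_mock_database(3000,
                                                           model = model,
                                                           seed = 2))
both$prediction$scores
#> Heterogeneity scores
#>   V_phi 0.132   V_psi 0.918   (phi convention: raw)
#>   S_phi 1.750   S_psi 1.916   S_total 3.112   dS_total 0.768
#>   F 0.889 (complement; peak fraction 0.111)
#>   R 1.026 (E-dominant; H 0.482, E 0.495)

both$comparison[, c("branch", "V_psi", "S_total", "F", "R")]
#>      branch V_psi S_total     F    R
#>  prediction 0.918    3.11 0.889 1.03
#>    database 0.874    3.23 0.895 1.03
```

Read: the 50/50 helix/extended mixture comes back with R ≈ 1 (balanced
populations, helix and extended masses 0.48/0.50), a large ψ circular
variance and S_total ≈ 3.1 nats (strongly bimodal ψ distribution), and
the two independent reconstruction routes agree closely.  A confined
single-conformer peak instead gives V_ψ < 0.1, ΔS ≈ 0 and R > 10.

Real spectra enter through `read_spectrum()` (single-file NMRPipe
streams or the portable JSON hypercube container); real predictor runs
through `prepare_predictor_inputs()` /
`run_prediction_branch(predictor = "files")`; real databases through
`load_database()` (documented CSV schema).  A thin command-line front
end lives at `inst/scripts/peakrama` (`simulate` and `run`
subcommands, YAML config).

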