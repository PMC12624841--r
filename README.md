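# Jdeconv

Conformer population deconvolution from scalar J-couplings.

## The problem

Solution NMR of a flexible molecule returns one ensemble-averaged value
per scalar coupling.  For N-glycosides — here the N-phenyl
glycosylamines of d-glucose, d-mannose, d-xylose and d-lyxose — the
conformational questions are (i) which chair the pyranose ring adopts
(⁴C₁ vs ¹C₄) and (ii) how the aniline aglycone is oriented about the
glycosidic bond (rotamers −gauche/+gauche/trans of the torsion
φ = O5–C1–N–Ci, each split by the R/S configuration of the pyramidal
nitrogen).  `Jdeconv` answers both by fitting conformer-pure
theoretical couplings to the measured set:

* **Karplus prediction.**  Basic form J(θ) = A·cos²θ + B·cosθ + C and
  the generalized (Haasnoot–Altona-type) form with substituent
  electronegativity corrections
  J(θ) = P₁cos²θ + P₂cosθ + P₃ + Σᵢ λᵢ[P₄ + P₅cos²(ξᵢθ + P₆|λᵢ|)],
  evaluated on exact ideal pyranose chairs with per-sugar templates.
* **Two-state ring fit.**  The ⁴C₁ fraction x minimizes the MAE (or
  SSE) of rᵢ = Jᵢᵉˣᵖ − [x·Jᵢ(⁴C₁) + (1−x)·Jᵢ(¹C₄)] over x ∈ [0,1].
* **Simplex deconvolution.**  Aglycone populations p minimize
  MAE(p) = (1/m)·Σᵢ |Jᵢᵉˣᵖ − |Σ_c p_c·J_{i,c}||, p on the probability
  simplex (exhaustive 0.01 grid + deterministic local refinement;
  degenerate optima are flagged and reported at maximum entropy).
* **Boltzmann machinery.**  pᵢ ∝ exp(−ΔGᵢ/RT) populations, per-group
  (per-anomer) totals, and Boltzmann-averaged properties.
* **Kinetics.**  Pseudo-first-order approach to equilibrium
  f(t) = f_eq(1 − e^(−kt)) for in situ glycosylamine formation, with
  t₉₉ = ln(100)/k as the operational time to equilibrium.
* **Synthetic data.**  A seeded generator producing conformer
  libraries, noisy ensemble-averaged "experimental" tables with known
  truth, dihedral scans and kinetics traces, so the whole pipeline is
  testable offline.

The experimental coupling table of the eight glycosylamines ships with
the package (`glycosylamineCouplings()`); per-conformer calculated
coupling libraries are read from structured JSON
(`readConformerLibrary()`).

## Worked example

Ring conformation of the α-d-lyxoside (compound 8a), whose unusual
ring couplings indicate a mostly inverted chair:

```r
library(Jdeconv)

tab <- glycosylamineCouplings()
round(pyranoseEndpoints("8a")$j4C1, 2)   # Karplus-predicted 4C1 couplings
#>  3J(H1,H2)  3J(H2,H3)  3J(H3,H4)  3J(H4,H5) 3J(H4,H5')
#>       2.83       2.44       9.75       4.32      10.12

ringFitCompound(tab, "8a")
#> TwoStateFit (objective: mae)
#>   populations: 4C1 = 10.0%, 1C4 = 90.0%
#>   MAE = 0.509 Hz over 5 coupling(s)
```

The fit says the lyxoside spends ~90% of its time in the ¹C₄ chair
(published analysis: 86%), with a 0.5 Hz mean misfit — about the
accuracy of the idealized Karplus endpoints themselves.

Aglycone deconvolution in closed loop, emulating the β-mannoside's
81/19 −gauche/trans split at realistic noise:

```r
sim <- simulateEnsemble(nConformers = 2, populations = c(0.81, 0.19),
                        labels = c("(R)-(-gauche)", "(R)-(trans)"),
                        noiseSigma = 0.3, seed = 1)
fitPopulations(sim$experimental, sim$library)
#> PopulationFit (objective: mae)
#>   populations: (R)-(-gauche) = 84.8%, (R)-(trans) = 15.2%
#>   MAE = 0.192 Hz over 8 coupling(s)
```

A single noisy replicate recovers the truth to a few percent; averaged
over replicates the estimator is unbiased (see the methods vignette).

Kinetics of the formation reaction (d-lyxose-like truth):

```r
tr <- simulateKinetics(k = 2.5e-4, fEq = 0.96,
                       times = seq(0, 7.2e4, length.out = 12))
fitFirstOrder(tr)
#> KineticsFit: k = 0.00025 1/s, f_eq = 0.960
#>   rmse = 0; t99 = 1.842e+04 s (5.12 h)
```

## Command line

```sh
Rscript inst/cli/jdeconv.R ring-fit --exp couplings.csv --compound 8a --out fit.json
Rscript inst/cli/jdeconv.R populations --exp couplings.csv --compound 6b --library lib.json
Rscript inst/cli/jdeconv.R simulate ensemble --seed 7 --out out/
```

See `Rscript inst/cli/jdeconv.R --help` for all subcommands.
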