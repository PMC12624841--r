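---
title: "Conformer populations from ensemble-averaged J-couplings"
author: "Jdeconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformer populations from ensemble-averaged J-couplings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(Jdeconv)
```

## The problem

Solution NMR of a flexible small molecule measures one number per
scalar coupling: the population-weighted average over all conformers in
fast exchange.  For N-glycosides such as N-phenyl glycosylamines, two
conformational questions dominate: which chair the pyranose ring adopts
(⁴C₁ vs ¹C₄), and how the aglycone is oriented about the glycosidic
bond (the torsion φ = O5–C1–N–Ci, with −gauche/+gauche/trans rotamers,
each further split by the R/S configuration of the shallowly pyramidal
aniline nitrogen).  Neither question can be answered from a single
coupling; both can be answered by fitting conformer-pure *theoretical*
couplings to the set of measured ones.  `Jdeconv` implements that
inference as a reusable, fully testable pipeline:

1. **Karplus prediction** of conformer-pure ³J(H,H) couplings from
   dihedral angles (`karplusJ()`, `pyranoseEndpoints()`);
2. **two-state ring fits** on the experimental ring couplings
   (`fitTwoState()`, `ringFitCompound()`);
3. **multi-conformer deconvolution** of redundant ¹⁵N-mediated
   couplings on the probability simplex (`fitPopulations()`);
4. **Boltzmann machinery** for energy-based populations and property
   averages (`boltzmannPopulations()`, `averageProperty()`);
5. **first-order kinetics fits** for the in situ formation reaction
   (`fitFirstOrder()`);
6. a **synthetic-data generator** that emulates every input the
   pipeline consumes (`simulateEnsemble()` and friends).

## Karplus model and the chair templates

The vicinal-coupling model is the generalized (Haasnoot–Altona-type)
equation

$$ J(\theta) = P_1\cos^2\theta + P_2\cos\theta + P_3 +
   \sum_i \lambda_i\left[P_4 + P_5\cos^2(\xi_i\theta + P_6|\lambda_i|)\right], $$

with the classic H–C–C–H coefficients (13.70, −0.73, 0, 0.56, −2.47,
16.9; Hz and degrees) as the shipped default.  Each non-hydrogen
substituent on the coupled fragment contributes a correction through
its group electronegativity difference λ (Huggins scale, corrected for
β-substituents: OH 1.30, ring O 1.24, anilino N 0.79, ring C 0.16,
exocyclic C 0.22) and an orientation sign ξ = ±1.  All coefficients and
λ values live in a versioned JSON registry
(`inst/extdata/karplus_params.json`) and can be overridden per run;
which exact parameterization the original ring-fit analysis used is not
recorded, so it is configuration, not a hard-coded guess.

Chair geometries are built from the *exact ideal chair*: six ring atoms
with tetrahedral angles and ring torsions of ±60°, so H–C–C–H torsions
come out exactly 180° (diaxial) or ±60° (gauche).  The per-compound
templates record only the chemistry: which substituent is axial or
equatorial at each ring carbon in ⁴C₁ (e.g. the C2-OH of lyxose
configured axial, the anomeric nitrogen axial for the α anomers).
Chair inversion to ¹C₄ swaps every assignment, which preserves all
relative configurations.  Substituent ξ signs are read directly off the
3-D geometry, as the sign of the ±120° offset between the substituent
torsion and the proton–proton torsion.

Two conventions in this construction were genuinely open and are fixed
as follows:

* **The global ξ sign.**  The generalized equation is invariant under
  mirroring (θ → −θ together with ξ → −ξ), so the literature's
  orientation convention cannot be recovered from the formula alone.
  The engine's sign was anchored on the chair-pure compounds of the
  measured series (the ⁴C₁-locked gluco/manno/xylo anomers): one of the
  two possible signs reproduces their measured gauche couplings
  (e.g. 3.8 vs 4.2 Hz for the α-glucoside H1–H2; 0.9 vs 1.0 Hz for the
  β-mannoside), the other fails by 3 Hz.  With the chosen sign the mean
  absolute deviation over all seventeen chair-pure anchor couplings is
  about 0.5 Hz.  Diaxial couplings are insensitive to ξ and agree with
  the measured 8.5–10.4 Hz band in any case.
* **Which C5 proton is H5′.**  For pentopyranoses the template defines
  H5′ as the proton axial in ⁴C₁, matching the observed large
  ³J(H4,H5′) of the ⁴C₁-locked β-xyloside.

`canonicalDihedral()` exposes the idealized 180/60 values directly;
template-derived values are available through `compound =`.

## Two-state ring fit

With endpoint vectors $J_i(^4C_1)$ and $J_i(^1C_4)$ from the templates
(or supplied by the user, e.g. from quantum-chemical calculations), the
chair fraction $x$ minimizes either the mean absolute error (default)
or the sum of squared residuals of

$$ r_i = J_i^{exp} - \left[x\,J_i(^4C_1) + (1-x)\,J_i(^1C_4)\right],
   \qquad x \in [0,1]. $$

SSE has a closed form (clipped to the interval); the MAE objective is
convex piecewise-linear in one variable and is solved by a 0.001 grid
refined with golden-section search.  MAE is the default for consistency
with the aglycone fit; both objectives are retained because the
original ring-fit objective is not stated.  By default all usable ring
³J(H,H) couplings enter the fit (measured zeros included, `nd`/broad
records excluded); the subset is configurable since the original
per-compound selection is also not stated.

On the bundled experimental table this reproduces the published
conclusions without any tuning: the α-lyxoside comes out 90% ¹C₄ (MAE)
or 85% (SSE) against the published 86%, and the β-xyloside 96% ⁴C₁.

## Simplex deconvolution of redundant couplings

For the aglycone, conformer populations $p$ minimize

$$ \mathrm{MAE}(p) = \frac{1}{m}\sum_{i=1}^{m}
   \Big|\,J_i^{exp} - \big|\textstyle\sum_c p_c J_{i,c}\big|\,\Big|,
   \qquad p_c \ge 0,\; \sum_c p_c = 1, $$

where $J_{i,c}$ are signed calculated couplings and the absolute value
mirrors the fact that experimental splittings are magnitudes.
Conformers are pre-filtered at ≤ 5 kcal/mol relative energy
(inclusive; `filterConformers()`).  The solver enumerates an exhaustive
simplex grid — step 0.01 for up to four conformers, matching
integer-percent reporting; step 0.05 beyond, where the 0.01 grid would
be astronomically large — and polishes the best distinct grid points by
Nelder–Mead on a softmax parametrization.  The multistart is
deterministic (top distinct grid points), so results are bit-for-bit
reproducible with no random state at all.

Because magnitudes discard sign, materially different population
vectors can fit equally well.  When vectors differing by more than 0.05
in some component lie within 0.01 Hz of the optimal MAE, the fit is
flagged `degenerate` and the reported vector is the maximum-entropy
member of the near-optimal set — deliberately the least committal
answer, to avoid overconfident single-conformer claims.  All couplings
are equally weighted in the MAE (per the stated procedure); a weight
vector is available as an option.

## Boltzmann machinery

`boltzmannPopulations()` uses $p_i \propto e^{-(G_i - G_{min})/RT}$ with
R = 1.987204×10⁻³ kcal/(mol K).  Two grouping conventions are
implemented exactly as used for anomer analyses: *global* scope
(one distribution over all conformers, then summed by group — the
anomer-ratio procedure) and *within-group* scope (separate
normalization per group — the property-averaging procedure).  The
default temperature is 298.15 K; the averaging temperature of the
original analysis is not stated (its MD used 300 K), so the value is a
flag, and populations at the two temperatures differ negligibly.

## Kinetics

Glycosylamine formation at excess amine is treated as pseudo-first
order, $f(t) = f_{eq}(1 - e^{-kt})$, with hydrolysis/back-reaction
lumped into the plateau $f_{eq}$ (one observed rate constant per
sugar).  The nonlinear least-squares solve is initialized from the
log-linearized trace.  `timeToEquilibrium()` with the default 99%
threshold, $t_{99} = \ln(100)/k$, reproduces the published
"time to equilibrium" values from the published rate constants within
rounding for three of the four sugars (5.1 h vs 5 for d-Lyx, 5.9 vs 6
for d-Xyl, 7.9 vs 8 for d-Man; 41 h vs the printed 36 for the slowest
sugar, d-Glc), supporting that operational definition.

## What the synthetic generator emulates — and what it does not

The per-conformer calculated coupling tables underlying the original
aglycone fits are not publicly deposited, so `simulateEnsemble()`
stands in for them and is itself first-class, tested code.  It draws
per-conformer couplings from per-coupling Karplus curves evaluated at
the rotamer torsions (−60/+60/180, shifted ±12° for the R/S nitrogen
configurations, plus a seeded jitter of s.d. 10°), forms the signed
population-weighted average, adds Gaussian noise (σ default 0.3 Hz,
mid-range of the 0.2–0.6 Hz fit-residual band of the real analysis)
and reports magnitudes.  The default coupling model's amplitudes were
set once to mirror the reported conformational sensitivities — about
13 Hz range for ³J(NH,H1) down to near-constant phenyl-ring couplings —
and its phase offsets encode that different couplings peak at different
rotamers, which is precisely what makes redundant couplings
informative.

What the generator does *not* emulate: systematic errors of
quantum-chemical coupling calculations (its curves are exact by
construction), correlations between couplings measured from the same
multiplet, solvent or temperature effects, and continuous torsional
distributions (populations are over discrete conformers only).
Passing closed-loop tests therefore demonstrates the *estimator* is
correct and well-conditioned at realistic noise; it cannot validate
the quality of any particular quantum-chemical coupling surface.

## Numerical choices and degenerate inputs

* Angles are normalized to (−180, 180], with −180 mapping to +180;
  normalization is idempotent.
* Library energies are min-shifted to 0 on construction; the energy
  filter is inclusive at the cutoff.
* Experimental tables distinguish a measured 0 Hz (used in fits) from
  `nd`/`b` flags (excluded); malformed numeric cells are rejected, not
  coerced.
* Identical conformer coupling columns trigger a non-identifiability
  warning and the degenerate flag; identical chair endpoint vectors are
  an error in the two-state fit.
* Flat kinetics traces (already equilibrated) are an error — the rate
  constant is unidentifiable; decreasing traces fit with a warning.
* Problem sizes used in the shipped checks: simplex-recovery runs use
  100 seeded replicates of 4 conformers × 8 couplings; closed-loop
  compound emulations use 6 conformers × 8 couplings; kinetics
  recoveries use 12–16-point traces.

## Known limitations

Idealized chairs ignore ring flattening and substituent-induced torsion
changes; the residual ~0.5 Hz anchor deviation and the 90% vs 86%
chair-fraction difference for the α-lyxoside are the observable cost.
Skew/boat states are not modeled in the ring fit.  Heteronuclear
(¹⁵N-mediated) couplings have no trusted literature Karplus forms, so
the package predicts them only inside the synthetic generator with
user-configurable coefficients — real analyses should supply calculated
per-conformer values through a `ConformerLibrary`.
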