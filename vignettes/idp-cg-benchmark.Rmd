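---
title: "Benchmarking coarse-grained IDP models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking coarse-grained IDP models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpbench)
```

## The problem

Intrinsically disordered proteins (IDPs) exist as broad conformational
ensembles, and their mean radius of gyration (Rg), measurable by small-angle
X-ray scattering, is the standard single-number summary of chain dimensions.
Coarse-grained (CG) simulation models trade chemical detail for sampling
speed, and models at very different resolutions — from a pure
chain-length power law, through one- and two-beads-per-residue models, to
the four-beads-per-residue Martini family — all claim useful Rg
predictions. `idpbench` packages a curated 24-protein benchmark (chain
lengths 24–441, experimental Rg 13.8–65 Å) together with the
predictions of four such models, and implements every statistic needed to
compare them, plus a working one-bead-per-residue "bead-necklace" Monte
Carlo simulator so that new sequences can be scored with the same physics.

## The benchmark table and its conventions

`load_benchmark()` returns the 24-system table: experimental Rg with
uncertainties where reported, per-system salt and temperature annotations,
and the Rg predicted by the scaling law, the SOP-IDP model, the
bead-necklace model, and the Martini model with the Stark corrections.
Three cells of the source table are dual-valued or internally inconsistent,
and the package resolves them by *explicit, recorded conventions* rather
than silent choices:

* **α-synuclein** is listed with two experimental values (40.0 and
  35.5 ± 0.5 Å, from different primary studies); the published per-cell
  deviations are only consistent with 35.5, which evaluation uses.
* **Prothymosin α** has bead-necklace predictions at 0 and 150 mM salt
  (72.3 and 44.6 Å); the published deviation (+18%) corresponds to the
  150 mM value, which evaluation uses.
* **K23**'s scaling-law cell prints 54.7 Å. That value is inconsistent
  with the same table's printed deviation (+14%), with the published
  χ² totals, and with the scaling law itself: a power law fitted to the
  other 23 printed predictions reproduces them to better than 0.07 Å and
  predicts 55.9 Å at N = 254, which also reproduces +14% and the χ²
  totals exactly. We treat 54.7 as a misprint: the table retains it, an
  alternate column stores the reconstructed 55.9, and evaluation uses the
  latter. `validate_consistency(tab, use_conventions = FALSE)` surfaces
  the discrepant cell.

## Evaluation statistics

Per system, the signed percentage deviation is
$\mathrm{dev}_i = 100\,(S_i - E_i)/E_i$ with $E_i$ experimental and $S_i$
predicted Rg; rounding to integers happens only at presentation. Per
model, the aggregate score is the modified Pearson chi-square
$\chi^2 = \sum_i (E_i - S_i)^2 / E_i$, an unnormalized sum — this plain
reading reproduces all six published totals (15.4, 7.1, 7.6, 17.8, and the
leave-one-out 13.0 and 8.8 with hTau40 removed) within the rounding of the
printed inputs. `chi2_leave_one_out()` uses the exact identity
$\chi^2 = \chi^2_{-p} + (E_p - S_p)^2/E_p$, which the tests assert.

Property-bias trendlines (`bias_trend()`) are ordinary least-squares fits
of the deviations against a protein property (experimental Rg, chain
length, FCR, NCPR, Kyte–Doolittle hydropathy, proline fraction, disorder
score). The published trendline captions label their statistic
"R²", but the printed values — including negative ones — are
reproduced, to the last digit in all eight checkable cases, by the *signed
Pearson correlation coefficient* r, not by R². `bias_trend()` therefore
reports `pearson_r` as the caption-compatible headline number and the plain
`r_squared` (and a sign-carrying `sign(slope)·R²`) alongside.

Disorder scores are accepted as external input only; the package predicts
nothing about disorder.

## Sequence descriptors and fixed charges

The bead-necklace model distinguishes residues by charge alone, fixed at
−1, 0 or +1. `assign_charges()` assigns these deterministically: each
titratable site (D, E, H, C, Y, K, R, and the two termini) takes the sign
of its dominant protonation state at the given pH under the
Henderson–Hasselbalch equation with intrinsic pKa values
(Nozaki–Tanford table, shipped as editable YAML), i.e. a mean site charge
of magnitude ≥ 0.5 rounds away from zero. The original workflow ran a
short constant-pH titration simulation to the same {−1, 0, +1} endpoint;
the deterministic rule is reproducible, dependency-free and, at the
default pH 7, gives histidine 0 and the canonical charges for all other
residues. Charge is monotonically non-increasing in pH by construction, a
property the tests check across the pH grid.

Terminal charges are handled in one of two documented modes because the
source description ("each amino acid residue and the end terminals as a
hard sphere") is ambiguous: `"merged"` (default) adds the terminal charges
onto the first/last residue beads, clamping to the model's ±1 ceiling
with a warning when a terminus lands on a like-charged residue;
`"extra_beads"` appends two dedicated ±1 terminal beads. Net charge can
differ by the clamped amount between modes — e.g. penta-lysine is +4
merged, +5 with extra beads — and the counterion count follows the mode.

FCR (= f₊ + f₋), NCPR (= |f₊ − f₋|), mean Kyte–Doolittle hydropathy and
proline fraction (`sequence_descriptors()`) use residue charges only;
termini are excluded from the fractions.

## The bead-necklace model

Every residue is a hard sphere of radius 2 Å on a harmonic bond with
equilibrium length 4.1 Å and force constant 0.4 N/m (≈ 0.972 kT/Å² at
298 K). Electrostatics use an extended Debye–Hückel potential that
accounts for particle volume,

$$ u_{ij}(r) = \lambda_B z_i z_j
   \frac{e^{-\kappa (r - a_i - a_j)}}{r\,(1+\kappa a_i)(1+\kappa a_j)}, $$

with Bjerrum length $\lambda_B = e^2/(4\pi\varepsilon_0\varepsilon_r k_BT)$
(7.15 Å at 298 K, εᵣ = 78.4) and inverse Debye length κ from the 1:1 salt
concentration (1/κ ≈ 7.9 Å at 150 mM); at 0 mM κ = 0 exactly and the
interaction is bare screened-free Coulomb. A uniform soft short-range
attraction acts between chain beads only; the source states only its
contact value ("0.6 kT at the closest contact"), so the functional form
was an open choice and we adopt the conventional dispersion form
$-\varepsilon\,(\sigma/r)^6$ with σ = 4 Å (the contact distance), which
is exactly −0.6 kT at r = 4 Å. Explicit counterions — one hard sphere of
radius 2 Å and opposite unit charge per charged bead, making the system
exactly electroneutral — feel electrostatics and the hard core but not
the chain–chain attraction. Salt enters only through κ (implicit salt);
counterions are the only explicit ions.

### Monte Carlo protocol

Sampling is canonical-ensemble Metropolis in a periodic cubic box (minimum
image convention) whose side defaults to 1.1 × the contour length
(N−1)·4.1 Å. Four move classes are used with weights 17:1:1:1 —
single-particle translation (counterion translations are folded into this
class, so every mobile particle is attempted with equal frequency), pivot
rotation of the shorter chain segment about a random interior bead,
rigid chain translation, and the slithering (reptation) move. One cycle is
one attempted move per mobile particle; the full published protocol is
200,000 equilibration plus 1,000,000 production cycles. The starting chain
is a self-avoiding random walk at the bond length; ions are placed
uniformly without overlap. Move amplitudes (bead 1.5 Å, ion 5 Å, chain
2 Å, pivot half-angle π/2) are configurable and were chosen for
intermediate acceptance fractions; the per-run acceptance statistics are
reported in every trajectory.

Two implementation details deserve emphasis:

* **Slither move.** The naive reptation — delete one end bead, regrow
  the other end at the fixed equilibrium distance r₀ — violates detailed
  balance: the reverse move can never propose the removed bead's actual
  bond length. The resulting bias is measurable (mean squared bond length
  ~3% low, mean squared end-to-end distance ~10% low in the
  zero-interaction limit). The package instead draws the regrown bond
  length from the exact radial bond Boltzmann density
  $p(b)\propto b^2 e^{-\beta k (b-r_0)^2/2}$ by inverse CDF; the end-bond
  energy difference then cancels against the proposal density, so the
  acceptance uses only the remaining energy terms. With this choice the
  phantom-chain oracle is matched to within sampling error.
* **Energy bookkeeping.** Single-particle moves update the total energy
  incrementally from the particle's interaction terms; pivot moves
  recompute all terms involving the moved segment; rigid chain
  translations recompute only chain–ion terms (chain-internal coordinate
  differences are exactly preserved, minimum image included); slither
  recomputes all chain-involved terms (charges stay with residue indices,
  so the charge-coordinate pairing changes). The running total is compared
  against a full recomputation at run end (`energy_drift`, typically
  ~1e−13 kT), and an independent, deliberately naive O(n²) double-loop
  oracle in R (`total_energy()`) must agree with the engine's stored frame
  energies to 1e−8 kT in the tests.

The engine is compiled (Rcpp) and uses R's RNG, so a run is reproducible
bit-for-bit from its seed. Rg is computed unweighted over chain beads
(the model has no masses); counterions are excluded.

### Observables and diagnostics

`counterion_rdf()` histograms the minimum-image distance from each
counterion to its nearest chain bead, with per-sign splits — oppositely
charged counterions of a net-charged chain sit systematically closer than
co-ions, which the tests assert by sign. `convergence_report()` gives
block-averaged replicate means with standard errors, the statistical
inefficiency g = 1 + 2Σ(1−t/n)ρₜ (truncated at the first non-positive
autocorrelation; for an AR(1) process g → (1+φ)/(1−φ), checked within
20%), and flags replicates further than a configurable multiple of the
pooled standard error from the grand mean — the signature of trapping in
local minima.

## Scaling law

The N-only power law Rg = A·Nᵛ is the benchmark's most minimal model. Its
constants are not printed in the source; they were recovered once by a
log-log fit to the 24 printed predictions (which the fit reproduces to
< 0.1 Å, K23 convention applied) and frozen as
`canonical_scaling_law()`: A = 2.1316 Å, ν = 0.58981 — a self-avoiding-
coil-like exponent. `fit_power_law()` fits either in log space (default;
the standard linearization) or by nonlinear least squares on the original
scale; fitting the 24 experimental (N, Rg) pairs gives R² ≈ 0.94 (log
space) / 0.93 (linear space) with exponents 0.50 / 0.46 — the fit space
behind the published R² = 0.93 is not stated, so both are computed and
both exponents are nearer the random-coil 0.5 than the self-avoiding 0.6.

## Synthetic data

The generators make every pipeline stage testable offline:

* `make_sequence()` builds random sequences with exact FCR, NCPR and
  proline targets (positives from {K, R}, negatives from {D, E};
  histidine excluded so charge targets are exact at pH 7) and a mean
  hydropathy matched by greedy composition plus swap refinement. The
  neutral-residue hydropathy alphabet is discrete with a 2.2-unit gap
  between glycine and alanine, so the KD mean is guaranteed only to about
  1/length (worst case 1.1/length); infeasible targets error with the
  nearest achievable value.
* `make_phantom_chain()` samples ideal chains whose bond lengths come
  from the exact radial Boltzmann density (inverse CDF) — the independent
  oracle for the simulator's zero-interaction limit, via
  ⟨R²ₑₑ⟩ = (N−1)⟨b²⟩ with ⟨b²⟩ from quadrature
  (`phantom_bond_moments()`).
* `make_power_law_dataset()` draws (N, Rg) pairs log-uniformly over the
  benchmark's N range with multiplicative lognormal noise.

These emulate composition and scaling statistics only: generated sequences
have no realistic dipeptide grammar, and phantom chains have no excluded
volume, so passing tests demonstrate correctness of the machinery, not
biological realism.

## Problem sizes and test design

The test suite runs the full statistics on the real fixture (they are
instantaneous) and scales simulations to what the physics check needs: the
phantom-chain limit uses a 10-mer over 150,000 production cycles (the
oracle is exact, so only sampling error matters); the salt-screening check
uses a 50-mer with FCR = NCPR = 0.5 at 0 vs 150 mM with duplicate
replicates of 12,000 production cycles, where the effect (≈ 35 Å vs 26 Å)
is many times the pooled block error; oracle-agreement checks use short
histatin 5 runs at 150 mM. Full-protocol reproduction of published
per-protein means (e.g. Hst5 13.8 Å) is a stochastic, long-run target and
is not asserted at short scale; a shortened two-replicate Hst5 campaign is
checked only for physical plausibility and replicate consistency. For
reference, full-protocol Hst5 runs at this implementation's defaults land
near 13.0–13.2 Å, within ~5% of the published value, which is the
expected agreement between two independent implementations of the same
model family that may differ in the exact screened-potential dialect and
attraction form.

## Known limitations

* The extended Debye–Hückel dialect and the $-\varepsilon(\sigma/r)^6$
  attraction are stated choices; the source text pins only the contact
  value and the "volume taken into account" property.
* Minimum-image electrostatics with a box ≈ 1.1 × contour length can fold
  interactions for near-fully-extended strongly charged chains; the
  original protocol has the same property ("side length large enough to
  contain each protein's contour length").
* Charges are fixed for the whole run; no charge regulation.
* The Martini and SOP-IDP numbers are benchmark inputs transcribed from
  the source, not computations of this package.
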