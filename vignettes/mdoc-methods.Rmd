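---
title: "Restrained dynamics with orientational NMR constraints: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restrained dynamics with orientational NMR constraints: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdoc)
```

## The problem

Flexible small molecules — natural products, catalysts, drug candidates —
interconvert between conformers fast on the NMR timescale, so every
measured NMR parameter is a dynamic average. Residual dipolar couplings
(RDCs) measured in weakly aligning media report on bond orientations
relative to the magnetic field, but interpreting *averaged* RDCs with the
classical alignment-tensor (Saupe/SVD) machinery requires assuming a small
set of rigid conformers sharing one alignment tensor, an assumption that
degrades exactly when the molecule is most flexible.

`mdoc` implements the alternative this package is named after: molecular
dynamics with orientational constraints. Instead of fitting an alignment
tensor, the simulation itself reorients and refolds the molecule under
*pseudo-forces* derived from the mismatch between time-averaged calculated
observables and their measured values. Three observable classes act as
constraints:

* **RDC tensors.** For each coupled spin pair the full symmetric traceless
  dipolar tensor is built in the laboratory frame from the instantaneous
  unit internuclear vector $u$:
  $D_{\alpha\beta}(u) = D_{\max}\,(3u_\alpha u_\beta - \delta_{\alpha\beta})/2$,
  with $D_{\max} = S_{am} D_{stat}$ the static splitting scaled into the
  residual regime by the order parameter of the alignment medium
  ($S_{am} = 0.004$ by default: a 47.96 kHz static one-bond C–H splitting
  becomes at most 191.84 Hz). All nine tensor components are constrained:
  the measured RDC is the $zz$ component of a diagonal target tensor
  $\mathrm{diag}(-D_{exp}/2, -D_{exp}/2, D_{exp})$ and the off-diagonal
  targets are zero, which is what forces the simulated molecule to tumble —
  a static orientation cannot zero the off-diagonal averages.
* **NOE distances**, averaged as $\bar r = \langle r^{-6}\rangle^{-1/6}$.
* **Vicinal couplings** $^3J_{HH}$ through the substituent-corrected
  Karplus relation
  $J(\phi) = P_1\cos^2\phi + P_2\cos\phi + P_3 + \sum_i
  \Delta\chi_i\,[P_4 + P_5\cos^2(\xi_i\phi + P_6|\Delta\chi_i|)]$,
  averaged directly (the mean of $J$, not of $\cos\phi$ moments).

## Exponential-memory averaging

Every observable is averaged over the running trajectory with an
exponential memory of time constant $\tau$:

$$\langle D(t)\rangle = \frac{1}{N(t)}\int_{t_0}^{t} e^{-(t-t')/\tau}
D(t')\,dt', \qquad N(t) = \int_{t_0}^{t} e^{-(t-t')/\tau}\,dt'.$$

Discretised per step this is the recursion
$N \leftarrow N e^{-\Delta t/\tau} + \Delta t$,
$S \leftarrow S e^{-\Delta t/\tau} + D\,\Delta t$, mean $= S/N$, applied
componentwise to tensors. $\tau$ sets the lifetime of an orientation:
after $5\tau$ less than 1% of the original weight remains, and the
pseudo-forces respond on the same timescale, which is what makes the
method behave like an accelerated exploration of conformational space.
The package default is $\tau = 200$ ps; the bundled synthetic benchmark
runs with $\tau = 100$ ps over 2 ns so that the run contains many memory
lifetimes at desk scale (problem sizes below).

## Pseudo-forces

Forces, not energies, enter the integrator. For an RDC constraint the
force on atoms $i, j$ is

$$F = \mathrm{ramp}(t)\,k \sum_{\alpha\beta}
f\!\left(\langle D_{\alpha\beta}\rangle - D^{exp}_{\alpha\beta},\,
\Delta D\right)\frac{\partial D^{theo}_{\alpha\beta}}{\partial x},$$

with three deliberate properties:

* **Saturating scale.** $f(\delta, \Delta D) = \tanh(\delta/\Delta D)$
  replaces the harmonic deviation, so badly violated constraints exert a
  bounded force instead of tearing the structure apart. The width
  $\Delta D$ defaults to 0.5 Hz for RDCs (about the experimental error),
  0.25 Å for NOE, 0.5 Hz for $^3J$.
* **Orientational derivative only.** The derivative of the theoretical
  tensor is taken with the internuclear distance held fixed
  ($\partial u/\partial x_i = (I - uu^T)/r$), so RDC pseudo-forces on the
  two atoms are equal, opposite and perpendicular to the internuclear
  vector: they are pure torques, never bond stretchers. Long-range H–H
  RDCs are likewise used only orientationally, never as distance
  restraints.
* **Magnitude from memory, direction from geometry.** The tanh factor is
  evaluated on the *memory-averaged* deviation (means as of the previous
  integration step — an explicit, not implicit, coupling), while the
  derivative uses the instantaneous geometry, so an orientation mismatch
  acts immediately.

At the start of a run no memory means exist, so every pseudo-force is
ramped in as $1 - e^{-t/\rho}$ with $\rho = \tau$ by default.

Methyl groups are one constraint each: the observable is the arithmetic
mean of the three C–H bond tensors and the force is distributed over the
three protons with weight 1/3. A NOE to a methyl group applies the
identical constraint to each of the three protons with the full force on
each — with one-bond RDCs also active, methyls spin fast and the three
protons are equivalent on the memory timescale. (Whether the 1/3-weight
or full-force convention is used for methyl NOEs is a package choice,
documented here because reasonable codes differ.)

## The classical force field

The restrained engine needs an ordinary molecular mechanics backbone:
harmonic bonds and angles, cosine torsions
($E = \tfrac{V}{2}(1 + \cos(n\phi - \gamma))$), Lennard-Jones and
fixed-charge Coulomb terms with 1-2/1-3 exclusions, 1-4 scaling (0.5) and
a 12 Å cutoff (no switching: these are vacuum simulations of small
molecules, well inside the cutoff). Partial charges are fixed numbers read
from the topology table. Units are Å, ps, u and kJ/mol throughout
(1 u Å² ps⁻² = 0.01 kJ/mol); the Boltzmann constant in these units is a
single named constant. Forces are the exact analytic negative gradient;
the test suite verifies them against central finite differences to 10⁻⁶
relative on batches of random conformations.

Integration is velocity Verlet with a Berendsen weak-coupling thermostat
(default 313 K, coupling time 0.5 ps, scaling clamped to [0.8, 1.25]).
This thermostat does not sample a strict canonical ensemble; that is an
accepted trade here because the method targets time-averaged observables,
not canonical statistics. The default time step is 0.5 fs, comfortably
below the ~12 fs period of the stiffest C–H stretch. Initial velocities
are Maxwell-Boltzmann draws from R's RNG under the run's single master
seed with centre-of-mass motion removed, which makes every run bit-for-bit
replayable.

## Evaluation criteria

RMS deviations discard the measurement error and cannot be compared across
data types, so quality is judged with error-aware criteria:

* $\chi^2 = \sum_i ((P^{theo}_i - P^{exp}_i)/\sigma_i)^2$ and the quality
  $n/\chi^2$, which exceeds 1 when the data are reproduced within their
  errors on average;
* the outlier criterion $1/\chi^2_{min} = \min_i (\sigma_i/\Delta_i)^2$,
  which exceeds 1 only when even the worst datum is inside its error;
* the fidelity $\mathcal{F}$, the fraction of valid data. A deviation
  exactly at the error bound counts as valid (strict inequality defines an
  outlier) — the boundary convention is a package decision;
* the RDC Q factor, $\mathrm{rms}(calc - obs)/\mathrm{rms}(obs)$
  (Cornilescu convention; other programs normalise differently, so
  cross-program Q comparisons are convention-sensitive).

Reports are computed per data type (one-bond RDC, long-range RDC, NOE,
$^3J$) and pooled over the raw vectors for the overall row — never by
averaging averages. The reported "theoretical" value of each datum is the
mean over retained snapshots of its memory-averaged observable; snapshots
are recorded every 5 ps by default after an equilibration drop (1 ns by
default) that discards the ramp-up period.

## The SVD baseline

For comparison with the classical analysis, `fit_saupe()` solves the
linear RDC equations for the five Saupe components
$(S_{zz}, S_{xx}-S_{yy}, S_{xy}, S_{xz}, S_{yz})$ by singular-value
decomposition (unweighted by default; 1/error weighting by flag — MSPIN's
weighting convention is not published, so ours is a documented choice),
reporting back-calculated RDCs, Q, the criteria above, singular values and
the condition number. `multi_conformer_fit()` extends this to several
conformers sharing one tensor by scanning population vectors on a simplex
grid (step 0.05) and returning the $\chi^2$-best fit; a grid search is
used instead of nonlinear optimisation because the intended analysis space
(a handful of rotamers) is tiny and the grid is exactly reproducible.
Fewer than five RDCs is an explicit underdetermined error; singular values
below $10^{-10}$ of the maximum attach a rank-deficiency warning (the
planar-vectors case).

## Ensemble analysis

`torsion_series()` extracts signed dihedrals (IUPAC convention, cis = 0°,
no unwrapping); `rotamer_populations()` bins them into trans
($|\omega| \ge 120°$), gauche(+) ($0 < \omega < 120°$) and gauche(−)
($-120 < \omega \le 0°$) — boundaries at ±120° and 0° are the natural
three-fold choice and a package decision. `dpca()` performs principal
component analysis on dihedrals mapped to the unit circle,
$z_j = e^{i\phi_j}$: the Hermitian covariance of the mean-centred $z$ is
diagonalised, dihedral contributions are the moduli of eigenvector
entries, and each snapshot projects onto component $n$ as the single angle
$\theta_n = \arg \sum_j v^*_{nj} z_j$. Whether the original complex-dPCA
variant projected through complex arguments or real linear combinations is
ambiguous in the literature; the complex-argument form is implemented
because it respects circular topology, and it is the documented extension
point.

## The synthetic benchmark

Real applications of this method used proprietary experimental datasets
and DFT geometries that cannot be redistributed, so the package carries
its own fully synthetic acceptance surface:

* `make_toy_molecule("single-rotor")` builds a 20-atom
  2,3-dimethylbutane-like molecule: two semi-rigid methine fragments, four
  methyls, 14 protons, and exactly one soft torsion (3-fold, 6 kJ/mol —
  hopping is fast at 313 K) connecting them; methyl torsions are kept
  stiff (18 kJ/mol) so the rotor is the single slow degree of freedom.
* `generate_reference_ensemble()` draws frames with the rotor sampled from
  a von Mises mixture at 180°/−60°/+60° (concentration κ = 50, ≈ 8°
  spread) with requested weights — the study condition is 70% trans / 30%
  gauche(−) — plus 0.02 Å Gaussian jitter. The fragment holding the first
  rotor atom keeps a fixed orientation; that frame hosts the imposed
  alignment tensor.
* `synthesize_constraints()` forward-models the tables: RDCs as ensemble
  averages of $D_{stat}(u^T A u)$ under one common Saupe tensor
  (defaults $(4, 2.5, 1, 0.5, 1.5)\times 10^{-4}$, i.e. a few Hz for C–H),
  NOE targets as ensemble $\langle r^{-6}\rangle^{-1/6}$, $^3J$ as
  ensemble-averaged Karplus values; Gaussian noise (0.3 Hz / 0.1 Å /
  0.3 Hz) and error floors of 1.0 Hz / 0.5 Å / 1.0 Hz chosen to match
  realistic experimental uncertainty. The mix — 6 one-bond RDC constraints
  (2 methine + 4 methyl), 8 long-range H–H RDCs, 7 NOEs, 5 couplings —
  mirrors the shape of a small-molecule dataset.

The single common alignment tensor across conformers is exactly the
simplification the tensor-free method is designed to avoid; it is used
here deliberately because it makes the forward model linear and the
ground truth known. Under strong shape–alignment coupling in real data,
recovery differences are expected behaviour, not bugs. Likewise the
generator does not emulate vibrational averaging, anisotropic solvent
friction or measurement systematics, so passing the benchmark shows the
estimator machinery is self-consistent — not that any real molecule's
populations would be recovered with the same accuracy.

### Recovery benchmark and calibration

The flagship property: synthesize tables from the 70/30 reference, run the
restrained simulation from a trans starting structure, and re-measure the
rotamer fractions. At desk scale we run 2 ns per seed (0.5 fs steps,
τ = ρ = 100 ps, snapshots every 1 ps, first 0.5 ns dropped) for three
seeds; these sizes keep the full test suite within a coffee break while
still covering ~15 memory lifetimes per run.

The pseudo-force constants are the one genuinely free calibration — no
published value exists for the conversion constant $k$ — and they were set
by this benchmark: `k_rdc = 0.12` kJ mol⁻¹ Hz⁻¹, `k_noe = 60` kJ mol⁻¹ Å⁻¹
at saturation, `k_j = 6` kJ mol⁻¹ Hz⁻¹. Weaker RDC constants leave the
tensor averages unconverged at the 2 ns scale; much stronger ones distort
the structure (mean force-field energy rises) and wash the rotamer
distribution toward uniformity. At the chosen values the three-seed runs
reproduce all four data types with $n/\chi^2 > 1$, the worst datum within
about one error bound, and seed-averaged fractions around 0.67/0.21/0.12
against the 0.70/0.30/0.00 truth — inside the ±0.10 acceptance band, with
the residual gauche(+) occupancy reflecting the intrinsic degeneracy of
mean-valued constraints rather than a force imbalance.

## Degenerate inputs and numerical choices

* Dihedral gradients are undefined for collinear central bonds; this is a
  hard error naming the frame, not a silent skip.
* Nonbonded pairs closer than 0.1 Å raise a singularity error; integrator
  blow-ups (non-finite or runaway coordinates) abort with the step, the
  worst atom and its force norm.
* The tanh scale is evaluated with `std::tanh`, safe for arbitrarily
  large arguments.
* The transformation matrix completing the internuclear z-axis starts
  from the Cartesian axis with the smallest vector component; any
  completion yields the same lab tensor, this one is deterministic.
* $\chi^2 = 0$ reports quality `Inf` as an explicit sentinel.
* Memory means are undefined before the first update (`memory_mean()`
  errors); inside the engine, constraints exert no force until their first
  update, and the ramp makes that moot.
* Long-range H–H static splittings are computed from the starting geometry
  ($240.2/r^3$ kHz·Å³ convention) and then frozen, so the forward model
  and the restrained run use identical $D_{\max}$ values.

## Known limitations

* The classical force field is a lightweight stand-in with fixed charges;
  it is adequate for the synthetic benchmark and for method development,
  not for quantitative conformer energetics of real molecules.
* Berendsen weak coupling biases kinetic-energy fluctuations; population
  estimates rest on the pseudo-force steering, not on canonical sampling.
* Only RDC, NOE and $^3J_{HH}$ constraint classes exist; residual
  chemical-shift anisotropy and quadrupolar couplings are out of scope, as
  are periodic boundaries, solvent boxes and Ewald electrostatics.
* One alignment scaling $S_{am}$ applies to all RDCs of a run.
* `dpca()` implements the standard complex formulation; adapted variants
  can be layered on top of the returned eigensystem.
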