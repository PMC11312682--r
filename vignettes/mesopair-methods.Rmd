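---
title: "Pair interaction energies, coordination numbers and DPD repulsions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pair interaction energies, coordination numbers and DPD repulsions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesopair)
```

## The model

The quantity at the center of this package is the intermolecular
interaction energy $E_{ij}^{C}(r)$ of two rigid monomers $i$ and $j$ at
center separation $r$ in a relative spatial configuration $C$. It is a
sum over all intermolecular atom pairs of a van der Waals term and a
point-charge electrostatic term; intramolecular terms are omitted
because they cancel exactly in dimer-minus-monomer differences as long
as the monomers are rigid. Two model families are supported:

* a **generic model** — Lennard-Jones 12-6 with Lorentz–Berthelot (or
  geometric) combination and plain Coulomb electrostatics
  ($C = 332.0637$ kcal·Å/(mol·e²)), parameterized from a bundled
  per-atom-type table for the fixture molecules; and
* an **MMFF94 backend** — the buffered 14-7 vdW form with the published
  buffering constants 0.07/0.12, MMFF94's own pairwise combination
  rules, bond-charge-increment charges and buffered Coulomb
  ($r + 0.05$ Å denominator, $C = 332.0716$). Typing, charges, pairwise
  vdW parameters and all-atom local minimization are delegated to RDKit
  through a small `python` helper; the package evaluates all sampling
  energies itself from the returned parameter matrices. A useful
  subtlety: with the published buffers the analytic minimum of the 14-7
  term sits a fraction of a percent inside $R^*$; the value at $R^*$
  is exactly $-\varepsilon$.

For each distance, a minimum configuration energy
$E^{C^*}(r)$ and a Boltzmann-weighted average
$\langle E \rangle(r) = \sum_C E_C w_C / \sum_C w_C$ with
$w_C = e^{-(E_C - E_{\min})/k_BT}$ are reported. The weights are
reference-independent (a constant shift cancels between numerator and
denominator); the per-batch minimum is subtracted for numerical
stability, which is mathematically equivalent to any other reference.

## Configuration sampling

Both monomers are centered, a unit sphere around each center is covered
with an `n_sphere`-point golden-angle Fibonacci lattice
($z_k = 1-(2k+1)/n$, azimuth $k\,2\pi(1-1/\varphi)$), and for every
ordered pair of lattice points both molecules are rotated (by the
minimal rotation, with a fixed fallback axis in the antiparallel
degenerate case) so the two points and both centers are collinear.
Molecule $j$ is then additionally spun about the axis in `n_rot` equal
steps — molecule $i$ is deliberately *not* spun, so the count is exactly
$n_{sphere}^2 \, n_{rot}$ (331,776 at the defaults 144/16). Equal
minimum energies are resolved toward the lexicographically smallest
(point$_i$, point$_j$, spin) index, making reruns deterministic.

Design choices worth recording:

* **Molecular center.** The center convention defines what "distance"
  means. Both the unweighted geometric center and the center of mass are
  supported; the *geometric center* is the default because it is the
  convention under which the reference acetic acid dimer reproduces its
  published center distance of 4.91 Å (the cyclic dimer's center-of-mass
  separation is 3.90 Å — the two conventions are easily distinguished).
* **Distance refinement.** The coarse 3–16 Å / 0.5 Å scan is refined by
  re-scanning ±0.5 Å around the incumbent at 0.1 Å and then ±0.1 Å at
  0.01 Å. The windows are one coarse step around the incumbent: the
  refined grid always contains the incumbent, so the refined minimum can
  never be worse. Ties go to the smallest grid distance.
* **Final optimization and the meaning of `e_min`.** The sampled
  minimum `C*` is locally optimized either over the 6 relative
  rigid-body degrees of freedom (Nelder–Mead on the interaction energy)
  or with an unconstrained all-atom MMFF94 minimization in which the
  monomers may deform. In both cases the reported `e_min` is the
  *intermolecular* pair energy at the optimized geometry — not the
  total-energy difference against relaxed monomers — because the
  pipeline's interaction energies are non-bonded intermolecular
  quantities throughout; for the all-atom backend the two differ by the
  monomer strain energy.
* **Initial monomer orientation.** Input-file orientation is used as-is
  and recorded; the sampled minimum depends on it only at the scale of
  the lattice spacing ($\approx \sqrt{4\pi/n_{sphere}}$ rad, 17° at
  n = 144).

## Coordination numbers from MD

Box construction ties every species to the water reference: one water
molecule has a VABC van der Waals volume of 17.35 Å³ and occupies
30.00 Å³ in the liquid at 298 K (from its density and molar mass), and
every molecule $X$ is given the same occupied-to-vdW volume ratio, so a
box of $N$ molecules has edge
$a = \sqrt[3]{N \cdot (30.00/17.35) \cdot V_{vdW}^X}$. VABC volumes are
atomic contributions minus 5.92 Å³ per bond and ring corrections
(14.7 aromatic / 3.8 non-aromatic, counted from the bond graph; the
bundled fixtures have none).

The solvent is packed on a jittered cubic sublattice with random
orientations followed by a deterministic rigid-body push-apart until no
intermolecular atom pair is closer than 1.5 Å; the solute replaces
overlapping solvent (any atom within 0.8 of the vdW-radius sum). The
box is then energy-minimized (L-BFGS on the analytic gradient, no
cutoff — a truncated potential is discontinuous at the cutoff and
breaks line searches) and integrated with velocity Verlet at 1 fs,
minimum-image periodic boundaries, a 9 Å non-bonded cutoff (no
long-range correction) and an Andersen thermostat that redraws atom
velocities from the Maxwell–Boltzmann distribution at 25 ps⁻¹ per atom
(the collision rate is a free parameter of the thermostat; this value
equilibrates small aqueous boxes in a few picoseconds without
overdamping). Intramolecular geometry is held near the input conformer
by stiff harmonic bond and 1-3 distance restraints
(k = 300 kcal/mol/Å²) — full bonded force-field terms are intentionally
out of scope, and the restraint frequencies remain stable at the 1 fs
step. All randomness (packing, insertion, initial velocities,
thermostat) flows from one seed, so trajectories are bit-reproducible.

Neighbor counting implements the inclusive criterion — molecules are
neighbors when *any* atom pair is within the Bondi radius sum plus the
catch radius (default 1 Å, "less than or equal to") — twice: a
brute-force double loop and a cell-index method whose cells are at
least as large as the largest threshold, so scanning the 27 neighboring
cells is exhaustive and the two counts are *identical by construction*,
which the test suite verifies on large ensembles of random frames.
Boxes shorter than three cells fall back to brute force with a notice.
The coordination number $Z_{ij}$ is the mean per-frame count; the
running mean is exported as a convergence series.

Default protocol sizes follow the reference conditions (400 solvent
molecules, 10,000 equilibration + 400,000 production steps, frames
every 100 steps). The full water-box protocol is an hours-scale
computation; the test suite instead runs the same code path on reduced
boxes (tens of molecules, hundreds of steps) plus the exact
cell-index/brute-force equivalence, and checks integrator sanity
(energy conservation without thermostat, kinetic temperature with it).
What the reduced runs do *not* establish is the converged value of
$Z_{ij}$ for realistic liquids under this restrained-geometry MD — that
is a validation-scale question, deliberately not asserted by the tests.

## Mesoscopic mapping

With the symmetric energy matrix ($E_{ij} = E_{ji}$) and the generally
asymmetric coordination matrix ($Z_{ij} \ne Z_{ji}$), the
coordination-weighted differential pair energy is
$\Delta E_{ij}^Z = \tfrac12(Z_{ij}E_{ij} + Z_{ji}E_{ji}) -
\tfrac12(Z_{ii}E_{ii} + Z_{jj}E_{jj})$, the Flory–Huggins parameter is
$\chi_{ij} = \Delta\langle E_{ij}\rangle^Z / k_BT$, and the DPD
repulsion is $a_{ij}(T) = 75\,k_BT/\rho_{DPD} + 3.4965\,k_BT\chi_{ij}$
(the coefficient is the reciprocal of 0.286, carried at full precision
internally and rounded to 4 decimals where quoted). Three conventions
needed fixing:

* **Thermal-energy units.** $k_BT$ in the repulsion mapping is
  expressed in units where $k_B \cdot 300\,\mathrm{K} = 1$; this
  reference reproduces the standard diagonal $a_{ii} = 75/3 = 25$ at
  300 K and the quoted 24.83 at 298 K ($25 \cdot 298/300$). The
  reference temperature is a configurable knob recorded in exported
  metadata.
* **DPD density.** $\rho_{DPD} = 3$, the standard Groot–Warren value.
* **Off-diagonal scaling.** $a'_{ij} = a_{ii} + s\,(a_{ij} - a_{ii})$
  with $s$ chosen so the smallest off-diagonal lands exactly
  `max_deviation` (default 20) away from the diagonal; the affine map
  preserves the ranking of repulsions, the diagonal is forced to its
  nominal value, and the pair attaining the minimum is recorded as the
  scaling base pair. A matrix whose off-diagonals all equal the
  diagonal has no defined scale and is rejected. A `zij_one` switch
  builds the variant that ignores coordination numbers
  ($Z_{ij} \equiv 1$).

The conservative DPD force $a_{ij}(1-r)\,\hat r$ for $r<1$ (zero at and
beyond the cutoff, continuously) is exposed as a standalone kernel;
dissipative/random forces and actual DPD integration are out of scope.

## Synthetic inputs and what the tests show

The seven bundled fixtures (water, methane, ethane, methanol, ethanol,
dimethyl ether, acetic acid) are MMFF94-optimized monomer geometries
stored as plain Tinker-XYZ text with generic atom-type labels; the
bundled table gives them OPLS-flavoured LJ parameters and charges
(water is TIP3P). They are real molecular geometries, not caricatures,
but the generic table is deliberately simple: no lone-pair sites, no
polarization, no torsional flexibility. Tests built on them exercise
every code path at realistic parameter magnitudes; they do not certify
force-field accuracy, which enters only through the parameter source.
Test problem sizes are chosen so the whole suite runs in seconds:
sampling lattices of 4–16 points in unit tests (the full 144-point
lattice where the check is about the default itself), solvent boxes of
8–64 molecules, MD runs of a few hundred to 10,000 steps.

## Numerical choices and limitations

* Units: kcal/mol, Å, fs, amu, elementary charges;
  $k_B = 1.987204259 \times 10^{-3}$ kcal/(mol·K). The
  force-to-acceleration conversion is $4.184 \times 10^{-4}$
  Å/fs² per (kcal/mol/Å)/amu.
* Dimer sampling uses no distance cutoff (finite systems, exactness is
  affordable); MD truncates at 9 Å without long-range corrections.
* Batch configuration energies are evaluated in compiled code over
  precomputed rotated coordinates; the scalar R implementation of the
  same pair sum is the reference in tests (agreement to 1e-10).
* The rigid-body optimizer is a derivative-free local search; it
  polishes `C*` and is not a global method — globality comes from the
  exhaustive lattice, up to lattice resolution.
* Monomer conformer search (torsional/global) is out of scope: inputs
  are taken as pre-optimized conformers, with only local optimization
  provided.
* Restrained-geometry MD approximates fully flexible force-field MD;
  its effect on coordination numbers is unquantified here and is the
  main caveat when comparing $Z_{ij}$ against fully bonded simulations.
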