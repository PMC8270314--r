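---
title: "Pseudoatom electrostatics: model, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudoatom electrostatics: model, numerics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudoatomES)
```

## The model

pseudoatomES evaluates electrostatic interaction energies between groups
of atoms (ligand vs. protein, chain vs. chain) from a molecular charge
density reconstructed atom-by-atom with the Hansen–Coppens pseudoatom
formalism. Each atom k contributes

$$\rho_k(r) = P_c\,\rho_{core}(r) \;+\; P_v\,\kappa^3 \rho_{valence}(\kappa r)
\;+\; \sum_{l=0}^{l_{max}} \kappa'^3 R_l(\kappa' r)
\sum_{m=-l}^{l} P_{lm}\, y_{lm}(\theta,\varphi),$$

where $\rho_{core}$ and $\rho_{valence}$ are spherical one-electron
densities (sums of normalized Slater functions), $R_l$ are
unit-normalized Slater radial functions, $y_{lm}$ are real spherical
harmonics in *density normalization* ($\int |y_{lm}|\,d\Omega = 2$ for
$l>0$, $y_{00}=1/4\pi$), and $P_c, P_v, \kappa, \kappa', P_{lm}$ are the
transferable parameters. In density normalization a deformation
population $P_{lm}$ directly counts electrons moved between the lobes of
its harmonic, which is what makes the parameters transferable between
chemically equivalent atoms and is why that convention is
non-negotiable here. Populations are defined in a local, per-atom
coordinate frame derived from the bonded neighbors, so one databank
entry can be applied to any orientation of the same chemical fragment.

A practical note on $\kappa$: because the normalization prefactor of a
Slater function is a pure power of its exponent, the scaling
$\kappa^3\rho(\kappa r)$ is implemented *exactly* by replacing every
$\zeta$ by $\kappa\zeta$; no separate scaling code path exists, hence no
approximation.

### Interaction energies: exact inner region, multipoles outside

For two atoms the electrostatic interaction is the Coulomb integral of
their total charge distributions (point nucleus plus electron cloud).
The package evaluates it with a hybrid scheme:

* **Inner region** (interatomic distance $\le$ `cutoff`, default 4.5 Å):
  the full integral. The potential of one pseudoatom is closed-form —
  regularized incomplete gamma functions for every spherical and
  deformation component — and is integrated against the partner's
  electron density on a spherical quadrature grid whose radial and
  angular orders are doubled until the energy changes by less than `tol`
  (default $10^{-5}$ hartree). Accuracy is therefore a contract, not a
  property of a fixed grid.
* **Outer region**: a Buckingham-type point-multipole expansion. Atomic
  multipole moments up to $l_{max}$ (default 4) are obtained in closed
  form from the populations; every interaction-tensor term with
  $l_i, l_j \le l_{max}$ is included, each decaying as
  $R^{-(l_i+l_j+1)}$.

The **charge penetration energy** of an inner pair is
$E_{pen} = E_{exact} - E_{multipole}$; outer pairs have $E_{pen}=0$
identically. Penetration is the physics the point-charge and plain
multipole pictures miss when electron clouds interpenetrate, and
profiling it is precisely what identifies residue pairs in direct
contact.

A classical **point-charge model** ($\sum q_iq_j/r_{ij}$, no cutoff) is
provided for contrast; with all $P_{lm}=0$ the multipole expansion
reduces to it exactly, which is tested.

### Units

Internally bohr and hartree throughout; interfaces take angstrom and
report kJ/mol (1 hartree = 2625.4996 kJ/mol, 1 Å = 1.8897259886 bohr).
Energies are accumulated in hartree and converted once at reporting.

## Parameters that matter

| parameter | unit | default | why |
|---|---|---|---|
| `cutoff` (inner/outer split) | Å | 4.5 | per-atom-pair distance criterion; the customary inner-region radius for exact-potential hybrid schemes |
| `tol` (exact integral) | hartree | 1e-5 | quadrature orders double until the energy moves less than this |
| `lmax` | — | 4 | hexadecapole, the customary databank truncation; entry data may lower it |
| connectivity tolerance | Å | 0.4 | bond iff $d \le r_{cov,i}+r_{cov,j}+0.4$, standard structure-perception slack |
| H-bond `d_max` / `theta_min` | Å / ° | 3.5 / 120 | conventional geometric criterion; deliberately user-adjustable because real contacts can sit slightly beyond textbook distances |
| `epen_threshold` (contacts) | kJ/mol | 0.1 | must be $>0$: inner-pair energies carry quadrature noise below this, while true overlap signals sit well above |

The cutoff is interpreted per atom pair (not per residue pair); that is
the standard reading of an exact-potential/multipole split and the only
one that makes $E_{pen}$ a sum of well-defined pair quantities.

## Local frames, rotations and rigid-motion invariance

Frames are built deterministically: z toward the highest-priority
neighbor (priority: higher Z, then shorter bond, then lower serial), x
in the plane of the next reference (for terminal atoms, a neighbor of
the neighbor), y completing a right-handed system; near-collinear
references (within 5°) are skipped, with a global-axis fallback.
Rotation matrices for the real harmonics are obtained by least-squares
projection on a fixed 64-direction spherical point set — exact to
numerical precision for any $l$, and immune to the sign-bookkeeping
errors that plague transcribed recursion tables. The Buckingham
interaction-tensor constants are likewise extracted numerically, once,
by expanding the irregular solid harmonic of one center in regular
harmonics about the other (the projection is exact because the potential
is harmonic there), and are anchored in tests by closed-form
charge–charge and dipole–dipole cases.

Two implementation choices make energies invariant under rigid motion of
the whole structure to far better than the 1e-6 kJ/mol requirement: the
quadrature grid of each inner pair is oriented by the pair axis plus a
partner-frame reference (so it co-rotates with the structure), and its
center is chosen as the more compact of the two densities (also making
the (A,B) and (B,A) computations bit-identical).

## Aggregation and ensemble statistics

Atom-pair energies sum exactly into residue- and chain-level matrices
(labels `chain:resno:resname`); marginal sums reproduce coarser levels
to floating-point accuracy, which is asserted rather than assumed. Over
a multi-model ensemble the package reports per-entry means and sample
standard deviations ($n-1$ denominator — snapshots are a sample of a
trajectory) and formats them in the crystallographic `mean(SD)` style,
with the SD expressed in units of the mean's last reported digit.
Hydrogen bonds are detected per snapshot (donor/acceptor in {N, O, S})
and summarized as occupancy fractions with mean geometry over the
present frames only.

## What the synthetic generator emulates — and what it does not

`make_ensemble()` reproduces the *statistical structure* of an MD
snapshot ensemble: one shared topology, per-frame Gaussian positional
jitter (default $\sigma = 0.05$ Å, small enough that perceived
connectivity is stable across frames), and hydrogen bonds whose
presence follows a planted per-frame schedule (bonded frames at
donor–acceptor 2.9 Å / 170°, unbonded frames at 4.5–5.5 Å). Seeds are
mandatory and the generators never touch the caller's RNG stream, so
every artifact is a pure function of (spec, seed).

It deliberately does **not** emulate: correlated or kinetic motion,
force-field energetics, solvation, counterions, or conformational
transitions. Consequently, green tests demonstrate that the
*electrostatics engine and statistics* are correct on controlled
inputs; they say nothing about force-field quality or sampling of real
trajectories, and the toy databank's single-Slater parameters are
chemically plausible but not fitted to any reference density.

The toy bank covers water, a formamide-like peptide unit, methanol and
the Li⁺/Cl⁻ pair, with per-molecule net charges that are exactly zero
before normalization; a `neutral_atoms` variant zeroes every atomic
charge while keeping multipoles, which is what the long-range
consistency checks use (neutral polar pairs isolate the dipole and
higher terms).

## Numerical choices and degenerate inputs

* Incomplete-gamma closed forms (`pgamma`) for all radial potentials and
  moments; deformation radial powers must satisfy $n \ge l$ so the
  outer Poisson integral converges (enforced on load).
* Electron–electron quadrature: Gauss–Legendre radial map
  $r = r_0 t/(1-t)$ with $r_0 = 2.5/\zeta_{min}$, Gauss–Legendre in
  $\cos\theta$ × uniform azimuth; start orders 24/10/20, doubling to
  convergence (angular capped at 48 to bound cost; a warning is raised
  if the tolerance is not met).
* Charge normalization scales valence populations uniformly,
  $P_v \leftarrow P_v(\Sigma P_v + \Delta)/\Sigma P_v$, and errors out
  rather than producing negative populations.
* Ties and degenerate frames: neighbor priority falls back to serial
  order; isolated atoms get identity frames with a warning (irrelevant
  for spherical ions, which skip frame perception entirely).
* Altlocs: highest occupancy wins, ties alphabetically. Waters/ions are
  kept on read but excluded from bare-chain selections unless named
  explicitly or `keep_solvent = TRUE`.
* Atom indices are 1-based throughout the R interfaces (PDB serials are
  carried separately); R's native indexing avoids a class of
  off-by-one translation errors that a 0-based internal convention
  would invite in this language.

## Design choices where the design was open

* **Local symmetry** for atom typing is approximated by the neighbor
  multiset plus a planarity flag for 3-connected atoms (least-squares
  plane residual ≤ 0.1 Å). This captures the sp²/sp³ distinction that
  dominates transferability; full site-symmetry recognition is out of
  scope and documented as such.
* **Reference core/valence densities and $l_{max}$** are properties of
  each databank entry (single-Slater toys suffice for the built-in
  bank); the engine is exact for whatever the entry carries.
* **Bank format**: a versioned, line-oriented text format (`PABANK 1`)
  with one block per atom type; readers reject unknown versions,
  duplicate keys and non-positive exponents.
* **Snapshot spacing** is recorded only as provenance; no spacing rule
  is imposed on ensembles.
* **H-bond criterion**: the geometric defaults above, configurable,
  since occupancy bars in trajectory analyses imply a per-snapshot rule
  that is rarely stated explicitly.

## Problem sizes used in the shipped checks

The test-suite and acceptance script run entirely on the synthetic
toys: water dimers (9 inter-group pairs), a 25-atom two-chain +
ligand complex, a 14-atom charged-contact complex, ensembles of 3–100
frames (energy evaluation on the smaller ones, geometric occupancy on
the 100-frame one), and ~20-frame ensembles in the acceptance script.
These sizes were chosen so every quantity the checks assert —
convergence of the exact integral, exact recovery of planted schedules,
bit-level determinism — is measured, not extrapolated.

## Known limitations

* Electrostatics only: exchange-repulsion, induction and dispersion are
  other components of an interaction energy and are out of scope, as is
  any periodic/Ewald treatment.
* No parameter refinement: the databank is an input; the package never
  fits populations to structure factors or densities.
* No protonation assignment, no trajectory formats (ensembles arrive as
  multi-model PDB), no aromaticity perception beyond the planarity flag.
* Improper (chirality-inverting) operations on populations are refused
  rather than handled.
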