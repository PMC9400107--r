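---
title: "Pseudoatom data banks: model, typing engine and parametrization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudoatom data banks: model, typing engine and parametrization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taamkit)
```

## The model

A pseudoatom is an atom-centered electron-density unit

$$\rho(\mathbf r) = \rho_{core}(r)
 + P_{val}\,\kappa^3\,\rho_{val}(\kappa r)
 + \sum_{l=0}^{l_{max}} \kappa'^3 R_l(\kappa' r)
   \sum_{m=-l}^{l} P_{lm}\, d_{lm}(\hat{\mathbf r}),$$

with a frozen spherical core, a spherical valence shell whose population
$P_{val}$ and radial scale $\kappa$ are adjustable, and an aspherical
deformation expansion over density-normalized real spherical harmonics
$d_{lm}$ with Slater-type radial functions
$R_l(r) \propto r^{n_l} e^{-\zeta_l r}$ contracted by $\kappa'$.
Non-hydrogen atoms carry terms to the hexadecapole level
($l_{max} = 4$); hydrogen stops at the quadrupole ($l_{max} = 2$) and
only its bond-directed $(1,0)$ and $(2,0)$ functions are ever refined.
The monopole population defines the atomic charge
$q = n_{val} - P_{val}$.

A *data bank* stores these parameters not per atom but per **atom
type**: a colored connectivity graph (central atom plus neighbor shells,
each vertex colored by element set, neighbor count, group planarity and
ring membership), a local-coordinate-system definition, a point-group
symmetry label, and parameter values averaged over many chemically
equivalent atoms together with their sample standard deviations — the
transferability metric.

## Conventions that matter

**Harmonic normalization.** The $d_{lm}$ are density-normalized:
$d_{00}$ integrates to 1 over the sphere and $\int |d_{lm}|\,d\Omega = 2$
for $l \ge 1$, so a unit population shifts one electron between lobes.
The conversion constants from unit-normalized harmonics were computed
once by high-accuracy quadrature and frozen into the source
(`taamkit:::.dlm_norm`); a quadrature test re-verifies them.

**Rotation of populations.** Populations transform within each $l$
block.  Rather than hard-coding recursive rotation-matrix formulas, the
block matrices are obtained by collocation: evaluate the $2l+1$
harmonics on a fixed quasi-uniform direction set, evaluate them again on
the rotated directions, and solve the exactly-determined least-squares
system.  Because the harmonics span an invariant subspace per $l$ the
result is exact to solver precision (the tests bound it at $10^{-10}$,
observed near machine epsilon).  One subtlety: since the $d_{lm}$ norms
differ across $|m|$ within one $l$, the bare sum $\sum_m P_{lm}^2$ is
*not* invariant under rotation — the conserved quantity is the
function-space norm $\sum_m (c_{lm} P_{lm})^2$ with $c_{lm}$ the
normalization constants, and that is what the tests assert.

**Selection rules.** Symmetry-forbidden populations are determined by a
group-averaging projector: for each point group the generator matrices
(in this package's documented standard orientation — principal axis
along $z$, one mirror through the $xz$ plane, cubic 4-fold axes along
the Cartesian axes, the 3-fold along $(1,1,1)$) are closed into the full
finite group, the representation matrices are averaged, and an index is
allowed when $d_{lm}$ has nonzero projection onto the invariant
subspace.  This reproduces the hand-derived tables (9 indices for
`mm2`, 7 for `3m` at $l_{max}=4$) and extends uniformly to the cubic
groups, where invariant combinations mix $(4,0)$ and $(4,4+)$.  The
conical site symmetries `cyl` (infinite rotation axis plus vertical
mirrors: all $(l,0)$) and `cylinf` (additionally a horizontal mirror:
even $l$ only) are represented by a 16-fold proxy rotation, which is
exact for $l \le 4$.  Mirrors enter only through the projector;
`rotate_plm()` deliberately rejects improper matrices.

**Radial models.** Deformation exponents and powers default to standard
single-$\zeta$ values per element, with the third-row hypervalent
choices $n_l = (2,4,6,8)$ for sulfur and $(6,6,6,6)$ for phosphorus
($l = 1..4$).  All lengths are Å and exponents Å$^{-1}$; values quoted
in bohr$^{-1}$ in the literature are converted at the table boundary.
The spherical core and valence densities are built from single-$\zeta$
Slater shells (Slater-rule screening for the core, twice the
Clementi–Raimondi orbital exponent for the density); this is a
documented approximation, and `spherical_atom_density()` accepts
external shell tables so multi-$\zeta$ tabulations can be plugged in
without code change.  The $\kappa'$ scaling follows the standard
convention $\kappa'^3 R_l(\kappa' r)$, which preserves the radial
normalization $\int R_l r^2 dr = 1$ for every $\kappa'$.

## The typing engine

An atom type compiles to a rooted colored graph.  Matching an atom asks
for an injective mapping of that graph into the molecular graph sending
the root to the atom, preserving edges and satisfying every color.  The
engine delegates the subgraph-isomorphism search to igraph's LAD solver
with per-vertex candidate domains computed from the colors; same-ring /
different-ring relations are verified afterwards against the perceived
rings, as a second stage.  A brute-force enumeration over all injective
mappings serves as the test oracle (200+ randomized colored graphs per
run, both generators seeded).

Matching semantics that the format fixes explicitly:

* the central atom's neighbor count is exact (its listed bonds are its
  whole first shell, as bank entries preserve first-neighbor counts);
  other vertices match subgraph-wise unless an `NB` color pins their
  degree;
* absent descriptors are wildcards (`planar any`, `rings any`,
  element `X`);
* `planar yes`/`no` require a defined planarity, so atoms with fewer
  than three neighbors (planarity undefined) only match `any`;
* `different_ring` requires both atoms to be ring members sharing no
  ring; `same_ring` requires at least one shared ring.

Assignment tries bank entries in file order and keeps the first match,
so detailed types must precede their generalizations; the pairwise
generality audit `check_entry_order()` flags violations.  The cluster
needed for matching is grown by breadth-first search to the bank's
maximum type-graph depth (`bank_depth()`), expanding across periodic
images when a cell is present.

**Structure perception.** Bonds follow the covalent-radii criterion
$d \le r_A + r_B + 0.4$ Å with a shipped single published radii set
(configurable).  Hydrogens that acquire two bonds this way — short
hydrogen bonds read as covalent — keep only the shortest bond and are
reported, so strongly hydrogen-bonded moieties are still typed as their
parent groups.  Ring perception is a smallest-set-of-smallest-rings
construction (candidate shortest cycles per edge, greedy GF(2)
independence) capped at nine-membered rings; planarity of a ring or of
an atom-plus-neighbors group means an RMS deviation of at most 0.1 Å
from the least-squares plane.  The 0.1 Å value is this package's fixed,
documented criterion — the descriptor needs *a* threshold to be testable
and transferable, and 0.1 Å cleanly separates aromatic rings from
puckered ones in the fixture set.  X–H distances are reset to averaged
neutron values (context-keyed configuration table) by moving the
hydrogen along the existing bond vector.

## Parametrization by structure-factor fitting

Bank parameters are recovered from *theoretical* valence-only structure
factors: the density of a model molecule is Fourier-sampled on the
reciprocal lattice of a cubic P1 cell with 30 Å edges up to
$\sin\theta/\lambda < 1.1$ Å$^{-1}$ (about $1.2\times10^6$ reflections),
and the Hansen–Coppens parameters are fitted by least squares.  The
Fourier–Bessel transforms $\langle j_l\rangle$ of the Slater radial
functions are evaluated in closed form — term-by-term Laplace transforms
of the trigonometric expansion of $j_l$, switching to the ascending
series in $(b/a)$ at small momentum transfer where the trig form cancels
catastrophically — and match adaptive quadrature to $10^{-13}$.

The refiner minimizes $\sum_h |F_{calc} - F_{target}|^2$ with complex
residuals, which for theoretical P1 targets is equivalent to
constraining phases to the calculated ones while being much simpler to
implement.  Gradients are fully analytic (population derivatives are
linear; $\kappa$ and $\kappa'$ derivatives reduce to the same closed
form with the Slater power raised by one).  The damped least-squares
iteration is delegated to MINPACK's Levenberg–Marquardt
(`minpack.lm::nls.lm`) with tight tolerances and a 100-iteration cap,
positivity bounds on the screening parameters, and an upfront QR rank
check that names the undetermined parameters when the normal matrix is
singular (for example $\kappa'$ of an atom with no deformation terms).
Constraint groups implement chemically-equivalent-hydrogen sharing of
$\kappa$ and $\kappa'$; per-site symmetry labels restrict the refinable
populations to `allowed_indices()`, and hydrogen sites additionally to
$(1,0)$ and $(2,0)$.  Unit weights are used throughout — the targets are
noise-free theoretical amplitudes.

At full resolution the water fixture's parameters are recovered from a
neutral spherical start to machine precision (the acceptance suite
asserts $10^{-3}$; observed $\sim10^{-17}$), which is the expected
behavior for an identifiable model with exact targets.

## Averaging and transferability

Per-atom instances are first re-expressed in the type frame
(`reorient_instance()` applies the population rotation
$R_{type}^{\mathsf T} R_{instance}$), then averaged arithmetically;
sample standard deviations use the $n-1$ denominator and are zero by
definition for a single instance.  Indices outside the entry's selection
rules are forced to zero after averaging, so small symmetry-breaking
leaks in individual refinements do not accumulate into the bank.  The
quality verdict compares every ssd against the transferability bounds —
0.1 e for $P_{val}$ and $\kappa'$, 0.01 for $\kappa$, 0.05 e per
$P_{lm}$ — and entries expected to vary strongly (delocalized bonding,
rare types) can opt out via an `allow_loose` flag while still listing
their violations.  The accept/redefine loop itself is a human decision;
the package automates the measurable part and emits machine-readable
verdicts.

The charge–screening regression (`q_kappa_analysis()`) fits
$\kappa$ and $\kappa'$ against $q$ by ordinary least squares per element
class (hydrogen, non-hydrogen, each element), requiring at least three
entries per class; $R^2$ is defined as zero for a constant response.

## The synthetic fixtures

The catalog molecules (methane, ethane, water, hydronium, benzene,
naphthalene, cyclopropane, nitromethane, perchlorate, PF$_6^-$, and a
toy P1 chain crystal whose bonds cross the cell boundary) are idealized
geometries from embedded constants — exact bond lengths and angles, no
thermal smearing, no disorder, no experimental coordinate noise.  The
noisy instance generator draws parameters around entry means with stated
Gaussian sigmas and applies random proper rotations to the instance
frames, emulating the frame diversity of real refinements but not their
correlated errors.  Tests passing on these fixtures therefore establish
the correctness of the algorithms — format round-trips, matching,
rotation, selection rules, transforms, recovery — and not the
statistical behavior of the pipeline on experimental crystal structures,
where disorder, missing hydrogens and basis-set limitations dominate.

## Numerical choices and problem sizes

* Rotation/projector exactness asserted at $10^{-10}$; observed at
  machine epsilon.
* Electron-count conservation via adaptive radial quadrature,
  $10^{-3}$ e bound.
* The structure-factor/FFT duality check runs water in an 8 Å cell on a
  $72^3$ grid to $\sin\theta/\lambda < 0.45$ Å$^{-1}$, comparing at
  $10^{-3}$ relative; the aliasing floor of that grid is
  $\sim10^{-4}$.
* The full-resolution recovery uses the complete 30 Å /
  1.1 Å$^{-1}$ grid; unit-test refinements use reduced cutoffs
  (0.6–0.7 Å$^{-1}$, 12 Å cells), which are already overdetermined for
  a three-atom model by orders of magnitude.
* Ties in ring selection are broken by lexicographic atom order, making
  perception deterministic under atom permutation (assignment
  determinism is property-tested).
* Degenerate frames (collinear axis targets within $10^{-6}$) and
  overlapping atoms (closer than 0.3 Å) are hard errors, not warnings.

## Known limitations

* Scattering assumes a cubic P1 cell — the theoretical parametrization
  protocol — and static densities with unit occupancies; it is not an
  experimental-data refinement engine.
* The built-in spherical atom densities are single-$\zeta$; quantitative
  work should supply better shell tables through the provided interface.
* Ring perception caps at nine-membered rings, and macrocycles beyond
  that are invisible to ring colors.
* Single-atom ions cannot be expressed as connectivity-based types (a
  one-vertex graph matches any atom of that element); such species need
  the bank-order convention or dedicated handling, as discussed for
  halide anions in the bank literature.
* `cyl`/`cylinf` selection rules are exact only to $l = 16$, far above
  the supported $l_{max} = 4$.
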