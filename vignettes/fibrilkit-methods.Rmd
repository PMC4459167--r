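---
title: "Methods: hydrogen bonding, adhesion and mechanics of cell-wall polymer models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hydrogen bonding, adhesion and mechanics of cell-wall polymer models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilkit)
```

# Scope and model

Plant fibres owe their mechanics to a composite architecture: stiff
cellulose microfibrils embedded in a matrix of hemicellulose and lignin,
crosslinked into a lignin--carbohydrate complex (LCC). fibrilkit
implements the analysis layer such studies run on atomistic
configurations of these materials: hydrogen-bond network statistics and
energetics, non-bonded interfacial energy decomposition, radial
distribution functions, virial-stress elastic moduli, glass-transition
extraction from specific-volume curves, and the composition algebra that
connects component densities to composite properties. It does not
contain a molecular-dynamics engine or a force-field parameterisation:
inputs are static configurations or pre-computed frame series, read from
extended XYZ or a PDB subset plus a topology sidecar.

Internal units follow force-field convention — Angstrom, kcal/mol, amu,
elementary charges — with SI conversions centralised in `fk_units`
(1 kcal/mol = 6.9477e-21 J; Coulomb constant 332.0637 kcal·Å/(mol·e²);
kcal/mol/Å³ = 6.9477 GPa; kcal/mol/Å² = 694.77 mJ/m²; amu/Å³ =
1.66054 g/cc). Lennard-Jones parameters are stored in the r_min
(equilibrium-distance) convention,
$V(r) = \varepsilon\left[(r_m/r)^{12} - 2 (r_m/r)^6\right]$, because the
stiffness analysis differentiates at $r_m$; σ-form inputs are converted
on read ($r_m = 2^{1/6}\sigma$). Atom indices are 1-based throughout, as
in R and in the PDB records the package reads; nothing external to R
imposes 0-based indexing here.

# Hydrogen bonds

Detection is purely geometric: a donor hydrogen (an H covalently bound to
O or N — bonds are explicit input, never guessed from distances, so
donor identification cannot drift with a heuristic) and an acceptor O or
N form a bond when the H···A minimum-image distance is at most 2.5 Å and
the donor–H–acceptor angle is at least 120°. The distance criterion
applies to H···A, not donor–acceptor. All qualifying acceptors per
hydrogen are reported by default (the criteria are a definition, not an
assignment); `unique_per_h` keeps the lowest-energy partner when a
one-bond-per-hydrogen census is wanted.

Energies use the 12–10 CHARMM/DREIDING-style form
$$E = D_{hb}\left[5\left(\tfrac{R_{hb}}{R_{DA}}\right)^{12} -
6\left(\tfrac{R_{hb}}{R_{DA}}\right)^{10}\right]\cos^p\theta_{DHA},$$
with defaults $D_{hb} = 4$ kcal/mol, $R_{hb} = 2.75$ Å (literature-typical
O···O values) and $p = 4$. The angular exponent is configurable (2 or 4)
because the two conventions coexist in the literature; no result in this
package's tests depends on the default parameter values, only on the
functional form's fixed points ($E(R_{hb}, 180°) = -D_{hb}$, node at
90°). The volumetric energy density is $\sum_i |E_i| / V$ in J/m³, an
intensive quantity under supercell duplication. Cooperativity chains
follow the rule that a bond is strengthened when its donor oxygen also
accepts a bond: a directed graph on bonds (edge $i \to j$ when donor of
$i$ = acceptor of $j$) whose maximal simple paths of two or more bonds
are the chains.

The closed-form stiffness of a single hydrogen bond modelled as an LJ
well is $k = V''(r_m) = 72\,\varepsilon/r_m^2$; with
$\varepsilon = 1.2\times10^{-20}$ J and $r_m = 1.85\times10^{-10}$ m this
gives 25.24 J/m².

# Non-bonded energies and adhesion

Pair energies are Lennard-Jones plus Coulomb point charges under the
minimum image; covalently bonded (1–2) pairs are excluded from all
non-bonded sums. Mixing rules are configurable (`sixth_power`, the
COMPASS-family default, or `lorentz_berthelot`); every oracle check
supplies per-pair-compatible parameters so no conclusion rests on the
rule choice. The default is *no* cutoff: at the desk scales this package
targets, exact all-pair sums are affordable and make oracle equivalence
bit-meaningful; an optional untruncated-shift cutoff exists for
sensitivity checks. There is no Ewald summation — electrostatics is a
direct sum, defensible for vacuum-slab geometries and net-neutral groups
at test scale, and stated here as a limitation. Direct minimum-image
sums without a cutoff are also not exactly extensive (a larger supercell
admits longer pairs), which is why the extensivity test pins a cutoff
below half the original cell.

Adhesion follows the energy identity
$E_{adh} = E_{tot} - (E_{mat} + E_{sub})$, which for pairwise-additive
potentials on a *fixed* configuration equals the cross-group pair sum
exactly; the package verifies this identity against an independently
coded double-loop oracle rather than assuming it. Intra-group relaxation
during dynamics, which contributes to ensemble-averaged adhesion
energies, is out of scope. Per-area values divide by one interface area
(not two), taken from the lateral box cross-section by default, and are
reported in mJ/m² with attraction as positive adhesion while signed raw
energies are retained.

# Structure

RDFs histogram minimum-image pair distances, normalised by the
$4\pi r^2\,dr$ shell, the partner number density and the reference count,
so $g \to 1$ for homogeneous systems; self-pairs are excluded when the
two selections coincide, frames are equal-weighted, and $r_{max}$ is
capped at half the smallest box dimension. Defaults ($dr = 0.05$ Å)
resolve sub-Å features such as the ~1.85 Å hydrogen-bond contact and the
~3.25 Å O–O second-neighbour distance. Peak detection uses topographic
prominence (default 0.1 in g-units; ties broken toward smaller r).
Axial concentration profiles normalise bin counts to mean 1 over
occupied bins, the convention used when comparing the exposure of
surface O–H and C–H hydrogens.

# Mechanics

The virial stress of a static configuration is the potential part only,
$$\sigma_{ab} = \frac{1}{V} \sum_{pairs} \frac{V'(r)}{r}\, r_a r_b,$$
which equals $+\frac{1}{V}\,\partial E/\partial\varepsilon$ for an
incremental affine strain about the *current* state — the continuum,
tension-positive convention, under which stable lattices have positive
moduli. The kinetic term is omitted deliberately: inputs are minimised
snapshots, not thermal ensembles, and this deviation from
finite-temperature NPT sampling is a documented modelling choice.
Young's modulus is the least-squares slope of axial stress against
engineering strain over an affine series (default 1% maximum strain in
10 steps plus the unstrained reference), fitted *with* an intercept so
residual pre-stress of an imperfectly relaxed reference does not bias
the slope; frames with non-finite stress are rejected and counted.

# Glass transition and composition

The glass transition is the breakpoint of a continuous two-segment
linear fit to specific volume vs temperature: grid search over interior
data temperatures, refined to 0.1 K, with the outer 10% of the
temperature range excluded so boundary-dependent breakpoints are never
reported, and a no-transition flag when the hinge improves a single
line's SSE by less than 5%. Rule-of-mixture density is
$\rho = (r_{LH}\rho_L + \rho_H)/(r_{LH} + 1)$, and the unit-count ratio
follows from equating the volume ratio:
$N_L/N_H = r_{LH}\,(\rho_L/\rho_H)\,(M_H/M_L)$. The diffusion-time
budget uses the one-dimensional mean-squared-displacement convention
$t = x^2/(2D)$ — the stated assumption behind the ~1.2 ns settling
estimate for a 0.5 nm mobile layer at $D = 10^{-10}$ m²/s.

# Synthetic systems and what passing tests show

Every analysis is exercised on generated configurations whose ground
truth comes from an *independent* oracle, never from the module under
test:

- `gen_hydroxyl_box` places C–O–H donor/acceptor fragments realizing
  sampled (H···A, angle) geometries — defaults 1.88 Å / 150.96°, the
  typical short, strong hydrogen bonds of hydroxyl-rich polymer glasses —
  with rejection sampling (pair centres ≥ 4 Å, any cross-fragment contact
  ≥ 2.7 Å) so no accidental contact can satisfy the detection window.
  The three-atom fragment exists so donor identification runs on a
  carbon skeleton, and hydroxyl density is a free parameter: real
  materials differ exactly in that density.
- `gen_bilayer` builds two non-overlapping random slabs, periodic in
  x,y only (vacuum-slab geometry, laterally a few nm as in surface
  studies), each slab charge-neutralised as a molecular layer would be;
  its interface energy is a scalar double-loop sum recorded with its
  vdW/electrostatic split.
- `gen_strain_series` produces a harmonic simple-cubic lattice
  (analytic modulus $E = k/a$) and an LJ FCC lattice whose ground truth
  is the least-squares slope of finite-difference stresses computed from
  energies only ($h = 10^{-4}$) at the same strain points — forces and
  energies are two independent routes to the same number.
- `gen_cooling_curve` draws 48 random temperatures over 100–700 K (the
  sampling style of a slow cooling ramp with snapshots at random steps)
  on a continuous two-slope curve, default break 450 K, glass/melt
  expansivities 2e-4 / 5e-4 cc/g/K about a 0.74 cc/g transition volume,
  Gaussian noise 0.002 cc/g.
- `gen_surface_slab` pins hydroxyl and alkyl hydrogens at two heights
  (defaults 18.3 and 19.8 Å, jitter 0.1 Å) for the profile analysis.

All generators draw from a single explicitly seeded RNG stream and are
bit-reproducible; the user's RNG state is restored afterwards.

These systems emulate the *statistical structure* the analyses assume —
contact geometry distributions, slab topology, affine strain, two-slope
thermal response. They do not emulate chemically realistic lignin or
xylan conformers, force-field-equilibrated packing, finite-temperature
ensembles, or cooperative polarisation. Passing tests therefore
demonstrate that the estimators recover known ground truth under their
stated assumptions, not that any particular material value (a modulus in
GPa, a Tg, a per-face adhesion energy) is reproduced; those depend on
equilibrated structures outside this package's scope.

# Numerical choices and degenerate inputs

Minimum-image displacements use the canonical fractional wrap refined by
a 3×3×3 neighbour search, so the true nearest image is returned even for
strongly skewed triclinic boxes (where plain rounding can pick a
non-nearest image). Energy sums run in a fixed, deterministic order, and
`total = vdw + elec` holds bit-exactly by construction. Coincident atoms
raise a degenerate-geometry error naming the pair rather than returning
infinities. Problem sizes are chosen for exactness at interactive speed:
boxes of a few hundred atoms, 20-frame trajectories, 50-replicate Monte
Carlo ensembles — the full test suite runs in well under a minute.

# Known limitations

No Ewald electrostatics; no kinetic virial term; no bonded terms beyond
the harmonic springs the lattice generators need; adhesion identities
hold for fixed configurations, not relaxing ensembles; the 12–10
hydrogen-bond parameters are literature-typical defaults, not fitted
constants; the PDB reader honours only ATOM/HETATM/CRYST1/CONECT.
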