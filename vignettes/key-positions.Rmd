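---
title: "Key positions for ligand-binding conformational diversity: model and methods"
author: "confkeys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Key positions for ligand-binding conformational diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question

Under conformational selection, a protein's native state is an ensemble of
conformers in dynamic equilibrium, and a ligand binds by shifting that
equilibrium toward its highest-affinity conformer. The ligand-free
conformer's intramolecular vibrations must therefore already contain the
unbound-to-bound transition. `confkeys` asks: which residues, if mutated,
would most disrupt the vibrations that carry that transition? Those residues
— the *key positions* — sustain the protein's functional conformational
diversity and are candidates for evolutionary conservation, independently of
whether they touch the ligand.

## The elastic network

Each conformer is reduced to its C-alpha trace and modeled as a network of
harmonic springs at the crystallographic equilibrium geometry. Spring
constants encode chemistry rather than a single uniform stiffness:

| pair type                              | constant   |
|----------------------------------------|------------|
| covalent neighbors (sequence adjacent) | `gamma`    |
| disulfide bridge (SG-SG <= 2.5 A)      | `gamma`    |
| hydrogen bond / salt bridge, within `r_c` | `0.1 gamma` |
| any other pair within `r_c`            | `0.01 gamma` |

Hydrogen bonds and salt bridges are detected by geometric rules (any N/O
atom pair at <= 3.5 A; opposite-charge side-chain N/O pairs at <= 4.0 A),
an internal, reproducible approximation to contact-classification programs.
Covalent and disulfide springs are not distance-gated; the two weak classes
are. `gamma` is a pure scale: every downstream quantity is either a rank
correlation or computed from normalized eigenvectors, so `gamma = 1`
throughout and no mass weighting is applied.

The 3N x 3N Hessian of the pairwise potential is assembled from the standard
anisotropic-network blocks `k_ij (r_hat r_hat^T) / 1` and diagonalized.
A connected, non-collinear network has exactly six zero eigenvalues (rigid
translations and rotations); the remaining 3N - 6 eigenpairs are the
internal modes. Null modes are identified by a relative threshold
(`1e-8 * max(lambda)`, configurable); more than six null modes means a
disconnected or mechanically floppy network and is treated as an error
naming the components, not silently tolerated — under-constrained networks
produce spurious zero-frequency "motions" that would corrupt every
downstream stage.

Theoretical B-factors are the inverse-eigenvalue-weighted sums of squared
mode components per residue, times `8 pi^2 / 3` (and `k_B T = 1`). The
cutoff `r_c` is calibrated per structure by scanning 7-20 A in 0.5 A steps
and maximizing the Spearman correlation between theoretical and experimental
B-factors; ties break toward the smaller cutoff (sparser network). The 0.5 A
step is a package choice — the calibration curve is flat near its optimum,
so finer grids change nothing but runtime. Since only the profile *shape*
is model-determined, `theoretical_bfactors(..., scale_to =)` can rescale a
profile to the experimental mean; this mirrors the role of `gamma` as the
constant matching theory to experiment and matters wherever B-factors enter
nonlinearly (see the weighting below).

## The binding subspace S

The two conformers are superposed by least squares over mapped C-alphas and
the displacement is damped per residue by `exp(-(B_free + B_bound) * w)`:
flexible, poorly resolved regions (loops, termini) should not define the
direction of the conformational change. The damping scale `w` defaults to
0.01 per-A^2, appropriate for crystallographic B-factor magnitudes (tens of
A^2); by default the theoretical profiles of each conformer's own network
(rescaled to the experimental mean) are used, with a switch for experimental
B-factors. The weighted difference is normalized and expanded on the
ligand-free internal modes, `c_k = v . q_k`.

Superposition leaves a small residual rigid-body component in `v`; the
coefficients are renormalized over the internal-mode span and the discarded
fraction is reported, which keeps the participation number
`P = 1 / sum(c_k^4)` inside `[1, 3N - 6]` as its interpretation requires.
`P` is the effective number of modes carrying the change: 1 when a single
mode dominates, 3N - 6 when the change is spread over everything. The
subspace **S** is the `M = ceiling(P)` modes with the largest squared
coefficients (exact ties break toward the lower mode index). The same
machinery applied to the per-residue B-factor profile (replicated over each
residue's three coordinates and unit-normalized — without that normalization
the participation number is ill-scaled) yields `P_B` and the flexibility
subspace **S_B**.

Mode collectivity `kappa = exp(H) / N`, with `H` the Shannon entropy of the
per-residue squared amplitudes, quantifies how many residues a mode moves:
1 for a uniformly distributed mode, 1/N for a single-residue mode. (The
printed convention is the standard one; the package follows the formula, so
*uniform* modes score 1.)

## Perturbation scan and the Gramian score

A point mutation at residue `i` is simulated by scaling every spring
incident to `i`: `k_ij -> k_ij (1 + delta_gamma)`. The perturbation is
multiplicative by design: an additive change of -0.05 gamma would drive the
weak generic springs (0.01 gamma) negative and destroy positive
semi-definiteness, while the multiplicative form preserves the class ratios
and PSD for either sign. `delta_gamma` defaults to 0.05 and results are
stable across 0.01-0.1 (a property the test suite checks by rank-correlating
profiles at the two extremes).

Perturbation reorders and mixes near-degenerate modes, so perturbed modes
cannot be identified by eigenvalue rank. The one-to-one correspondence is
recovered by maximizing the summed squared overlaps between the two internal
mode sets, solved exactly as a linear assignment problem (an O(n^3)
shortest-augmenting-path solver in compiled code, verified against
exhaustive permutation enumeration in the tests). The assignment is computed
over the full internal space so it is globally consistent; only the images
of **S** are consumed.

The perturbed image **S^i** is compared to **S** through the Gramian of the
projections of the perturbed modes onto span(**S**): `zeta = sum(lambda_G) / M`,
1 for identical spans, 0 for orthogonal ones. Numerically `zeta` equals
`sum((q^i_j . q_k)^2) / M`, and the eigenvalue route is cross-checked
against that trace identity; Gramian eigenvalues are clipped to `[0, 1]`
at a 1e-9 tolerance. `zeta` is computed at `+delta` and `-delta`
(mutations can stiffen or soften local packing), averaged, and standardized
across residues into `ZscoreS` (mean 0, sd 1). Key positions are the
`ceiling(0.05 N)` residues with the lowest `ZscoreS` — the ceiling is what
makes a 125-residue protein yield exactly 7 key positions and a 183-residue
one exactly 10 — with boundary ties broken toward the lower residue index.

Because low-frequency modes are collective, scores are also read as spatial
regions: `neighbor_average()` replaces a residue's value by the mean over
all residues within 7 A. The package ranks key positions on the raw
`ZscoreS` and uses the averaged profiles for correlations with conservation;
both choices are switchable (`rank_averaged` in the run configuration), as
the two readings answer slightly different questions (single-site mutation
vs. regional importance).

## Conservation

Alignments (aligned FASTA or Stockholm; the structure's sequence is the
reference row) are filtered to rows covering at least 80% of the reference
columns, with a warning when 100 or fewer homologs survive — correlations
against conservation are then underpowered. Sequence redundancy is corrected
with position-based weights: in each column a sequence receives
`1 / (r * s)` (r = distinct residue types, s = copies of its own type), gap
cells contribute nothing, and per-sequence sums are normalized. Per column,
the weighted amino-acid frequencies (gaps excluded and renormalized; columns
over 50% gapped are flagged low-confidence) give a normalized entropy
conservation index `1 - H / ln 20`, standardized over structure-mapped
positions into `Zscore_evol` (higher = more conserved). The published
description of the entropy measure leaves the exact weighting variant open;
position-based weighting plus weighted Shannon entropy is the documented
choice here. The headline analysis is the Spearman correlation between the
7 A-averaged `ZscoreS` and `Zscore_evol` profiles, expected negative when
dynamically critical positions are conserved.

## Characterization

Incidence ratios compare relative frequencies among key residues to the
remaining residues: by amino-acid type, by DSSP 8-letter secondary
structure, and — for residues on strands and helices — by participation in
contacts bridging to a *different* secondary-structure element of each type.
For the inter-element table the denominator is the like-with-like frequency
(non-key residues on X with a contact to Y, among non-key residues on X);
the published definition is ambiguous on this point and the choice is
recorded here. Cells with empty denominators are reported as undefined
(`NA`), never as numbers.

Relative orientation changes between contacting elements are measured from
the principal axes of each segment's C-alpha gyration tensor: for each of
the three axes, the angle between the X and Y axes is computed in both
conformers (axes sign-disambiguated into `[0, 90]` degrees) and the largest
absolute change is reported — "largest difference" is read as the maximum
over the three axis pairs. Distances to active sites are Euclidean distances
from each C-alpha to the C-alpha centroid of each site, minimized over
sites. Solvent accessibility uses DSSP output files with an embedded
extended ALA-X-ALA tripeptide reference table (theoretical maxima of Tien et
al. 2013); residues at >= 10% relative accessibility count as exposed.
Contact counts use heavy atoms at 5 A with sequence separation >= 2.
DSSP itself is consumed, not reimplemented; a coarse C-alpha-distance-based
fallback assigner exists for synthetic fixtures only and is labelled
approximate.

## Synthetic fixtures and what they show

`synth_fixture()` generates conformer pairs with known ground truth:

* **Geometry.** The two-domain topology places two compact self-avoiding
  bead clusters (~110 A^3 per residue) facing each other across a ~6 A
  interface, joined by a short curled linker — a clamshell. This shape was
  chosen deliberately: a long single-strand bridge between *separated*
  domains is an under-constrained mechanism in a central-force network
  (constraint counting leaves 1-3 zero-energy modes), whereas the clamshell
  is rigid and its softest internal modes are genuine inter-domain motions
  whose elastic strain concentrates in the linker/interface region. Helix
  pairs and single globules are also available. Fixture networks use
  `r_c = 12` A.
* **Planted displacement.** The bound conformer is the free one displaced
  along chosen internal modes (defaults: modes 1 and 2, amplitudes
  0.4/0.28 A — the soft bend/twist pair of the clamshell) plus a random
  rigid transform to exercise superposition. Internal modes are orthogonal
  to the rigid-body span, so the expansion recovers the planted subspace to
  machine precision at these amplitudes.
* **B-factors.** The network's own profile rescaled to a mean of 30 A^2
  (typical crystallographic magnitude) plus seeded Gaussian noise (default
  20% of the profile spread), floored at a small positive value.
* **Coupled MSA.** Per column, the substitution probability is
  `plogis(2 * coupling * z + noise)` of the standardized score profile, so
  low-scoring (key-like) positions are conserved. Rows are sampled
  independently; the reference row is preserved.

Random streams are separated per component (geometry, rigid transform,
B-noise, MSA) so changing one leaves the others bit-identical; everything is
a deterministic function of the fixture spec.

The ground-truth recovery analyses (and the acceptance script) run the scan
at `w = 0`: the fixture's displacement lies exactly in the low-mode span and
its coordinates carry none of the crystallographic loop/terminus noise the
Gaussian damping exists to suppress, so damping would only reorient the
planted direction. With `w = 0.01` on fixtures, the reoriented vector drags
one arbitrary localized mode into **S**, whose near-degenerate mixing then
dominates the zeta variance — an artifact of planting an exactly two-mode
change, not of the method. On real pairs, where the displacement is never
exactly low-mode and coordinate noise is real, the default `w = 0.01`
stands.

What the fixtures do *not* emulate: real side-chain packing and hydrogen-bond
networks (pseudo-atoms are placed randomly around each bead, so the typed
contact classes are exercised but not chemically meaningful), realistic
secondary structure (except the ideal helix pair), sequence evolution along
phylogenies, and crystallographic artifacts beyond Gaussian B-factor noise.
Passing the fixture suite therefore demonstrates the correctness of the
machinery and the recoverability of planted signal, not performance on real
proteins.

Problem sizes in the test suite — 40-60 residues, 10-20 seeds per stochastic
property, 100-150 alignment rows — are the package's chosen desk-scale
conditions: large enough that hinge regions, interfaces and conservation
statistics are meaningful, small enough that the full suite rediagonalizes
thousands of Hessians in about a minute.

## Numerical choices and degenerate inputs

* Null-mode threshold: relative `1e-8`; exposed as `tol` in the run config.
* `M = ceiling(P - 1e-9)` so that an exact `P = 1.0` yields `M = 1`.
* Zero conformational change, all-zero B-factor profiles, vectors entirely
  in the rigid-body span, constant score or conservation profiles, and
  all-gap columns are errors (or flagged `NA` cells), never silent zeros.
* A perturbation scan whose zeta profile has essentially zero variance
  (sd < 1e-10, e.g. on a fully symmetric toy) errors rather than emitting
  meaningless z-scores.
* Eigen-solver sign and degenerate-subspace arbitrariness are handled where
  they matter: assignment by squared overlaps, angles folded to `[0, 90]`
  degrees, participation numbers invariant to sign flips (tested).
* Altloc resolution: highest occupancy, ties toward the first altloc letter.
  Missing C-alpha B-factors are an error since calibration and weighting
  require them.

## Limitations

* C-alpha elastic networks linearize around one crystal structure; large
  conformational changes are represented by their initial direction only.
* The hydrogen-bond/salt-bridge rules are geometric approximations; real
  contact chemistry (bifurcated bonds, waters, aromatic interactions) is out
  of scope.
* The scan rediagonalizes the full Hessian per residue and sign (exact, not
  perturbative), so cost grows as N * (3N)^3; proteins of a few hundred
  residues are comfortable on a desktop, very large assemblies are not the
  target.
* Conservation scoring is alignment-quality-bound and phylogeny-blind;
  `Zscore_evol` inherits any bias in the homolog set.
* Multi-model NMR files use the first model; mmCIF is not parsed.
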