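---
title: "Building coarse-grained minimal cells with minicell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building coarse-grained minimal cells with minicell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`minicell` constructs molecular-resolution coarse-grained (CG) models of
minimal bacterial cells — the kind of starting structures needed for
whole-cell molecular dynamics. The pipeline mirrors how such systems are
assembled in practice: a circular chromosome is grown and relaxed inside
the crowded cell volume, the cytosol is filled by rigid-body packing,
a vesicle membrane is realized from a triangulated surface, and the whole
assembly is solvated and neutralized in a periodic box. Every stage is a
pure function of its inputs and a seed, so a configuration plus a master
seed determines the output bytes.

This vignette records the models, parameter choices and numerical
decisions behind each stage, in the spirit of a methods section.

## The chromosome model

### Continuum stage: a twistable worm-like chain

The chromosome is first represented at 10 bp per monomer as a closed bead
chain with bond length $l_0 = 3.4$ nm (10 bp at a 0.34 nm rise). Its
elastic energy is a standard discretization of the twistable worm-like
chain:

$$
E = \sum_i \frac{k_s}{2}\,(|\mathbf{b}_i| - l_0)^2
  + \sum_i \frac{\kappa_b}{2 l_0}\,\theta_i^2
  + \sum_i \frac{\kappa_t}{2 l_0}\,\phi_i^2
  + E_{\mathrm{ev}} + E_{\mathrm{conf}},
$$

where $\mathbf{b}_i$ are bond vectors, $\theta_i$ the angles between
consecutive bonds and $\phi_i$ per-joint twist angles. Defaults are
$\kappa_b = 50\,k_BT\,$nm (the canonical 50-nm dsDNA bend persistence
length), $\kappa_t = 100\,k_BT\,$nm, and a stiff bond
$k_s = 100\,k_BT/\mathrm{nm}^2$. The excluded-volume term is a purely
repulsive quadratic ramp $\epsilon\,(1 - r/\sigma)^2$ below
$\sigma = 2.5$ nm — smooth at the cutoff, cheap to differentiate, and
sufficient for a builder whose output is later energy-minimized anyway.
Confinement is harmonic outside the confining radius; spherical obstacles
(ribosomes) contribute the mirrored harmonic penalty inside their radius.
All parameters are user-visible through `wlc_params()`.

On a regular $N$-gon the bend term evaluates to
$\kappa_b\,2\pi^2/(N l_0)$ exactly, which the test suite uses as a
closed-form anchor at $10^{-9}$ tolerance.

### Lattice growth

The initial conformation is a closed self-avoiding ring grown on a cubic
lattice (spacing $l_0$) inside the confining sphere, avoiding obstacle
spheres. Growth is Monte Carlo chain extension with two ingredients:

* a *feasibility constraint* — a new site is admissible only if its
  Manhattan distance to the start does not exceed the number of bonds
  still available, which (with an even ring length) guarantees the ring
  can still close;
* a *compactness bias* — candidate sites are weighted by
  $(1 + n_{\mathrm{blocked}})^{\alpha}$, where $n_{\mathrm{blocked}}$
  counts occupied or forbidden face neighbors. This fills pockets as it
  goes and produces compact, territorially organized conformations rather
  than swollen walks; $\alpha = 2$ by default.

Dead ends trigger retraction of the chain head (depth escalating with
consecutive failures) and, for persistent stalls, a full restart from a
fresh seed site. The grower routinely fills ~50–70% of the admissible
lattice sites, which is what a 5-kbp ring demands inside a 50-nm cell.
Contact-map scaling of the resulting ensembles is *reported* via
`contact_map()`, never enforced.

### Relaxation, interpolation, framing, backmapping

The lattice ring is relaxed by overdamped Euler–Maruyama Brownian
dynamics ($x \leftarrow x - (dt/\gamma)\nabla E +
\sqrt{2 k_BT\,dt/\gamma}\,\xi$). The default $dt = 10^{-3}$ keeps a free
bead's RMS step below $0.1\,l_0$ (enforced at construction), and any
single-step displacement exceeding $l_0$ aborts with a divergence error
rather than silently producing garbage. A short zero-temperature descent
follows the thermal run inside `build_cell()` so that thermal
penetrations of the confinement and obstacle margins are settled before
the next stage; at zero temperature the integrator is plain gradient
descent and the energy is non-increasing, which the tests check step by
step.

The relaxed chain is resampled to one point per base pair with a periodic
cubic spline, re-parameterized to uniform arc length (12-fold
oversampling of the spline, inverted by linear interpolation of the
cumulative chord length). Rotation-minimizing frames are then propagated
along the closed contour by the double-reflection method. Because the
path is closed, parallel transport returns with a holonomy mismatch; the
residual rotation about the tangent is measured at closure and
distributed linearly along the contour — the distribution that minimizes
the local distortion. On top of the corrected frames a uniform
equilibrium twist of $34.3^\circ$/bp (10.5 bp per turn, canonical B-DNA)
is applied.

Base-pair templates are idealized B-DNA-like bead layouts: per
nucleotide, three backbone beads (the first carrying the $-1e$ phosphate
charge) plus four side beads for purines and three for pyrimidines, so
every base pair contributes 13 beads and $-2e$, with both strands
antiparallel in the same template. The geometry was drawn for structure
building (all beads within 1.2 nm of the frame origin); no force-field
files were copied, and energetics are out of scope. After placement a
short capped steepest descent on bonds plus soft repulsion
(`minimize_clashes()`) removes residual clashes without disturbing the
helix.

## Cytosol packing

`pack()` performs random sequential insertion of rigid bead bodies:
uniformly random orientation (Shoemake quaternions), position uniform in
the region (or bias-weighted by a radial profile via rejection), accepted
only if every bead stays in the region and no bead approaches a placed or
obstacle bead closer than the contact threshold (0.47 nm, one CG bead
diameter, configurable). Collision queries run on a uniform spatial hash
grid with cell size equal to the threshold, the same compiled kernel used
for water carving and overlap certification. Failure to place a copy
within the trial budget is an error reporting the achieved volume
fraction — never silent under-filling. Large bodies (ribosome stand-ins,
complexes) are packed first and frozen as obstacles for subsequent
species, and ribosome positions may equally be supplied rather than
sampled.

`check_overlaps()` certifies packings: the default method is the
exhaustive $O(N^2)$ scan (the oracle), and the spatial-hash fast path
must agree with it — both are exercised against each other in the tests.

## The membrane

The vesicle surface is a subdivided icosahedron projected to the sphere;
Euler characteristic 2 and outward normal orientation are asserted for
every surface. Per-leaflet lipid counts come from the areas of the
surfaces offset by half the bilayer thickness along the normals:
$n_{\pm} = \mathrm{round}\!\big(A(R \pm t/2)/a_L\big)$, with area per
lipid $a_L = 0.60$ nm$^2$ and thickness $t = 4$ nm by default (typical
CG bilayer values; both configurable). How to balance leaflet counts on
curved membranes is genuinely unsettled in the field; the offset-area
rule is this package's stated convention.

Species are allocated by largest-remainder rounding (counts sum exactly
to the leaflet total and deviate from $n \times$ fraction by less than
one) and assigned to sites in a random permutation. Sites themselves are
dart-thrown on the offset surfaces, area-weighted over triangles, with a
minimum head–head spacing of $0.7\sqrt{a_L}$. The spacing factor
deserves a note: at one site per $a_L$, a minimum spacing of
$f\sqrt{a_L}$ corresponds to a disk coverage of $\pi f^2/4$, and random
sequential adsorption jams near coverage 0.547. A factor of 0.9 (coverage
0.64) can therefore never reach the required density; 0.7 (coverage 0.38)
places exact leaflet counts reliably while still preventing head-group
pile-ups. Membrane proteins are inserted before any lipid, at random
surface sites with random in-plane rotation and axis along the local
normal; each claims a cylindrical footprint of its in-plane bounding
radius plus 0.5 nm, and lipid darts are excluded by *lateral* distance to
the footprint axis (the darts live on offset surfaces, so a 3D distance
test would leak).

Lipid internal geometry uses packaged idealized templates — head, linker
and tail beads stacked along the local normal, cholesterol shorter,
cardiolipin doubly charged — with fully saturated tails, as the template
names indicate. Heads point outward on the outer leaflet and inward on
the inner one.

## Solvation and ionization

The periodic box is a rhombic dodecahedron (square-top GROMACS
convention): for image distance $d$, vectors $(d,0,0)$, $(0,d,0)$,
$(d/2, d/2, d\sqrt{2}/2)$ and volume $d^3\sqrt{2}/2$ — about 71% of the
bounding cube, the natural choice for a spherical solute. The image
distance is the cell diameter plus twice the padding.

Water is tiled on a simple cubic lattice at 8.33 beads/nm$^3$ (bulk
water, 33.3 molecules/nm$^3$, four molecules per CG bead), clipped to the
primitive cell, and carved against the solute at a 0.45 nm minimum
distance; periodic images of solute beads near the cell faces are
included in the carving so no water hides behind the boundary. Waters
are classified inside/outside the membrane mid-surface radius using
minimum-image distances. The lattice choice is immaterial because
positions are relaxed downstream.

Salt follows a water-count convention, stated explicitly because a target
like "135 mM" is ambiguous in a box partially filled by solute:
$n_{\mathrm{pair}} = \mathrm{round}(c \cdot 4 N_{\mathrm{water}}/55.5)$,
i.e. relative to the real-water count with the 55.5 M molarity of pure
water as reference. Neutralizing counterions are created by converting
the waters *nearest* to charged solute beads (within 1.5 nm, falling back
to random waters when exhausted) — placing the counter charge where the
chromosome and ribosomes are; salt pairs convert uniformly random
remaining waters. Each water is consumed exactly once and
$n_{\mathrm{Na}} - n_{\mathrm{Cl}} = -q_{\mathrm{solute}}$ is an exact
integer identity, so every finished build reports net charge zero.

## Orchestration and determinism

`build_cell()` runs the stages in the order chromosome → ribosomes →
cytosol → membrane → solvation, each stage's output becoming the next
stage's obstacles. The membrane is built before solvation so waters can
be classified against the mid-surface. Cross-stage geometry margins are
explicit: the cytosol packing region ends one contact threshold below the
inner leaflet surface, and the chromosome path is confined a further
2 nm inside so that template beads (up to 1.2 nm off-path) plus
relaxation drift stay clear. After assembly the packing contract is
re-checked globally on the solute with the spatial hash; distinct
non-lipid bodies below the threshold abort the build. Adjacent lipids in
a curved leaflet are the one sanctioned exception — deep in the tail
region of the inner leaflet, neighboring lipids of a fluid bilayer
legitimately brush below a threshold that was calibrated for packed
rigid bodies.

Every stochastic operation derives its stream from the master seed via a
stable string hash (`stage_seed()`), so inserting a stage never perturbs
another, and the same configuration and seed reproduce a build
byte-for-byte — the test suite asserts this on whole GRO files.
Provenance (seed and configuration hash) is embedded in the GRO title
line.

## What the synthetic generators emulate — and what they do not

The fixtures module generates random genomes (independent bases at a
target GC content), toy proteins (uniform bead blobs with the manifest
charge spread over beads), and complete mini-cell configurations. The
packaged 452-species proteome manifest reproduces the published
localization split of the minimal cell proteome (281 cytosolic, 63
transmembrane, 42 peripheral, 66 unknown); its species identifiers, copy
numbers, charges and structures are synthetic stand-ins, as is the
10-nm-scale ribosome blob. Passing tests therefore certify the
*construction machinery* — geometry, counting, determinism, contracts —
not the biological realism of any individual structure: real builds
inject real CG structures through the same manifest interface.

Desk-scale configurations shrink the problem, not the physics, with one
exception: the `tiny` (50-nm) configuration inflates the area per lipid
to 7.8 nm$^2$ so its vesicle carries the intended ~2,000-lipid budget; a
physical 0.60 nm$^2$ at that radius would need ~26,000 lipids. Full-scale
geometry (400-nm cell, 543-kbp genome, 0.60 nm$^2$) is accepted by the
same code paths but is not run in the test suite. The problem sizes the
suite does run — a 5-kbp ring in a 50-nm cell with 100 proteins and
~1.5 million waters, built twice for the byte-determinism check — were
chosen to exercise every stage at full fidelity in well under the
15-minute envelope a desk build should respect.

## Numerical notes

* **Bend gradients.** The angle-gradient formula degenerates as
  $\theta \to 0$; the implementation takes the $\theta/\sin\theta \to 1$
  limit explicitly, and the full gradient is verified against central
  differences in the tests.
* **Equipartition testing.** The bond-length variance of a stiff-spring
  ring recovers $k_BT/k_s$ only in *equilibrium*. A taut regular ring is
  far from it: its slow shape modes relax over thousands of sweeps and
  the taut geometry couples transverse entropy into bond stretch,
  inflating the variance by ~25% (confirmed with an independent
  Metropolis sampler during development). The parameter-recovery test
  therefore starts from a compact lattice ring, and uses a time step
  small enough that even the stiffest normal mode (eigenvalue $4k_s$ on
  a ring) carries negligible Euler discretization bias.
* **Ties and degenerate inputs.** Zero-length paths, repeated path
  points, empty manifests, zero-atom structures, all-blocked lattices,
  and insufficient solvent all raise classed conditions
  (`minicell_*_error`) rather than propagating NaNs.
* **GRO precision.** Coordinates are fixed-width `%8.3f` nm; round trips
  are lossless to 0.001 nm, and indices wrap modulo 100,000 with true
  indices kept in memory.

## Known limitations

No supercoiling or linking-number bookkeeping; no sequence-dependent
elasticity; no lipid sorting, fingerprints or leaflet asymmetry beyond
what configuration allows; no osmotic balancing of interior versus
exterior solvent; no force-field topologies — the output is coordinates
plus composition reports, for downstream tools to parameterize.
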