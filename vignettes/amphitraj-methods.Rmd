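---
title: "Methods: fingerprinting fatty-acid interactions with membrane proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fingerprinting fatty-acid interactions with membrane proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`amphitraj` analyses molecular-dynamics trajectories of membrane proteins
surrounded by amphipathic ligands — typically free fatty acids such as
docosahexaenoic acid (DHA, a 22:6 polyunsaturated fatty acid, PUFA) or
docosanoic acid (DA, its fully saturated 22:0 counterpart, SFA) — in a
phospholipid bilayer around a tetrameric voltage-gated channel. The
scientific question it serves is where and how the ligand's charged
carboxyl head group and lipophilic acyl tail engage the protein, and how
the tail's conformational disorder (set by its degree of unsaturation)
shapes those interactions. This vignette documents the model behind each
analysis, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the numerical choices a
maintainer should know about.

## Data model and conventions

All internal units are Angstrom and nanoseconds; conversion happens only
at the I/O boundary (GRO nm, DCD cell parameters). Boxes are orthorhombic;
triclinic input is rejected with an explicit message. Atom indices are
0-based in the atom table; residue ids are taken verbatim from the input
file, because published mutagenesis work refers to author numbering
(I325, R362, ...), so region maps are declared in file numbering. The
membrane normal is fixed to the z axis, the bilayer convention of the
systems this package targets; it is a parameter of
`order_parameters()` for other conventions.

Every distance in the package is a minimum-image distance
(`minimum_image_distance()`, `pairwise_min_image()`). Contact detection
uses exact vectorized all-pairs distance matrices rather than a cell
list: at the problem sizes this package is built for (10^2–10^3 atoms per
selection, 10^3–10^4 frames) the vectorized computation is faster in R
than an interpreted neighbor grid, and it is exact by construction. The
test suite nevertheless keeps the dual-route check, comparing against an
independent scalar triple-loop brute-force oracle on randomized
instances.

## Chain descriptors

**Deuterium order parameters.** For each tail carbon i,
S_CD(i) = ⟨(3 cos²θ − 1)/2⟩ with θ the angle between the C–H bond and the
membrane normal, averaged over frames, ligand copies and the carbon's
hydrogens. Bounds are −0.5 (bond perpendicular to the normal) and 1
(parallel); the isotropic average is 0. Explicit (pseudo-)hydrogens are
required by default; an optional fallback uses the C(i−1)→C(i+1) axis
when hydrogens are absent and flags the affected carbons in the output.
The strict definition through hydrogens is preferred because the
generator plants them exactly.

**Radius of gyration.** Unweighted over the tail carbon positions (C2 to
the terminal carbon): the measure targets the carbon tail's compaction,
so head oxygens are excluded and no mass weighting is applied; both
choices are recorded here because other conventions exist. Positions are
unwrapped relative to the first tail carbon before the Rg computation so
molecules split across the periodic boundary are handled.

**Head-to-tail distance.** The minimum-image distance between the
schema-designated head oxygen (O1 by default; carboxyl groups have two
oxygens, so one must be designated) and the terminal carbon. The summary
mean pools ligands and frames by default; `per_ligand = TRUE` averages
per-ligand means instead. Pooling is the default because the overall
time-and-copy average is the single-number summary used when contrasting
saturated and polyunsaturated chains.

## Contact analysis

A residue is in contact with a ligand *part* (head = carboxyl oxygens +
C1; tail = C2..C22) in a frame when the minimum atom–atom minimum-image
distance is ≤ the distance cutoff (default 3.5 Å). A (residue, part) pair
qualifies when its persistence measure strictly exceeds the persistence
threshold (default 300 ns) — "more than" is read strictly, so a pair at
exactly the threshold is excluded; the boundary is unit-tested. The
persistence measure defaults to *cumulative* contact time: contact
frequencies are reported as cumulative-time fractions of the trajectory,
which is only coherent under the cumulative reading. The
longest-continuous alternative is available
(`persistence_mode = "longest_continuous"`) and the mode is carried in
the result object. Frame durations come from the time stamps; the last
frame inherits the preceding interval's duration (a trapezoid scheme was
rejected as needless complexity for uniform sampling).

Contacts pool all ligand copies by default (any copy's head counts),
matching the many-copy design of the target simulations; per-copy
resolution is available via `per_ligand = TRUE`. Distances use heavy
atoms by default: hydrogen positions are model conventions in the
synthetic data and are the least reliable atoms in force-field data too.
Residue chemical classes (hydrophobic / polar / charged) come from a
fixed three-way dictionary of the twenty standard amino acids, since the
colour scheme this mirrors does not define its partition.
`region_summary()` reports per-region and per-class counts and
fractions, the tail-to-head contact-count ratio, and the fraction of
contacting residues on the extracellular halves of S3 and S4 — the
spatial statistic of interest for voltage-sensor modulation.

Hydrogen bonds are *not* detected geometrically (no donor–H–acceptor
angle criterion); proximity is the implemented surrogate. Ion-mediated
bridging (e.g. Na⁺ between a carboxylate head and acidic linker
residues) can be approximated by chaining two `proximity_count()` calls,
but no single-call criterion is provided because none is well defined.

## Segment distances, residency, RMSD

**Segment minimum distances.** The ligand is sectioned either into five
parts — HEAD plus tail quarters TAIL-A (C2–6), TAIL-B (C7–11), TAIL-C
(C12–16), TAIL-D (C17–22) — or into head vs the terminal analysis tail
(C12–22), the reduced tail used for probe-residue proximity analyses.
The two schemes are mutually exclusive modes. Per frame and per subunit
the minimum over (subunit atom, segment atom) pairs is recorded;
summaries report each subunit's time mean, the cross-subunit mean, and
the standard error across subunits (sd of the n subunit means / √n).
Time means are taken per subunit first, then the cross-subunit
statistics, which is what a per-subunit standard error requires.

**Residency.** A probe molecule is resident while any of its atoms is
within the cutoff (default 2 Å) of the target; continuous intervals are
computed on the frame grid. Interruption handling is undefined in the
field, so the gap tolerance defaults to 0 frames (strict) and is
exposed; per-frame resident counts are emitted alongside the intervals,
and the two views are cross-checked in tests. A site restriction confines
the target to a residue list's atoms for site-local residency.

**Backbone RMSD.** Two passes: all frames are least-squares superposed
(Kabsch, SVD-based with reflection correction) onto frame 1 over the
chosen selection and averaged; each frame is then superposed onto that
average and its RMSD reported. The reference protocol (average after
initial alignment to frame 1) is a documented choice; it makes the
average well defined without iterating to self-consistency. RMSD is
invariant to rigid transformations of any frame, verified to 1e-9.

## Occupancy density and lateral diffusion

**Occupancy grids.** Space is voxelized (default 1 Å edge) and each voxel
records the fraction of frames in which at least one selected atom lies
inside it. "X % occupancy" iso-surfaces are level sets of this
fraction-of-frames field; that reading is a documented choice, since
rendering tools define their isovalues in tool-specific ways. Frames are
by default superposed onto the first frame over a protein selection
before binning (protein-centered view); a raw lab-frame mode exists.
The iso-surface is exported as the boundary quad mesh of the
above-threshold voxel set — the exact level set of the voxelized field —
in Wavefront OBJ, with the volumetric grid in OpenDX text format readable
by common molecular viewers. A marching-cubes triangulation was
considered and rejected: no maintained R implementation was available to
build on, and the voxel-boundary surface answers the same question
(which voxels exceed the threshold) without interpolation assumptions.
Voxel counts above threshold are reported and are non-increasing in the
threshold.

**Lateral diffusion.** Per-molecule center-of-geometry xy tracks are
unwrapped by accumulating minimum-image steps (valid while no physical
step exceeds half the box). The MSD is time- and ensemble-averaged over
all overlapping origins (FFT-based, O(N log N)), and D = slope/4 by the
2D Einstein relation, fitted by least squares over a lag window. The
default window is 2–20 % of the trajectory length: the relative variance
of a time-averaged MSD grows roughly linearly with lag/length, so short
lags carry most of the information, and windows reaching 50 % of the
trajectory make single-ensemble estimates too noisy to recover a planted
constant within 15 % at 8 molecules × 10^4 frames. The window is
configurable. A curvature diagnostic compares the slope in the two
halves of the window and flags non-linear MSD curves (drift gives
MSD = v²t²); the fit is still reported, flagged. D is reported in both
Å²/ns and cm²/s (1 Å²/ns = 10⁻⁷ cm²/s).

## The synthetic generator: what it emulates, and what it does not

`generate_system()` builds a toy version of the target systems: a rigid
4-subunit helix bundle (one backbone and one side-chain bead per
pseudo-residue, helices S1–S4 at 14 Å radius, pore helices inside, an
S3–S4 linker above, residues marked extracellular above the membrane
midplane), static two-leaflet lipid rods with head nitrogens at ±15 Å,
and amphipathic ligands: a carboxyl head (O1, O2, C1) and a 22-carbon
tail with two pseudo-hydrogens per tail carbon placed perpendicular to
the local C–C–C plane, so order parameters are computable exactly as
defined.

Tail conformations are resampled each frame from a torsional model:
fixed bond length 1.53 Å and angle 111°, dihedrals trans/gauche± with
gauche probability 2·flexibility/3 (flexibility 0 is an exact all-trans
chain; flexibility 1 makes the three rotamers equiprobable). This is a
statistics generator, not physics: there is no force field, no excluded
volume, no temporal correlation between frames, and no claim that the
dihedral populations match any real PUFA. It exists so the analyses have
configurable, known chain statistics. When two disorder levels are
compared (`generate_fatty_acid_pair()`), both chains share every random
draw (common random numbers), so the more flexible chain is more compact
frame by frame and monotonicity tests are sharp rather than statistical.
At high disorder the per-carbon S_CD fluctuates around zero, so the
monotone statistic swept in the tests is the magnitude of the mean
profile, not the mean of per-carbon magnitudes.

Ligand lateral motion is a 2D Gaussian random walk with the planted
diffusion constant (default 4×10⁻⁹ cm²/s, the regime reported for fatty
acids in bilayers). Free ligands are reflected off an exclusion cylinder
(protein radius + 14 Å) so that only *planted* contacts can persist; the
reflection makes their motion obstructed diffusion, so planted-D
recovery is validated on protein-free patches (`n_subunits = 0`), where
the walk is free. Contacts are planted by overriding the ligand's
conformation during declared intervals — an all-trans chain laid out
radially outward in the horizontal plane of the target residue's
side-chain bead, with the designated part atom (O1 for head, the
terminal carbon for tail) held at `steer_distance` (default 3 Å, inside
the 3.5 Å cutoff) — rather than by forces. Overriding gives exact ground
truth: the radial layout guarantees every other ligand atom is farther
from the protein than the contact atom, so the planted (residue, part)
pair is the only qualifying contact. The protein is static; backbone
RMSD of synthetic systems is therefore exactly zero, and RMSD behaviour
is tested on constructed fixtures with known displacements instead.

Everything is drawn from one seeded generator in a fixed order, so a
configuration and seed determine the output bitwise; determinism is
asserted end to end by checksumming pipeline outputs.

What passing tests on synthetic data shows: the estimators implement
their definitions (closed forms, brute-force equivalence), recover
planted truth (contacts, residencies, diffusion constants), and rank
disorder levels correctly. What it does not show: anything about
force-field accuracy, sampling convergence, or the realism of contact
lifetimes in real membranes — those are properties of the input
trajectory, not of the analysis.

## Problem sizes and numerical notes

The shipped tests and the acceptance script run at desk scale, chosen so
the full battery completes in a few minutes: contact-recovery sweeps use
4-subunit systems with ~250 protein beads, 4–6 ligands and 400 frames
over 20 seeds; diffusion recovery uses 8 molecules × 10^4 frames;
closed-form Monte-Carlo checks use 2×10^4–10^5 orientation samples.
Degenerate inputs are defined errors, not silent results: empty
selections, cutoffs exceeding half the smallest box edge (minimum-image
ambiguity), collinear geometry in superposition, fewer than 3 lags in
the MSD fit window, and planted contacts to nonexistent residues all
stop with messages naming the offending object. Unknown residue names
are assigned the ligand role with a warning, never dropped. An empty
iso-surface (no voxel above threshold) is a warning, because a high
threshold is a legitimate query.

## Known limitations

* XTC/TRR trajectories are not read natively (no R reader exists);
  convert to DCD or the plaintext dialect. DCD is read via bio3d.
* Orthorhombic boxes only.
* No hydrogen-bond angle criterion, no free-energy or kinetics
  estimators, no anomalous-diffusion models beyond the curvature flag.
* The synthetic protein is rigid and its lipids are static; analyses
  that need protein internal motion (RMSD plateaus) or lipid dynamics
  must be validated on constructed fixtures or real data.
* `region_summary()` fractions are over qualifying residues, not
  contact time; weight by `cumulative_ns` externally if time-weighted
  attribution is wanted.
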