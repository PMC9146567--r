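---
title: "Methods: assessing G-quadruplex integrity under strand-break damage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assessing G-quadruplex integrity under strand-break damage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4integrity)
```

## The scientific problem

Guanine-quadruplexes (G4s) are four-stranded nucleic-acid structures built
from stacked guanine tetrads: cyclic quartets in which each guanine donates
two Hoogsteen hydrogen bonds (N1-H...O6 and N2-H...N7) to its neighbour,
with monovalent cations (typically K+) coordinated in the central channel
between tetrad planes. The human telomeric repeat
`AGGGTTAGGGTTAGGGTTAGGG` (h-telo) folds intramolecularly into a
three-tetrad parallel G4 whose core is rigid while the three TTA
propeller loops stay flexible.

Ionizing radiation and oxidative stress cleave the sugar-phosphate
backbone. Two lesion chemistries occur: the canonical break (CA), leaving
5'-phosphate/3'-hydroxyl termini that ligases can reseal, and the
non-canonical break (NC), leaving 5'-hydroxyl/3'-phosphate termini that are
poorly repaired. The question this package operationalizes is structural:
does a G4 that already carries one or two such backbone nicks keep its
fold? Answering it requires a reproducible way to (i) enumerate where the
breaks can sit, (ii) measure the geometry of the tetrad stack along a
conformational ensemble, and (iii) turn those measurements into a
per-structure verdict.

## The damage scheme

Breaks are specified in a star notation in which a marker between two
letters cuts the backbone between those residues:

```{r}
cfg <- parse_star_notation("A GG*G TTA GGG TTA G*GG TTA GGG", "CA")
cfg
```

The full scheme pairs six single and six double tetrad-backbone positions
with both chemistries and adds loop breaks in CA chemistry only, giving 27
damaged configurations:

```{r}
length(enumerate_break_scheme())
```

The loop-break positions are not published as coordinates anywhere we could
machine-read, so the package defaults to the first inter-nucleotide
junction of each TTA loop (5-6, 11-12, 17-18); they are arguments of
`enumerate_break_scheme()` and can be overridden. `apply_breaks()` edits
only the connectivity table and attaches terminal-chemistry annotations;
it never moves or rebuilds atoms, because parameterizing the lesioned
termini at the atomic level is a quantum-chemistry task outside the scope
of a geometry toolkit.

## Tetrad detection

Tetrads are detected from geometry alone. A directed Hoogsteen pair
`i -> j` is accepted when both heavy-atom donor-acceptor distances,
d(N1_i, O6_j) and d(N2_i, N7_j), are at most `dmax`; tetrads are the simple
directed 4-cycles of that graph. The default `dmax` of 3.5 A is the common
heavy-atom hydrogen-bond convention, not a published value for this system;
it is exposed in `g4_thresholds()`. A pure distance criterion (no
donor-hydrogen angle) was chosen deliberately: lesioned termini change
hydrogen counts, and many deposited or reconstructed models carry no
hydrogens at all. The criterion is monotone in `dmax` and invariant under
rigid motion, and both properties are exercised in the test suite.

The stack is then ordered along the channel axis (principal direction of
the tetrad centroids, sign fixed 5' to 3' along the strands), and the
cyclic guanine order of every tetrad is rotated so that column k follows
one strand - the alignment the twist descriptor needs. By default the
pipeline detects the topology once, on an early frame, and tracks that
fixed tetrad definition across the whole ensemble; per-frame re-detection
is reserved for the expulsion detector, which must notice bonds breaking.

## The descriptor suite

* **Guanine angles.** For each tetrad, the angle subtended at the tetrad
  centroid by the base-heavy-atom centres of mass of two guanines:
  four adjacent (cyclic-neighbour) angles and two opposite (diagonal)
  angles. An undamaged four-fold tetrad gives exactly 90 and 180 degrees,
  which is the native reference the damaged ensembles are compared
  against. Angles are computed with the atan2 form, which stays
  numerically stable near 0 and 180 degrees.
* **Tetrad COM distance (rise).** Euclidean distance between mass-weighted
  centres of mass of the guanine heavy atoms of consecutive tetrads.
* **Twist.** For consecutive tetrads and each strand column k, the C1'
  edge vector (column k to column k+1) is projected perpendicular to the
  channel axis and the signed angle between corresponding projections is
  taken; the twist is the circular mean of the four signed angles,
  positive for a right-handed stack. Whether published helical-parameter
  scripts use C1' or N9 anchors is not recoverable in general, so both are
  offered (`anchor` argument); C1' is the default and the builder
  construction makes either exact on ideal geometry. The axis is
  recomputed per frame from the tracked tetrad centroids so the descriptor
  is rigid-motion invariant.
* **RMSD.** `kabsch_superpose()` implements the SVD form of the optimal
  proper-rotation superposition (reflections excluded, optional weights).
  `rmsd_series()` tracks deviation from a reference frame on a selection -
  "tetrads only" (guanine heavy atoms) versus "whole DNA" (all nucleic
  heavy atoms) is the contrast that separates core rigidity from loop
  flexibility - and `rmsd_matrix()` produces the pairwise 2D-RMSD map,
  with a stride argument to keep maps at a tractable size.
* **Cation tracking.** An ion is inside the channel when it is within
  `radius` (default 3 A) of the per-frame axis and within the axial span
  of the tetrad centroids extended by `margin` (default 2 A). A leakage
  event is an in-to-out transition that persists at least `min_out`
  (default 10) frames; the hysteresis suppresses single-frame excursions.
  No quantitative leakage criterion is published for this system; this
  cylinder-plus-dwell operationalization is the package's own, with every
  constant exposed.

## Destabilization events and the verdict

A guanine expulsion is flagged when a tracked tetrad guanine loses both
its Hoogsteen partnerships (the pair it donates and the pair it accepts)
for at least `hbond_frames` consecutive frames while its base centre of
mass strays more than `dist_thresh` (default 8 A) beyond its
reference-frame distance from the per-frame tetrad centroid. The *excess*
form of the distance matters: a native guanine base already sits about
4.7 A from its tetrad centroid, so thresholding the raw distance would
misclassify small displacements; the excess is also invariant under rigid
motion. The verdict rule is deliberately conservative and mirrors the
observed phenomenology of damaged-G4 simulations: a structure is
`destabilized` only when a disruption-class event (expulsion or tetrad
disruption) persists to the final frame; cation leakage alone is recorded
but flips nothing - in the one known destabilized replica it co-occurred
with tetrad disruption, and leakage with recovery is otherwise a rare,
survivable event. "Stable" in the source literature is a qualitative call;
this rule is our operationalization, and every threshold sits in
`g4_thresholds()`.

Twist distributions are summarized circularly (2-degree bins by default,
mode as the circular mean within the fullest bin, width as circular
standard deviation); distribution shifts against the native reference are
circular differences of modes, so data straddling the +/-180 boundary are
handled exactly.

## The synthetic ensemble generator

`build_ideal_g4()` constructs an ideal parallel G4 from a planar guanine
template placed at four-fold rotations about the channel axis, with tetrad
k rotated by `k * twist` and lifted by `k * rise`, loop and overhang
residues on smooth outer arcs, and one K+ on the axis midway between
consecutive tetrad planes. Requiring the four Hoogsteen heavy-atom
distances to equal 2.9 A exactly determines the in-plane placement of the
template up to a global rotation and a discrete choice of orientation; the
physical branch (O6 carbonyls lining the channel, 2.30 A from the axis,
giving a 2.83 A K+-O6 coordination distance) has a C1' radius of 8.207 A,
which is therefore the builder default. The derivation is a one-off
numerical calibration whose script ships in `tools/calibrate_tetrad.R`;
the constants are frozen in the package source. A different C1' radius can
be requested and translates the template radially (stretching the
Hoogsteen bonds accordingly).

`generate_ensemble()` adds i.i.d. Gaussian noise per coordinate -
`sigma_core` on tetrad guanines and ions, `sigma_loop` (default 4x) on
loops - and, by default, a random global rigid motion per frame, so any
orientation dependence in a descriptor fails tests immediately. The noise
model is explicitly non-physical: it has no covariance structure, no
bonded constraints and no thermodynamics. It is sufficient to validate
estimators, thresholds and event detectors against injected ground truth,
which is all the package claims; passing these tests says nothing about
force fields or real conformational kinetics. Injected events
(`cation_leak`, `guanine_expulsion`) displace the target radially from a
given onset frame, giving detectors an exact truth to recover.

Default generator conditions used throughout the tests: 22-mer h-telo
sequence, three tetrads, rise 3.3 A, twist 30 degrees, ensembles of
100-500 frames with core noise 0.3-0.4 A. The demonstration batch that
re-enacts the published 26-of-27 outcome runs 27 damaged configurations at
120 frames each with one injected leak-plus-expulsion run ("CA 14-15",
where the single destabilized replica was reported); it is a synthetic
re-enactment of the classification logic, not a physics result. Problem
sizes were chosen so the whole suite runs comfortably on one CPU.

## Numerical choices and degenerate inputs

* Angles use `atan2(|cross|, dot)`; circular statistics are used wherever
  angles are averaged or histogrammed.
* Kabsch uses the SVD determinant correction to exclude reflections and
  flags collinear point sets instead of failing.
* Plane fits reject fewer than 3 points and collinear inputs; the normal
  sign follows an optional axis hint.
* Tetrad search resolves overlapping candidate 4-cycles by the smaller
  mean donor-acceptor distance, with lexicographic tie-breaks, so output
  is deterministic.
* Coincident tetrad centroids (degenerate axis) fall back to the mean
  tetrad normal and are flagged on the topology object.
* The ensemble generator requires an explicit seed and restores the
  caller's RNG state.

## Known limitations

Antiparallel and hybrid topologies are not classified (no glycosidic-angle
analysis); bulges are not handled; only PDB input is supported; terminal
chemistry is annotation-level; and the Gaussian generator cannot emulate
correlated motions, so distribution *widths* from synthetic runs should
never be compared with real MD - only recovery of injected parameters and
events is meaningful.
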