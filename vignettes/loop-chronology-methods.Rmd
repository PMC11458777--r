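---
title: "Methods: chronologies of loop prototypes and structural domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chronologies of loop prototypes and structural domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopchron)
```

## The problem

Protein domains and the loop prototypes that build them did not appear all
at once: comparative genomics can order their origins in time. The raw
observable is a census of genomic abundance — how often each structural
domain family occurs in each sampled proteome of Archaea (A), Bacteria (B),
Eukarya (E) and viruses (V). Two premises make a chronology possible:
*generality* (families found across all supergroups are older than
lineage-restricted ones) and *abundance* (older families have had longer to
amplify). loopchron turns these premises into a reproducible pipeline:
censuses are encoded as linearly ordered multistate characters, a
most-parsimonious tree of domains is inferred and rooted, leaf depths become
relative ages (`nd`), a molecular clock converts `nd` to Gya, loop
prototypes are dated through the families they map to, and accretion across
four-set Venn groups and six evolutionary phases is tabulated, down to the
repertoires of LUCA and LUCellA.

## Character coding

Each family column of the census becomes one character. Abundance `g` is
mapped to a state by `round(ln(1+g)/ln(1+g_max) * (S-1))`, rounding half
away from zero, with `S = 24` states by default (NEXUS symbols `0-9A-N`).
The log compresses the heavy tail of abundance distributions; the rescale
pins absence to state 0 and the per-character maximum to state `S-1`, so
Wagner (linear-cost) parsimony counts graded abundance change.

`g_max` is taken per family by default; a `"global"` scope is available.
We examined both on simulated censuses: the per-family scope recovers
planted birth orders distinctly better (Spearman 0.75 vs 0.63 at the
default preset), because a matrix-wide maximum compresses most characters
into few states. Per-family scaling does, however, erase *absolute*
abundance differences between families — only breadth and within-family
contrast remain — which bounds how much of the planted order any downstream
tree can recover (see *Limitations*).

## Tree of domains, rooting, node distances

The taxa of the tree are the domain families; the characters are the
proteomes (the encoded matrix is transposed internally by
`build_chronology()`). Tree length is the Wagner parsimony score computed
by Sankoff dynamic programming with cost `|i - j|`; the linear cost admits
an O(S) distance-transform per branch (forward/backward sweeps) instead of
the generic O(S^2) min-plus product, implemented in C++.

The search is classic random-addition plus NNI hill climbing: leaves are
added in seeded random order, each on the branch minimising length, then
nearest-neighbor interchanges are accepted on first improvement until a
local optimum; the best of `n_starts` restarts is kept. On every instance
small enough to enumerate (<= 9 leaves) the heuristic is validated against
exhaustive search in the test suite. Ties among equally parsimonious trees
keep the first tree found and are reported.

Rooting is Lundberg ancestor attachment: a hypothetical ancestor with all
states `S-1` (`"max"`, the generality criterion: the oldest lineage is
maximally abundant everywhere) is attached to every branch in turn and the
cheapest attachment becomes the root. An all-zero `"min"` ancestor is
available for sensitivity analysis. The attachment costs come from an
inside/outside decomposition of the same dynamic program, and the tests
compare them against explicitly built trees.

Each leaf's relative age is its node distance: the count `d` of internal
nodes on the root-to-leaf path (root included), rescaled as
`nd = (d-1)/(d_max-1)` so the oldest leaves sit at 0 (the alternative
`(d-d_min)/(d_max-d_min)` scaling is available). A least-squares clock
`age = a + b*nd` through anchor pairs converts `nd` to Gya; the default
anchors are (0, 3.8) and (1, 0) — the origin of the domain world at
3.8 Gya and the present — and negative calibrated ages are clipped to 0
with a warning rather than treated as errors.

## Prototypes, Venn groups, phases

Prototype-family mappings are filtered at e-value `< 0.001` (strict).
A prototype whose surviving families share a single `nd` is *non-modular*;
otherwise it is *modular* and marks recruitment. Every prototype is dated
at the minimum `nd` of its families — its first appearance — a declared
convention for modular prototypes (non-modular ones have a single age
anyway); an `nd` tolerance for jittered ties is configurable (default
exact).

A family's Venn group is the set of supergroups where it has `g > 0` in at
least one proteome (a min-proteome count is available for noise
robustness). The six phases partition [0, 3.8] Gya at
3.6/3.2/2.5/2.0/0.9; intervals are closed at the older end, so an age on an
internal boundary belongs to the younger phase (2.5 Gya is Phase III) and
0 Gya belongs to Phase V. Accretion tables count items per (phase, Venn
group); per-phase prototype/family ratios are rounded half away from zero
to two decimals, and phases without families yield a flagged undefined
ratio. LUCA's repertoire is everything in Phase 0; LUCellA's adds Phase I,
so LUCA is always nested in LUCellA. Missing annotations map to
"Other/Unknown" rather than being dropped.

## Reticulation statistics

The network analysis uses 5 taxa — A, B, E, V and a hypothetical ancestor
`ANC` — against the 15 Venn groups as binary characters weighted by item
counts. The fifth taxon is underdetermined by convention; we default to an
all-absent ancestor (consistent with rooting networks on a zero profile)
and expose all-present and four-taxon modes.
Distances are weighted uncorrected-P; the delta score sorts each quartet's
three pairwise sums `m1 >= m2 >= m3` and averages `(m1-m2)/(m1-m3)`
(defined as 0 when all sums tie); the Q-residual averages `(m1-m2)^2`
after rescaling so the mean off-diagonal distance is 1, making it
scale-invariant. Both are exactly 0 on additive metrics and the delta
score is exactly 1 on the unit 4-cycle. Neighbor joining (via ape) stands
in for split-network layouts, with negative branch lengths clamped to 0
and flagged; bootstrap resampling draws the item-level units (not the 15
columns, whose weights are item counts), regenerates weights
multinomially, and reports per-split support percentages over the
replicates (2000 by default).

## Loop geometry

A loop motif is two periodic bracing elements (alpha-helix H, 3-10 helix
G, beta-strand E) joined by an aperiodic region. Its four internal
coordinates come from the oriented principal axes M1, M2 of the bracing
elements (dominant singular vector of the centered C-alpha coordinates,
signed N-to-C) and the vector joining the boundary C-alpha atoms:
`D` (Angstroms), hoist `delta = angle(M1, D)`, packing
`theta = angle(M1, M2)`, and meridian `rho`, the right-handed rotation of
M2's projection about the D-axis measured from M1's projection, in
[0, 360). The meridian convention deserves a note: published descriptions of the
reference plane Gamma are ambiguous, so the projection-angle convention
above is this package's declared interpretation — the name-to-symbol
pairing (hoist/packing/meridian) is chosen so that meridian values above
180 degrees are representable, which only the [0, 360) range permits. The generator/measurement round trip in
the tests defines the convention operationally. When an element is
parallel to the D-axis the projection degenerates and `rho` is reported as
0 with a flag.

Loop types concatenate the two SS labels, except strand-strand motifs,
which split into beta-hairpins (BN: sequence-adjacent strands packed
antiparallel, `theta > 90`) and beta-links (BK) — a declared convention
for a rule that classification databases do not publish in closed form.
Only C-alpha atoms are used, and SS labels are inputs (a sidecar TSV next
to each minimal PDB file); no DSSP-style assignment is attempted.

The simulator builds ideal traces (helix 2.3 A radius / 1.5 A rise /
100 deg per residue; 3-10 helix 1.9 / 2.0 / 120; strand 3.3 A extended
zigzag), orients each so its *computed* principal axis — not the nominal
helix axis, which differs by a fraction of a degree for short elements —
realises the requested geometry exactly, then adds optional Gaussian
noise. The four coordinates are mutually constrained
(`cos(theta) = cos(delta)cos(alpha) + sin(delta)cos(rho)sin(alpha)` for
M2's polar angle `alpha`); infeasible requests error rather than being
silently adjusted.

## The synthetic world

`simulate_accretion()` emulates the study inputs with known ground truth:
sorted-uniform birth times on [0, 1]; a Venn label drawn at birth from a
phase-indexed schedule (universal ABEV early, superkingdom losses in the
middle phases, lineage-specific groups late — mirroring the qualitative
accretion narrative; labels never change after birth, the simplest
generative stand-in for observed end states); abundance
`Poisson(lambda0 * exp(-k * t))` inside the label and 0 outside, with
per-cell dropout. Defaults are 60 families, 8 proteomes per supergroup,
`lambda0 = 50`, `k = 2`, dropout 0.05 — a desk-scale shape chosen once
as a realistic miniature of a proteome census; the presets are
calibration-free stand-ins, not estimates of any real census.
All generators consume exactly one seed and record it; the same seed
reproduces outputs bit-for-bit.

What the generator does *not* emulate: real SCOP abundance distributions
(power-law tails, genome-size effects), horizontal transfer, census
ascertainment biases, or any sequence-level process. Passing tests
therefore certify the pipeline's internal correctness — encoding, search
optimality on small instances, rooting, dating, counting — not the
biological fidelity of a real census analysis.

## Problem sizes and numerical choices

The test suite validates the Sankoff program against brute-force
enumeration of internal states on 50 random matrices of up to 6 leaves at
the full 24-state alphabet, the heuristic search against exhaustive
enumeration up to 7 leaves, and Lundberg rooting against explicit
attachment on 20 instances — sizes where exact references are computable
in seconds. The end-to-end recovery experiment uses the default preset
(60 families, 32 proteomes, 3 restarts), which completes in under a
minute. Rounding is half-away-from-zero wherever a printed two-decimal
convention is reproduced; rooting ties break on the first postorder
branch; quartet deltas with `m1 = m3` are defined as 0.

## Limitations

On simulated censuses at the default preset the inferred chronology
correlates with the planted birth order at Spearman rho of about 0.75.
The loss is attributable, in order, to (i) per-family normalisation
discarding absolute abundance (the raw census total-abundance ranking
alone correlates at 0.87); (ii) the discreteness of node distances — many
families share a depth, and equally parsimonious topologies differ in
their tie structure. Scanning all possible rootings of the inferred
topology improves rho by less than 0.001, and deeper search (more
restarts, shorter trees) does not improve it, so neither rooting nor
search is the bottleneck; the ceiling is informational, set by the
encoding and by how much late-born but universally distributed families
resemble old ones. Users analysing real censuses should treat `nd` ranks
within a phase as weakly resolved and lean on the phase-level summaries,
which are robust to these ties.
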