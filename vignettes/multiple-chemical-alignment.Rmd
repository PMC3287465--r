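---
title: "Multiple chemical alignment: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple chemical alignment: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucha)
```

## The problem

Many secondary metabolites are synthesized by transferring building blocks
(methyl, methoxy, sugar, acyl groups, ...) onto an existing scaffold. Given
a family of such metabolites, a consistent multi-molecule atom-atom mapping
separates the conserved core substructure from the position-aware branch
substructures, and those branches tend to correspond to single enzymatic
transfer steps. That is a different goal from pharmacophore alignment
(which matches electrostatically "similar" groups in 3D) and from frequent
subgraph mining (which ignores where a substructure sits relative to the
core): here both the atom typing and the relative position of every
substructure matter.

Molecules are hydrogen-suppressed labeled graphs in KCF form. Each vertex
carries a KEGG atom label such as `C8y`: the first character is the atom
species (element), the first two the atom class (element + orbital
environment), and the third encodes the bonded neighbourhood. The three
levels form a prefix hierarchy, and the package treats the labels as opaque
hierarchical tokens — no atom typing from raw connectivity is attempted, so
labels must arrive in the input. Bond orders are parsed and preserved but
take no part in matching: chemical environment is already encoded in the
atom labels, and no matching rule in the pipeline compares orders.

## Positional identifiers: DMAID

"Distance" always means shortest-path length in bonds, computed once per
molecule by breadth-first search and cached. The **self-DMAID** of an atom
string (a simple path) is the square matrix of whole-molecule distances
between its atoms, in string order; the **anchored-DMAID** of a string
against an anchor is the (generally rectangular) matrix of distances from
string atoms to anchor atoms. Two design points deserve emphasis:

* Distances are taken in the *whole molecule*, not in the subgraph induced
  by the string. For a benzene-ring string covering five of the six ring
  atoms, the distance between the first and the fifth atom is 2 — through
  the sixth ring atom outside the string. The induced-subgraph reading
  would give 4 and is inconsistent with how ring strings compare.
* DMAID comparison is order-sensitive, entry-wise equality. There is no
  permutation search (that would reintroduce graph-isomorphism cost);
  instead every string is put into a canonical orientation first.

Canonical orientation picks, between a path and its reversal, the one with
the lexicographically smaller (label sequence, flattened self-DMAID,
atom-index sequence). The flattened DMAID participates before the index
tie-break so that the chosen orientation is stable *across molecules* even
for palindromic label sequences with asymmetric distance structure; atom
indices are molecule-specific and only break exact ties within one
molecule.

## Per-atom fingerprints: DECAF

The DECAF fingerprint of atom *i* counts, for every distance *d* and atom
class *k*, the number of atoms of class *k* at distance *d* from *i*; the
*d* = 0 entry is the atom's own class. Keying entries by the (distance,
destination class) pair — rather than by whole backward path strings — is
what makes fingerprints comparable between molecules whose interior paths
differ; only the endpoints of shortest paths are typed. Total fingerprint
mass equals the molecule's atom count, a conservation property the test
suite checks on random molecules.

Two atoms are scored by

$$\mathrm{score}(i,j) \;=\; \sum_d \frac{\sum_k \min(n_{i,k,d},\, n_{j,k,d})}{d+1},$$

so shared environment close to the atom counts more than shared
environment far away. Atom-atom scores are memoized in a hash table;
string-string scores are position-wise sums. For the two shipped fixture
molecules, scoring the side-chain-bearing ring carbons decomposes as
1/1 + (1+2)/2 + (1+2)/3 + 1/4 + 1/5 = 3.95, the package's reference
worked example (recomputed, not asserted, by `scripts/acceptance.R`).

## Stage 1: longest common atom strings (LCAS)

Every atom starts as a length-1 string; strings are classified by (full
label sequence, self-DMAID); classes missing from any query molecule are
discarded; survivors are extended by one bonded neighbour of the terminal
atom; the search stops when no longer common class exists. Because a
common string's every prefix and suffix is also common (labels restrict,
DMAIDs restrict to leading submatrices), level-wise pruning is complete,
and because both traversal directions of each path survive each level,
terminal-only extension covers both ends. Mirror duplicates are collapsed
by canonical orientation — a symmetric molecule holds *two*, not four,
instances of a string that crosses its mirror axis.

When molecules hold several LCAS instances (symmetry), one instance per
molecule is selected to maximize the sum of pairwise string DECAF scores.
The search is exhaustive up to `exhaustive_limit` (default 10 000)
combinations; beyond that a seeded genetic algorithm takes over
(population 50, generations 100, tournament size 3, one-point crossover
0.9, per-gene mutation 0.1, elitism 1). These GA defaults are ordinary
textbook settings — the method's behaviour does not hinge on them because
the objective landscape over instance choices is tiny and flat in the
symmetric cases that trigger it; they are exposed in `mucha_config()`.
When several maximal-length classes tie, all compete under the same
objective, which keeps selection deterministic.

## Stage 2: extending the core

Frontier atoms adjacent to the current core are grouped by (atom species,
anchored-DMAID against the current core columns). A group is promoted to
new core columns only when it identifies exactly one atom per molecule in
*every* molecule. Ambiguous groups pass through a fixed cascade: incident
ring-bond count (ring bonds are non-bridge edges), then atom class, then
full label, and finally — for genuinely symmetric leftovers — pairing by
ascending atom index. A group still carrying unequal candidate counts
after the full cascade is dropped rather than force-paired; that is the
conservative reading, and it is what keeps, e.g., the two equivalent
carboxyl oxygens of an acid out of a core aligned against a single
alcohol oxygen. Species-level matching at this stage is deliberately
looser than the full-label matching of stage 1: it is what lets a phenolic
`O1a` align with a glycosidic `O2a` occupying the same ring position.

The anchor is re-computed against the *grown* core at each iteration (not
the original seed only): the growing core is the natural generalization of
"anchored against the core substructure", and re-anchoring strengthens the
positional constraint as more columns accumulate. Growth is monotone —
columns are never removed — so the fixpoint is reached in at most |V|
iterations. With exactly two query molecules the pipeline stops here.

## Stage 3: branches, conflicts, building blocks

Branch seeds are short common atom strings over the non-core atoms, keyed
by (species-level label sequence, anchored-DMAID against the core) — again
deliberately looser than stage 1, since building blocks recur across
chemically diverging contexts. A branch string need not appear in all
molecules; any key shared by at least `min_support` molecules (default 2,
the weakest sensible floor) is kept. Strings extend greedily from length
1; a key is retired only when a one-atom-longer key with the identical
member set supersedes it in every member molecule. Keys that extend in
only some members are kept alongside their longer children and any atom
overlap is left to conflict removal — the stage that the method already
owns for exactly this purpose.

Each seed is extended with the same grouping machinery as the core,
restricted to its member molecules and to non-core atoms, anchored
against the core columns plus the branch's own columns (core atoms are
frozen and never absorbed; a branch may attach next to another branch,
which permits nested blocks). Because seeds are generated independently,
different branch columns can claim the same atom. Conflict removal is
randomized greedy: per restart, columns are visited in random order and
accepted when disjoint from everything accepted so far; the score is the
total number of atoms kept; the best of 20 restarts (configurable) wins.
This is a characterized heuristic, not an optimal weighted independent
set solver: on crafted 6-column instances the test suite measures how
often 20 restarts attain the exhaustive-ordering optimum (at least 95 of
100 seeded trials). Finally, conflict-free branch columns with the same
member set whose atoms are bonded in every member molecule merge into one
building block, with deterministic `B1, B2, ...` ids.

## Determinism and degenerate inputs

All randomness (GA, conflict restarts) flows from `config$seed` through a
local RNG scope that restores global RNG state, so identical inputs and
configuration give byte-identical text and JSON outputs. Disconnected
molecules are rejected at parse time rather than silently split — every
distance is required to be finite. Molecules sharing no length-1 string
yield an empty alignment with a warning. A single-atom molecule is legal;
an empty one is not.

## The fixtures and the random generator

The shipped fixtures are hand-encoded from their known structures:
sinapic acid (16 heavy atoms; ring labels `C8y-C8x-C8y-C8y-C8y` with atom
1 the side-chain-bearing carbon), p-coumaryl alcohol 4-O-glucoside (22
heavy atoms; ring `C8y-C8x-C8x-C8y-C8x`; full heavy-atom glucose with
standard KEGG sugar labels), and the monolignol panel (p-coumaryl,
coniferyl, sinapyl alcohols with 0, 1, 2 methoxy groups). Substituent
labels follow standard KEGG atom-typing conventions and are documented in
the fixture help pages; the exact sugar labels affect no reference value,
since every worked quantity involves distances at most 4 from atom 1 or
the printed ring strings.

`random_molecule()` generates property-test input: a random spanning tree
plus Binomial(n, `ring_prob` = 0.15) ring-closing edges, labels drawn from
a KEGG-like alphabet. This emulates the size and ring density of
hydrogen-suppressed metabolites but none of their chemistry — no valence
constraints, no label/degree correlation. Passing the oracle-equivalence
tests on such graphs therefore demonstrates graph-algorithmic correctness
(distances, path enumeration, string classes), not chemical validity of
alignments on real compound families; the fixture-panel tests carry that
burden. Oracle tests use molecules of at most 12 atoms and 100 random
pairs, sizes at which exhaustive simple-path enumeration is exact and the
whole suite runs in well under a minute.

## Known limitations

* The alignment is a greedy heuristic seeded by the longest common string;
  it carries no maximum-common-substructure optimality guarantee, and on
  structurally diverse inputs (where no meaningful common substructure
  exists) it finds small or empty cores.
* Stage-4 index pairing resolves genuine symmetry arbitrarily (though
  deterministically): cell contents may permute under atom renumbering,
  but column counts do not, which is the invariant the tests pin.
* Label hierarchies are trusted as given; there is no fuzzy matching
  across label levels at the seed stage, no stereochemistry, no aromatic
  perception, and no charge handling.
* `min_support = 2` admits coincidental two-molecule branches in large
  panels; raise it when querying many molecules.
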