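# mucha — multiple chemical alignment of small-molecule graphs

`mucha` aligns two or more small molecules, given as hydrogen-suppressed
KCF (KEGG Chemical Function) graphs, into a single consistent
multi-molecule atom-atom mapping. The output separates the **core
substructure** shared by all query molecules from the **position-aware
branch substructures** ("building blocks") shared by subsets of them. It
is aimed at metabolomic questions — grouping secondary metabolites by
their biosynthetic scaffold and spotting the groups transferred in single
enzymatic steps — where both the KEGG atom typing and the *position* of a
substructure relative to the core matter, unlike pharmacophore alignment
or plain frequent-subgraph mining.

## Method in brief

Vertices carry hierarchical KEGG atom labels (`C8y`: species `C`, class
`C8`, full label `C8y`); "distance" is shortest-path length in bonds.
Three devices drive the alignment:

* **DMAID** — distance-matrix atom identifiers. The *self-DMAID* of an
  atom string (simple path) is the matrix of whole-molecule distances
  among its atoms; the *anchored-DMAID* is the rectangular matrix of
  distances from a string to an anchor (the core). Equal label sequences +
  equal self-DMAIDs identify topologically interchangeable strings without
  any isomorphism search.
* **DECAF** — per-atom fingerprints counting atoms of class *k* at
  distance *d*, scored by
  `score(i,j) = Σ_d [ Σ_k min(n_ikd, n_jkd) ] / (d+1)`.
* **Seed and extend** — (1) the longest common atom strings (full labels +
  self-DMAID, present in *all* molecules) seed the alignment, with DECAF
  picking one representative instance per molecule among symmetric
  alternatives (exhaustively, or by a seeded genetic algorithm when
  combinations explode); (2) the core grows by grouping frontier atoms on
  (species, anchored-DMAID) with a ring-bond / atom-class / full-label /
  index-order tie-break cascade; (3) for three or more molecules, branch
  strings over the non-core atoms (species level, anchored against the
  core, shared by ≥ `min_support` molecules) are extended the same way,
  de-conflicted by randomized greedy restarts, and merged into building
  blocks. Two-molecule queries stop after the core.

## Worked example

The two classic fixture molecules ship with the package: sinapic acid
(KEGG C00482) and p-coumaryl alcohol 4-O-glucoside (C05855).

```r
library(mucha)
s <- sinapic_acid()
g <- p_coumaryl_alcohol_glucoside()

decaf_score(build_decaf(s, 1), build_decaf(g, 1))
#> [1] 3.95

aln <- mucha(list(s, g))
print(aln)
#> # MUCHA multiple chemical alignment
#> # molecules: C00482(16 atoms) C05855(22 atoms)
#> # columns: 10 core, 0 branch
#> GROUP  CORE   CORE  CORE  CORE  CORE   CORE  CORE  CORE  CORE  CORE
#> C00482 11:C2b 7:C2b 1:C8y 2:C8x 14:C6a 6:C8x 3:C8y 5:C8y 4:C8y 9:O1a
#> C05855 9:C2b  7:C2b 1:C8y 2:C8x 11:C1b 6:C8x 3:C8x 5:C8x 4:C8y 8:O2a
```

The `3.95` is the DECAF similarity of the two side-chain-bearing ring
carbons: their environments agree completely out to distance 2, and
partially at distances 3–4 (`1/1 + 3/2 + 3/3 + 1/4 + 1/5`). The alignment
maps the whole benzene ring, three side-chain carbons and the para oxygen
of each molecule — note the species-level matches in the core (`C6a`
carboxyl vs `C1b` alcohol carbon; phenolic `O1a` vs glycosidic `O2a`),
while the glucose, the two methoxy groups and the terminal oxygens stay
unaligned, as nothing corresponds to them in the partner molecule.

On the three-molecule monolignol panel the branch stage activates:
`mucha(monolignol_panel())` aligns an 11-column core and one methoxy
building block (`B1`: an `O2a` and a `C1a` column) shared by coniferyl and
sinapyl alcohol, leaving sinapyl's second, differently positioned methoxy
unaligned.

A command-line front end is installed with the package
(`inst/exec/mucha`):

```sh
mucha align a.kcf b.kcf -o out.txt
mucha align panel.kcf --seed 7 --format json
mucha synth --seed 5 --n-atoms 12 -o random.kcf
```

## Documentation

See the vignette `vignettes/multiple-chemical-alignment.Rmd` for the full
account of the model, the parameter defaults and the numerical design
decisions, and the help pages (`?mucha`, `?build_decaf`, `?find_lcas`,
`?extend_core`, `?find_scas`, `?remove_conflicts`) for per-function
contracts.
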