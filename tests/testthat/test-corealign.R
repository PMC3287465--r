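core_cells <- function(aln, id) {
  sort(vapply(Filter(function(c) c$role == "core", aln$columns),
              function(col) col$cells[[id]], 1L))
}

test_that("the fixture pair core is ring + chain carbons + para oxygen", {
  # hand-audited maximal consistent mapping under the grouping rules:
  # 6 ring atoms, 3 side-chain carbons, and the para oxygen
  # (O1a in sinapic acid matched to the glycosidic O2a at species level)
  mols <- list(sinapic_acid(), p_coumaryl_alcohol_glucoside())
  aln <- mucha(mols)
  expect_length(aln$columns, 10L)
  expect_true(all(vapply(aln$columns, function(c) c$role == "core", TRUE)))
  expect_identical(core_cells(aln, "C00482"),
                   sort(c(1:6, 7L, 11L, 14L, 9L)))
  expect_identical(core_cells(aln, "C05855"),
                   sort(c(1:6, 7L, 9L, 11L, 8L)))
  # the species-level O1a/O2a column maps 9 (sinapic) to 8 (glucoside)
  ocol <- Filter(function(c) c$cells[["C00482"]] == 9L, aln$columns)
  expect_identical(ocol[[1]]$cells[["C05855"]], 8L)
})

test_that("two identical molecules align completely", {
  m <- sinapic_acid()
  aln <- mucha(list(m, clone_molecule(m, "DUP")))
  expect_length(aln$columns, nrow(m$atoms))
  expect_identical(core_cells(aln, "C00482"), sort(m$atoms$index))
  expect_identical(core_cells(aln, "DUP"), sort(m$atoms$index))
})

test_that("a seed with no extendable neighbours is the fixpoint", {
  m1 <- path_molecule("P1", c("C1a", "C1b", "C1a"))
  m2 <- path_molecule("P2", c("C1a", "C1b", "C1a"))
  aln <- mucha(list(m1, m2))
  expect_length(aln$columns, 3L)
})

test_that("the disambiguation cascade splits groups at the right stage", {
  s <- sinapic_acid()
  mols <- list(C00482 = s, DUP = clone_molecule(s, "DUP"))
  # stage 1: ring carbon vs chain carbon (2 vs 0 ring bonds)
  got <- disambiguate(list(C00482 = c(2L, 7L), DUP = c(2L, 7L)), mols)
  expect_length(got, 2L)
  expect_setequal(vapply(got, function(c) c[["C00482"]], 1L), c(2L, 7L))
  expect_identical(got[[1]][["C00482"]], got[[1]][["DUP"]])
  # stage 2/3: same species, class C8 vs C2 then full label
  got <- disambiguate(list(C00482 = c(7L, 12L), DUP = c(7L, 12L)), mols)
  expect_length(got, 2L)
  expect_identical(got[[1]][["C00482"]], got[[1]][["DUP"]])
  got <- disambiguate(list(C00482 = c(3L, 4L), DUP = c(3L, 4L)), mols)
  expect_length(got, 2L)  # both C8y, same ring bonds: index pairing
  # stage 4: symmetric atoms paired by ascending index
  got <- disambiguate(list(C00482 = c(6L, 2L), DUP = c(2L, 6L)), mols)
  expect_length(got, 2L)
  expect_identical(got[[1]], c(C00482 = 2L, DUP = 2L))
  expect_identical(got[[2]], c(C00482 = 6L, DUP = 6L))
  # unequal multiplicities after the cascade are dropped, not force-paired
  got <- disambiguate(list(C00482 = c(15L, 16L), DUP = 15L), mols)
  expect_length(got, 0L)
  # a molecule with no candidate kills the group
  got <- disambiguate(list(C00482 = integer(), DUP = 15L), mols)
  expect_length(got, 0L)
})

test_that("full-label disambiguation separates C8y from C8x candidates", {
  # crafted 8-atom molecule: center O2a bonded to C8y-like and C8x-like arms
  # at equal distance; species and anchored profile agree, classes agree,
  # full labels differ
  mk <- function(id) kcf_molecule(id,
    data.frame(index = 1:5,
               label = c("O2a", "C8y", "C8x", "C1a", "C1a")),
    data.frame(a = c(1, 1, 2, 3), b = c(2, 3, 4, 5), order = 1L))
  mols <- list(A = mk("A"), B = mk("B"))
  got <- disambiguate(list(A = c(2L, 3L), B = c(2L, 3L)), mols)
  expect_length(got, 2L)
  expect_identical(got[[1]][["A"]], got[[1]][["B"]])
})

test_that("two-molecule queries stop at the core; three run the branch stage", {
  pair <- mucha(list(sinapic_acid(), p_coumaryl_alcohol_glucoside()))
  expect_true(all(vapply(pair$columns, function(c) c$role, "") == "core"))
  panel <- mucha(monolignol_panel())
  expect_true(any(vapply(panel$columns, function(c) c$role, "") == "branch"))
})

test_that("alignments are conflict-free and grow monotonically", {
  for (mols in list(list(sinapic_acid(), p_coumaryl_alcohol_glucoside()),
                    monolignol_panel(),
                    monolignol_panel(include_glucoside = TRUE))) {
    aln <- mucha(mols)
    expect_true(conflict_free(aln$columns))
    # core columns cover every molecule
    for (col in aln$columns) {
      if (col$role == "core")
        expect_setequal(names(col$cells), names(aln$molecules))
    }
  }
})

test_that("core size is invariant under atom renumbering", {
  base <- mucha(list(sinapic_acid(), p_coumaryl_alcohol_glucoside()))
  n_core <- sum(vapply(base$columns, function(c) c$role == "core", TRUE))
  set.seed(33)
  for (rep in 1:5) {
    s2 <- permute_atom_indices(sinapic_acid(), sample(16))
    g2 <- permute_atom_indices(p_coumaryl_alcohol_glucoside(), sample(22))
    aln <- mucha(list(s2, g2))
    expect_identical(sum(vapply(aln$columns, function(c) c$role == "core",
                                TRUE)), n_core)
  }
})
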