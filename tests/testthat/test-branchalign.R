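# coumaryl-alcohol scaffold with an extra residue attached at `at`
with_residue <- function(id, at, residue_labels = c("O2a", "C1a")) {
  base <- monolignol_panel()[[1]]           # p-coumaryl alcohol, 11 atoms
  atoms <- base$atoms[c("index", "label")]
  atoms$label[atoms$index == at] <- "C8y"   # substituted ring carbon
  n <- nrow(atoms)
  extra <- data.frame(index = n + seq_along(residue_labels),
                      label = residue_labels)
  bonds <- base$bonds
  prev <- at
  for (k in seq_along(residue_labels)) {
    bonds <- rbind(bonds, data.frame(a = prev, b = n + k, order = 1L))
    prev <- n + k
  }
  kcf_molecule(id, rbind(atoms, extra), bonds)
}

branch_columns <- function(aln) {
  Filter(function(c) identical(c$role, "branch"), aln$columns)
}

test_that("methoxy branches appear only in the molecules bearing them", {
  aln <- mucha(monolignol_panel())
  bc <- branch_columns(aln)
  # one methoxy group shared by coniferyl and sinapyl: O2a + C1a columns
  expect_length(bc, 2L)
  for (col in bc) {
    expect_setequal(names(col$cells), c("C00590", "C02325"))
    expect_identical(col$group, "B1")
  }
  labs <- sort(vapply(bc, function(col) {
    unname(aln$molecules[["C00590"]]$labels[as.character(col$cells[["C00590"]])])
  }, ""))
  expect_identical(labs, c("C1a", "O2a"))
  # sinapyl's second methoxy has no partner at its position: unaligned
  aligned_sinapyl <- unlist(lapply(aln$columns, function(col)
    col$cells[["C02325"]]))
  expect_length(setdiff(monolignol_panel()[[3]]$atoms$index,
                        aligned_sinapyl), 2L)
})

test_that("two-molecule queries skip the branch stage entirely", {
  aln <- mucha(list(sinapic_acid(), p_coumaryl_alcohol_glucoside()))
  expect_length(branch_columns(aln), 0L)
})

test_that("identical triplicated molecules leave no branch atoms", {
  m <- sinapic_acid()
  aln <- mucha(list(m, clone_molecule(m, "D2"), clone_molecule(m, "D3")))
  expect_length(branch_columns(aln), 0L)
  expect_length(aln$columns, nrow(m$atoms))  # core covers everything
})

test_that("a residue shared by two of three molecules aligns as one group", {
  mols <- list(with_residue("RA", 3, c("C1b", "C1y", "O1a")),
               with_residue("RB", 3, c("C1b", "C1y", "O1a")),
               clone_molecule(monolignol_panel()[[1]], "RC"))
  aln <- mucha(mols)
  bc <- branch_columns(aln)
  expect_length(bc, 3L)  # whole residue, one column per residue atom
  expect_true(all(vapply(bc, function(col)
    setequal(names(col$cells), c("RA", "RB")), TRUE)))
  expect_length(unique(vapply(bc, function(col) col$group, "")), 1L)
  expect_true(conflict_free(aln$columns))
})

test_that("equal residues at different anchor positions are not merged", {
  # ortho- vs meta-attached methoxy: same chemical structure, different
  # anchored-DMAID against the core, so neither reaches min_support
  mols <- list(with_residue("PO", 2), with_residue("PM", 3),
               clone_molecule(monolignol_panel()[[1]], "PP"))
  aln <- mucha(mols)
  expect_length(branch_columns(aln), 0L)
})

test_that("one-atom branches with no extendable neighbour stay length 1", {
  mols <- list(with_residue("QA", 3, "O2a"),
               with_residue("QB", 3, "O2a"),
               clone_molecule(monolignol_panel()[[1]], "QC"))
  aln <- mucha(mols)
  bc <- branch_columns(aln)
  expect_length(bc, 1L)
  expect_setequal(names(bc[[1]]$cells), c("QA", "QB"))
})

test_that("conflict removal keeps one of two overlapping columns", {
  cols <- list(list(cells = c(A = 1L, B = 1L), note = "x"),
               list(cells = c(A = 1L, B = 2L), note = "y"))
  kept <- remove_conflicts(cols, restarts = 20, seed = 0)
  expect_length(kept, 1L)
  # disjoint columns are all retained whatever the seed
  cols2 <- list(list(cells = c(A = 1L, B = 1L), note = "x"),
                list(cells = c(A = 2L, B = 2L), note = "y"))
  for (seed in 0:3)
    expect_length(remove_conflicts(cols2, restarts = 1, seed = seed), 2L)
})

crafted_conflicts <- function() {
  list(list(cells = c(A = 1L, B = 1L), note = "c1"),
       list(cells = c(A = 2L, B = 1L), note = "c2"),
       list(cells = c(A = 1L, C = 1L), note = "c3"),
       list(cells = c(C = 2L, D = 1L), note = "c4"),
       list(cells = c(C = 2L, D = 2L), note = "c5"),
       list(cells = c(A = 3L, B = 3L, C = 3L, D = 3L), note = "c6"))
}

test_that("best-of-20 restarts reaches the exhaustive ordering optimum", {
  cols <- crafted_conflicts()
  opt <- best_over_all_orderings(cols)
  expect_equal(opt, 10)
  got <- columns_score(remove_conflicts(cols, restarts = 20, seed = 0))
  expect_gte(got, columns_score(cols[greedy_accept(cols, seq_along(cols))]))
  expect_equal(got, opt)
})

test_that("the best-of-n score is monotone in the number of restarts", {
  cols <- crafted_conflicts()
  for (seed in 0:4) {
    scores <- vapply(c(1, 5, 20), function(r)
      columns_score(remove_conflicts(cols, restarts = r, seed = seed)), 0)
    expect_true(all(diff(scores) >= 0))
  }
})

test_that("branch groups merge adjacent columns and separate anchors", {
  mols <- list(with_residue("GA", 3, c("C1b", "O1a")),
               with_residue("GB", 3, c("C1b", "O1a")),
               clone_molecule(monolignol_panel()[[1]], "GC"))
  aln <- mucha(mols)
  bc <- branch_columns(aln)
  expect_length(unique(vapply(bc, function(c) c$group, "")), 1L)
  # isolated single column forms a singleton group
  cols <- list(list(cells = c(GA = 12L, GB = 12L), note = "n1"))
  g <- group_branches(cols, stats::setNames(mols[1:2], c("GA", "GB")))
  expect_identical(g[[1]]$group, "B1")
  # columns non-adjacent in the molecules fall into distinct groups
  cols2 <- list(list(cells = c(GA = 12L, GB = 12L), note = "n1"),
                list(cells = c(GA = 8L, GB = 8L), note = "n2"))
  g2 <- group_branches(cols2, stats::setNames(mols[1:2], c("GA", "GB")))
  expect_length(unique(vapply(g2, function(c) c$group, "")), 2L)
})

test_that("every branch group has >= 2 members and no core overlap", {
  aln <- mucha(monolignol_panel(include_glucoside = TRUE))
  core_atoms <- lapply(names(aln$molecules), function(id)
    vapply(Filter(function(c) c$role == "core", aln$columns),
           function(col) col$cells[[id]], 1L))
  names(core_atoms) <- names(aln$molecules)
  for (col in branch_columns(aln)) {
    expect_gte(length(col$cells), 2L)
    for (id in names(col$cells))
      expect_false(col$cells[[id]] %in% core_atoms[[id]])
  }
  expect_true(conflict_free(aln$columns))
})
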