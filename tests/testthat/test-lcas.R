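test_that("canonical orientation collapses a string and its reversal", {
  s <- sinapic_acid()
  st <- atom_string(s, c(11, 7, 1, 6))
  expect_identical(canonical_orientation(st)$atoms,
                   canonical_orientation(atom_string(s, rev(st$atoms)))$atoms)
  # idempotent
  once <- canonical_orientation(st)
  expect_identical(canonical_orientation(once)$atoms, once$atoms)
  # palindromic labels: tie broken deterministically by the index sequence
  pm <- path_molecule("PAL", c("C1a", "C1b", "C1a"))
  expect_identical(canonical_orientation(atom_string(pm, c(3, 2, 1)))$atoms,
                   canonical_orientation(atom_string(pm, c(1, 2, 3)))$atoms)
})

test_that("the fixture pair has one maximal string class, two instances each", {
  sets <- find_lcas(list(sinapic_acid(), p_coumaryl_alcohol_glucoside()))
  expect_length(sets, 1L)
  expect_identical(sets[[1]]$length, 4L)
  counts <- lengths(sets[[1]]$instances)
  expect_identical(unname(counts), c(2L, 2L))
  # labels of the shared string: the chain plus two ring carbons
  labs <- sets[[1]]$instances[["C00482"]][[1]]$labels
  expect_setequal(labs, c("C2b", "C2b", "C8y", "C8x"))
})

test_that("level-wise search equals brute-force path enumeration", {
  # two copies of the same molecule: LCAS is its longest unique simple path
  for (seed in c(7, 101:115)) {
    m1 <- random_molecule(seed, n_atoms = 10L)
    m2 <- clone_molecule(m1, "COPY")
    sets <- find_lcas(list(m1, m2))
    got <- sort(vapply(sets, function(s) s$key, ""))
    expect_identical(got, brute_lcas_keys(list(m1, m2)))
  }
  # independent random pairs
  for (seed in 121:140) {
    m1 <- random_molecule(seed, n_atoms = 9L)
    m2 <- random_molecule(seed + 5000L, n_atoms = 9L)
    got <- sort(vapply(find_lcas(list(m1, m2)), function(s) s$key, ""))
    want <- brute_lcas_keys(list(m1, m2))
    expect_identical(got, want)
  }
})

test_that("prefixes of a common string class are themselves common", {
  # justifies the level-wise pruning
  m1 <- sinapic_acid(); m2 <- p_coumaryl_alcohol_glucoside()
  sets <- find_lcas(list(m1, m2))
  inst <- sets[[1]]$instances[["C00482"]][[1]]
  d1 <- fw_distances(m1); d2 <- fw_distances(m2)
  all2 <- vapply(all_simple_paths_brute(m2), function(p)
    brute_string_key(m2, p, d2), "")
  for (L in seq_len(length(inst$atoms) - 1L)) {
    prefix_key <- brute_string_key(m1, inst$atoms[seq_len(L)], d1)
    expect_true(prefix_key %in% all2)
  }
})

test_that("molecules with disjoint label sets share no string", {
  m1 <- path_molecule("ALLC", c("C1a", "C1b", "C1a"))
  m2 <- path_molecule("ALLO", c("O1a", "O2a", "O1a"))
  expect_length(find_lcas(list(m1, m2)), 0L)
})

test_that("output is invariant under molecule order and atom renumbering", {
  m1 <- sinapic_acid(); m2 <- p_coumaryl_alcohol_glucoside()
  k12 <- sort(vapply(find_lcas(list(m1, m2)), function(s) s$key, ""))
  k21 <- sort(vapply(find_lcas(list(m2, m1)), function(s) s$key, ""))
  expect_identical(k12, k21)
  set.seed(9)
  m1p <- permute_atom_indices(m1, sample(16))
  kp <- sort(vapply(find_lcas(list(m1p, m2)), function(s) s$key, ""))
  expect_identical(kp, k12)
})

test_that("symmetric instances give equal representative objectives", {
  sets <- find_lcas(list(sinapic_acid(), p_coumaryl_alcohol_glucoside()))
  inst <- sets[[1]]$instances
  cache <- new_score_cache()
  vals <- c()
  for (i in 1:2) for (j in 1:2) {
    vals <- c(vals, string_decaf_score(inst[[1]][[i]], inst[[2]][[j]], cache))
  }
  expect_equal(max(vals), min(vals))
  rep <- select_representative(sets)
  expect_s3_class(rep, "seed_alignment")
  expect_equal(rep$value, vals[1])
})

test_that("single-instance seeds are returned unchanged", {
  m1 <- path_molecule("S1", c("C1a", "O2a", "C8y"))
  m2 <- path_molecule("S2", c("C1a", "O2a", "C8y"))
  sets <- find_lcas(list(m1, m2))
  expect_length(sets, 1L)
  rep <- select_representative(sets)
  expect_identical(lengths(lapply(rep$strings, function(s) s$atoms)),
                   c(S1 = 3L, S2 = 3L))
})

test_that("the genetic algorithm attains the exhaustive optimum on 2x2x2", {
  # three copies of a symmetric molecule, forced through the GA path
  base <- sinapic_acid()
  mols <- list(base, clone_molecule(base, "M2"), clone_molecule(base, "M3"))
  sets <- find_lcas(mols)
  sets_small <- sets[which.max(vapply(sets, function(s)
    prod(lengths(s$instances)), 0))]
  exh <- select_representative(sets_small, mucha_config(seed = 1))
  for (seed in c(1, 2, 3)) {
    ga <- select_representative(sets_small,
                                mucha_config(seed = seed,
                                             exhaustive_limit = 1L,
                                             ga_generations = 20L))
    expect_equal(ga$value, exh$value)
  }
})
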