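# Independent oracles used to cross-check the package implementation.
# Everything here is computed from the raw atom/bond tables, without the
# package's BFS/igraph machinery.

# Floyd-Warshall all-pairs shortest paths from the bond table
fw_distances <- function(mol) {
  idx <- as.character(mol$atoms$index)
  n <- length(idx)
  d <- matrix(Inf, n, n, dimnames = list(idx, idx))
  diag(d) <- 0
  if (nrow(mol$bonds) > 0) {
    for (r in seq_len(nrow(mol$bonds))) {
      a <- as.character(mol$bonds$a[r]); b <- as.character(mol$bonds$b[r])
      d[a, b] <- 1; d[b, a] <- 1
    }
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      nd <- d[i, k] + d[k, ]
      upd <- nd < d[i, ]
      d[i, upd] <- nd[upd]
    }
  }
  storage.mode(d) <- "integer"
  d
}

# adjacency list straight from the bond table
adj_from_bonds <- function(mol) {
  idx <- as.character(mol$atoms$index)
  adj <- stats::setNames(lapply(idx, function(x) integer()), idx)
  if (nrow(mol$bonds) > 0) {
    for (r in seq_len(nrow(mol$bonds))) {
      a <- as.character(mol$bonds$a[r]); b <- as.character(mol$bonds$b[r])
      adj[[a]] <- c(adj[[a]], mol$bonds$b[r])
      adj[[b]] <- c(adj[[b]], mol$bonds$a[r])
    }
  }
  adj
}

# every simple path (directed) in the molecule, as integer vectors
all_simple_paths_brute <- function(mol) {
  adj <- adj_from_bonds(mol)
  paths <- list()
  extend <- function(path) {
    paths[[length(paths) + 1L]] <<- path
    for (nb in adj[[as.character(path[length(path)])]]) {
      if (!(nb %in% path)) extend(c(path, nb))
    }
  }
  for (a in mol$atoms$index) extend(a)
  paths
}

# canonical (labels, self-DMAID) key of a path, from oracle distances
brute_string_key <- function(mol, atoms, d) {
  labs <- unname(mol$labels[as.character(atoms)])
  D <- d[as.character(atoms), as.character(atoms), drop = FALSE]
  rl <- rev(seq_along(atoms))
  k1 <- paste(c(labs, as.integer(D)), collapse = ",")
  k2 <- paste(c(rev(labs), as.integer(D[rl, rl, drop = FALSE])),
              collapse = ",")
  min(k1, k2)
}

# brute-force longest common atom strings: enumerate all simple paths per
# molecule, group by canonical key, keep keys covering all molecules,
# return the keys of maximal length
brute_lcas_keys <- function(mols) {
  per <- lapply(mols, function(m) {
    d <- fw_distances(m)
    paths <- all_simple_paths_brute(m)
    list(keys = vapply(paths, function(p) brute_string_key(m, p, d), ""),
         lens = lengths(paths))
  })
  common <- Reduce(intersect, lapply(per, function(x) unique(x$keys)))
  if (length(common) == 0L) return(character())
  lens <- per[[1L]]$lens[match(common, per[[1L]]$keys)]
  sort(common[lens == max(lens)])
}

# edge lies on a cycle iff its endpoints stay connected after removal
ring_edges_brute <- function(mol) {
  n_edges <- nrow(mol$bonds)
  vapply(seq_len(n_edges), function(e) {
    adj <- adj_from_bonds(mol)
    a <- mol$bonds$a[e]; b <- mol$bonds$b[e]
    adj[[as.character(a)]] <- setdiff(adj[[as.character(a)]], b)
    adj[[as.character(b)]] <- setdiff(adj[[as.character(b)]], a)
    seen <- a; queue <- a
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (nb in adj[[as.character(v)]]) {
        if (!(nb %in% seen)) { seen <- c(seen, nb); queue <- c(queue, nb) }
      }
    }
    b %in% seen
  }, TRUE)
}

ring_bond_count_brute <- function(mol, atom) {
  ring <- ring_edges_brute(mol)
  sum(ring & (mol$bonds$a == atom | mol$bonds$b == atom))
}

# --- shared crafted fixtures ---

# 10-atom fused bicyclic: two 6-rings sharing the 1-2 edge
fused_bicyclic <- function() {
  kcf_molecule("FUSED",
    data.frame(index = 1:10, label = rep("C8x", 10)),
    data.frame(a = c(1, 2, 3, 4, 5, 6, 2, 7, 8, 9, 10),
               b = c(2, 3, 4, 5, 6, 1, 7, 8, 9, 10, 1),
               order = 1L))
}

# n-atom path molecule with the given labels
path_molecule <- function(id, labels) {
  n <- length(labels)
  kcf_molecule(id,
    data.frame(index = seq_len(n), label = labels),
    if (n > 1)
      data.frame(a = seq_len(n - 1L), b = seq(2L, n), order = 1L)
    else data.frame(a = integer(), b = integer(), order = integer()))
}

# duplicate a molecule under a new id
clone_molecule <- function(mol, id) kcf_molecule(id, mol$atoms, mol$bonds)

# total atoms over columns (conflict-removal score)
columns_score <- function(columns) {
  sum(vapply(columns, function(col) length(col$cells), 1L))
}

# are the columns pairwise atom-disjoint (and disjoint from extra sets)?
conflict_free <- function(columns) {
  keys <- unlist(lapply(columns, function(col)
    paste(names(col$cells), col$cells, sep = "#")))
  !anyDuplicated(keys)
}

# greedy conflict removal for one fixed ordering (oracle helper)
greedy_accept <- function(columns, ord) {
  taken <- character(0)
  sel <- logical(length(columns))
  for (i in ord) {
    keys <- paste(names(columns[[i]]$cells), columns[[i]]$cells, sep = "#")
    if (!any(keys %in% taken)) { sel[i] <- TRUE; taken <- c(taken, keys) }
  }
  sel
}

# exhaustive best greedy score over every column ordering (n <= 7)
best_over_all_orderings <- function(columns) {
  n <- length(columns)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  max(vapply(perms(seq_len(n)), function(ord) {
    sum(lengths(lapply(columns[greedy_accept(columns, ord)],
                       function(col) col$cells)))
  }, 0))
}
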