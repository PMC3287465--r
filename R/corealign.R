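# internal constructor for the alignment container
new_alignment <- function(mols, columns, config) {
  ids <- vapply(mols, function(m) m$id, "")
  names(mols) <- ids
  structure(list(molecules = mols, columns = columns, config = config),
            class = "mucha_alignment")
}

# atoms already used per molecule id, as a named list of integer vectors
used_atoms <- function(columns, ids) {
  out <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) out[[id]] <- integer()
  for (col in columns) {
    for (id in names(col$cells))
      out[[id]] <- c(out[[id]], col$cells[[id]])
  }
  out
}

#' Refine an ambiguous candidate group into alignment columns
#'
#' A candidate group (one set of atoms per molecule sharing atom species
#' and anchored-DMAID) is refined by a fixed cascade until the atoms pair
#' one-to-one across molecules: (1) number of incident ring bonds,
#' (2) atom class, (3) full KEGG atom type, (4) ascending atom-index
#' order, pairing the i-th smallest index in each molecule. The cascade
#' stops, per subgroup, at the first stage achieving per-molecule
#' uniqueness; subgroups absent from some molecule are dropped, and a
#' group still carrying unequal candidate counts after stage 3 is dropped
#' entirely rather than force-paired.
#'
#' @param group named list (molecule id -> integer vector of candidate
#'   atoms).
#' @param mols named list of molecules covering \code{names(group)}.
#' @param stage internal recursion stage (1..4).
#' @return list of named integer vectors, each a column's cells; possibly
#'   empty.
#' @export
disambiguate <- function(group, mols, stage = 1L) {
  counts <- lengths(group)
  if (any(counts == 0L)) return(list())
  if (all(counts == 1L)) {
    cells <- vapply(group, function(a) a[1L], 1L)
    return(list(stats::setNames(cells, names(group))))
  }
  if (stage <= 3L) {
    subkey <- switch(stage,
      function(m, a) as.character(ring_bond_count(m, a)),
      function(m, a) label_at_level(unname(m$labels[as.character(a)]), "class"),
      function(m, a) label_at_level(unname(m$labels[as.character(a)]), "full"))
    keys <- mapply(function(id, atoms) {
      vapply(atoms, function(a) subkey(mols[[id]], a), "")
    }, names(group), group, SIMPLIFY = FALSE)
    vals <- sort(unique(unlist(keys)))
    out <- list()
    for (v in vals) {
      sub <- mapply(function(atoms, k) atoms[k == v], group, keys,
                    SIMPLIFY = FALSE)
      out <- c(out, disambiguate(sub, mols, stage + 1L))
    }
    return(out)
  }
  # stage 4: symmetric leftovers paired by index order
  k <- counts[[1L]]
  if (!all(counts == k)) return(list())
  lapply(seq_len(k), function(j) {
    vapply(group, function(a) sort(a)[j], 1L)
  })
}

# one growth pass shared by the core and branch stages: candidates adjacent
# to the current alignment atoms, grouped by (species, distances to the
# anchor atoms in column order), promoted via the disambiguation cascade.
# mols: named list restricted to the participating molecules.
# anchor: named list id -> integer vector (anchor atoms, common column order).
# used: named list id -> atoms excluded from candidacy (already aligned).
# forbidden: named list id -> additional atoms never eligible (e.g. core
#   atoms during the branch stage).
grow_once <- function(mols, anchor, used, forbidden = NULL) {
  ids <- names(mols)
  cand <- lapply(ids, function(id) {
    m <- mols[[id]]
    front <- unique(unlist(lapply(anchor[[id]], function(a) neighbors_of(m, a))))
    front <- setdiff(front, used[[id]])
    if (!is.null(forbidden)) front <- setdiff(front, forbidden[[id]])
    sort(front)
  })
  names(cand) <- ids
  if (all(lengths(cand) == 0L)) return(list())
  keys <- lapply(ids, function(id) {
    m <- mols[[id]]
    vapply(cand[[id]], function(a) {
      paste(label_at_level(unname(m$labels[as.character(a)]), "species"),
            paste(m$dist[as.character(a), as.character(anchor[[id]])],
                  collapse = ","),
            sep = "|")
    }, "")
  })
  names(keys) <- ids
  common <- Reduce(intersect, lapply(keys, unique))
  if (length(common) == 0L) return(list())
  cols <- list()
  for (k in sort(common)) {
    group <- mapply(function(atoms, kk) atoms[kk == k], cand, keys,
                    SIMPLIFY = FALSE)
    for (cells in disambiguate(group, mols)) {
      cols[[length(cols) + 1L]] <- list(cells = cells, key = k)
    }
  }
  cols
}

#' Extend a seed alignment into the core substructure
#'
#' Iterative frontier growth: atoms adjacent to the current core are
#' grouped by atom species and anchored-DMAID against the current core
#' columns; a group is promoted to new core columns only when, after the
#' disambiguation cascade, it identifies exactly one atom per molecule in
#' every query molecule. The anchor is re-computed against the full grown
#' core at each iteration, and iteration stops at the fixpoint. Core
#' columns always cover all molecules and never conflict.
#'
#' @param mols list of \code{\link{kcf_molecule}} objects (unique ids).
#' @param seed a \code{seed_alignment} from
#'   \code{\link{select_representative}}.
#' @param config a \code{\link{mucha_config}}.
#' @return a \code{mucha_alignment} containing core columns only.
#' @export
extend_core <- function(mols, seed, config = mucha_config()) {
  ids <- vapply(mols, function(m) m$id, "")
  names(mols) <- ids
  L <- length(seed$strings[[1L]]$atoms)
  columns <- lapply(seq_len(L), function(p) {
    cells <- vapply(seed$strings[ids], function(s) s$atoms[p], 1L)
    list(cells = stats::setNames(cells, ids), role = "core", note = "seed")
  })
  repeat {
    anchor <- lapply(ids, function(id)
      vapply(columns, function(col) col$cells[[id]], 1L))
    names(anchor) <- ids
    used <- used_atoms(columns, ids)
    grown <- grow_once(mols, anchor, used)
    if (length(grown) == 0L) break
    for (g in grown) {
      columns[[length(columns) + 1L]] <-
        list(cells = g$cells, role = "core",
             note = paste0("extend:", g$key))
    }
  }
  new_alignment(mols, columns, config)
}
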