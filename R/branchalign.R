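# canonical key of a branch string: species-level label sequence plus the
# anchored-DMAID against the core (rows in string order), minimized over the
# two traversal directions
scas_key <- function(mol, atoms, core_atoms) {
  labs <- label_at_level(unname(mol$labels[as.character(atoms)]), "species")
  A <- mol$dist[as.character(atoms), as.character(core_atoms), drop = FALSE]
  kf <- paste(c(labs, as.integer(t(A))), collapse = ",")
  ratoms <- rev(seq_along(atoms))
  kb <- paste(c(rev(labs), as.integer(t(A[ratoms, , drop = FALSE]))),
              collapse = ",")
  if (kb < kf) kb else kf
}

# canonical orientation for a branch instance, by (species labels, anchored
# matrix, atom indices)
scas_canonical <- function(mol, atoms, core_atoms) {
  if (length(atoms) == 1L) return(atoms)
  labs <- label_at_level(unname(mol$labels[as.character(atoms)]), "species")
  A <- as.integer(t(mol$dist[as.character(atoms), as.character(core_atoms),
                             drop = FALSE]))
  rlabs <- rev(labs)
  rA <- as.integer(t(mol$dist[as.character(rev(atoms)),
                              as.character(core_atoms), drop = FALSE]))
  fwd <- list(labs = labs, dm = A, idx = atoms)
  bwd <- list(labs = rlabs, dm = rA, idx = rev(atoms))
  if (lex_leq(fwd, bwd)) atoms else rev(atoms)
}

#' Find short common atom strings over the non-core atoms
#'
#' Branch seeds: simple paths over atoms outside the core substructure,
#' keyed by their species-level label sequence and their anchored-DMAID
#' against the core columns (species matching is deliberately looser than
#' the full-label matching of the core seed stage). Strings start at length
#' 1 and are extended greedily for as long as an extension keeps enough
#' support; unlike the core seed, a branch string need not appear in all
#' molecules — any key shared by at least \code{config$min_support}
#' molecules is kept. A key is retired only when a one-atom-longer key with
#' the identical member set supersedes it in every member molecule;
#' leftover overlaps are resolved later by randomized conflict removal.
#'
#' @param mols named list of all query molecules.
#' @param core a core-only \code{mucha_alignment} from
#'   \code{\link{extend_core}}.
#' @param config a \code{\link{mucha_config}}.
#' @return list of branch seeds: each a list with \code{key}, \code{length},
#'   \code{members}, and \code{instances} (named list over member ids of
#'   integer atom vectors in canonical orientation).
#' @export
find_scas <- function(mols, core, config = mucha_config()) {
  ids <- vapply(mols, function(m) m$id, "")
  names(mols) <- ids
  core_atoms <- lapply(ids, function(id)
    vapply(core$columns, function(col) col$cells[[id]], 1L))
  names(core_atoms) <- ids

  noncore <- lapply(ids, function(id)
    setdiff(mols[[id]]$atoms$index, core_atoms[[id]]))
  names(noncore) <- ids

  cur <- lapply(ids, function(id) lapply(noncore[[id]], identity))
  names(cur) <- ids
  parents <- lapply(ids, function(id) rep(NA_character_, length(cur[[id]])))
  names(parents) <- ids

  seeds <- list()
  prev_keys <- NULL  # surviving keys of previous level, with member sets
  repeat {
    keys <- lapply(ids, function(id) {
      vapply(cur[[id]], function(a)
        scas_key(mols[[id]], a, core_atoms[[id]]), "")
    })
    names(keys) <- ids
    support <- table(unlist(lapply(keys, unique)))
    surviving <- names(support)[support >= config$min_support]
    # which previous-level keys were extended into a surviving key, per mol
    if (!is.null(prev_keys)) {
      extended <- lapply(ids, function(id) {
        unique(parents[[id]][keys[[id]] %in% surviving])
      })
      names(extended) <- ids
      for (pk in names(prev_keys)) {
        members <- prev_keys[[pk]]$members
        superseded <- all(vapply(members, function(id) pk %in% extended[[id]],
                                 TRUE))
        if (!superseded) seeds[[length(seeds) + 1L]] <- prev_keys[[pk]]
      }
    }
    if (length(surviving) == 0L) break
    # record surviving keys at this level
    prev_keys <- list()
    for (k in surviving) {
      members <- ids[vapply(ids, function(id) k %in% keys[[id]], TRUE)]
      inst <- lapply(members, function(id) {
        hits <- cur[[id]][keys[[id]] == k]
        canon <- lapply(hits, function(a)
          scas_canonical(mols[[id]], a, core_atoms[[id]]))
        sig <- vapply(canon, function(a) paste(a, collapse = ","), "")
        canon[!duplicated(sig)]
      })
      names(inst) <- members
      prev_keys[[k]] <- list(key = k, length = length(cur[[members[1L]]][[
        which(keys[[members[1L]]] == k)[1L]]]),
        members = members, instances = inst)
    }
    # extend surviving instances over non-core atoms only
    nxt <- lapply(ids, function(id) {
      out <- list(); par <- character()
      keep <- keys[[id]] %in% surviving
      for (w in which(keep)) {
        s <- cur[[id]][[w]]
        for (nb in neighbors_of(mols[[id]], s[length(s)])) {
          if (!(nb %in% s) && nb %in% noncore[[id]]) {
            out[[length(out) + 1L]] <- c(s, nb)
            par <- c(par, keys[[id]][w])
          }
        }
      }
      list(inst = out, par = par)
    })
    names(nxt) <- ids
    if (all(vapply(nxt, function(x) length(x$inst), 1L) == 0L)) {
      # nothing extends: every surviving key at this level is maximal
      for (pk in names(prev_keys))
        seeds[[length(seeds) + 1L]] <- prev_keys[[pk]]
      break
    }
    cur <- lapply(nxt, function(x) x$inst)
    parents <- lapply(nxt, function(x) x$par)
  }
  seeds
}

#' Extend a branch seed into a branch substructure
#'
#' Same growth machinery as \code{\link{extend_core}}, restricted to the
#' seed's member molecules and to atoms outside the core: frontier atoms
#' are grouped by species and by their distances to the anchor (core
#' columns followed by the branch's own columns), refined by the
#' disambiguation cascade, and promoted when they pair one-to-one across
#' all member molecules. Core atoms are frozen and never absorbed.
#'
#' @param mols named list of all query molecules.
#' @param seed_strings named list (member id -> integer atom vector), one
#'   instance of the branch seed per member molecule.
#' @param core core-only \code{mucha_alignment}.
#' @return list of branch columns; each a list with \code{cells} (named
#'   integer vector over the member ids) and \code{note}.
#' @export
extend_branch <- function(mols, seed_strings, core) {
  members <- names(seed_strings)
  mm <- mols[members]
  ids_all <- vapply(mols, function(m) m$id, "")
  core_atoms <- lapply(members, function(id)
    vapply(core$columns, function(col) col$cells[[id]], 1L))
  names(core_atoms) <- members
  L <- length(seed_strings[[1L]])
  columns <- lapply(seq_len(L), function(p) {
    cells <- vapply(seed_strings, function(a) a[p], 1L)
    list(cells = stats::setNames(cells, members), note = "scas-seed")
  })
  repeat {
    anchor <- lapply(members, function(id)
      c(core_atoms[[id]], vapply(columns, function(col) col$cells[[id]], 1L)))
    names(anchor) <- members
    used <- used_atoms(columns, members)
    grown <- grow_once(mm, anchor, used, forbidden = core_atoms)
    if (length(grown) == 0L) break
    for (g in grown) {
      columns[[length(columns) + 1L]] <-
        list(cells = g$cells, note = paste0("extend:", g$key))
    }
  }
  columns
}

#' Randomized greedy removal of conflicting alignment columns
#'
#' Independently generated branch columns may claim the same atom. Per
#' restart, columns are visited in random order and accepted greedily when
#' disjoint from all previously accepted columns; the restart score is the
#' total number of atoms in the accepted columns, and the best of
#' \code{restarts} restarts wins. Deterministic for a fixed seed, and the
#' best-of-n score is monotone in n for a fixed seed stream.
#'
#' @param columns list of columns (lists with a \code{cells} named integer
#'   vector).
#' @param restarts number of random restarts (default 20).
#' @param seed RNG seed.
#' @return the accepted columns, in their original relative order.
#' @export
remove_conflicts <- function(columns, restarts = 20L, seed = 0L) {
  n <- length(columns)
  if (n <= 1L) return(columns)
  atom_keys <- lapply(columns, function(col)
    paste(names(col$cells), col$cells, sep = "#"))
  sizes <- lengths(atom_keys)
  best_sel <- NULL; best_score <- -1L
  with_local_seed(seed, {
    for (r in seq_len(restarts)) {
      ord <- sample.int(n)
      taken <- character(0)
      sel <- logical(n)
      for (i in ord) {
        if (!any(atom_keys[[i]] %in% taken)) {
          sel[i] <- TRUE
          taken <- c(taken, atom_keys[[i]])
        }
      }
      score <- sum(sizes[sel])
      if (score > best_score) { best_score <- score; best_sel <- sel }
    }
  })
  columns[best_sel]
}

#' Group conflict-free branch columns into building blocks
#'
#' Columns with the same member-molecule set merge into one branch group
#' when their atoms are bonded in every member molecule; connected
#' components of this relation are the building blocks. Group identifiers
#' \code{B1, B2, ...} are assigned deterministically by decreasing total
#' atom count, then anchor signature, then the lexical order of the cells.
#'
#' @param columns conflict-free branch columns (lists with \code{cells}).
#' @param mols named list of molecules.
#' @return the columns, each annotated with \code{role = "branch"} and a
#'   \code{group} id, ordered by group then within-group discovery order.
#' @export
group_branches <- function(columns, mols) {
  n <- length(columns)
  if (n == 0L) return(list())
  member_sig <- vapply(columns, function(col)
    paste(sort(names(col$cells)), collapse = ","), "")
  adj <- lapply(seq_len(n), function(i) integer())
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (member_sig[i] != member_sig[j]) next
      ok <- all(vapply(names(columns[[i]]$cells), function(id) {
        columns[[j]]$cells[[id]] %in%
          neighbors_of(mols[[id]], columns[[i]]$cells[[id]])
      }, TRUE))
      if (ok) {
        adj[[i]] <- c(adj[[i]], j)
        adj[[j]] <- c(adj[[j]], i)
      }
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, adj[[v]][is.na(comp[adj[[v]]])])
    }
  }
  # deterministic group ordering
  ginfo <- lapply(seq_len(cid), function(g) {
    idx <- which(comp == g)
    total <- sum(vapply(idx, function(i) length(columns[[i]]$cells), 1L))
    anchor_sig <- columns[[idx[1L]]]$note
    lex <- paste(vapply(idx, function(i)
      paste(names(columns[[i]]$cells), columns[[i]]$cells,
            sep = ":", collapse = ";"), ""), collapse = "|")
    list(idx = idx, total = total, anchor = anchor_sig, lex = lex)
  })
  ord <- order(-vapply(ginfo, `[[`, 0, "total"),
               vapply(ginfo, `[[`, "", "anchor"),
               vapply(ginfo, `[[`, "", "lex"))
  out <- list()
  for (rank in seq_along(ord)) {
    g <- ginfo[[ord[rank]]]
    for (i in g$idx) {
      col <- columns[[i]]
      col$role <- "branch"
      col$group <- paste0("B", rank)
      out[[length(out) + 1L]] <- col
    }
  }
  out
}
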