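#' Construct a molecule graph
#'
#' Builds the hydrogen-suppressed labeled graph used throughout the package:
#' atoms carry KEGG atom labels (e.g. \code{"C8y"}), bonds carry integer
#' orders. The constructor validates the graph (unique 1-based atom indices,
#' referential integrity of bonds, connectedness) and precomputes the
#' machinery every later stage relies on: the all-pairs shortest-path
#' distance matrix (bond counts, breadth-first search) and the per-atom
#' count of incident ring bonds (non-bridge edges).
#'
#' @param id molecule identifier (e.g. a KEGG Compound ID such as "C00482").
#' @param atoms data.frame with columns \code{index} (unique positive
#'   integers), \code{label} (KEGG atom label, 2-4 characters), and
#'   optionally \code{x}, \code{y} drawing coordinates.
#' @param bonds data.frame with columns \code{a}, \code{b} (atom indices)
#'   and \code{order} (integer >= 1). May have zero rows for a single-atom
#'   molecule.
#' @return an object of class \code{kcf_molecule}: a list with elements
#'   \code{id}, \code{atoms}, \code{bonds}, plus cached \code{labels}
#'   (named character), \code{adj} (named list of neighbour indices),
#'   \code{dist} (named integer distance matrix) and \code{ring_bonds}
#'   (named integer vector).
#' @export
kcf_molecule <- function(id, atoms, bonds) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("molecule id must be a non-empty string")
  atoms <- as.data.frame(atoms)
  bonds <- as.data.frame(bonds)
  if (nrow(atoms) < 1L)
    stop(sprintf("molecule %s: at least one atom is required", id))
  idx <- as.integer(atoms$index)
  if (anyNA(idx) || any(idx < 1L))
    stop(sprintf("molecule %s: atom indices must be positive integers", id))
  if (anyDuplicated(idx))
    stop(sprintf("molecule %s: duplicate atom index %d", id,
                 idx[duplicated(idx)][1L]))
  labs <- as.character(atoms$label)
  bad <- !grepl("^[A-Z][A-Za-z0-9]{0,3}$", labs) | nchar(labs) < 1L
  if (any(bad))
    stop(sprintf("molecule %s: malformed atom label '%s'", id, labs[bad][1L]))
  atoms$index <- idx
  atoms$label <- labs
  atoms$element <- substr(labs, 1L, 1L)
  if (is.null(atoms$x)) atoms$x <- NA_real_
  if (is.null(atoms$y)) atoms$y <- NA_real_
  atoms <- atoms[, c("index", "label", "element", "x", "y")]

  if (nrow(bonds) > 0L) {
    a <- as.integer(bonds$a); b <- as.integer(bonds$b)
    ord <- as.integer(bonds$order)
    if (anyNA(a) || anyNA(b) || anyNA(ord) || any(ord < 1L))
      stop(sprintf("molecule %s: malformed bond record", id))
    miss <- setdiff(c(a, b), idx)
    if (length(miss))
      stop(sprintf("molecule %s: bond references missing atom %d",
                   id, miss[1L]))
    if (any(a == b))
      stop(sprintf("molecule %s: self-bond on atom %d", id, a[a == b][1L]))
    key <- paste(pmin(a, b), pmax(a, b))
    if (anyDuplicated(key))
      stop(sprintf("molecule %s: duplicate bond %s", id,
                   key[duplicated(key)][1L]))
    bonds <- data.frame(a = a, b = b, order = ord)
  } else {
    bonds <- data.frame(a = integer(), b = integer(), order = integer())
  }

  g <- igraph::make_empty_graph(n = nrow(atoms), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(idx))
  if (nrow(bonds) > 0L)
    g <- igraph::add_edges(g, as.character(rbind(bonds$a, bonds$b)))
  if (!igraph::is_connected(g))
    stop(sprintf("molecule %s: graph is disconnected", id))

  d <- igraph::distances(g, algorithm = "unweighted")
  storage.mode(d) <- "integer"
  d <- d[as.character(idx), as.character(idx), drop = FALSE]

  # ring bonds: edges lying on >= 1 cycle, i.e. non-bridges
  rb <- stats::setNames(integer(nrow(atoms)), as.character(idx))
  if (nrow(bonds) > 0L) {
    bridge_ids <- igraph::bridges(g)
    nonbridge <- setdiff(seq_len(nrow(bonds)), as.integer(bridge_ids))
    for (e in nonbridge) {
      rb[as.character(bonds$a[e])] <- rb[as.character(bonds$a[e])] + 1L
      rb[as.character(bonds$b[e])] <- rb[as.character(bonds$b[e])] + 1L
    }
  }

  adj <- lapply(as.character(idx), function(v) {
    nb <- c(bonds$b[bonds$a == as.integer(v)], bonds$a[bonds$b == as.integer(v)])
    sort(as.integer(nb))
  })
  names(adj) <- as.character(idx)

  structure(list(id = id, atoms = atoms, bonds = bonds,
                 labels = stats::setNames(labs, as.character(idx)),
                 adj = adj, dist = d, ring_bonds = rb),
            class = "kcf_molecule")
}

#' @export
print.kcf_molecule <- function(x, ...) {
  cat(sprintf("<kcf_molecule %s: %d atoms, %d bonds>\n",
              x$id, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

#' Parse molecules from KCF text
#'
#' Reads one or more entries in the KEGG Chemical Function (KCF) dialect:
#' \preformatted{
#' ENTRY       C00482   Compound
#' ATOM        16
#'             1  C8y C  0.0  0.0
#'             ...
#' BOND        16
#'             1  1 2 2
#'             ...
#' ///
#' }
#' Parsing is whitespace-delimited and tolerant of column widths. Every
#' entry must be a connected graph; errors name the offending entry and
#' line.
#'
#' @param text a single string or a character vector of lines.
#' @return a list of \code{\link{kcf_molecule}} objects.
#' @export
parse_kcf <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1L]] else as.character(text)
  mols <- list()
  i <- 1L
  n <- length(lines)
  tok <- function(s) strsplit(trimws(s), "[[:space:]]+")[[1L]]
  while (i <= n) {
    while (i <= n && !nzchar(trimws(lines[i]))) i <- i + 1L
    if (i > n) break
    t <- tok(lines[i])
    if (t[1L] != "ENTRY")
      stop(sprintf("KCF parse error at line %d: expected ENTRY, got '%s'",
                   i, t[1L]))
    if (length(t) < 2L)
      stop(sprintf("KCF parse error at line %d: ENTRY has no identifier", i))
    id <- t[2L]
    i <- i + 1L
    atoms <- NULL; bonds <- NULL
    while (i <= n && !startsWith(trimws(lines[i]), "///")) {
      t <- tok(lines[i])
      if (identical(t[1L], "ATOM")) {
        na <- suppressWarnings(as.integer(t[2L]))
        if (is.na(na))
          stop(sprintf("entry %s, line %d: malformed ATOM count", id, i))
        rows <- vector("list", na)
        for (k in seq_len(na)) {
          i <- i + 1L
          if (i > n)
            stop(sprintf("entry %s: truncated ATOM block", id))
          f <- tok(lines[i])
          if (length(f) < 3L)
            stop(sprintf("entry %s, line %d: malformed ATOM line", id, i))
          rows[[k]] <- data.frame(
            index = suppressWarnings(as.integer(f[1L])),
            label = f[2L],
            x = if (length(f) >= 4L) suppressWarnings(as.numeric(f[4L])) else NA_real_,
            y = if (length(f) >= 5L) suppressWarnings(as.numeric(f[5L])) else NA_real_)
        }
        atoms <- do.call(rbind, rows)
        i <- i + 1L
      } else if (identical(t[1L], "BOND")) {
        nb <- suppressWarnings(as.integer(t[2L]))
        if (is.na(nb))
          stop(sprintf("entry %s, line %d: malformed BOND count", id, i))
        rows <- vector("list", nb)
        for (k in seq_len(nb)) {
          i <- i + 1L
          if (i > n)
            stop(sprintf("entry %s: truncated BOND block", id))
          f <- tok(lines[i])
          if (length(f) < 4L)
            stop(sprintf("entry %s, line %d: malformed BOND line", id, i))
          rows[[k]] <- data.frame(
            a = suppressWarnings(as.integer(f[2L])),
            b = suppressWarnings(as.integer(f[3L])),
            order = suppressWarnings(as.integer(f[4L])))
        }
        bonds <- if (nb > 0L) do.call(rbind, rows) else
          data.frame(a = integer(), b = integer(), order = integer())
        i <- i + 1L
      } else {
        i <- i + 1L  # unknown block line, ignored
      }
    }
    if (i <= n) i <- i + 1L  # consume ///
    if (is.null(atoms))
      stop(sprintf("entry %s: missing ATOM block", id))
    if (is.null(bonds))
      bonds <- data.frame(a = integer(), b = integer(), order = integer())
    mols[[length(mols) + 1L]] <- kcf_molecule(id, atoms, bonds)
  }
  if (length(mols) == 0L) stop("KCF parse error: no entries found")
  mols
}

#' Read molecules from KCF files
#'
#' @param paths character vector of file paths; multi-entry files allowed.
#' @return a list of \code{\link{kcf_molecule}} objects.
#' @export
read_kcf <- function(paths) {
  out <- list()
  for (p in paths) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p))
    out <- c(out, parse_kcf(readLines(p, warn = FALSE)))
  }
  out
}

#' Serialize a molecule to KCF text
#'
#' The writer emits the exact dialect accepted by \code{\link{parse_kcf}},
#' so \code{parse_kcf(write_kcf(m))} reproduces the molecule atom-for-atom
#' and bond-for-bond.
#'
#' @param mol a \code{kcf_molecule}.
#' @return a single string (KCF document for one entry).
#' @export
write_kcf <- function(mol) {
  stopifnot(inherits(mol, "kcf_molecule"))
  if (nrow(mol$atoms) == 0L) stop("cannot write an empty molecule")
  a <- mol$atoms
  b <- mol$bonds
  fmt_num <- function(v) ifelse(is.na(v), "0.0000", sprintf("%.4f", v))
  lines <- c(
    sprintf("ENTRY       %s   Compound", mol$id),
    sprintf("ATOM        %d", nrow(a)),
    sprintf("            %-3d %-4s %-2s %9s %9s",
            a$index, a$label, a$element, fmt_num(a$x), fmt_num(a$y)),
    sprintf("BOND        %d", nrow(b)),
    if (nrow(b) > 0L)
      sprintf("            %-3d %3d %3d %d", seq_len(nrow(b)), b$a, b$b, b$order),
    "///")
  paste(lines, collapse = "\n")
}

#' Renumber the atoms of a molecule
#'
#' Applies a permutation to the atom indices, relabeling bonds accordingly.
#' Used for numbering-invariance checks: alignments should have the same
#' column count whatever the (arbitrary, tool-assigned) atom numbering.
#'
#' @param mol a \code{kcf_molecule} with contiguous indices 1..n.
#' @param perm integer permutation of 1..n; old atom i becomes \code{perm[i]}.
#' @return a new \code{kcf_molecule}.
#' @export
permute_atom_indices <- function(mol, perm) {
  n <- nrow(mol$atoms)
  stopifnot(length(perm) == n, all(sort(perm) == seq_len(n)),
            all(sort(mol$atoms$index) == seq_len(n)))
  map <- stats::setNames(as.integer(perm), as.character(mol$atoms$index))
  a <- mol$atoms
  a$index <- map[as.character(a$index)]
  a <- a[order(a$index), , drop = FALSE]
  b <- mol$bonds
  if (nrow(b) > 0L) {
    b$a <- unname(map[as.character(b$a)])
    b$b <- unname(map[as.character(b$b)])
  }
  kcf_molecule(mol$id, a, b)
}
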