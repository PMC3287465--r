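#' Construct an atom string
#'
#' An atom string is a simple path in one molecule: an ordered sequence of
#' pairwise-distinct atom indices in which every consecutive pair is bonded.
#' Atom strings are the unit of the seed-and-extend alignment: the longest
#' common atom strings seed the core, short common atom strings seed the
#' branches.
#'
#' @param mol a \code{\link{kcf_molecule}}.
#' @param atoms integer vector of atom indices forming a simple path
#'   (length >= 1).
#' @return an object of class \code{atom_string}: list with \code{mol},
#'   \code{atoms}, and the derived \code{labels} sequence.
#' @export
atom_string <- function(mol, atoms) {
  stopifnot(inherits(mol, "kcf_molecule"))
  atoms <- as.integer(atoms)
  if (length(atoms) < 1L) stop("atom string must contain at least one atom")
  key <- as.character(atoms)
  if (!all(key %in% names(mol$labels)))
    stop(sprintf("molecule %s has no atom %s", mol$id,
                 key[!key %in% names(mol$labels)][1L]))
  if (anyDuplicated(atoms))
    stop("atom string atoms must be pairwise distinct")
  if (length(atoms) > 1L) {
    for (p in seq_len(length(atoms) - 1L)) {
      if (!(atoms[p + 1L] %in% neighbors_of(mol, atoms[p])))
        stop(sprintf("atoms %d and %d are not bonded in %s",
                     atoms[p], atoms[p + 1L], mol$id))
    }
  }
  structure(list(mol = mol, atoms = atoms,
                 labels = unname(mol$labels[key])),
            class = "atom_string")
}

#' @export
print.atom_string <- function(x, ...) {
  cat(sprintf("<atom_string %s: %s (%s)>\n", x$mol$id,
              paste(x$atoms, collapse = ","),
              paste(x$labels, collapse = "-")))
  invisible(x)
}

#' Self distance-matrix atom identifier
#'
#' The self-DMAID of an atom string is the square matrix of whole-molecule
#' shortest-path distances between the string's atoms, rows and columns in
#' string order. Distances are taken in the whole molecular graph, not in
#' the subgraph induced by the string (e.g. for a benzene-ring string
#' 1..5, the distance between the first and the fifth atom is 2, going
#' through the sixth ring atom outside the string). Two atom strings with
#' equal label sequences and equal self-DMAIDs are topologically
#' interchangeable, which is the membership test for common atom strings.
#'
#' @param mol a \code{\link{kcf_molecule}}.
#' @param string an \code{\link{atom_string}} or an integer vector of atom
#'   indices forming a simple path.
#' @return square integer matrix in string order.
#' @export
self_dmaid <- function(mol, string) {
  atoms <- if (inherits(string, "atom_string")) string$atoms else
    atom_string(mol, string)$atoms
  key <- as.character(atoms)
  m <- mol$dist[key, key, drop = FALSE]
  dimnames(m) <- list(key, key)
  m
}

#' Anchored distance-matrix atom identifier
#'
#' The anchored-DMAID of an atom string against an anchor string is the
#' (not necessarily square) matrix of whole-molecule distances from the
#' string's atoms (rows, string order) to the anchor's atoms (columns,
#' anchor order). It encodes where a string sits relative to the anchor
#' (typically the growing core alignment), so that identically shaped
#' branches attached at different positions are kept apart.
#'
#' @param mol a \code{\link{kcf_molecule}}.
#' @param string an \code{\link{atom_string}} or integer vector (rows).
#' @param anchor an \code{\link{atom_string}} or integer vector (columns);
#'   the anchor need not be a simple path (the core substructure is used as
#'   an anchor), so plain integer vectors are accepted unchecked.
#' @return \code{length(string) x length(anchor)} integer matrix.
#' @export
anchored_dmaid <- function(mol, string, anchor) {
  satoms <- if (inherits(string, "atom_string")) string$atoms else
    atom_string(mol, string)$atoms
  aatoms <- if (inherits(anchor, "atom_string")) anchor$atoms else as.integer(anchor)
  akey <- as.character(aatoms)
  if (!all(akey %in% names(mol$labels)))
    stop(sprintf("molecule %s has no atom %s", mol$id,
                 akey[!akey %in% names(mol$labels)][1L]))
  m <- mol$dist[as.character(satoms), akey, drop = FALSE]
  dimnames(m) <- list(as.character(satoms), akey)
  m
}

#' Compare two DMAID matrices
#'
#' Order-sensitive, entry-wise equality: two matrices are equal iff they
#' have the same shape and identical entries, with rows/columns in the
#' order fixed by the strings they came from. No permutation search is
#' performed; canonical string orientation guarantees comparability
#' across molecules.
#'
#' @param a,b integer matrices.
#' @return logical scalar.
#' @export
dmaid_equal <- function(a, b) {
  if (!identical(dim(a), dim(b))) return(FALSE)
  all(a == b)
}
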