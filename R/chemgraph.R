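#' All-pairs shortest-path distances of a molecule
#'
#' Distances are bond counts along shortest paths in the hydrogen-suppressed
#' graph, computed by breadth-first search once at construction time and
#' cached on the molecule; this accessor returns the cached matrix. Rows and
#' columns are named by atom index.
#'
#' @param mol a \code{\link{kcf_molecule}}.
#' @return integer matrix \code{d} with \code{d[i, j]} the shortest-path
#'   length between atoms \code{i} and \code{j}.
#' @export
all_pairs_distances <- function(mol) {
  stopifnot(inherits(mol, "kcf_molecule"))
  mol$dist
}

#' Number of ring bonds incident to an atom
#'
#' A ring bond is an edge lying on at least one cycle (equivalently, a
#' non-bridge edge). Used by the tie-break cascade when extending the core
#' alignment: ring and chain atoms with identical species and distance
#' profile are separated by this count.
#'
#' @param mol a \code{\link{kcf_molecule}}.
#' @param atom_index atom index (1-based, as in the KCF ATOM block).
#' @return integer count of incident non-bridge edges.
#' @export
ring_bond_count <- function(mol, atom_index) {
  stopifnot(inherits(mol, "kcf_molecule"))
  key <- as.character(atom_index)
  if (!key %in% names(mol$ring_bonds))
    stop(sprintf("molecule %s has no atom %s", mol$id, key))
  unname(mol$ring_bonds[key])
}

#' Truncate a KEGG atom label to a hierarchy level
#'
#' KEGG atom labels are hierarchical: the first character is the atom
#' species (element), the first two characters the atom class (element +
#' orbital environment), and the full 3-character label adds the bonded
#' neighbourhood. The three levels are used at different stages of the
#' alignment (full labels for the seed strings, classes for fingerprints,
#' species for branch strings).
#'
#' @param label character vector of KEGG atom labels.
#' @param level one of \code{"species"}, \code{"class"}, \code{"full"}
#'   (case-insensitive).
#' @return character vector of truncated labels.
#' @export
label_at_level <- function(label, level = c("full", "class", "species")) {
  level <- tolower(level[1L])
  level <- match.arg(level, c("full", "class", "species"))
  if (any(!nzchar(label)) || anyNA(label)) stop("empty atom label")
  switch(level,
         species = substr(label, 1L, 1L),
         class   = substr(label, 1L, 2L),
         full    = label)
}

# neighbours of an atom, as integer indices
neighbors_of <- function(mol, atom_index) {
  mol$adj[[as.character(atom_index)]]
}
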