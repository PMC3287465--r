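#' Distance-embedded common atom fingerprint (DECAF)
#'
#' The DECAF of an atom summarizes its whole-molecule environment: every
#' other atom \code{j} of the molecule contributes one count to the entry
#' keyed by (shortest-path distance \code{d(i, j)}, atom class of \code{j}).
#' The distance-0 entry is the atom's own class with count 1, and the walk
#' extends to the molecule's breadth-first horizon, so total fingerprint
#' mass always equals the molecule's atom count. Destination atoms are
#' recorded at the two-character atom-class level: only the class of the
#' endpoint of each shortest path matters, which keeps fingerprints
#' comparable between molecules whose interior paths differ.
#'
#' @param mol a \code{\link{kcf_molecule}}.
#' @param atom_index atom whose fingerprint is built.
#' @return an object of class \code{decaf}: data.frame with columns
#'   \code{d} (distance), \code{class} (destination atom class) and
#'   \code{n} (occurrence count), ordered by (\code{d}, \code{class}).
#' @export
build_decaf <- function(mol, atom_index) {
  stopifnot(inherits(mol, "kcf_molecule"))
  key <- as.character(atom_index)
  if (!key %in% names(mol$labels))
    stop(sprintf("molecule %s has no atom %s", mol$id, key))
  d <- stats::setNames(as.integer(mol$dist[key, ]), colnames(mol$dist))
  cls <- label_at_level(mol$labels[names(d)], "class")
  tab <- stats::aggregate(list(n = rep(1L, length(d))),
                          by = list(d = as.integer(d), class = unname(cls)),
                          FUN = sum)
  tab <- tab[order(tab$d, tab$class), c("d", "class", "n")]
  rownames(tab) <- NULL
  structure(tab, class = c("decaf", "data.frame"))
}

#' DECAF similarity score between two atoms
#'
#' For each distance layer \code{d} the shared fingerprint mass
#' \code{sum_k min(n_A(k, d), n_B(k, d))} (over destination atom classes
#' \code{k}) is divided by \code{d + 1} and the layers are summed:
#' \deqn{score = \sum_d \frac{\sum_k \min(n_{A,k,d}, n_{B,k,d})}{d + 1}.}
#' Nearby shared environment therefore counts more than distant shared
#' environment; two atoms in identical environments score
#' \code{sum_d |atoms at distance d| / (d + 1)}.
#'
#' @param fA,fB fingerprints from \code{\link{build_decaf}}.
#' @return non-negative numeric scalar.
#' @export
decaf_score <- function(fA, fB) {
  m <- merge(as.data.frame(fA), as.data.frame(fB), by = c("d", "class"))
  if (nrow(m) == 0L) return(0)
  m <- m[order(m$d, m$class), ]
  shared <- pmin(m$n.x, m$n.y)
  layers <- tapply(shared, m$d, sum)
  sum(unname(layers) / (as.integer(names(layers)) + 1))
}

#' Create a DECAF score cache
#'
#' Atom-atom scores are needed repeatedly while choosing representative
#' strings; they are computed once per unordered atom pair and memoized.
#'
#' @return an environment usable as the \code{cache} argument of
#'   \code{\link{string_decaf_score}}.
#' @export
new_score_cache <- function() new.env(parent = emptyenv())

# memoized atom-atom DECAF score
atom_decaf_score <- function(molA, a, molB, b, cache = NULL) {
  if (is.null(cache))
    return(decaf_score(build_decaf(molA, a), build_decaf(molB, b)))
  k1 <- paste0(molA$id, "#", a)
  k2 <- paste0(molB$id, "#", b)
  key <- if (k1 <= k2) paste(k1, k2, sep = "|") else paste(k2, k1, sep = "|")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- decaf_score(build_decaf(molA, a), build_decaf(molB, b))
  assign(key, val, envir = cache)
  val
}

#' DECAF similarity between two equal-length atom strings
#'
#' Position-wise sum of atom-atom DECAF scores. Used as the objective when
#' selecting one representative string per molecule among symmetric or
#' otherwise interchangeable candidates.
#'
#' @param sA,sB \code{\link{atom_string}} objects of equal length (their
#'   molecules are carried inside the strings).
#' @param cache optional environment from \code{\link{new_score_cache}}.
#' @return numeric scalar; symmetric in its arguments.
#' @export
string_decaf_score <- function(sA, sB, cache = NULL) {
  stopifnot(inherits(sA, "atom_string"), inherits(sB, "atom_string"))
  if (length(sA$atoms) != length(sB$atoms))
    stop("atom strings must have equal length")
  s <- 0
  for (p in seq_along(sA$atoms))
    s <- s + atom_decaf_score(sA$mol, sA$atoms[p], sB$mol, sB$atoms[p], cache)
  s
}
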