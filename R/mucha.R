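#' Multiple chemical alignment
#'
#' Aligns two or more molecules in three stages: (1) find the longest
#' common atom strings (full KEGG labels + self-DMAID) and select one
#' representative per molecule by DECAF similarity; (2) extend the seed
#' into the core substructure shared by all molecules, grouping frontier
#' atoms by species and anchored-DMAID with a ring-bond / atom-class /
#' full-label / index-order tie-break cascade; (3) for three or more
#' molecules, seed and extend branch substructures over the non-core atoms
#' (species-level strings anchored against the core), remove conflicting
#' columns by randomized greedy restarts, and group the survivors into
#' building blocks. A two-molecule query stops after the core stage.
#'
#' @param mols list of >= 2 \code{\link{kcf_molecule}} objects with unique
#'   ids, e.g. from \code{\link{read_kcf}}.
#' @param config a \code{\link{mucha_config}}.
#' @return an object of class \code{mucha_alignment}: molecules, ordered
#'   columns (each with \code{cells} mapping molecule id to atom index,
#'   \code{role} core/branch, branch \code{group} id, and a provenance
#'   \code{note}), and the configuration echo.
#' @export
mucha <- function(mols, config = mucha_config()) {
  if (length(mols) < 2L)
    stop("at least two molecules are required")
  ids <- vapply(mols, function(m) m$id, "")
  if (anyDuplicated(ids))
    stop("molecule ids must be unique")
  names(mols) <- ids

  cache <- new_score_cache()
  sets <- find_lcas(mols)
  if (length(sets) == 0L) {
    warning("molecules share no common atom string; alignment is empty")
    return(new_alignment(mols, list(), config))
  }
  seed <- select_representative(sets, config, cache)
  aln <- extend_core(mols, seed, config)
  if (length(mols) == 2L) return(aln)  # pairwise queries stop at the core

  seeds <- find_scas(mols, aln, config)
  branch_cols <- list()
  for (sd in seeds) {
    counts <- lengths(sd$instances)
    strings <- if (all(counts == 1L)) {
      lapply(sd$instances, `[[`, 1L)
    } else {
      set <- list(instances = lapply(names(sd$instances), function(id) {
        lapply(sd$instances[[id]], function(a) atom_string(mols[[id]], a))
      }))
      names(set$instances) <- names(sd$instances)
      res <- if (prod(counts) <= config$exhaustive_limit)
        best_combo_exhaustive(set, cache)
      else
        with_local_seed(config$seed, best_combo_ga(set, config, cache))
      lapply(res$strings, function(s) s$atoms)
    }
    branch_cols <- c(branch_cols, extend_branch(mols, strings, aln))
  }
  branch_cols <- remove_conflicts(branch_cols,
                                  restarts = config$conflict_restarts,
                                  seed = config$seed)
  branch_cols <- group_branches(branch_cols, mols)
  aln$columns <- c(aln$columns, branch_cols)
  aln
}

#' @export
print.mucha_alignment <- function(x, ...) {
  cat(render_text(x), sep = "\n")
  invisible(x)
}

#' @export
summary.mucha_alignment <- function(object, ...) {
  roles <- vapply(object$columns, function(col) col$role, "")
  groups <- vapply(object$columns, function(col)
    if (is.null(col$group)) NA_character_ else col$group, "")
  n_core <- sum(roles == "core")
  res <- list(
    molecules = names(object$molecules),
    atom_counts = vapply(object$molecules, function(m) nrow(m$atoms), 1L),
    n_core_columns = n_core,
    n_branch_columns = sum(roles == "branch"),
    branch_groups = unique(groups[!is.na(groups)]),
    coverage = vapply(names(object$molecules), function(id) {
      aligned <- sum(vapply(object$columns, function(col)
        id %in% names(col$cells), TRUE))
      aligned / nrow(object$molecules[[id]]$atoms)
    }, 0))
  class(res) <- "summary.mucha_alignment"
  res
}

#' @export
print.summary.mucha_alignment <- function(x, ...) {
  cat(sprintf("Multiple chemical alignment of %d molecules\n",
              length(x$molecules)))
  for (i in seq_along(x$molecules))
    cat(sprintf("  %s: %d atoms, %.0f%% aligned\n", x$molecules[i],
                x$atom_counts[i], 100 * x$coverage[i]))
  cat(sprintf("Core columns: %d\n", x$n_core_columns))
  cat(sprintf("Branch columns: %d in %d group(s)\n", x$n_branch_columns,
              length(x$branch_groups)))
  invisible(x)
}
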