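#' Alignment configuration
#'
#' Collects the tunable parameters of the pipeline in one object. All
#' randomness (genetic-algorithm representative selection, conflict
#' removal) is driven by \code{seed}, so identical inputs and configuration
#' give byte-identical outputs.
#'
#' @param seed integer RNG seed (default 0).
#' @param exhaustive_limit representative-selection combinations up to
#'   which the search is exhaustive; beyond it a genetic algorithm is used
#'   (default 10000).
#' @param ga_population,ga_generations,ga_tournament,ga_crossover,ga_mutation,ga_elitism
#'   genetic-algorithm parameters: population size 50, generations 100,
#'   tournament size 3, one-point crossover rate 0.9, per-gene mutation
#'   rate 0.1, elite count 1.
#' @param min_support minimum number of molecules sharing a branch string
#'   (default 2).
#' @param conflict_restarts random restarts of greedy conflict removal
#'   (default 20).
#' @return a list of class \code{mucha_config}.
#' @export
mucha_config <- function(seed = 0L, exhaustive_limit = 10000L,
                         ga_population = 50L, ga_generations = 100L,
                         ga_tournament = 3L, ga_crossover = 0.9,
                         ga_mutation = 0.1, ga_elitism = 1L,
                         min_support = 2L, conflict_restarts = 20L) {
  structure(list(seed = as.integer(seed),
                 exhaustive_limit = as.integer(exhaustive_limit),
                 ga_population = as.integer(ga_population),
                 ga_generations = as.integer(ga_generations),
                 ga_tournament = as.integer(ga_tournament),
                 ga_crossover = ga_crossover,
                 ga_mutation = ga_mutation,
                 ga_elitism = as.integer(ga_elitism),
                 min_support = as.integer(min_support),
                 conflict_restarts = as.integer(conflict_restarts)),
            class = "mucha_config")
}

# evaluate code under a temporary RNG seed, restoring global state after
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# orientation comparison key: labels (at level), then flattened self-DMAID,
# then the atom-index sequence as a final tie-break
orientation_keys <- function(mol, atoms, level = "full") {
  labs <- label_at_level(unname(mol$labels[as.character(atoms)]), level)
  D <- mol$dist[as.character(atoms), as.character(atoms), drop = FALSE]
  list(labs = labs, dm = as.integer(D), idx = atoms)
}

# lexicographic comparison of two equally-typed list keys; TRUE if a <= b
lex_leq <- function(a, b) {
  for (part in c("labs", "dm", "idx")) {
    x <- a[[part]]; y <- b[[part]]
    cmp <- which(x != y)
    if (length(cmp)) return(x[cmp[1L]] < y[cmp[1L]])
  }
  TRUE
}

#' Canonical orientation of an atom string
#'
#' A path and its reversal are the same substructure; this chooses a single
#' orientation deterministically so that mirror traversals collapse to one
#' object. The orientation with the lexicographically smaller
#' (label sequence, flattened self-DMAID, atom-index sequence) wins;
#' the function is idempotent and maps a string and its reversal to the
#' same result.
#'
#' @param s an \code{\link{atom_string}}.
#' @param level label level used for the comparison (default full labels).
#' @return an \code{\link{atom_string}} equal to \code{s} or its reversal.
#' @export
canonical_orientation <- function(s, level = "full") {
  stopifnot(inherits(s, "atom_string"))
  if (length(s$atoms) == 1L) return(s)
  fwd <- orientation_keys(s$mol, s$atoms, level)
  rev_atoms <- rev(s$atoms)
  bwd <- orientation_keys(s$mol, rev_atoms, level)
  if (lex_leq(fwd, bwd)) s else atom_string(s$mol, rev_atoms)
}

# cross-molecule string key: canonical (labels, self-DMAID) as one string
string_key <- function(mol, atoms, level = "full") {
  labs <- label_at_level(unname(mol$labels[as.character(atoms)]), level)
  D <- mol$dist[as.character(atoms), as.character(atoms), drop = FALSE]
  rlabs <- rev(labs)
  rD <- D[rev(seq_along(atoms)), rev(seq_along(atoms)), drop = FALSE]
  kf <- paste(c(labs, as.integer(D)), collapse = ",")
  kb <- paste(c(rlabs, as.integer(rD)), collapse = ",")
  if (kb < kf) kb else kf
}

#' Find the longest common atom strings
#'
#' Level-wise search for the longest simple paths present, as (full KEGG
#' label sequence, self-DMAID) classes, in every query molecule. Every atom
#' starts as a length-1 string; classes missing from any molecule are
#' discarded; survivors are extended by one bonded neighbour of the
#' terminal atom; the search stops when no longer common string exists and
#' the previous level's classes are returned. Both traversal directions of
#' each path live in the queue, so terminal-only extension covers both
#' ends, and mirror traversals are collapsed by canonical orientation in
#' the output.
#'
#' @param mols list of >= 2 \code{\link{kcf_molecule}} objects with unique
#'   ids.
#' @return a list of common string sets, each a list with \code{key},
#'   \code{length}, and \code{instances} (named by molecule id; each a list
#'   of canonical \code{\link{atom_string}}s). Empty list when the
#'   molecules share no length-1 string.
#' @export
find_lcas <- function(mols) {
  if (length(mols) < 2L) stop("at least two molecules are required")
  ids <- vapply(mols, function(m) m$id, "")
  if (anyDuplicated(ids)) stop("molecule ids must be unique")
  names(mols) <- ids

  # directed instances per molecule: list of integer vectors
  cur <- lapply(mols, function(m) lapply(m$atoms$index, identity))
  survivors <- NULL
  repeat {
    keys <- mapply(function(m, inst) {
      vapply(inst, function(a) string_key(m, a), "")
    }, mols, cur, SIMPLIFY = FALSE)
    common <- Reduce(intersect, lapply(keys, unique))
    if (length(common) == 0L) break
    kept <- mapply(function(inst, k) inst[k %in% common],
                   cur, keys, SIMPLIFY = FALSE)
    survivors <- list(instances = kept,
                      keys = mapply(function(k) k[k %in% common],
                                    keys, SIMPLIFY = FALSE))
    # extend each surviving directed instance at its terminal atom
    nxt <- mapply(function(m, inst) {
      out <- list()
      for (s in inst) {
        for (nb in neighbors_of(m, s[length(s)])) {
          if (!(nb %in% s)) out[[length(out) + 1L]] <- c(s, nb)
        }
      }
      out
    }, mols, survivors$instances, SIMPLIFY = FALSE)
    if (all(lengths(nxt) == 0L)) break
    cur <- nxt
  }
  if (is.null(survivors)) return(list())

  all_keys <- sort(unique(unlist(survivors$keys)))
  lapply(all_keys, function(k) {
    inst <- mapply(function(m, ss, kk) {
      hits <- ss[kk == k]
      canon <- lapply(hits, function(a)
        canonical_orientation(atom_string(m, a)))
      sig <- vapply(canon, function(s) paste(s$atoms, collapse = ","), "")
      canon[!duplicated(sig)]
    }, mols, survivors$instances, survivors$keys, SIMPLIFY = FALSE)
    names(inst) <- ids
    list(key = k,
         length = length(inst[[1L]][[1L]]$atoms),
         instances = inst)
  })
}

# objective: sum of pairwise string DECAF scores for one instance choice
seed_objective <- function(strings, cache) {
  ids <- names(strings)
  s <- 0
  if (length(ids) < 2L) return(0)
  for (i in seq_len(length(ids) - 1L)) {
    for (j in seq(i + 1L, length(ids))) {
      s <- s + string_decaf_score(strings[[i]], strings[[j]], cache)
    }
  }
  s
}

# exhaustive search over instance combinations for one common string set
best_combo_exhaustive <- function(set, cache) {
  counts <- lengths(set$instances)
  grid <- expand.grid(lapply(counts, seq_len))
  best <- NULL; best_val <- -Inf
  for (r in seq_len(nrow(grid))) {
    choice <- mapply(function(inst, k) inst[[k]],
                     set$instances, as.integer(grid[r, ]),
                     SIMPLIFY = FALSE)
    v <- seed_objective(choice, cache)
    if (v > best_val) { best_val <- v; best <- choice }
  }
  list(strings = best, value = best_val)
}

# genetic algorithm over instance combinations for one common string set;
# caller is responsible for seeding the RNG
best_combo_ga <- function(set, cfg, cache) {
  counts <- lengths(set$instances)
  M <- length(counts)
  rand_chrom <- function() vapply(counts, function(k) sample.int(k, 1L), 1L)
  evaluate <- function(ch) {
    choice <- mapply(function(inst, k) inst[[k]], set$instances, ch,
                     SIMPLIFY = FALSE)
    seed_objective(choice, cache)
  }
  pop <- replicate(cfg$ga_population, rand_chrom(), simplify = FALSE)
  fit <- vapply(pop, evaluate, 0)
  for (g in seq_len(cfg$ga_generations)) {
    ord <- order(fit, decreasing = TRUE)
    newpop <- pop[ord[seq_len(cfg$ga_elitism)]]
    while (length(newpop) < cfg$ga_population) {
      pick <- function() {
        cand <- sample.int(length(pop), cfg$ga_tournament, replace = TRUE)
        pop[[cand[which.max(fit[cand])]]]
      }
      p1 <- pick(); p2 <- pick()
      child <- p1
      if (M > 1L && stats::runif(1) < cfg$ga_crossover) {
        cut <- sample.int(M - 1L, 1L)
        child <- c(p1[seq_len(cut)], p2[seq(cut + 1L, M)])
      }
      mut <- stats::runif(M) < cfg$ga_mutation
      if (any(mut))
        child[mut] <- vapply(counts[mut], function(k) sample.int(k, 1L), 1L)
      newpop[[length(newpop) + 1L]] <- child
    }
    pop <- newpop
    fit <- vapply(pop, evaluate, 0)
  }
  bi <- which.max(fit)
  choice <- mapply(function(inst, k) inst[[k]], set$instances, pop[[bi]],
                   SIMPLIFY = FALSE)
  list(strings = choice, value = fit[bi])
}

#' Select the representative seed alignment
#'
#' When a molecule holds several instances of the longest common atom
#' string (typically because of molecular symmetry), one instance per
#' molecule is chosen to maximize the sum of pairwise string DECAF scores.
#' The search is exhaustive while the number of combinations is at most
#' \code{cfg$exhaustive_limit}, otherwise a seeded genetic algorithm finds
#' a suboptimal combination deterministically. Several maximal-length
#' string classes compete under the same objective.
#'
#' @param sets output of \code{\link{find_lcas}} (non-empty).
#' @param cfg a \code{\link{mucha_config}}.
#' @param cache optional DECAF score cache.
#' @return a list of class \code{seed_alignment}: \code{key},
#'   \code{strings} (one canonical \code{\link{atom_string}} per molecule,
#'   named by id) and the objective \code{value}.
#' @export
select_representative <- function(sets, cfg = mucha_config(), cache = NULL) {
  if (length(sets) == 0L) stop("no common atom strings to select from")
  if (is.null(cache)) cache <- new_score_cache()
  total <- sum(vapply(sets, function(s) prod(lengths(s$instances)), 0))
  best <- NULL; best_val <- -Inf; best_key <- NULL
  for (set in sets) {
    res <- if (total <= cfg$exhaustive_limit) {
      best_combo_exhaustive(set, cache)
    } else {
      with_local_seed(cfg$seed, best_combo_ga(set, cfg, cache))
    }
    if (res$value > best_val) {
      best_val <- res$value; best <- res$strings; best_key <- set$key
    }
  }
  structure(list(key = best_key, strings = best, value = best_val),
            class = "seed_alignment")
}
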