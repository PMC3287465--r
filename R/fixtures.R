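fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "mucha")
  if (!nzchar(p)) p <- file.path("inst", "extdata", file)  # pre-install use
  p
}

#' Sinapic acid (KEGG C00482) fixture
#'
#' Hand-encoded hydrogen-suppressed graph of sinapic acid
#' (3,5-dimethoxy-4-hydroxy-cinnamic acid), 16 heavy atoms / 16 bonds.
#' Numbering: benzene ring atoms 1-6 with atom 1 the side-chain-bearing
#' carbon, so atoms 1-5 read \code{C8y-C8x-C8y-C8y-C8y}; substituents
#' numbered breadth-first from the ring (7 = first chain carbon C2b,
#' 8/10 = methoxy oxygens O2a, 9 = phenolic O1a, 11 = second chain carbon
#' C2b, 12/13 = methyl carbons C1a, 14 = carboxyl C6a, 15/16 = carboxyl
#' oxygens O6a). Substituent labels follow standard KEGG atom typing.
#'
#' @return a \code{\link{kcf_molecule}}.
#' @export
sinapic_acid <- function() {
  read_kcf(fixture_path("C00482.kcf"))[[1L]]
}

#' p-Coumaryl alcohol 4-O-glucoside (KEGG C05855) fixture
#'
#' Hand-encoded graph, 22 heavy atoms / 23 bonds. Ring atoms 1-6 with
#' atom 1 bearing the C2b-C2b-C1b-O1a coumaryl-alcohol chain, so atoms 1-5
#' read \code{C8y-C8x-C8x-C8y-C8x}; atom 4 carries the glycosidic oxygen
#' (O2a, atom 8) to a pyranose ring (ring carbons C1y, ring oxygen O2x,
#' exocyclic C1b/O1a) with standard KEGG sugar atom labels. Substituents
#' numbered breadth-first from the ring.
#'
#' @return a \code{\link{kcf_molecule}}.
#' @export
p_coumaryl_alcohol_glucoside <- function() {
  read_kcf(fixture_path("C05855.kcf"))[[1L]]
}

#' Monolignol fixture panel
#'
#' p-Coumaryl alcohol (C02646, no methoxy), coniferyl alcohol (C00590, one
#' methoxy) and sinapyl alcohol (C02325, two methoxys): the phenylpropanoid
#' panel used to exercise the branch stage, whose shared core is the
#' ring + C3 chain + phenolic oxygen skeleton and whose methoxy groups are
#' position-aware building blocks.
#'
#' @param include_glucoside also append p-coumaryl alcohol 4-O-glucoside
#'   (C05855), adding a sugar-residue branch.
#' @return list of \code{\link{kcf_molecule}} objects.
#' @export
monolignol_panel <- function(include_glucoside = FALSE) {
  mols <- read_kcf(fixture_path("monolignols.kcf"))
  if (include_glucoside)
    mols <- c(mols, list(p_coumaryl_alcohol_glucoside()))
  mols
}

#' Generate a random connected molecule
#'
#' Property-test input: a random spanning tree (each new atom attaches to a
#' uniformly chosen earlier atom) plus \code{Binomial(n_atoms, ring_prob)}
#' extra ring-closing edges between non-adjacent atom pairs, with labels
#' drawn from a KEGG-like alphabet. Deterministic per seed. The generator
#' makes no attempt at chemical valence realism; it produces arbitrary
#' connected labeled graphs of the size and ring density typical of
#' hydrogen-suppressed metabolites.
#'
#' @param seed integer seed.
#' @param n_atoms number of atoms (>= 1).
#' @param ring_prob expected extra ring edges per atom (default 0.15).
#' @param label_alphabet labels to draw from.
#' @param id molecule id (default derived from the seed).
#' @return a \code{\link{kcf_molecule}}.
#' @export
random_molecule <- function(seed, n_atoms, ring_prob = 0.15,
                            label_alphabet = c("C1a", "C1b", "C1y", "C2b",
                                               "C8x", "C8y", "C6a", "O1a",
                                               "O2a", "O2x", "O6a", "N1a"),
                            id = sprintf("RND%05d", seed)) {
  if (n_atoms < 1L) stop("n_atoms must be >= 1")
  if (ring_prob < 0 || ring_prob > 1) stop("ring_prob must be in [0, 1]")
  with_local_seed(seed, {
    labs <- sample(label_alphabet, n_atoms, replace = TRUE)
    atoms <- data.frame(index = seq_len(n_atoms), label = labs)
    edges <- NULL
    if (n_atoms > 1L) {
      a <- vapply(seq(2L, n_atoms), function(i)
        sample.int(i - 1L, 1L), 1L)
      edges <- data.frame(a = a, b = seq(2L, n_atoms))
      n_extra <- stats::rbinom(1L, n_atoms, ring_prob)
      if (n_extra > 0L && n_atoms > 2L) {
        have <- paste(pmin(edges$a, edges$b), pmax(edges$a, edges$b))
        pairs <- utils::combn(n_atoms, 2L)
        key <- paste(pairs[1L, ], pairs[2L, ])
        free <- which(!(key %in% have))
        if (length(free) > 0L) {
          pick <- free[sample.int(length(free),
                                  min(n_extra, length(free)))]
          edges <- rbind(edges, data.frame(a = pairs[1L, pick],
                                           b = pairs[2L, pick]))
        }
      }
      edges$order <- 1L
    } else {
      edges <- data.frame(a = integer(), b = integer(), order = integer())
    }
    kcf_molecule(id, atoms, edges)
  })
}
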