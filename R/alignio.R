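#' Render an alignment as sequence-alignment-style text
#'
#' One fixed-width column per alignment column, core block first and branch
#' groups in id order; rows are molecules; a cell is
#' \code{"atomIndex:KEGGlabel"} or the gap \code{"-"} for molecules outside
#' a branch group. The banner row names each column's group (CORE, B1,
#' B2, ...). The document parses back losslessly with
#' \code{\link{parse_alignment_text}}.
#'
#' @param aln a \code{mucha_alignment}.
#' @return character vector of lines.
#' @export
render_text <- function(aln) {
  ids <- names(aln$molecules)
  cols <- aln$columns
  header <- c("# MUCHA multiple chemical alignment",
              sprintf("# molecules: %s",
                      paste(sprintf("%s(%d atoms)", ids,
                                    vapply(aln$molecules,
                                           function(m) nrow(m$atoms), 1L)),
                            collapse = " ")),
              sprintf("# columns: %d core, %d branch",
                      sum(vapply(cols, function(c) c$role == "core", TRUE)),
                      sum(vapply(cols, function(c) c$role == "branch", TRUE))))
  if (length(cols) == 0L)
    return(c(header, "GROUP", ids))
  tags <- vapply(cols, function(col)
    if (col$role == "core") "CORE" else col$group, "")
  cells <- vapply(ids, function(id) {
    vapply(cols, function(col) {
      if (id %in% names(col$cells)) {
        a <- col$cells[[id]]
        sprintf("%d:%s", a, unname(aln$molecules[[id]]$labels[as.character(a)]))
      } else "-"
    }, "")
  }, character(length(cols)))
  cells <- matrix(cells, nrow = length(cols))  # cols x mols
  width <- pmax(nchar(tags),
                apply(matrix(nchar(cells), nrow = length(cols)), 1L, max))
  idw <- max(nchar(c("GROUP", ids)))
  pad <- function(s, w) formatC(s, width = w, flag = "-")
  banner <- paste(c(pad("GROUP", idw),
                    mapply(pad, tags, width)), collapse = " ")
  rows <- vapply(seq_along(ids), function(i) {
    paste(c(pad(ids[i], idw), mapply(pad, cells[, i], width)),
          collapse = " ")
  }, "")
  c(header, trimws(banner, "right"), trimws(rows, "right"))
}

#' Parse an alignment document back into its column structure
#'
#' Inverse of \code{\link{render_text}} for the column structure: returns
#' the molecule ids and, per column, the role, the group tag and the cells
#' (molecule id -> atom index). The molecule graphs themselves are not part
#' of the document.
#'
#' @param lines character vector of lines (or one string with newlines).
#' @return list with \code{molecules} (ids) and \code{columns}.
#' @export
parse_alignment_text <- function(lines) {
  if (length(lines) == 1L) lines <- strsplit(lines, "\n", fixed = TRUE)[[1L]]
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(trimws(lines))]
  tok <- function(s) strsplit(trimws(s), "[[:space:]]+")[[1L]]
  banner <- tok(lines[1L])
  if (banner[1L] != "GROUP") stop("malformed alignment document: no GROUP row")
  tags <- banner[-1L]
  ids <- character()
  cells <- list()
  for (ln in lines[-1L]) {
    f <- tok(ln)
    ids <- c(ids, f[1L])
    body <- f[-1L]
    if (length(body) != length(tags))
      stop("malformed alignment document: ragged row")
    cells[[f[1L]]] <- body
  }
  columns <- lapply(seq_along(tags), function(p) {
    cc <- list()
    for (id in ids) {
      v <- cells[[id]][p]
      if (v != "-") {
        cc[[id]] <- as.integer(strsplit(v, ":", fixed = TRUE)[[1L]][1L])
      }
    }
    list(cells = unlist(cc),
         role = if (tags[p] == "CORE") "core" else "branch",
         group = if (tags[p] == "CORE") NULL else tags[p])
  })
  list(molecules = ids, columns = columns)
}

#' Convert an alignment to its JSON representation
#'
#' Machine-facing ground truth of the alignment:
#' \code{{"molecules": [...], "columns": [{"role", "group", "cells"}],
#' "config": {...}}}. The text rendering is a view of the same structure.
#'
#' @param aln a \code{mucha_alignment}.
#' @return a JSON string.
#' @export
alignment_to_json <- function(aln) {
  obj <- list(
    molecules = names(aln$molecules),
    columns = lapply(aln$columns, function(col) {
      list(role = col$role,
           group = if (is.null(col$group)) NA else col$group,
           cells = as.list(col$cells),
           note = col$note)
    }),
    config = unclass(aln$config))
  jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", digits = NA)
}

#' Write the per-atom group table
#'
#' TSV with columns \code{molecule}, \code{atom}, \code{group} (CORE or a
#' branch id) for every aligned atom, so external drawing tools can color
#' structures by building block.
#'
#' @param aln a \code{mucha_alignment}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_atom_groups <- function(aln, path) {
  rows <- list()
  for (col in aln$columns) {
    g <- if (col$role == "core") "CORE" else col$group
    for (id in names(col$cells)) {
      rows[[length(rows) + 1L]] <-
        data.frame(molecule = id, atom = col$cells[[id]], group = g)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(molecule = character(), atom = integer(), group = character())
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
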