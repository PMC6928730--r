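#' Canonical node identifier from four lining-atom serials
#'
#' A pathway node (a Voronoi vertex on a cavity centreline) is determined by
#' four non-coplanar atoms; its identity must not depend on the order in
#' which an extraction tool reports them. The canonical ID is the dot-join
#' of the serials sorted ascending, so `"2.3.1.4"` and `"3.4.2.1"` collapse
#' to `"1.2.3.4"`.
#'
#' @param serials Integer vector of exactly four distinct positive atom
#'   serials, in any order.
#'
#' @return The canonical node-ID string.
#' @export
#' @examples
#' canonical_node_id(c(2, 3, 1, 4)) # "1.2.3.4"
canonical_node_id <- function(serials) {
  if (length(serials) != 4) {
    abort(sprintf("a node is identified by exactly 4 atom serials, got %d.",
                  length(serials)))
  }
  serials <- as.integer(serials)
  if (anyNA(serials) || any(serials <= 0)) {
    abort("atom serials must be positive integers.")
  }
  if (anyDuplicated(serials)) {
    abort("degenerate node: duplicated atom serial (a Voronoi vertex needs four distinct atoms).")
  }
  paste(sort(serials), collapse = ".")
}

#' Select the four lining atoms of a pathway sphere
#'
#' Finds the four atoms closest to a sphere centre. Mode `"center"` uses
#' plain Euclidean centre-to-centre distance; mode `"surface"` subtracts
#' each atom's van der Waals radius, so big atoms whose surface reaches
#' closer win over small ones. Ties are broken by the lower serial.
#'
#' @param center Numeric length-3 sphere centre (Angstrom).
#' @param atoms Atom tibble (see [generate_molecule()] / [read_pdb()]).
#' @param mode `"center"` (default) or `"surface"`.
#'
#' @return Integer vector of the 4 winning serials, ordered by increasing
#'   distance (not canonicalised; see [canonical_node_id()]).
#' @export
select_lining_atoms <- function(center, atoms, mode = c("center", "surface")) {
  mode <- match.arg(mode)
  if (nrow(atoms) < 4) {
    abort(sprintf("need at least 4 atoms to line a node, got %d.", nrow(atoms)))
  }
  d <- sqrt((atoms$x - center[1])^2 + (atoms$y - center[2])^2 +
              (atoms$z - center[3])^2)
  if (mode == "surface") d <- d - atoms$vdw_radius
  ord <- order(d, atoms$serial)
  atoms$serial[ord[1:4]]
}

#' Encode one cavity record into a node-ID sequence
#'
#' Walks the record's spheres in order, attaches lining atoms per sphere and
#' canonicalises each quadruple. Consecutive duplicate node IDs are kept:
#' token frequency carries signal for the skip-gram model, and collapsing
#' runs would distort it.
#'
#' @param record A one-row cavity-record tibble (columns `cavity_id`,
#'   `snapshot`, `spheres`), or a list with those fields.
#' @param atoms Atom tibble.
#' @param mode Distance mode, see [select_lining_atoms()].
#'
#' @return The record with `node_ids` (character) and `lining` (n x 4
#'   integer matrix) filled in.
#' @export
encode_record <- function(record, atoms, mode = c("center", "surface")) {
  mode <- match.arg(mode)
  spheres <- record$spheres
  if (is.list(spheres) && !is.data.frame(spheres)) spheres <- spheres[[1]]
  if (is.null(spheres) || nrow(spheres) < 1) {
    abort(sprintf("cavity '%s' has no spheres.", record$cavity_id))
  }
  n <- nrow(spheres)
  lining <- matrix(NA_integer_, n, 4)
  tokens <- character(n)
  for (i in seq_len(n)) {
    res <- tryCatch(
      {
        s <- select_lining_atoms(c(spheres$x[i], spheres$y[i], spheres$z[i]),
                                 atoms, mode = mode)
        list(serials = s, token = canonical_node_id(s))
      },
      error = function(e) {
        abort(sprintf("cavity '%s', sphere %d: %s",
                      record$cavity_id, i, conditionMessage(e)))
      }
    )
    lining[i, ] <- res$serials
    tokens[i] <- res$token
  }
  record$node_ids <- if (is.data.frame(record)) list(tokens) else tokens
  record$lining <- if (is.data.frame(record)) list(lining) else lining
  record
}

#' Encode a table of cavity records
#'
#' Tibble-in, tibble-out version of [encode_record()]: adds `node_ids` and
#' `lining` list-columns to a cavity-record tibble.
#'
#' @inheritParams encode_record
#' @param records Cavity-record tibble, one row per cavity (see
#'   [read_cavity_records()]).
#'
#' @return `records` with `node_ids` and `lining` list-columns.
#' @export
encode_records <- function(records, atoms, mode = c("center", "surface")) {
  mode <- match.arg(mode)
  out <- purrr::map(seq_len(nrow(records)), function(i) {
    encode_record(records[i, ], atoms, mode = mode)
  })
  dplyr::bind_rows(out)
}
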