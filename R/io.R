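#' Write atoms as PDB ATOM/HETATM records
#'
#' Emits fixed-column PDB v3.3 coordinate records (serial, name, resName,
#' chainID, resSeq, x, y, z, occupancy 1.00, B 0.00, element). Coordinates
#' are written to 3 decimals, the format's native precision.
#'
#' @param atoms Atom tibble (see [generate_molecule()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(atoms, path) {
  rec <- if ("hetatm" %in% names(atoms)) {
    ifelse(atoms$hetatm, "HETATM", "ATOM")
  } else {
    rep("ATOM", nrow(atoms))
  }
  name <- ifelse(nchar(atoms$name) < 4, paste0(" ", atoms$name), atoms$name)
  lines <- sprintf(
    "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, atoms$serial, name, "", atoms$res_name, atoms$chain, atoms$res_seq,
    "", atoms$x, atoms$y, atoms$z, 1, 0, atoms$element
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

.parse_num <- function(s, what, lineno) {
  v <- suppressWarnings(as.numeric(trimws(s)))
  if (anyNA(v)) {
    abort(sprintf("PDB line %d: malformed %s field '%s'.",
                  lineno[is.na(v)][1], what, trimws(s)[is.na(v)][1]))
  }
  v
}

#' Read atoms from a PDB file
#'
#' Fixed-column PDB v3.3 parsing of ATOM and HETATM records only. The
#' element is taken from columns 77-78 when present and otherwise inferred
#' from the atom-name columns; van der Waals radii come from [vdw_radii()]
#' with a 1.70 Angstrom default for unknown elements. Malformed fixed-width
#' fields are rejected with the offending line number.
#'
#' @param path PDB file path.
#' @return Atom tibble with the columns of [generate_molecule()] plus
#'   `hetatm` (logical; `TRUE` flags non-protein HETATM records).
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  raw <- readLines(path, warn = FALSE)
  sel <- grepl("^(ATOM  |HETATM)", raw)
  lines <- raw[sel]
  lineno <- which(sel)
  if (length(lines) == 0) {
    abort(sprintf("%s: no ATOM/HETATM records (empty structure).", path))
  }
  short <- nchar(lines) < 47
  if (any(short)) {
    abort(sprintf("PDB line %d: record truncated before the coordinate fields.",
                  lineno[short][1]))
  }
  lines <- sprintf("%-80s", lines)
  f <- function(a, b) substr(lines, a, b)
  serial <- .parse_num(f(7, 11), "serial", lineno)
  bad <- serial != round(serial) | serial <= 0
  if (any(bad)) abort(sprintf("PDB line %d: invalid serial.", lineno[bad][1]))
  name <- trimws(f(13, 16))
  elem_field <- trimws(substr(lines, 77, 78))
  elem <- ifelse(elem_field != "", elem_field,
                 toupper(substr(gsub("[^A-Za-z]", "", name), 1, 1)))
  tibble::tibble(
    serial = as.integer(serial),
    name = name,
    element = elem,
    res_name = trimws(f(18, 20)),
    chain = trimws(f(22, 22)),
    res_seq = as.integer(.parse_num(f(23, 26), "resSeq", lineno)),
    x = .parse_num(f(31, 38), "x", lineno),
    y = .parse_num(f(39, 46), "y", lineno),
    z = .parse_num(f(47, 54), "z", lineno),
    vdw_radius = .vdw_lookup(elem),
    hetatm = substr(lines, 1, 6) == "HETATM"
  )
}

.sig6 <- function(x) signif(x, 6)

#' Write cavity records as JSON Lines
#'
#' One JSON object per line with keys `cavity_id`, `snapshot`, `spheres`
#' (array of `{x, y, z, radius}`), and, when present, `node_ids` and
#' `lining_atom_serials`. Floats are written with 6 significant digits;
#' record and sphere order is preserved.
#'
#' @param records Cavity-record tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cavity_records <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    sp <- records$spheres[[i]]
    obj <- list(
      cavity_id = records$cavity_id[i],
      snapshot = records$snapshot[i],
      spheres = purrr::map(seq_len(nrow(sp)), function(j) {
        list(x = .sig6(sp$x[j]), y = .sig6(sp$y[j]), z = .sig6(sp$z[j]),
             radius = .sig6(sp$radius[j]))
      })
    )
    if (!is.null(records$node_ids)) obj$node_ids <- as.list(records$node_ids[[i]])
    if (!is.null(records$lining)) {
      m <- records$lining[[i]]
      obj$lining_atom_serials <- purrr::map(seq_len(nrow(m)), ~ as.list(m[.x, ]))
    }
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read cavity records from JSON Lines
#'
#' Inverse of [write_cavity_records()]. Readers reject rather than repair:
#' a missing required key, a non-positive radius, or a node-ID list whose
#' length disagrees with the sphere list aborts with the line number.
#'
#' @param path JSONL file path.
#' @return Cavity-record tibble with list-columns `spheres`, and `node_ids`
#'   / `lining` where present in the file.
#' @export
read_cavity_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort(sprintf("%s: no records.", path))
  rows <- purrr::map(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e) {
                      abort(sprintf("line %d: invalid JSON: %s", i,
                                    conditionMessage(e)))
                    })
    for (key in c("cavity_id", "snapshot", "spheres")) {
      if (is.null(obj[[key]])) {
        abort(sprintf("line %d: missing required key '%s'.", i, key))
      }
    }
    sp <- obj$spheres
    if (length(sp) < 1) abort(sprintf("line %d: cavity has no spheres.", i))
    spheres <- tibble::tibble(
      x = purrr::map_dbl(sp, "x"), y = purrr::map_dbl(sp, "y"),
      z = purrr::map_dbl(sp, "z"), radius = purrr::map_dbl(sp, "radius")
    )
    if (any(spheres$radius <= 0)) {
      abort(sprintf("line %d: sphere radius must be > 0.", i))
    }
    row <- tibble::tibble(
      cavity_id = obj$cavity_id,
      snapshot = as.integer(obj$snapshot),
      spheres = list(spheres)
    )
    if (!is.null(obj$node_ids)) {
      ids <- unlist(obj$node_ids)
      if (length(ids) != nrow(spheres)) {
        abort(sprintf("line %d: %d node_ids for %d spheres.",
                      i, length(ids), nrow(spheres)))
      }
      row$node_ids <- list(ids)
    }
    if (!is.null(obj$lining_atom_serials)) {
      row$lining <- list(do.call(rbind, purrr::map(obj$lining_atom_serials,
                                                   ~ as.integer(unlist(.x)))))
    }
    row
  })
  dplyr::bind_rows(rows)
}

#' Write a token corpus
#'
#' One cavity per line: `cavity_id<TAB>token token ...`. Tokens may not be
#' empty or contain whitespace, and cavity IDs must be unique, so the file
#' is its own provenance record.
#'
#' @param corpus Tibble with `cavity_id` and `tokens` (list-column), see
#'   [corpus_from_records()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  if (anyDuplicated(corpus$cavity_id)) {
    abort(sprintf("duplicate cavity_id '%s' in corpus.",
                  corpus$cavity_id[duplicated(corpus$cavity_id)][1]))
  }
  toks <- unlist(corpus$tokens)
  if (any(!nzchar(toks)) || any(grepl("\\s", toks))) {
    abort("corpus tokens must be non-empty and contain no whitespace.")
  }
  lines <- paste(corpus$cavity_id,
                 purrr::map_chr(corpus$tokens, paste, collapse = " "),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a token corpus
#'
#' Exact inverse of [write_corpus()].
#'
#' @param path Corpus file path.
#' @return Tibble with `cavity_id` and `tokens`.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort(sprintf("%s: empty corpus.", path))
  no_tab <- !grepl("\t", lines)
  if (any(no_tab)) {
    abort(sprintf("corpus line %d: no TAB separator.", which(no_tab)[1]))
  }
  id <- sub("\t.*$", "", lines)
  body <- sub("^[^\t]*\t", "", lines)
  tokens <- strsplit(body, " ", fixed = TRUE)
  empty <- purrr::map_lgl(tokens, ~ any(!nzchar(.x)) || length(.x) == 0)
  if (any(empty)) {
    abort(sprintf("corpus line %d: empty token.", which(empty)[1]))
  }
  if (anyDuplicated(id)) {
    abort(sprintf("duplicate cavity_id '%s' in corpus.", id[duplicated(id)][1]))
  }
  tibble::tibble(cavity_id = id, tokens = tokens)
}

#' Write vectors in word2vec text format
#'
#' Header line `V d`, then one line per token: the token followed by `d`
#' floats at 6 significant digits. Accepts a fitted skip-gram model (its
#' input vectors are written) or any numeric matrix with row names.
#'
#' @param x An `sg_model` or a numeric matrix with row names.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(x, path) {
  m <- if (inherits(x, "sg_model")) x$input else x
  if (is.null(rownames(m))) abort("embedding matrix needs row names (tokens).")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(m), ncol(m)), con)
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(rownames(m)[i], paste(sprintf("%.6g", m[i, ]), collapse = " "))
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read vectors in word2vec text format
#'
#' @param path Embedding file path.
#' @return Numeric matrix, one row per token, row names = tokens.
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1) abort(sprintf("%s: empty embedding file.", path))
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]]))
  if (length(hdr) != 2 || anyNA(hdr)) {
    abort("embedding header must be two integers 'V d'.")
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) != hdr[1]) {
    abort(sprintf("embedding header declares %d vectors but file has %d.",
                  hdr[1], length(body)))
  }
  parts <- strsplit(body, " ", fixed = TRUE)
  tokens <- purrr::map_chr(parts, 1)
  if (anyDuplicated(tokens)) {
    abort(sprintf("duplicate token '%s' in embedding file.",
                  tokens[duplicated(tokens)][1]))
  }
  vecs <- purrr::map(parts, function(p) {
    v <- suppressWarnings(as.numeric(p[-1]))
    if (length(v) != hdr[2] || anyNA(v)) {
      abort(sprintf("token '%s': expected %d finite components.", p[1], hdr[2]))
    }
    v
  })
  m <- do.call(rbind, vecs)
  rownames(m) <- tokens
  m
}
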