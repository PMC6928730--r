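#' Van der Waals radii used throughout the package
#'
#' Bondi radii (Angstrom) for the elements the generator and the PDB reader
#' emit. Elements not in the table fall back to the carbon radius (1.70).
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80)
}

.vdw_lookup <- function(element) {
  tab <- vdw_radii()
  r <- unname(tab[element])
  r[is.na(r)] <- 1.70
  r
}

# three-letter residue alphabet: the 20 standard amino acids plus the HID
# protonation-state variant of histidine used by simulation topologies
.residue_codes <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HID"
)

# fixed 8-atom residue template (name, element); covers all table elements
.atom_template <- list(
  name    = c("N", "CA", "C", "O", "CB", "HA", "SD", "OD"),
  element = c("N", "C", "C", "O", "C", "H", "S", "O")
)

#' Generate a random hard-sphere molecule
#'
#' Places `n_atoms` atoms uniformly inside a rectangular box and organises
#' them into 8-atom residues with names drawn from the 20 standard amino
#' acids plus HID. The result is a purely geometric stand-in for a protein:
#' no bonding or force field, just positioned spheres with van der Waals
#' radii, which is all the lining-atom machinery needs.
#'
#' @param n_atoms Number of atoms (>= 8; a pathway node needs 4 lining atoms
#'   and fewer than 8 atoms gives degenerate token corpora).
#' @param box Numeric length-3 box extent in Angstrom.
#' @param seed Integer seed; identical arguments reproduce the table exactly.
#'
#' @return A tibble with columns `serial`, `name`, `element`, `res_name`,
#'   `chain`, `res_seq`, `x`, `y`, `z`, `vdw_radius`.
#' @export
#' @examples
#' atoms <- generate_molecule(64, box = c(30, 30, 30), seed = 1)
generate_molecule <- function(n_atoms, box = c(40, 40, 40), seed = 1) {
  if (!is.numeric(n_atoms) || length(n_atoms) != 1 || n_atoms < 8) {
    abort("`n_atoms` must be a single integer >= 8 (4 lining atoms per node; fewer than 8 atoms gives a degenerate corpus).")
  }
  if (length(box) != 3 || any(box <= 0)) {
    abort("`box` must be three positive extents in Angstrom.")
  }
  n_atoms <- as.integer(n_atoms)
  set.seed(seed)

  res_seq <- ((seq_len(n_atoms) - 1L) %/% 8L) + 1L
  pos_in_res <- ((seq_len(n_atoms) - 1L) %% 8L) + 1L
  res_names <- sample(.residue_codes, max(res_seq), replace = TRUE)

  element <- .atom_template$element[pos_in_res]
  tibble::tibble(
    serial = seq_len(n_atoms),
    name = .atom_template$name[pos_in_res],
    element = element,
    res_name = res_names[res_seq],
    chain = "A",
    res_seq = res_seq,
    x = runif(n_atoms, 0, box[1]),
    y = runif(n_atoms, 0, box[2]),
    z = runif(n_atoms, 0, box[3]),
    vdw_radius = .vdw_lookup(element)
  )
}

#' Generate channel templates
#'
#' Each template is a smooth random walk from near the box centre (the
#' "active site") outward, with a per-waypoint sphere radius profile. The
#' templates play the role of a protein's recurring transport pathways:
#' every synthetic cavity trajectory is a noisy realisation of one template.
#'
#' @param k Number of templates.
#' @param box Box extent (Angstrom), matching the molecule the templates
#'   thread through.
#' @param n_waypoints Length-2 range; each template draws its node count
#'   uniformly from this range.
#' @param radius_range Length-2 range of sphere radii (Angstrom).
#' @param step Waypoint spacing along the walk (Angstrom).
#' @param margin Minimum distance (Angstrom) kept between waypoints and the
#'   box walls, so every waypoint retains a full shell of candidate lining
#'   atoms around it.
#' @param seed Integer seed.
#'
#' @return A tibble with columns `template_id`, `label`, `waypoints`
#'   (list of n x 3 matrices) and `radii` (list of numeric vectors).
#' @export
channel_templates <- function(k, box = c(40, 40, 40), n_waypoints = c(10, 40),
                              radius_range = c(0.9, 2.5), step = 1.2,
                              margin = 8, seed = 1) {
  stopifnot(k >= 1, step > 0, all(radius_range > 0), n_waypoints[1] >= 2,
            all(box > 2 * margin))
  set.seed(seed)
  centre <- box / 2
  walks <- purrr::map(seq_len(k), function(id) {
    n <- sample(seq(n_waypoints[1], n_waypoints[2]), 1)
    dir <- runif(3, -1, 1)
    dir <- dir / sqrt(sum(dir^2))
    pts <- matrix(NA_real_, n, 3)
    pts[1, ] <- centre + runif(3, -1, 1)
    for (i in seq_len(n - 1)) {
      dir <- dir + runif(3, -0.25, 0.25)
      dir <- dir / sqrt(sum(dir^2))
      nxt <- pts[i, ] + step * dir
      # reflect at the box walls so the walk stays inside the atom cloud
      for (ax in 1:3) {
        if (nxt[ax] < margin || nxt[ax] > box[ax] - margin) {
          dir[ax] <- -dir[ax]
          nxt[ax] <- pts[i, ax] + step * dir[ax]
        }
      }
      pts[i + 1, ] <- nxt
    }
    r <- runif(n, radius_range[1], radius_range[2])
    # light smoothing so profiles look like channel radius traces
    r <- as.numeric(stats::filter(r, rep(1 / 3, 3), sides = 2, circular = TRUE))
    r <- pmin(pmax(r, radius_range[1]), radius_range[2])
    list(waypoints = pts, radii = r)
  })
  tibble::tibble(
    template_id = seq_len(k),
    label = seq_len(k),
    waypoints = purrr::map(walks, "waypoints"),
    radii = purrr::map(walks, "radii")
  )
}

#' Generate a synthetic cavity-trajectory dataset
#'
#' Builds a random molecule, `k_templates` channel templates, and
#' `k_templates * n_per_template` cavity trajectories. Each trajectory walks
#' its template's waypoints, attaches the four nearest atoms per waypoint
#' (the lining-atom rule), and then applies token-level noise: independent
#' per-node dropout, and swap of a node for a random node drawn from the
#' pool of all template nodes. Ground-truth template labels are recorded so
#' that clustering recovery can be scored.
#'
#' @param k_templates Number of distinct channel patterns.
#' @param n_per_template Trajectories (snapshots) per pattern.
#' @param node_dropout_prob,node_swap_prob Per-node noise probabilities in
#'   `[0, 1)`.
#' @param seed Integer seed; the dataset is reproducible bit-for-bit.
#' @param n_atoms,box,n_waypoints,step,radius_range Passed to
#'   [generate_molecule()] and [channel_templates()].
#' @param search_radius Maximum distance (Angstrom) within which a waypoint
#'   must find its four lining atoms; a template violating this aborts with
#'   the template named.
#' @param mode Lining-atom distance mode, see [select_lining_atoms()].
#'
#' @return An object of class `cavity_synth`: a list with tibbles `atoms`,
#'   `templates`, `records` (one row per trajectory: `cavity_id`, `snapshot`,
#'   `spheres`, `node_ids`, `lining`), `labels` (`cavity_id`, `template_id`)
#'   and the `seed`.
#' @export
#' @examples
#' ds <- generate_trajectories(k_templates = 2, n_per_template = 3, seed = 1)
#' ds$labels
generate_trajectories <- function(k_templates = 3, n_per_template = 50,
                                  node_dropout_prob = 0, node_swap_prob = 0,
                                  seed = 1, n_atoms = 300, box = c(40, 40, 40),
                                  n_waypoints = c(10, 40), step = 1.2,
                                  radius_range = c(0.9, 2.5),
                                  search_radius = 12, mode = "center") {
  stopifnot(k_templates >= 1, n_per_template >= 1)
  if (node_dropout_prob < 0 || node_dropout_prob >= 1 ||
      node_swap_prob < 0 || node_swap_prob >= 1) {
    abort("noise probabilities must lie in [0, 1).")
  }

  atoms <- generate_molecule(n_atoms, box = box, seed = seed)
  templates <- channel_templates(k_templates, box = box,
                                 n_waypoints = n_waypoints,
                                 radius_range = radius_range, step = step,
                                 seed = seed + 1L)

  # encode each template walk once; this is the noise-free token sequence
  walks <- purrr::pmap(templates, function(template_id, label, waypoints, radii) {
    lining <- matrix(NA_integer_, nrow(waypoints), 4)
    for (i in seq_len(nrow(waypoints))) {
      d <- sqrt((atoms$x - waypoints[i, 1])^2 +
                  (atoms$y - waypoints[i, 2])^2 +
                  (atoms$z - waypoints[i, 3])^2)
      if (sum(d <= search_radius) < 4) {
        abort(sprintf(
          "template %d: fewer than 4 atoms within %.1f A of waypoint %d",
          template_id, search_radius, i))
      }
      lining[i, ] <- select_lining_atoms(waypoints[i, ], atoms, mode = mode)
    }
    tokens <- apply(lining, 1, canonical_node_id)
    list(tokens = tokens, lining = lining, waypoints = waypoints, radii = radii)
  })

  # pool of all template nodes: the reservoir for swap noise
  pool_tokens <- unlist(purrr::map(walks, "tokens"))
  pool_lining <- do.call(rbind, purrr::map(walks, "lining"))

  set.seed(seed + 2L)
  rows <- list()
  idx <- 0L
  for (t in seq_len(k_templates)) {
    w <- walks[[t]]
    n <- length(w$tokens)
    for (rep in seq_len(n_per_template)) {
      idx <- idx + 1L
      keep <- runif(n) >= node_dropout_prob
      if (!any(keep)) keep[sample.int(n, 1)] <- TRUE
      tokens <- w$tokens[keep]
      lining <- w$lining[keep, , drop = FALSE]
      centers <- w$waypoints[keep, , drop = FALSE]
      radii <- w$radii[keep]
      swap <- runif(length(tokens)) < node_swap_prob
      if (any(swap)) {
        pick <- sample.int(length(pool_tokens), sum(swap), replace = TRUE)
        tokens[swap] <- pool_tokens[pick]
        lining[swap, ] <- pool_lining[pick, , drop = FALSE]
      }
      rows[[idx]] <- tibble::tibble(
        cavity_id = sprintf("t%02d_c%03d", t, rep),
        snapshot = rep,
        spheres = list(tibble::tibble(
          x = centers[, 1], y = centers[, 2], z = centers[, 3], radius = radii
        )),
        node_ids = list(tokens),
        lining = list(lining),
        template_id = t
      )
    }
  }
  records <- dplyr::bind_rows(rows)
  labels <- dplyr::select(records, "cavity_id", "template_id")
  records <- dplyr::select(records, -"template_id")

  structure(
    list(atoms = atoms, templates = templates, records = records,
         labels = labels, seed = seed),
    class = "cavity_synth"
  )
}

#' @export
print.cavity_synth <- function(x, ...) {
  cat(sprintf(
    "<cavity_synth> %d trajectories, %d templates, %d atoms (seed %d)\n",
    nrow(x$records), nrow(x$templates), nrow(x$atoms), x$seed))
  invisible(x)
}

#' Extract the token corpus from cavity records
#'
#' @param records A tibble of cavity records carrying a `node_ids`
#'   list-column (as produced by [generate_trajectories()] or
#'   [encode_records()]), or a `cavity_synth` object.
#'
#' @return A tibble with columns `cavity_id` and `tokens` (list of character
#'   vectors), one row per cavity.
#' @export
corpus_from_records <- function(records) {
  if (inherits(records, "cavity_synth")) records <- records$records
  if (!"node_ids" %in% names(records)) {
    abort("records carry no `node_ids`; encode them first (see `encode_records()`).")
  }
  tibble::tibble(cavity_id = records$cavity_id, tokens = records$node_ids)
}
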