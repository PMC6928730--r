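.cosine_distance_matrix <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) abort("zero-norm cavity vector: cosine distance undefined.")
  x <- m / nrm
  d <- 1 - tcrossprod(x)
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' Average-link hierarchical clustering of cavity vectors
#'
#' Agglomerative clustering on the distance 1 - cosine similarity, cut
#' either at a fixed number of clusters or at a dendrogram height. The full
#' dendrogram (an `hclust` object) is attached so the merge structure can
#' be inspected.
#'
#' @param vectors Cavity-vector tibble from [cavity_vectors()].
#' @param n_clusters Number of clusters to cut at (exclusive with `h`).
#' @param h Dendrogram height to cut at (exclusive with `n_clusters`).
#' @param linkage Agglomeration method; `"average"` is the intended one.
#'
#' @return Tibble with `cavity_id` and `cluster` (dense integers 1..k),
#'   with attributes `hclust` (the dendrogram), `method` and `parameters`.
#' @export
cluster_hierarchical <- function(vectors, n_clusters = NULL, h = NULL,
                                 linkage = "average") {
  if (is.null(n_clusters) == is.null(h)) {
    abort("give exactly one of `n_clusters` or `h`.")
  }
  m <- vectors_as_matrix(vectors)
  if (nrow(m) < 2) abort("need at least 2 cavities to cluster.")
  d <- .cosine_distance_matrix(m)
  hc <- hclust(as.dist(d), method = linkage)
  cl <- if (!is.null(n_clusters)) cutree(hc, k = n_clusters) else cutree(hc, h = h)
  # dense relabel 1..k keeps the contract independent of cutree's numbering
  cl <- match(cl, unique(cl))
  out <- tibble::tibble(cavity_id = rownames(m), cluster = cl)
  attr(out, "hclust") <- hc
  attr(out, "method") <- "hierarchical"
  attr(out, "parameters") <- list(linkage = linkage, n_clusters = n_clusters, h = h)
  out
}

# k-means++ seeding (Arthur & Vassilvitskii): first centre uniform, later
# centres with probability proportional to squared distance to the nearest
# chosen centre. stats::kmeans has no ++ initialisation of its own.
.kmeans_pp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      pick <- sample.int(n, 1)
    } else {
      pick <- sample.int(n, 1, prob = d2)
    }
    centers[j + 1, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j + 1, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

#' K-means clustering of cavity vectors
#'
#' Lloyd's algorithm on L2-normalised vectors, so squared Euclidean
#' distance is monotone in cosine similarity and the geometry matches the
#' similarity measure used everywhere else. Centres are seeded with
#' k-means++; the best of `n_init` restarts by total within-cluster sum of
#' squares (inertia) is returned. Deterministic given `seed`.
#'
#' @param vectors Cavity-vector tibble.
#' @param k Number of clusters, `2 <= k <= n` (k = n is allowed and gives
#'   singletons).
#' @param seed Integer seed.
#' @param n_init Number of seeded restarts.
#'
#' @return Tibble with `cavity_id` and `cluster` (1..k); attributes
#'   `inertia`, `centers`, `method`, `parameters`.
#' @export
cluster_kmeans <- function(vectors, k, seed = 1, n_init = 10) {
  m <- vectors_as_matrix(vectors)
  n <- nrow(m)
  if (k > n) abort(sprintf("k = %d exceeds the number of cavities (%d).", k, n))
  if (k < 1) abort("k must be >= 1.")
  x <- m / sqrt(rowSums(m^2))
  set.seed(seed)
  best <- NULL
  for (i in seq_len(n_init)) {
    centers <- .kmeans_pp_centers(x, k)
    fit <- suppressWarnings(
      kmeans(x, centers = centers, iter.max = 100, algorithm = "Lloyd")
    )
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  cl <- match(best$cluster, unique(best$cluster))
  out <- tibble::tibble(cavity_id = rownames(m), cluster = as.integer(cl))
  attr(out, "inertia") <- best$tot.withinss
  attr(out, "centers") <- best$centers
  attr(out, "method") <- "kmeans"
  attr(out, "parameters") <- list(k = k, seed = seed, n_init = n_init)
  out
}

#' 2-D t-SNE projection of cavity vectors
#'
#' Projects cavity vectors to two dimensions for visual inspection of the
#' number of change patterns. The projection is for the eye only — cluster
#' assignments are always computed on the full-dimensional vectors, never
#' on these coordinates.
#'
#' @param vectors Cavity-vector tibble.
#' @param perplexity t-SNE perplexity; requires `n > 3 * perplexity`.
#' @param seed Integer seed (fixed seed, identical coordinates).
#' @param ... Passed to [Rtsne::Rtsne()].
#'
#' @return Tibble with `cavity_id`, `x`, `y`.
#' @export
project_tsne <- function(vectors, perplexity = 10, seed = 1, ...) {
  m <- vectors_as_matrix(vectors)
  if (nrow(m) <= 3 * perplexity) {
    abort(sprintf("perplexity %g too large for %d cavities (need n > 3*perplexity).",
                  perplexity, nrow(m)))
  }
  set.seed(seed)
  fit <- Rtsne::Rtsne(m, dims = 2, perplexity = perplexity,
                      check_duplicates = FALSE, pca = FALSE, ...)
  tibble::tibble(cavity_id = rownames(m), x = fit$Y[, 1], y = fit$Y[, 2])
}

#' Length-width profile of a cavity
#'
#' Arc length along the sphere centres (starting at 0 at the active-site
#' end) against sphere radius — the view in which bottlenecks are read off.
#'
#' @param record One-row cavity-record tibble (or list) with `spheres`.
#'
#' @return Tibble with `cavity_id`, `node`, `arc_length`, `radius`;
#'   attribute `bottleneck` = list(node, radius) at the radius minimum
#'   (first one on ties).
#' @export
length_width_profile <- function(record) {
  sp <- record$spheres
  if (is.list(sp) && !is.data.frame(sp)) sp <- sp[[1]]
  n <- nrow(sp)
  arc <- c(0, cumsum(sqrt(diff(sp$x)^2 + diff(sp$y)^2 + diff(sp$z)^2)))
  out <- tibble::tibble(
    cavity_id = record$cavity_id, node = seq_len(n),
    arc_length = arc, radius = sp$radius
  )
  b <- which.min(sp$radius)
  attr(out, "bottleneck") <- list(node = b, radius = sp$radius[b])
  out
}

#' Length-width profiles for a table of cavity records
#'
#' @param records Cavity-record tibble.
#' @return Long tibble, one row per (cavity, node), columns as in
#'   [length_width_profile()].
#' @export
length_width_profiles <- function(records) {
  dplyr::bind_rows(purrr::map(seq_len(nrow(records)),
                              ~ length_width_profile(records[.x, ])))
}

#' Bottleneck summary per cavity
#'
#' @param profiles Long profile tibble from [length_width_profiles()].
#' @return Tibble with `cavity_id`, `bottleneck_node`, `bottleneck_radius`
#'   and total `length`.
#' @export
bottlenecks <- function(profiles) {
  profiles |>
    dplyr::group_by(.data$cavity_id) |>
    dplyr::summarise(
      bottleneck_node = .data$node[which.min(.data$radius)],
      bottleneck_radius = min(.data$radius),
      length = max(.data$arc_length),
      .groups = "drop"
    )
}

#' Amino-acid composition of cavities or clusters
#'
#' Per cavity, counts the distinct residues (chain + residue number) whose
#' atoms appear among the cavity's lining atoms, tallied by 3-letter code
#' (HID stays distinct from HIS — protonation states are real chemistry in
#' simulation topologies). With a cluster assignment, returns the
#' arithmetic mean of the member-cavity counts per cluster. `level =
#' "atom"` counts lining atoms per residue type instead of distinct
#' residues.
#'
#' @param records Cavity-record tibble with a `lining` list-column.
#' @param atoms Atom tibble covering every lining serial.
#' @param clusters Optional assignment tibble (`cavity_id`, `cluster`).
#' @param level `"residue"` (default) or `"atom"`.
#'
#' @return Long tibble: per cavity `cavity_id`, `res_name`, `n`; per
#'   cluster `cluster`, `res_name`, `mean_n`, `n_cavities`.
#' @export
amino_acid_profile <- function(records, atoms, clusters = NULL,
                               level = c("residue", "atom")) {
  level <- match.arg(level)
  if (!"lining" %in% names(records)) {
    abort("records carry no `lining` atoms; encode them first.")
  }
  atom_key <- setNames(seq_len(nrow(atoms)), atoms$serial)
  per_cavity <- purrr::map(seq_len(nrow(records)), function(i) {
    serials <- as.integer(records$lining[[i]])
    miss <- setdiff(unique(serials), as.integer(names(atom_key)))
    if (length(miss) > 0) {
      abort(sprintf("cavity '%s': lining atom serial %d absent from atom table.",
                    records$cavity_id[i], miss[1]))
    }
    rows <- atoms[atom_key[as.character(serials)], ]
    counted <- if (level == "residue") {
      dplyr::distinct(rows, .data$chain, .data$res_seq, .data$res_name)
    } else {
      rows
    }
    counted |>
      dplyr::count(.data$res_name, name = "n") |>
      dplyr::mutate(cavity_id = records$cavity_id[i], .before = 1)
  })
  per_cavity <- dplyr::bind_rows(per_cavity)
  if (is.null(clusters)) return(per_cavity)

  members <- dplyr::select(clusters, "cavity_id", "cluster")
  # zero-fill so cluster means average over every member cavity, including
  # those not touching a residue type at all
  full <- tidyr::complete(
    dplyr::inner_join(per_cavity, members, by = "cavity_id"),
    tidyr::nesting(!!rlang::sym("cavity_id"), !!rlang::sym("cluster")),
    .data$res_name, fill = list(n = 0L)
  )
  full |>
    dplyr::group_by(.data$cluster, .data$res_name) |>
    dplyr::summarise(mean_n = mean(.data$n),
                     n_cavities = dplyr::n(), .groups = "drop")
}
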