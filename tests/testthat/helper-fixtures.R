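# fixture builders shared across test files; everything is generated in
# code so the suite carries no data files

# atom tibble from explicit coordinates, defaults filled in
make_atoms <- function(x, y = 0, z = 0, element = "C", res_name = "ALA",
                       res_seq = seq_along(x), chain = "A") {
  n <- length(x)
  tibble::tibble(
    serial = seq_len(n),
    name = "CA",
    element = rep_len(element, n),
    res_name = rep_len(res_name, n),
    chain = rep_len(chain, n),
    res_seq = rep_len(res_seq, n),
    x = x, y = rep_len(y, n), z = rep_len(z, n),
    vdw_radius = unname(vdw_radii()[rep_len(element, n)])
  )
}

# minimal sg_model-shaped object with given vector tables
make_model <- function(input, output = NULL, window = 2) {
  W <- nrow(input)
  tokens <- rownames(input)
  if (is.null(tokens)) {
    tokens <- paste0("w", seq_len(W))
    rownames(input) <- tokens
  }
  if (is.null(output)) output <- matrix(0, W, ncol(input))
  rownames(output) <- tokens
  structure(
    list(
      vocab = tibble::tibble(token = tokens, index = seq_len(W),
                             count = rep(1L, W)),
      input = input, output = output,
      config = list(dim = ncol(input), window = window, epochs = 0,
                    negative = 0, min_count = 1, lr = 0, lr_min = 0,
                    dynamic_window = FALSE, seed = 0),
      objective = NULL
    ),
    class = "sg_model"
  )
}

# small synthetic dataset for pipeline-ish tests
small_dataset <- function(k = 3, n = 6, dropout = 0, swap = 0, seed = 1,
                          n_atoms = 200) {
  generate_trajectories(
    k_templates = k, n_per_template = n, node_dropout_prob = dropout,
    node_swap_prob = swap, seed = seed, n_atoms = n_atoms,
    n_waypoints = c(8, 16)
  )
}

# mean Jaccard token overlap between two groups of token sets
mean_jaccard <- function(sets_a, sets_b = NULL) {
  jac <- function(a, b) {
    length(intersect(a, b)) / length(union(a, b))
  }
  if (is.null(sets_b)) {
    pairs <- utils::combn(length(sets_a), 2)
    mean(apply(pairs, 2, function(p) jac(sets_a[[p[1]]], sets_a[[p[2]]])))
  } else {
    mean(outer(seq_along(sets_a), seq_along(sets_b),
               Vectorize(function(i, j) jac(sets_a[[i]], sets_b[[j]]))))
  }
}

# within- minus between-template mean Jaccard overlap of a dataset
overlap_gap <- function(ds) {
  toks <- ds$records$node_ids
  tpl <- ds$labels$template_id
  within <- mean(vapply(unique(tpl), function(t) {
    mean_jaccard(toks[tpl == t])
  }, numeric(1)))
  ts <- unique(tpl)
  pairs <- utils::combn(length(ts), 2)
  between <- mean(apply(pairs, 2, function(p) {
    mean_jaccard(toks[tpl == ts[p[1]]], toks[tpl == ts[p[2]]])
  }))
  within - between
}

# cavity-vector tibble from a plain matrix, for tests that control geometry
vec_tbl <- function(m, ids = paste0("c", seq_len(nrow(m)))) {
  dplyr::bind_cols(
    tibble::tibble(cavity_id = ids, n_nodes_used = 1),
    tibble::as_tibble(setNames(as.data.frame(m), paste0("V", seq_len(ncol(m)))))
  )
}

# ground-truth labels aligned to a cavity-id vector
labels_for <- function(ds, ids) {
  ds$labels$template_id[match(ids, ds$labels$cavity_id)]
}
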