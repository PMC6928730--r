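#' Cavity vector of a single token sequence
#'
#' The cavity-level representation is the unweighted mean of the input
#' vectors of its node tokens — no length or radius weighting. Tokens
#' outside the vocabulary (e.g. dropped by `min_count`) are skipped under
#' the default policy and counted; `"strict"` raises instead.
#'
#' @param tokens Character vector of node IDs (n >= 1).
#' @param model A fitted `sg_model`.
#' @param oov `"skip"` (default) or `"strict"`.
#'
#' @return Numeric vector of length d with attribute `n_nodes_used`.
#' @export
cavity_vector <- function(tokens, model, oov = c("skip", "strict")) {
  oov <- match.arg(oov)
  if (length(tokens) == 0) abort("cavity has no nodes.")
  known <- tokens %in% model$vocab$token
  if (oov == "strict" && !all(known)) {
    abort(sprintf("token '%s' not in vocabulary.", tokens[!known][1]))
  }
  used <- tokens[known]
  if (length(used) == 0) {
    abort("no in-vocabulary tokens: cavity vector is undefined.")
  }
  v <- colMeans(model$input[used, , drop = FALSE])
  attr(v, "n_nodes_used") <- length(used)
  v
}

#' Cavity vectors for a whole corpus
#'
#' Tibble-in, tibble-out: averages node embeddings per cavity.
#'
#' @param corpus Corpus tibble (`cavity_id`, `tokens`).
#' @param model A fitted `sg_model`.
#' @param oov OOV policy, see [cavity_vector()].
#' @param normalize L2-normalise each cavity vector. Off by default; cosine
#'   similarity is scale-invariant, but normalised vectors make Euclidean
#'   k-means match cosine geometry.
#'
#' @return Tibble with `cavity_id`, `n_nodes_used` and vector components
#'   `V1..Vd`.
#' @export
cavity_vectors <- function(corpus, model, oov = c("skip", "strict"),
                           normalize = FALSE) {
  oov <- match.arg(oov)
  rows <- purrr::map(seq_len(nrow(corpus)), function(i) {
    v <- tryCatch(cavity_vector(corpus$tokens[[i]], model, oov = oov),
                  error = function(e) {
                    abort(sprintf("cavity '%s': %s", corpus$cavity_id[i],
                                  conditionMessage(e)))
                  })
    n_used <- attr(v, "n_nodes_used")
    if (normalize) v <- v / sqrt(sum(v^2))
    out <- tibble::as_tibble(as.list(setNames(as.numeric(v),
                                              paste0("V", seq_along(v)))))
    dplyr::bind_cols(
      tibble::tibble(cavity_id = corpus$cavity_id[i], n_nodes_used = n_used),
      out
    )
  })
  dplyr::bind_rows(rows)
}

#' Convert a cavity-vector tibble to a matrix
#'
#' @param vectors Tibble from [cavity_vectors()].
#' @return Numeric matrix, rows named by `cavity_id`.
#' @export
vectors_as_matrix <- function(vectors) {
  cols <- grep("^V[0-9]+$", names(vectors), value = TRUE)
  if (length(cols) == 0) abort("no vector components V1..Vd found.")
  m <- as.matrix(vectors[, cols])
  rownames(m) <- vectors$cavity_id
  m
}

#' Cosine similarity of two vectors
#'
#' `sum(v1 * v2) / (||v1|| ||v2||)`, clamped to `[-1, 1]` against rounding.
#' A zero-norm vector has no direction, so similarity against it is an
#' error, not silently 0.
#'
#' @param v1,v2 Numeric vectors of equal dimension.
#' @return Similarity in `[-1, 1]`.
#' @export
#' @examples
#' cosine_similarity(c(1, 0), c(0, 1)) # 0
cosine_similarity <- function(v1, v2) {
  if (length(v1) != length(v2)) abort("vectors differ in dimension.")
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) {
    abort("cosine similarity is undefined for a zero-norm vector.")
  }
  min(1, max(-1, sum(v1 * v2) / (n1 * n2)))
}

#' Query cavities by similarity to a target
#'
#' Returns every cavity (other than the target) whose cosine similarity to
#' the target falls in the interval `(low, high]` — open below, closed
#' above, so the conventional thresholds "larger than 0.9" and "between 0
#' and 0.1" are `(0.9, 1]` and `(0, 0.1]`.
#'
#' @param vectors Cavity-vector tibble from [cavity_vectors()].
#' @param target_id The query cavity's `cavity_id`.
#' @param low,high Interval bounds, `low < high`.
#'
#' @return Tibble with `cavity_id` and `similarity`, sorted by descending
#'   similarity, ties by `cavity_id`.
#' @export
query_by_similarity <- function(vectors, target_id, low, high) {
  stopifnot(low < high)
  m <- vectors_as_matrix(vectors)
  if (!target_id %in% rownames(m)) {
    abort(sprintf("unknown cavity '%s'.", target_id))
  }
  v <- m[target_id, ]
  others <- setdiff(rownames(m), target_id)
  sim <- vapply(others, function(id) cosine_similarity(m[id, ], v), numeric(1))
  out <- tibble::tibble(cavity_id = others, similarity = unname(sim))
  out <- dplyr::filter(out, .data$similarity > low, .data$similarity <= high)
  dplyr::arrange(out, dplyr::desc(.data$similarity), .data$cavity_id)
}
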