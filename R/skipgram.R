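.as_sentences <- function(corpus) {
  if (is.data.frame(corpus)) {
    if (!"tokens" %in% names(corpus)) {
      abort("corpus tibble needs a `tokens` list-column.")
    }
    corpus$tokens
  } else if (is.list(corpus)) {
    corpus
  } else {
    abort("corpus must be a tibble with a `tokens` column or a list of character vectors.")
  }
}

#' Build the node vocabulary of a corpus
#'
#' Counts every token over the full corpus, then keeps tokens whose count
#' reaches `min_count`. Dropped tokens are simply removed from sentences at
#' training time — no placeholder token is inserted. Indices are dense and
#' deterministic: tokens sorted by decreasing count, ties alphabetically.
#'
#' @param corpus Corpus tibble (`cavity_id`, `tokens`) or list of character
#'   vectors.
#' @param min_count Minimum corpus count for a token to be kept.
#'
#' @return Tibble with `token`, `index` (1..W) and `count` (full-corpus
#'   count, before dropping).
#' @export
build_vocabulary <- function(corpus, min_count = 1) {
  sentences <- .as_sentences(corpus)
  tok <- unlist(sentences)
  if (length(tok) == 0) abort("corpus is empty.")
  counts <- table(tok)
  keep <- counts[counts >= min_count]
  if (length(keep) == 0) {
    abort(sprintf("empty vocabulary: no token reaches min_count = %d.", min_count))
  }
  ord <- order(-as.integer(keep), names(keep))
  tibble::tibble(
    token = names(keep)[ord],
    index = seq_along(keep),
    count = as.integer(keep)[ord]
  )
}

#' Enumerate skip-gram training pairs of one sentence
#'
#' For each position t the pairs (center, context) with context offset j in
#' `[-window, window]`, j != 0, truncated at the sentence boundaries. With
#' `dynamic_window = TRUE` the effective window at each position is drawn
#' uniformly from 1..window (the word2vec distance-weighting trick); it is
#' off by default so pair sets are exactly enumerable.
#'
#' @param tokens Character vector, one sentence.
#' @param window Maximum context offset c >= 1.
#' @param dynamic_window Draw a per-position window in 1..window.
#'
#' @return Tibble with columns `center` and `context` (possibly 0 rows).
#' @export
#' @examples
#' training_pairs(c("a", "b", "c"), window = 1)
training_pairs <- function(tokens, window, dynamic_window = FALSE) {
  stopifnot(window >= 1)
  n <- length(tokens)
  if (n < 2) return(tibble::tibble(center = character(), context = character()))
  rows <- purrr::map(seq_len(n), function(t) {
    b <- if (dynamic_window) sample.int(window, 1) else window
    j <- setdiff(seq(t - b, t + b), t)
    j <- j[j >= 1 & j <= n]
    if (length(j) == 0) return(NULL)
    tibble::tibble(center = tokens[t], context = tokens[j])
  })
  dplyr::bind_rows(rows)
}

# dense W x W pair-count matrix over vocabulary indices; sentences already
# restricted to vocabulary tokens
.pair_counts <- function(sentences, vocab, window) {
  W <- nrow(vocab)
  idx <- setNames(vocab$index, vocab$token)
  N <- matrix(0, W, W)
  for (s in sentences) {
    if (length(s) < 2) next
    p <- training_pairs(s, window)
    i <- idx[p$center]
    j <- idx[p$context]
    for (k in seq_along(i)) N[i[k], j[k]] <- N[i[k], j[k]] + 1
  }
  N
}

.row_log_softmax <- function(S) {
  m <- apply(S, 1, max)
  S - m - log(rowSums(exp(S - m)))
}

#' Softmax probability of a context token given a center token
#'
#' p(target | center) = exp(u_target . v_center) / sum_w exp(u_w . v_center)
#' over the whole vocabulary, computed with max-subtraction so large dot
#' products cannot overflow.
#'
#' @param model A fitted `sg_model` (see [train_skipgram()]).
#' @param center,target Tokens, both in the vocabulary.
#'
#' @return The probability (sums to 1 over `target`).
#' @export
softmax_probability <- function(model, center, target) {
  for (tk in c(center, target)) {
    if (!tk %in% model$vocab$token) abort(sprintf("unknown token '%s'.", tk))
  }
  scores <- drop(model$output %*% model$input[center, ])
  scores <- scores - max(scores)
  e <- exp(scores)
  unname(e[target] / sum(e))
}

#' Average log probability of a corpus under a model
#'
#' The skip-gram objective: (1/T) sum over positions t and offsets j in
#' `[-window, window]`, j != 0, of log p(token_{t+j} | token_t), with the
#' exact softmax over the vocabulary and boundary-truncated windows. T is
#' the total token count of the (vocabulary-restricted) corpus.
#'
#' @param model A fitted `sg_model`.
#' @param corpus Corpus tibble or list of character sentences.
#' @param window Context size; defaults to the model's training window.
#'
#' @return The average log probability (a scalar, <= 0).
#' @export
sg_objective <- function(model, corpus, window = model$config$window) {
  sentences <- purrr::map(.as_sentences(corpus),
                          ~ .x[.x %in% model$vocab$token])
  T_tok <- sum(lengths(sentences))
  if (T_tok == 0) abort("no in-vocabulary tokens in corpus.")
  N <- .pair_counts(sentences, model$vocab, window)
  logP <- .row_log_softmax(model$input %*% t(model$output))
  sum(N * logP) / T_tok
}

# full-batch exact-softmax objective and analytic gradients.
# N: W x W pair counts (rows = center), T_tok: total tokens.
.sg_exact_gradient <- function(input, output, N, T_tok) {
  S <- input %*% t(output)
  m <- apply(S, 1, max)
  E <- exp(S - m)
  P <- E / rowSums(E)
  logP <- (S - m) - log(rowSums(E))
  n_w <- rowSums(N)
  R <- N - n_w * P
  list(
    objective = sum(N * logP) / T_tok,
    grad_input = (R %*% output) / T_tok,
    grad_output = (t(R) %*% input) / T_tok
  )
}

# negative-sampling objective for one positive pair with FIXED negatives:
# log sigma(u_o . v_c) + sum_n log sigma(-u_n . v_c)
.sg_ns_loss <- function(input, output, center, target, negatives) {
  vc <- input[center, ]
  s <- function(x) 1 / (1 + exp(-x))
  sum_neg <- if (length(negatives)) {
    sum(log(s(-drop(output[negatives, , drop = FALSE] %*% vc))))
  } else 0
  log(s(sum(output[target, ] * vc))) + sum_neg
}

.sg_ns_gradient <- function(input, output, center, target, negatives) {
  vc <- input[center, ]
  s <- function(x) 1 / (1 + exp(-x))
  gi <- matrix(0, nrow(input), ncol(input))
  go <- matrix(0, nrow(output), ncol(output))
  g_pos <- 1 - s(sum(output[target, ] * vc))
  gi[center, ] <- g_pos * output[target, ]
  go[target, ] <- g_pos * vc
  for (n in negatives) {
    g_neg <- -s(sum(output[n, ] * vc))
    gi[center, ] <- gi[center, ] + g_neg * output[n, ]
    go[n, ] <- go[n, ] + g_neg * vc
  }
  list(grad_input = gi, grad_output = go)
}

#' Train skip-gram node embeddings
#'
#' Learns distributed representations of cavity pathway nodes from a token
#' corpus. Two regimes share initialisation and vocabulary handling:
#'
#' * `negative = 0`: exact-softmax **full-batch gradient ascent** on the
#'   average log probability, one update per epoch. Exact but O(W^2);
#'   intended for small vocabularies and for verifying gradients.
#' * `negative = k > 0`: stochastic gradient **negative sampling**, k noise
#'   tokens per positive pair drawn from the unigram distribution raised to
#'   the 3/4 power; the practical regime (the exact softmax gradient costs
#'   O(W) per pair, which does not scale).
#'
#' Input vectors start uniform in `[-0.5/d, 0.5/d]`, output vectors at zero;
#' the learning rate decays linearly from `lr` to `lr_min`. Training is
#' single-threaded and fully seeded: the same corpus, configuration and seed
#' reproduce the model bit for bit.
#'
#' @param corpus Corpus tibble (`cavity_id`, `tokens`) or list of character
#'   sentences.
#' @param dim Embedding dimension d (>= 2). Default 128, in line with
#'   cavity representations using >100 dimensions; tests and small corpora
#'   use 8-32.
#' @param window Context size c.
#' @param epochs Passes over the corpus (or full-batch iterations when
#'   `negative = 0`).
#' @param negative Noise samples per positive pair; 0 selects the exact
#'   regime.
#' @param min_count Vocabulary threshold, see [build_vocabulary()].
#' @param lr,lr_min Start and end learning rate of the linear decay.
#' @param dynamic_window Per-position window shrinking (SGD regime only).
#' @param seed Integer seed.
#'
#' @return An object of class `sg_model`: list with `vocab`, `input` and
#'   `output` (W x d matrices, rows named by token), `config`, and (exact
#'   regime) the per-iteration `objective` trace.
#' @export
train_skipgram <- function(corpus, dim = 128, window = 5, epochs = 15,
                           negative = 5, min_count = 1, lr = 0.025,
                           lr_min = 1e-4, dynamic_window = FALSE, seed = 1) {
  stopifnot(dim >= 2, window >= 1, epochs >= 1, negative >= 0,
            lr > 0, lr_min >= 0, lr >= lr_min)
  vocab <- build_vocabulary(corpus, min_count = min_count)
  sentences <- purrr::map(.as_sentences(corpus), ~ .x[.x %in% vocab$token])
  sentences <- sentences[lengths(sentences) > 0]
  T_tok <- sum(lengths(sentences))
  if (!any(lengths(sentences) >= 2)) {
    abort("degenerate corpus: no sentence has 2 in-vocabulary tokens, so there are no training pairs.")
  }
  W <- nrow(vocab)

  set.seed(seed)
  input <- matrix(runif(W * dim, -0.5 / dim, 0.5 / dim), W, dim)
  output <- matrix(0, W, dim)
  rownames(input) <- rownames(output) <- vocab$token

  config <- list(dim = dim, window = window, epochs = epochs,
                 negative = negative, min_count = min_count, lr = lr,
                 lr_min = lr_min, dynamic_window = dynamic_window, seed = seed)
  trace <- NULL

  if (negative == 0) {
    N <- .pair_counts(sentences, vocab, window)
    trace <- numeric(epochs)
    for (e in seq_len(epochs)) {
      alpha <- if (epochs == 1) lr else {
        lr + (lr_min - lr) * (e - 1) / (epochs - 1)
      }
      g <- .sg_exact_gradient(input, output, N, T_tok)
      trace[e] <- g$objective
      input <- input + alpha * g$grad_input
      output <- output + alpha * g$grad_output
      if (!all(is.finite(input)) || !all(is.finite(output))) {
        abort(sprintf("non-finite gradient update at iteration %d; lower `lr`.", e))
      }
    }
  } else {
    idx <- setNames(vocab$index, vocab$token)
    flat <- unlist(purrr::map(sentences, ~ unname(idx[.x]) - 1L))
    offsets <- c(0L, cumsum(lengths(sentences)))
    res <- sg_train_ns_cpp(t(input), t(output), as.integer(flat),
                           as.integer(offsets), as.numeric(vocab$count),
                           as.integer(window), as.integer(negative),
                           as.integer(epochs), lr, lr_min,
                           as.integer(seed), isTRUE(dynamic_window))
    input <- t(res$input)
    output <- t(res$output)
    rownames(input) <- rownames(output) <- vocab$token
    if (!all(is.finite(input)) || !all(is.finite(output))) {
      abort("non-finite values after training; lower `lr`.")
    }
  }

  structure(list(vocab = vocab, input = input, output = output,
                 config = config, objective = trace),
            class = "sg_model")
}

#' @export
print.sg_model <- function(x, ...) {
  cat(sprintf(
    "<sg_model> W = %d tokens, d = %d, window = %d, %s, %d epochs (seed %d)\n",
    nrow(x$vocab), x$config$dim, x$config$window,
    if (x$config$negative == 0) "exact softmax"
    else sprintf("negative sampling k = %d", x$config$negative),
    x$config$epochs, x$config$seed))
  invisible(x)
}

#' Nearest nodes in embedding space
#'
#' @param model A fitted `sg_model`.
#' @param token A vocabulary token.
#' @param n Number of neighbours.
#'
#' @return Tibble with `token` and `similarity` (cosine, descending),
#'   excluding the query token.
#' @export
nearest_nodes <- function(model, token, n = 5) {
  if (!token %in% model$vocab$token) abort(sprintf("unknown token '%s'.", token))
  v <- model$input[token, ]
  sims <- apply(model$input, 1, function(u) cosine_similarity(u, v))
  sims <- sims[names(sims) != token]
  out <- tibble::tibble(token = names(sims), similarity = unname(sims))
  dplyr::slice_head(dplyr::arrange(out, dplyr::desc(.data$similarity),
                                   .data$token), n = n)
}

#' @rdname train_skipgram
#' @param x A fitted `sg_model`.
#' @param ... Unused.
#' @export
tidy.sg_model <- function(x, ...) {
  vec <- tibble::as_tibble(x$input, .name_repair = ~ paste0("V", seq_along(.x)))
  dplyr::bind_cols(x$vocab[, c("token", "count")], vec)
}

#' @rdname train_skipgram
#' @export
glance.sg_model <- function(x, ...) {
  tibble::tibble(
    vocab_size = nrow(x$vocab),
    dim = x$config$dim,
    window = x$config$window,
    negative = x$config$negative,
    epochs = x$config$epochs,
    min_count = x$config$min_count,
    seed = x$config$seed,
    objective = if (is.null(x$objective)) NA_real_ else tail(x$objective, 1)
  )
}
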