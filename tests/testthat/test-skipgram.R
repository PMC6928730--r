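test_that("build_vocabulary counts the full corpus and applies min_count", {
  v1 <- build_vocabulary(list(c("a", "b", "a")), min_count = 1)
  expect_equal(nrow(v1), 2)
  expect_equal(v1$count[v1$token == "a"], 2L)
  expect_equal(sort(v1$index), 1:2)

  v2 <- build_vocabulary(list(c("a", "b", "a")), min_count = 2)
  expect_equal(v2$token, "a")

  expect_error(build_vocabulary(list(c("a", "b")), min_count = 3),
               "empty vocabulary")
  expect_error(build_vocabulary(list(character(0))), "empty")
})

test_that("vocabulary counts match a hand-rolled tally on synthetic corpora", {
  ds <- small_dataset(k = 3, n = 5, dropout = 0.1, swap = 0.05, seed = 3)
  corp <- corpus_from_records(ds)
  vocab <- build_vocabulary(corp, min_count = 2)
  tally <- new.env()
  for (s in corp$tokens) {
    for (tok in s) {
      assign(tok, (if (exists(tok, tally)) get(tok, tally) else 0L) + 1L, tally)
    }
  }
  keep <- Filter(function(tok) get(tok, tally) >= 2, ls(tally))
  expect_setequal(vocab$token, keep)
  for (tok in vocab$token) {
    expect_equal(vocab$count[vocab$token == tok], get(tok, tally))
  }
})

test_that("training_pairs enumerates boundary-truncated windows", {
  p <- training_pairs(c("a", "b", "c"), window = 1)
  expect_equal(
    paste(p$center, p$context),
    c("a b", "b a", "b c", "c b")
  )
  expect_equal(nrow(training_pairs("a", window = 3)), 0)

  # brute-force double loop on a longer sentence
  s <- letters[1:10]
  got <- training_pairs(s, window = 3)
  want <- 0L
  for (t in seq_along(s)) {
    for (j in -3:3) {
      if (j != 0 && t + j >= 1 && t + j <= length(s)) want <- want + 1L
    }
  }
  expect_equal(nrow(got), want)
})

test_that("interior context pairs are symmetric", {
  set.seed(5)
  s <- sample(letters[1:4], 30, replace = TRUE)
  p <- training_pairs(s, window = 2)
  key_fwd <- table(paste(p$center, p$context))
  key_rev <- table(paste(p$context, p$center))
  expect_equal(key_fwd[sort(names(key_fwd))], key_rev[sort(names(key_fwd))])
})

test_that("softmax is uniform for zero vectors and matches closed forms", {
  m0 <- make_model(matrix(0, 5, 3))
  for (tok in paste0("w", 1:5)) {
    expect_equal(softmax_probability(m0, "w1", tok), 0.2)
  }

  inp <- matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE,
                dimnames = list(c("a", "b"), NULL))
  out <- matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE,
                dimnames = list(c("a", "b"), NULL))
  m <- make_model(inp, out)
  expect_equal(softmax_probability(m, "a", "a"), exp(1) / (exp(1) + 1),
               tolerance = 1e-12)
  expect_error(softmax_probability(m, "a", "zz"), "unknown token")
})

test_that("softmax over the vocabulary sums to one for random models", {
  set.seed(6)
  for (W in c(5, 50)) {
    m <- make_model(matrix(rnorm(W * 8, sd = 2), W, 8),
                    matrix(rnorm(W * 8, sd = 2), W, 8))
    total <- sum(vapply(m$vocab$token,
                        function(tok) softmax_probability(m, "w1", tok),
                        numeric(1)))
    expect_equal(total, 1, tolerance = 1e-10)
  }
})

test_that("the average log probability matches brute-force recomputation", {
  # uniform case computed by hand: "a b c d e", window 2 -> 14 pairs, T = 5
  corpus <- list(c("a", "b", "c", "d", "e"))
  m0 <- make_model(matrix(0, 5, 4, dimnames = list(letters[1:5], NULL)))
  expect_equal(sg_objective(m0, corpus, window = 2), (14 / 5) * log(0.2),
               tolerance = 1e-12)

  set.seed(7)
  corpus <- list(c("a", "b", "c", "a"), c("b", "c", "c"))
  m <- make_model(matrix(rnorm(9), 3, 3, dimnames = list(c("a", "b", "c"), NULL)),
                  matrix(rnorm(9), 3, 3, dimnames = list(c("a", "b", "c"), NULL)))
  brute <- 0
  T_tok <- 0
  for (s in corpus) {
    T_tok <- T_tok + length(s)
    for (t in seq_along(s)) {
      for (j in -2:2) {
        u <- t + j
        if (j != 0 && u >= 1 && u <= length(s)) {
          brute <- brute + log(softmax_probability(m, s[t], s[u]))
        }
      }
    }
  }
  expect_equal(sg_objective(m, corpus, window = 2), brute / T_tok,
               tolerance = 1e-12)
})

test_that("analytic exact-softmax gradients match central differences", {
  set.seed(8)
  W <- 6; d <- 4
  input <- matrix(rnorm(W * d, sd = 0.5), W, d)
  output <- matrix(rnorm(W * d, sd = 0.5), W, d)
  N <- matrix(rpois(W * W, 2), W, W); diag(N) <- 0
  T_tok <- 20
  obj <- function(inp, outp) {
    S <- inp %*% t(outp)
    lse <- apply(S, 1, function(r) { mm <- max(r); mm + log(sum(exp(r - mm))) })
    sum(N * (S - lse)) / T_tok
  }
  g <- cavity2vec:::.sg_exact_gradient(input, output, N, T_tok)
  expect_equal(g$objective, obj(input, output), tolerance = 1e-12)
  h <- 1e-5
  for (mat in c("input", "output")) {
    M <- if (mat == "input") input else output
    num <- matrix(NA_real_, W, d)
    for (i in seq_len(W)) for (j in seq_len(d)) {
      Mp <- M; Mp[i, j] <- M[i, j] + h
      Mm <- M; Mm[i, j] <- M[i, j] - h
      num[i, j] <- if (mat == "input") {
        (obj(Mp, output) - obj(Mm, output)) / (2 * h)
      } else {
        (obj(input, Mp) - obj(input, Mm)) / (2 * h)
      }
    }
    ana <- if (mat == "input") g$grad_input else g$grad_output
    rel <- abs(ana - num) / pmax(abs(num), 1e-4)
    expect_lt(max(rel), 1e-5)
  }
})

test_that("analytic negative-sampling gradients match central differences", {
  set.seed(9)
  W <- 6; d <- 4
  input <- matrix(rnorm(W * d, sd = 0.5), W, d)
  output <- matrix(rnorm(W * d, sd = 0.5), W, d)
  center <- 2; target <- 5; negs <- c(1, 3, 3, 6)
  g <- cavity2vec:::.sg_ns_gradient(input, output, center, target, negs)
  h <- 1e-5
  for (mat in c("input", "output")) {
    M <- if (mat == "input") input else output
    num <- matrix(NA_real_, W, d)
    for (i in seq_len(W)) for (j in seq_len(d)) {
      Mp <- M; Mp[i, j] <- M[i, j] + h
      Mm <- M; Mm[i, j] <- M[i, j] - h
      num[i, j] <- if (mat == "input") {
        (cavity2vec:::.sg_ns_loss(Mp, output, center, target, negs) -
           cavity2vec:::.sg_ns_loss(Mm, output, center, target, negs)) / (2 * h)
      } else {
        (cavity2vec:::.sg_ns_loss(input, Mp, center, target, negs) -
           cavity2vec:::.sg_ns_loss(input, Mm, center, target, negs)) / (2 * h)
      }
    }
    ana <- if (mat == "input") g$grad_input else g$grad_output
    rel <- abs(ana - num) / pmax(abs(num), 1e-4)
    expect_lt(max(rel), 1e-5)
  }
})

test_that("full-batch exact-softmax ascent never decreases the objective", {
  corpus <- list(c("a", "b", "c", "a", "b"), c("c", "a", "b", "b"))
  fit <- train_skipgram(corpus, dim = 4, window = 2, epochs = 10,
                        negative = 0, lr = 0.05, lr_min = 0.05, seed = 21)
  trace <- c(fit$objective, sg_objective(fit, corpus))
  expect_length(fit$objective, 10)
  expect_true(all(diff(trace) >= -1e-12))
})

test_that("training is bit-identical under a repeated seed in both regimes", {
  ds <- small_dataset(k = 2, n = 4, dropout = 0.1, swap = 0.05, seed = 12)
  corp <- corpus_from_records(ds)
  for (k in c(0, 5)) {
    a <- train_skipgram(corp, dim = 8, window = 2, epochs = 5, negative = k,
                        seed = 13)
    b <- train_skipgram(corp, dim = 8, window = 2, epochs = 5, negative = k,
                        seed = 13)
    expect_identical(a$input, b$input)
    expect_identical(a$output, b$output)
  }
})

test_that("trained neighbours respect template structure on clean corpora", {
  ds <- generate_trajectories(k_templates = 3, n_per_template = 10,
                              node_dropout_prob = 0, node_swap_prob = 0,
                              seed = 14)
  corp <- corpus_from_records(ds)
  fit <- train_skipgram(corp, dim = 16, window = 2, epochs = 50, negative = 5,
                        seed = 15)
  # map unambiguous tokens to their template
  tok_tpl <- list()
  for (t in unique(ds$labels$template_id)) {
    for (tok in unique(unlist(ds$records$node_ids[ds$labels$template_id == t]))) {
      tok_tpl[[tok]] <- c(tok_tpl[[tok]], t)
    }
  }
  tok_tpl <- tok_tpl[lengths(tok_tpl) == 1]
  hits <- vapply(names(tok_tpl), function(tok) {
    nb <- nearest_nodes(fit, tok, n = 1)$token
    identical(tok_tpl[[nb]], tok_tpl[[tok]])
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("degenerate corpora raise informative training errors", {
  expect_error(train_skipgram(list("a"), dim = 4, negative = 5),
               "degenerate corpus")
  expect_error(train_skipgram(list(c("a", "b")), dim = 4, min_count = 5),
               "empty vocabulary")
})

test_that("tidy and glance summarise a fitted model", {
  fit <- train_skipgram(list(c("a", "b", "a", "c")), dim = 4, window = 1,
                        epochs = 2, negative = 2, seed = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), 3)
  expect_true(all(c("token", "count", "V1", "V4") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$vocab_size, 3)
  expect_equal(gl$dim, 4)
  expect_equal(gl$negative, 2)
})
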