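#' Default pipeline configuration
#'
#' Nested list of per-stage parameter blocks. [run_pipeline()] merges a
#' user configuration over these defaults and rejects unknown keys before
#' any stage runs, so typos cannot silently fall back to defaults.
#'
#' @param seed Global seed; each stage derives its own seed from it.
#' @return Named nested list.
#' @export
pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    synth = list(
      enabled = TRUE, k_templates = 3, n_per_template = 50,
      node_dropout_prob = 0.1, node_swap_prob = 0.05,
      n_atoms = 300, box = c(40, 40, 40)
    ),
    inputs = list(pdb = NULL, cavities = NULL),
    encode = list(mode = "center"),
    train = list(dim = 128, window = 5, epochs = 15, negative = 5,
                 min_count = 1, lr = 0.025, lr_min = 1e-4),
    embed = list(oov = "skip", normalize = FALSE),
    similar = list(enabled = TRUE, target = NULL, low = 0.9, high = 1.0),
    cluster = list(hierarchical = list(n_clusters = 3),
                   kmeans = list(k = 3, n_init = 10)),
    project = list(enabled = TRUE, perplexity = 10)
  )
}

.merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    if (!key %in% names(defaults)) {
      abort(sprintf("unknown configuration key '%s%s'.", path, key))
    }
    if (is.list(defaults[[key]]) && is.list(user[[key]])) {
      defaults[[key]] <- .merge_config(defaults[[key]], user[[key]],
                                       paste0(path, key, "."))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full cavity-embedding pipeline
#'
#' Chains synth (or external inputs) -> encode -> train -> embed ->
#' similar / cluster / project / profile and writes every artifact plus a
#' run manifest to `out_dir`. All randomness flows from the single global
#' seed through fixed per-stage offsets; re-running with the same
#' configuration reproduces every file bit for bit. A stage failure aborts
#' with the stage name attached to the underlying error.
#'
#' @param config Partial configuration list merged over
#'   [pipeline_config()]; unknown keys are rejected up front.
#' @param out_dir Output directory (created if missing).
#'
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- .merge_config(pipeline_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  seeds <- list(synth = cfg$seed, train = cfg$seed + 10L,
                kmeans = cfg$seed + 20L, tsne = cfg$seed + 30L)

  labels <- NULL
  if (isTRUE(cfg$synth$enabled)) {
    ds <- .stage("synth", generate_trajectories(
      k_templates = cfg$synth$k_templates,
      n_per_template = cfg$synth$n_per_template,
      node_dropout_prob = cfg$synth$node_dropout_prob,
      node_swap_prob = cfg$synth$node_swap_prob,
      seed = seeds$synth, n_atoms = cfg$synth$n_atoms, box = cfg$synth$box,
      mode = cfg$encode$mode
    ))
    atoms <- ds$atoms
    records <- ds$records
    labels <- ds$labels
    write_pdb(atoms, p("atoms.pdb"))
    utils::write.table(labels, p("labels.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    atoms <- .stage("inputs", {
      if (is.null(cfg$inputs$pdb) || is.null(cfg$inputs$cavities)) {
        abort("synth disabled but `inputs$pdb` / `inputs$cavities` not given.")
      }
      read_pdb(cfg$inputs$pdb)
    })
    records <- .stage("inputs", read_cavity_records(cfg$inputs$cavities))
  }

  records <- .stage("encode", {
    if (!"node_ids" %in% names(records)) {
      encode_records(records, atoms, mode = cfg$encode$mode)
    } else {
      records
    }
  })
  write_cavity_records(records, p("cavities.jsonl"))
  corpus <- corpus_from_records(records)
  write_corpus(corpus, p("corpus.txt"))

  model <- .stage("train", train_skipgram(
    corpus, dim = cfg$train$dim, window = cfg$train$window,
    epochs = cfg$train$epochs, negative = cfg$train$negative,
    min_count = cfg$train$min_count, lr = cfg$train$lr,
    lr_min = cfg$train$lr_min, seed = seeds$train
  ))
  write_embeddings(model, p("node_vectors.vec"))

  vectors <- .stage("embed", cavity_vectors(
    corpus, model, oov = cfg$embed$oov, normalize = cfg$embed$normalize
  ))
  write_embeddings(vectors_as_matrix(vectors), p("cavity_vectors.vec"))

  if (isTRUE(cfg$similar$enabled)) {
    .stage("similar", {
      target <- cfg$similar$target %||% vectors$cavity_id[1]
      sim <- query_by_similarity(vectors, target,
                                 low = cfg$similar$low, high = cfg$similar$high)
      utils::write.table(sim, p("similar.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
  }

  hier <- .stage("cluster", cluster_hierarchical(
    vectors, n_clusters = cfg$cluster$hierarchical$n_clusters
  ))
  km <- .stage("cluster", cluster_kmeans(
    vectors, k = cfg$cluster$kmeans$k, seed = seeds$kmeans,
    n_init = cfg$cluster$kmeans$n_init
  ))
  utils::write.table(hier, p("clusters_hierarchical.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(km, p("clusters_kmeans.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  if (isTRUE(cfg$project$enabled)) {
    coords <- .stage("project", project_tsne(
      vectors, perplexity = cfg$project$perplexity, seed = seeds$tsne
    ))
    utils::write.table(coords, p("projection.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  .stage("profile", {
    prof <- length_width_profiles(records)
    utils::write.csv(prof, p("length_width.csv"), row.names = FALSE)
    aa <- amino_acid_profile(records, atoms, clusters = km)
    utils::write.csv(aa, p("amino_acids.csv"), row.names = FALSE)
  })

  yaml::write_yaml(cfg, p("config.yaml"))
  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    package = "cavity2vec",
    version = as.character(utils::packageVersion("cavity2vec")),
    seed = cfg$seed,
    stage_seeds = seeds,
    config = cfg,
    files = as.list(setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files
    ))
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
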