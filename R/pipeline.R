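#' Run the full training pipeline from a config file
#'
#' Executes load -> vocabulary -> TF-IDF -> embeddings -> LDA target ->
#' double-target training from a flat YAML config, then writes three
#' artefacts into `outdir`: `checkpoint.rds` (the trained model),
#' `trace.csv` (the per-step loss / alpha trace) and `manifest.yaml`
#' (effective config, derived stage seeds, input digests, artefact paths).
#' Any stage failure aborts with a stage-named error and removes partial
#' outputs.
#'
#' Config keys: `tokens` (required), `labels`, `vectors` (optional
#' pre-trained word2vec-format table), `outdir` (required), `min_tokens`,
#' `min_doc_freq`, `lowercase`, `embedding_dim`, `subword_n`, `window`,
#' `emb_epochs`, `tfidf_variant`, `lda_passes`, plus every [dsc_config()]
#' field under its own name.
#'
#' @param config_path Path to the YAML config.
#' @return Invisibly, a list with `checkpoint`, `trace`, `manifest` paths
#'   and the fitted `model`.
#' @export
run_fit <- function(config_path) {
  cfg <- read_pipeline_config(config_path)
  outdir <- cfg$outdir
  if (is.null(outdir)) abort("stage config: 'outdir' is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  artefacts <- file.path(outdir, c("checkpoint.rds", "trace.csv",
                                   "manifest.yaml"))
  names(artefacts) <- c("checkpoint", "trace", "manifest")
  cleanup <- function() unlink(artefacts[file.exists(artefacts)])

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cleanup()
      abort(paste0("stage ", name, ": ", conditionMessage(e)))
    })
  }

  tcfg <- stage("config", do.call(dsc_config, cfg$train))
  if (!tcfg$use_topic_loss && !tcfg$use_cluster_loss) {
    abort("stage config: both losses disabled, nothing to optimize")
  }
  corpus <- stage("load", read_corpus(cfg$tokens, cfg$labels,
                                      min_tokens = cfg$min_tokens,
                                      lowercase = cfg$lowercase))
  vocab <- stage("vocabulary", build_vocabulary(corpus, cfg$min_doc_freq))
  tfidf <- stage("tfidf", compute_tfidf(corpus, vocab, cfg$tfidf_variant))
  table <- stage("embeddings", {
    if (!is.null(cfg$vectors)) {
      read_embeddings(cfg$vectors)
    } else {
      train_embeddings(corpus, dim = cfg$embedding_dim,
                       subword_n = cfg$subword_n, window = cfg$window,
                       epochs = cfg$emb_epochs, seed = tcfg$seed)
    }
  })
  topics <- stage("topic_target", {
    lda <- fit_topic_model(corpus, tcfg$r_topics, seed = tcfg$seed,
                           passes = cfg$lda_passes)
    document_topic_distribution(lda, corpus)
  })
  model <- stage("train", dsc_train(corpus, table, tfidf, topics, tcfg))

  stage("write", {
    save_checkpoint(model, artefacts[["checkpoint"]])
    utils::write.csv(model$trace, artefacts[["trace"]], row.names = FALSE)
    manifest <- list(
      package_version = as.character(utils::packageVersion("dsclust")),
      config = cfg$raw,
      seeds = list(
        master = tcfg$seed,
        embeddings = stage_seed(tcfg$seed, "embeddings"),
        lda = stage_seed(tcfg$seed, "lda"),
        train = stage_seed(tcfg$seed, "train"),
        predict = stage_seed(tcfg$seed, "predict")
      ),
      inputs = c(
        list(tokens = unname(tools::md5sum(cfg$tokens))),
        if (!is.null(cfg$labels)) {
          list(labels = unname(tools::md5sum(cfg$labels)))
        }
      ),
      artefacts = as.list(artefacts)
    )
    yaml::write_yaml(manifest, artefacts[["manifest"]])
  })
  invisible(list(checkpoint = artefacts[["checkpoint"]],
                 trace = artefacts[["trace"]],
                 manifest = artefacts[["manifest"]],
                 model = model))
}

read_pipeline_config <- function(config_path) {
  if (!file.exists(config_path)) {
    abort(paste0("stage config: file not found: ", config_path))
  }
  raw <- yaml::read_yaml(config_path)
  train_keys <- names(formals(dsc_config))
  defaults <- list(min_tokens = 1L, min_doc_freq = 1L, lowercase = FALSE,
                   embedding_dim = 64L, subword_n = 2L, window = 5L,
                   emb_epochs = 15L, tfidf_variant = "smooth",
                   lda_passes = 200L)
  cfg <- utils::modifyList(defaults, raw[setdiff(names(raw), train_keys)])
  cfg$train <- raw[intersect(names(raw), train_keys)]
  cfg$raw <- raw
  cfg
}

#' Predict cluster labels for a token file with a saved checkpoint
#'
#' @param checkpoint_path Path to a checkpoint written by [run_fit()].
#' @param tokens_path Token file, one document per line.
#' @param out_path Optional output path; one integer label per line, aligned
#'   with the input order.
#' @param seed Integer seed for the final k-means.
#' @return The integer label vector, invisibly when `out_path` is given.
#' @export
run_predict <- function(checkpoint_path, tokens_path, out_path = NULL,
                        seed = 1L) {
  model <- read_checkpoint(checkpoint_path)
  corpus <- read_corpus(tokens_path, min_tokens = 1L)
  labels <- predict_clusters(model, corpus,
                             seed = stage_seed(seed, "predict"))
  if (!is.null(out_path)) {
    writeLines(as.character(labels), out_path)
    return(invisible(labels))
  }
  labels
}

#' Evaluate predicted labels against gold labels
#'
#' @param pred_path File with one predicted integer label per line.
#' @param gold_path File with one gold integer label per line.
#' @param out_path Optional path for the metrics JSON.
#' @return The metrics tibble (see [evaluate_clustering()]), invisibly if
#'   written to file; the JSON carries keys `acc`, `nmi`, `ari`,
#'   `f1_macro`, `f1_pairwise`, `n`.
#' @export
run_evaluate <- function(pred_path, gold_path, out_path = NULL) {
  pred <- read_label_file(pred_path)
  gold <- read_label_file(gold_path)
  if (length(pred) != length(gold)) {
    abort(sprintf("alignment error: %d predicted vs %d gold labels",
                  length(pred), length(gold)))
  }
  report <- evaluate_clustering(gold, pred)
  json <- jsonlite::toJSON(as.list(report), auto_unbox = TRUE, digits = NA)
  if (!is.null(out_path)) {
    writeLines(json, out_path)
    return(invisible(report))
  }
  report
}

read_label_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  labels <- suppressWarnings(as.integer(lines))
  if (anyNA(labels)) {
    abort(sprintf("label parse error in %s at line %d", path,
                  which(is.na(labels))[1]))
  }
  labels
}

#' Run the TF-IDF + k-means baseline on a token file
#'
#' @param tokens_path Token file.
#' @param K Number of clusters.
#' @param out_path Optional label output path.
#' @param seed Integer seed.
#' @return Integer labels (invisibly when written).
#' @export
run_baseline <- function(tokens_path, K, out_path = NULL, seed = 1L) {
  corpus <- read_corpus(tokens_path, min_tokens = 1L)
  labels <- baseline_tfidf_kmeans(corpus, K = K, seed = seed)
  if (!is.null(out_path)) {
    writeLines(as.character(labels), out_path)
    return(invisible(labels))
  }
  labels
}

#' Write a synthetic benchmark corpus to disk
#'
#' Generates a labelled synthetic corpus (see [synth_corpus()]) and writes
#' the token file, the label file and the generation parameters (YAML) next
#' to each other.
#'
#' @param outdir Output directory (created if missing).
#' @param ... Passed to [synth_corpus()].
#' @return Invisibly, the paths of the three files.
#' @export
run_synth <- function(outdir, ...) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  spec <- list(...)
  corpus <- synth_corpus(...)
  paths <- file.path(outdir, c("tokens.txt", "labels.txt", "synth.yaml"))
  write_corpus(corpus, paths[1], paths[2])
  yaml::write_yaml(spec, paths[3])
  invisible(setNames(as.list(paths), c("tokens", "labels", "spec")))
}
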