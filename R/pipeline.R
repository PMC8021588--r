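# Workflow orchestration: encode, experiment, simulate, predict.
#
# Every experiment run directory contains a manifest (config, seed,
# input hashes, package version) sufficient to reproduce the run.

.file_hash <- function(path) unname(tools::md5sum(path))

#' Read a structured run configuration file
#'
#' YAML with optional sections `thermo` (`temperature_K`,
#' `min_separation`), `encoder` (fields of [sentence_config()]),
#' `model` (fields of [model_config()]), `evaluation` (`folds`,
#' `undersample`) and a global `seed`.
#'
#' @param path Path to the YAML file.
#' @return A list with `sentence_cfg`, `model_cfg`, `folds`,
#'   `undersample`, `seed`.
#' @export
read_run_config <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  th <- do.call(thermo_config, raw$thermo %||% list())
  enc <- raw$encoder %||% list()
  enc$thermo <- th
  scfg <- do.call(sentence_config, enc)
  mcfg <- do.call(model_config, raw$model %||% list())
  ev <- raw$evaluation %||% list()
  list(sentence_cfg = scfg, model_cfg = mcfg,
       folds = ev$folds %||% 5L,
       undersample = isTRUE(ev$undersample),
       seed = raw$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Encode all primer-pair x template combinations to a corpus file
#'
#' @param templates Path to a FASTA file of templates.
#' @param primers Path to a primer table (TSV/CSV).
#' @param labels Optional path to a label table; combinations without an
#'   entry are written with label `?`.
#' @param out Output corpus path.
#' @param cfg A [sentence_config()].
#' @return The corpus (list of `pseudo_sentence`), invisibly; the file
#'   at `out` has one line per combination.
#' @export
cmd_encode <- function(templates, primers, labels = NULL, out,
                       cfg = sentence_config()) {
  tpl <- read_fasta(templates)
  prs <- parse_primer_table(primers)
  lab <- if (!is.null(labels)) parse_label_table(labels)
  corpus <- make_corpus(prs, tpl, lab, cfg)
  write_corpus(corpus, out)
  invisible(corpus)
}

#' Run a full cross-validated experiment on a labeled corpus
#'
#' Optionally undersamples to per-template label parity, runs k-fold
#' grouped cross-validation, and writes metrics JSON, the pooled cross
#' table, per-fold epoch-accuracy histories, the Gibbs scatter table,
#' per-fold model checkpoints, and a reproducibility manifest.
#'
#' @param corpus Corpus file path or a list of labeled
#'   `pseudo_sentence` objects.
#' @param out_dir Output directory (created if missing).
#' @param model_cfg A [model_config()].
#' @param folds Number of cross-validation folds (default 5).
#' @param undersample Equalize per-template label counts first?
#' @param seed Seed for undersampling and fold assignment.
#' @return The [cross_validate()] result, invisibly.
#' @export
cmd_experiment <- function(corpus, out_dir, model_cfg = model_config(),
                           folds = 5L, undersample = FALSE, seed = 1L) {
  corpus_path <- NULL
  if (is.character(corpus)) {
    corpus_path <- corpus
    corpus <- read_corpus(corpus)
  }
  corpus <- Filter(function(s) !is.na(s$label), corpus)
  labels <- .sample_labels(corpus)
  if (length(unique(labels)) < 2L) {
    stop("corpus contains a single class; cannot train", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (undersample) corpus <- undersample(corpus, seed = seed)
  res <- cross_validate(corpus, k = folds, model_cfg = model_cfg,
                        seed = seed)

  m <- res$pooled_metrics
  jsonlite::write_json(
    list(pooled = list(tn = res$pooled$tn, fn = res$pooled$fn,
                       fp = res$pooled$fp, tp = res$pooled$tp,
                       sensitivity = m$sensitivity,
                       specificity = m$specificity,
                       accuracy = m$accuracy),
         per_fold = res$fold_metrics),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows", na = "null")
  utils::write.table(
    data.frame(tn = res$pooled$tn, fn = res$pooled$fn,
               fp = res$pooled$fp, tp = res$pooled$tp),
    file.path(out_dir, "cross_table.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  hist_all <- do.call(rbind, lapply(seq_along(res$histories), function(f) {
    h <- res$histories[[f]]
    if (is.null(h)) return(NULL)
    cbind(fold = f, h)
  }))
  utils::write.table(hist_all, file.path(out_dir, "history.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(gibbs_scatter_table(res$predictions),
                     file.path(out_dir, "gibbs_scatter.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(
    seed = seed, folds = folds, undersample = undersample,
    n_samples = length(corpus),
    n_positive = sum(labels == 1L), n_negative = sum(labels == 0L),
    model_config = unclass(model_cfg),
    corpus_md5 = if (!is.null(corpus_path)) .file_hash(corpus_path),
    package_version = as.character(utils::packageVersion("pcrlingo")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(res)
}

#' Generate and write a synthetic dataset
#'
#' @param cfg A [synth_config()].
#' @param out_dir Output directory; writes `templates.fasta`,
#'   `primers.tsv` and `labels.tsv` in the formats the package reads
#'   back.
#' @return The [generate_dataset()] result, invisibly.
#' @export
cmd_simulate <- function(cfg = synth_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- generate_dataset(cfg)
  write_fasta(ds$templates, file.path(out_dir, "templates.fasta"))
  utils::write.table(ds$pairs[, c("pair_id", "fwd_name", "fwd_seq",
                                  "rev_name", "rev_seq")],
                     file.path(out_dir, "primers.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(ds$labels, file.path(out_dir, "labels.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(ds)
}

#' Predict PCR outcomes for a corpus with a saved model
#'
#' @param model_path Checkpoint path from [save_model()].
#' @param corpus Corpus file path or list of `pseudo_sentence` objects.
#' @param out Output TSV path.
#' @return The prediction data.frame, invisibly.
#' @export
cmd_predict <- function(model_path, corpus, out) {
  model <- load_model(model_path)
  if (is.character(corpus)) corpus <- read_corpus(corpus)
  pr <- predict_samples(model, corpus)
  res <- data.frame(
    pair_id = vapply(corpus, function(s) s$pair_id, character(1)),
    template_id = vapply(corpus, function(s) s$template_id, character(1)),
    probability = pr$probability, prediction = pr$label,
    stringsAsFactors = FALSE)
  utils::write.table(res, out, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(res)
}
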