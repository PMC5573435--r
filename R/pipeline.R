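# File-level pipeline: the run_* functions behind the command-line
# interface (inst/cli/kmervote.R). Each takes paths in, writes TSV/JSON
# out, and logs the stage counts needed to reproduce staged summaries.

#' Pipeline run configuration
#'
#' Collects the parameters shared by the pipeline stages. A config can
#' also be read from a key=value file with [read_run_config()]; values
#' given directly override file values.
#'
#' @param reference_fasta,reference_labels Reference sequences and their
#'   `id<TAB>species` mapping.
#' @param query_fasta Query fragments to classify.
#' @param model_file Path of the serialized ensemble.
#' @param out_dir Output directory.
#' @param kset,omega,vote_threshold Ensemble parameters (defaults
#'   6:10, 32, 5).
#' @param policy Fallback policy preset name (`"default"`/`"strict"`).
#' @param fallback Logical: run the alignment fallback stage.
#' @param level_map Optional species-to-level TSV for coarser reports.
#' @param seed Integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(reference_fasta = NULL, reference_labels = NULL,
                       query_fasta = NULL, model_file = NULL,
                       out_dir = ".", kset = 6:10, omega = 32,
                       vote_threshold = NULL, policy = "default",
                       fallback = TRUE, level_map = NULL, seed = 1) {
  cfg <- list(
    reference_fasta = reference_fasta, reference_labels = reference_labels,
    query_fasta = query_fasta, model_file = model_file, out_dir = out_dir,
    kset = as.integer(kset), omega = omega,
    vote_threshold = as.integer(vote_threshold %||% length(kset)),
    policy = policy, fallback = isTRUE(fallback),
    level_map = level_map, seed = as.integer(seed)
  )
  check_threshold(cfg$vote_threshold, length(cfg$kset))
  structure(cfg, class = "run_config")
}

#' Read a key=value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. `kset` may be
#' a comma-separated list. Keys match the arguments of [run_config()].
#'
#' @param path Config file path.
#' @param ... Overrides, as in [run_config()] (an explicit argument wins
#'   over the file).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(x) trimws(paste(x[-1], collapse = "=")))
  names(vals) <- trimws(vapply(kv, `[[`, character(1), 1))
  for (num in c("omega", "seed", "vote_threshold")) {
    if (!is.null(vals[[num]])) vals[[num]] <- as.numeric(vals[[num]])
  }
  if (!is.null(vals$kset)) {
    vals$kset <- as.integer(trimws(strsplit(vals$kset, ",")[[1]]))
  }
  if (!is.null(vals$fallback)) vals$fallback <- toupper(vals$fallback) %in% c("TRUE", "1", "YES")
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

log_stage <- function(stage, ...) {
  kv <- list(...)
  msg <- paste(vapply(seq_along(kv), function(i) {
    sprintf("%s=%s", names(kv)[i], format(kv[[i]]))
  }, character(1)), collapse = " ")
  message(sprintf("[kmervote] stage=%s %s", stage, msg))
}

require_file <- function(path, what) {
  if (is.null(path) || !file.exists(path)) {
    abort(sprintf("Cannot read %s: '%s'.", what, path %||% "<missing>"))
  }
  path
}

#' Pipeline stage: simulate a dataset
#'
#' @param spec A [synthetic_spec()] or path to a JSON manifest of one.
#' @param out_dir Output directory.
#' @return The output directory, invisibly.
#' @export
run_simulate <- function(spec, out_dir) {
  if (is.character(spec)) {
    spec <- do.call(synthetic_spec, jsonlite::read_json(require_file(spec, "spec"),
                                                        simplifyVector = TRUE))
  }
  ds <- make_dataset(spec)
  write_dataset(ds, out_dir)
  log_stage("simulate", n_species = spec$n_species,
            n_reference = nrow(ds$reference_fragments),
            n_validation = nrow(ds$validation_fragments))
  invisible(out_dir)
}

#' Pipeline stage: train the ensemble
#'
#' Shreds the reference genomes to `fragment_length` windows, trains one
#' SVM per k in `kset`, and serializes the model to
#' `config$model_file`.
#'
#' @param config A [run_config()].
#' @param fragment_length Shredding window for the reference (bp);
#'   sequences at or below this length are used as-is.
#' @return The trained `kmer_ensemble`, invisibly.
#' @export
run_train <- function(config, fragment_length = 400) {
  ref <- read_fragments_fasta(
    require_file(config$reference_fasta, "reference FASTA"),
    labels = require_file(config$reference_labels, "reference label mapping"))
  if (anyNA(ref$label)) {
    abort(paste0("Reference sequence(s) without a label: ",
                 paste(head(ref$id[is.na(ref$label)], 5), collapse = ", ")))
  }
  frags <- if (all(nchar(ref$sequence) <= fragment_length)) ref else {
    dplyr::bind_rows(purrr::pmap(ref, function(id, sequence, label) {
      shred_genome(sequence, fragment_length, id = id, label = label)
    }))
  }
  ens <- train_ensemble(frags, kset = config$kset, omega = config$omega)
  for (m in ens$members) {
    log_stage("train", k = m$k, n_fragments = nrow(frags),
              n_classes = length(m$classes), omega = config$omega)
  }
  if (!is.null(config$model_file)) write_ensemble(ens, config$model_file)
  invisible(ens)
}

#' Pipeline stage: classify query fragments
#'
#' Loads the model and queries, runs the voting stage and (unless
#' `config$fallback` is `FALSE`) the alignment fallback against the
#' reference, and writes `classification.tsv` with one row per fragment:
#' id, per-member votes, plurality, agreement, set tag, final label and
#' hit statistics.
#'
#' @param config A [run_config()].
#' @param model Optional in-memory `kmer_ensemble` (else read from
#'   `config$model_file`).
#' @return The classification tibble, invisibly.
#' @export
run_classify <- function(config, model = NULL) {
  ens <- model %||% read_ensemble(require_file(config$model_file, "model file"))
  queries <- read_fragments_fasta(require_file(config$query_fasta, "query FASTA"))
  reference <- if (config$fallback) {
    read_fragments_fasta(
      require_file(config$reference_fasta, "reference FASTA"),
      labels = require_file(config$reference_labels, "reference label mapping"))
  }
  res <- classify_fragments(ens, queries, reference = reference,
                            threshold = config$vote_threshold,
                            policy = fallback_policy(config$policy))
  part <- attr(res, "partition")
  out <- dplyr::left_join(
    part[, c("id", paste0("k", ens$kset), "plurality", "agreement", "set")],
    res[, c("id", "label", "method", "e_value", "percent_identity")],
    by = "id")
  if (!config$fallback) {
    out <- out[, setdiff(names(out), c("label", "method", "e_value",
                                       "percent_identity"))]
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(out, file.path(config$out_dir, "classification.tsv"))
  log_stage("classify", n_queries = nrow(res),
            n_confident = sum(res$set == "confident"),
            n_diffident = sum(res$set == "diffident"),
            n_unknown = sum(res$label == "unknown"),
            threshold = config$vote_threshold)
  invisible(res)
}

#' Pipeline stage: evaluate predictions
#'
#' Joins a predictions TSV (columns `id`, `label`, optionally `set`) to
#' a truth TSV (`id<TAB>label`, no header) and writes staged and
#' per-class reports; with a species-to-level mapping, reports at that
#' level are written too.
#'
#' @param predictions_tsv Predictions file (TSV with a header).
#' @param truth_tsv Two-column truth mapping (no header).
#' @param out_dir Output directory.
#' @param level_map Optional two-column species-to-level TSV (no
#'   header).
#' @return The staged (or single) report tibble, invisibly.
#' @export
run_evaluate <- function(predictions_tsv, truth_tsv, out_dir = ".",
                         level_map = NULL) {
  pred <- readr::read_tsv(require_file(predictions_tsv, "predictions"),
                          col_types = readr::cols(), progress = FALSE)
  truth <- read_label_map(require_file(truth_tsv, "truth labels"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reports <- list(species = eval_one(pred, truth))
  if (!is.null(level_map)) {
    mp <- read_label_map(require_file(level_map, "level mapping"))
    pred2 <- pred
    pred2$label <- map_taxonomy(pred2$label, mp)
    truth2 <- truth
    truth2$label <- map_taxonomy(truth2$label, mp)
    reports$mapped <- eval_one(pred2, truth2)
  }
  for (lvl in names(reports)) {
    readr::write_tsv(reports[[lvl]],
                     file.path(out_dir, sprintf("report_%s.tsv", lvl)))
  }
  pt <- join_truth(pred, truth)
  per_class <- confusion_counts(pt$truth, pt$label)
  readr::write_tsv(per_class, file.path(out_dir, "per_class.tsv"))
  log_stage("evaluate", n = nrow(pred),
            accuracy = round(reports$species$accuracy[nrow(reports$species)], 2))
  invisible(reports$species)
}

eval_one <- function(pred, truth) {
  if ("set" %in% names(pred)) {
    staged_report(pred, truth)
  } else {
    evaluate_predictions(pred, truth)
  }
}

#' Pipeline stage: voting-threshold sweep
#'
#' Trains nothing: classifies the queries at each threshold with the
#' given model and writes `sweep.tsv` (one row per threshold x stage).
#'
#' @inheritParams run_classify
#' @param truth_tsv Two-column truth mapping for the queries.
#' @param thresholds Thresholds to evaluate (default all).
#' @return The sweep tibble, invisibly.
#' @export
run_sweep <- function(config, truth_tsv, thresholds = NULL, model = NULL) {
  ens <- model %||% read_ensemble(require_file(config$model_file, "model file"))
  queries <- read_fragments_fasta(require_file(config$query_fasta, "query FASTA"))
  truth <- read_label_map(require_file(truth_tsv, "truth labels"))
  reference <- if (config$fallback) {
    read_fragments_fasta(
      require_file(config$reference_fasta, "reference FASTA"),
      labels = require_file(config$reference_labels, "reference label mapping"))
  }
  sw <- sweep_thresholds(ens, queries, truth,
                         thresholds = thresholds %||% seq_along(ens$kset),
                         reference = reference,
                         policy = fallback_policy(config$policy))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(sw, file.path(config$out_dir, "sweep.tsv"))
  log_stage("sweep", thresholds = paste(unique(sw$threshold), collapse = ","))
  invisible(sw)
}
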