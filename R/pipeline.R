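#' Pipeline run configuration
#'
#' Collects every tunable of the train/predict/evaluate workflow with its
#' default: length window `[200, 20000)`, FSC cut `p = 30`, 8 x 8 SOM grid
#' with a per-class target of `L = 2000` training samples, 300 trees, the
#' 54-nt MaxORF shortcut and a 0.5 decision threshold. One explicit seed is
#' recorded per stochastic stage, all derived from `seed` so that a single
#' integer reproduces a run.
#'
#' @param min_len,max_len Training-mode length window (half-open).
#' @param p Number of FSC-selected features.
#' @param som_rows,som_cols,som_epochs SOM grid and schedule.
#' @param L Per-class training-set target (capped at the pool size by
#'   [run_train()]).
#' @param n_trees Forest size.
#' @param orf_shortcut MaxORF shortcut threshold (nt).
#' @param decision_threshold Non-coding score decision threshold.
#' @param fsc_on_subset Compute the FSC ranking on the SOM-selected subset
#'   instead of the full labelled pool.
#' @param seed Base seed from which the stage seeds are derived.
#' @return A `run_config` list; serializable with [save_config()].
#' @export
run_config <- function(min_len = 200L, max_len = 20000L, p = 30L,
                       som_rows = 8L, som_cols = 8L, som_epochs = 10L,
                       L = 2000L, n_trees = 300L, orf_shortcut = 54L,
                       decision_threshold = 0.5, fsc_on_subset = FALSE,
                       seed = 1L) {
  cfg <- list(min_len = as.integer(min_len), max_len = as.integer(max_len),
              p = as.integer(p), som_rows = as.integer(som_rows),
              som_cols = as.integer(som_cols),
              som_epochs = as.integer(som_epochs), L = as.integer(L),
              n_trees = as.integer(n_trees),
              orf_shortcut = as.integer(orf_shortcut),
              decision_threshold = decision_threshold,
              fsc_on_subset = isTRUE(fsc_on_subset),
              seed = as.integer(seed),
              seeds = list(som = as.integer(seed) + 101L,
                           forest = as.integer(seed) + 211L,
                           importance = as.integer(seed) + 307L))
  class(cfg) <- "run_config"
  cfg
}

#' Save / load a run configuration
#'
#' Configurations round-trip losslessly through YAML.
#'
#' @param config A `run_config`.
#' @param path File path.
#' @return `save_config` invisibly returns `path`; `load_config` returns the
#'   `run_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- run_config()
  stopifnot(setequal(names(cfg), names(base)))
  int_fields <- c("min_len", "max_len", "p", "som_rows", "som_cols",
                  "som_epochs", "L", "n_trees", "orf_shortcut", "seed")
  for (f in int_fields) cfg[[f]] <- as.integer(cfg[[f]])
  cfg$seeds <- lapply(cfg$seeds, as.integer)
  class(cfg) <- "run_config"
  cfg
}

#' Hash of a run configuration
#'
#' @param config A `run_config`.
#' @return MD5 hex digest of the serialized configuration.
#' @export
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(unclass(config), f, version = 2L)
  unname(tools::md5sum(f))
}

.log_stage <- function(log, fmt, ...) {
  line <- sprintf(fmt, ...)
  message(line)
  c(log, line)
}

#' Train a coding-potential model end to end
#'
#' Runs the full training workflow: clean both FASTA inputs with the strict
#' dataset filters, extract the 89 features, rank by FSC and keep the top
#' `p`, pick about `L` representative transcripts per class with a SOM,
#' drop short-ORF non-coding examples, fit the forest, and persist the model
#' bundle. A cleaning log (rejected records with reason codes) and a
#' machine-readable provenance block (config hash, seeds, stage counts) are
#' written alongside the bundle.
#'
#' @param config A `run_config`.
#' @param coding_fasta,noncoding_fasta Paths to the labelled FASTA inputs.
#' @param out_model Path for the model bundle (RDS).
#' @return Invisibly, a list with `model`, `ranking`, `selection`,
#'   `provenance`, and the training log lines.
#' @export
run_train <- function(config, coding_fasta, noncoding_fasta, out_model) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)

  pools <- lapply(list(CODING = coding_fasta, NONCODING = noncoding_fasta),
                  function(f) {
                    cl <- clean_transcripts(read_fasta(f),
                                            min_len = config$min_len,
                                            max_len = config$max_len)
                    cl
                  })
  for (lbl in names(pools)) {
    pools[[lbl]]$transcripts$label <- rep(lbl, nrow(pools[[lbl]]$transcripts))
    r <- pools[[lbl]]$report
    log <- .log_stage(log, "clean [%s]: kept %d (alphabet %d, length %d, duplicate %d rejected)",
                      lbl, r$kept, r$rejected_alphabet, r$rejected_length,
                      r$rejected_duplicate)
  }
  rejects <- rbind(pools$CODING$rejects, pools$NONCODING$rejects)
  utils::write.table(rejects, paste0(out_model, ".rejects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  all_tx <- rbind(pools$CODING$transcripts, pools$NONCODING$transcripts)
  if (length(unique(all_tx$label)) < 2L || any(vapply(pools, function(p)
      nrow(p$transcripts), integer(1L)) == 0L)) {
    stop("train stage requires non-empty coding and non-coding pools")
  }
  fm <- feature_matrix(all_tx)
  X <- as.matrix(fm[, -1L, drop = FALSE])
  rownames(X) <- fm$id
  y <- all_tx$label
  log <- .log_stage(log, "features: %d transcripts x %d features",
                    nrow(X), ncol(X))

  L <- min(config$L, sum(y == "CODING"), sum(y == "NONCODING"))
  if (L < config$L) {
    log <- .log_stage(log, "L capped at smaller pool size: %d", L)
  }

  if (config$fsc_on_subset) {
    # SOM on all z-scored features first, FSC afterwards on the subset only
    sel0 <- select_training_set(X[y == "NONCODING", , drop = FALSE],
                                X[y == "CODING", , drop = FALSE],
                                L = L, rows = config$som_rows,
                                cols = config$som_cols,
                                epochs = config$som_epochs,
                                seed = config$seeds$som)
    sub_ids <- c(sel0$positive_ids, sel0$negative_ids)
    ranking <- fsc_scores(X[sub_ids, , drop = FALSE],
                          y[match(sub_ids, rownames(X))])
    selection <- sel0
  } else {
    ranking <- fsc_scores(X, y)
    selection <- NULL
  }
  selected <- select_top(ranking, config$p)
  log <- .log_stage(log, "FSC: %d -> %d feature reduction",
                    ncol(X), length(selected))

  Xs <- X[, selected, drop = FALSE]
  if (is.null(selection)) {
    selection <- select_training_set(Xs[y == "NONCODING", , drop = FALSE],
                                     Xs[y == "CODING", , drop = FALSE],
                                     L = L, rows = config$som_rows,
                                     cols = config$som_cols,
                                     epochs = config$som_epochs,
                                     seed = config$seeds$som)
  }
  train_ids <- c(selection$positive_ids, selection$negative_ids)
  log <- .log_stage(log, "SOM selection: %d non-coding + %d coding training samples",
                    length(selection$positive_ids),
                    length(selection$negative_ids))

  Xt <- Xs[train_ids, , drop = FALSE]
  yt <- y[match(train_ids, rownames(X))]
  model <- train_classifier(Xt, yt, n_trees = config$n_trees,
                            seed = config$seeds$forest,
                            orf_shortcut = config$orf_shortcut,
                            decision_threshold = config$decision_threshold,
                            max_orf_values = X[train_ids, "MaxORF"])
  log <- .log_stage(log, "forest: %d trees on %d coding / %d non-coding (%d short-ORF non-coding dropped)",
                    config$n_trees, model$training$n_coding,
                    model$training$n_noncoding,
                    model$training$n_shortcut_dropped)

  save_model(model, out_model)
  provenance <- list(config_hash = config_hash(config),
                     seeds = config$seeds,
                     stage_counts = list(
                       input = nrow(all_tx) + nrow(rejects),
                       cleaned = nrow(all_tx),
                       features = ncol(X),
                       selected_features = length(selected),
                       training_noncoding = length(selection$positive_ids),
                       training_coding = length(selection$negative_ids),
                       shortcut_dropped = model$training$n_shortcut_dropped))
  jsonlite::write_json(provenance, paste0(out_model, ".provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log <- .log_stage(log, "model bundle written: %s", out_model)
  invisible(list(model = model, ranking = ranking, selection = selection,
                 provenance = provenance, log = log))
}

#' Predict coding potential for a FASTA file
#'
#' Prediction-mode cleaning normalizes the alphabet and rejects records with
#' disallowed characters, but does not drop out-of-window lengths: such
#' records are flagged in a `length_flag` column instead (a deployed
#' classifier must answer for arbitrary user input). Records shorter than
#' the shortcut threshold necessarily take the shortcut.
#'
#' @param config A `run_config`.
#' @param model A `coding_potential_model` or the path to a saved bundle.
#' @param fasta Input FASTA path.
#' @param out_tsv Output report path (see [write_report()]).
#' @return Invisibly, the prediction data.frame.
#' @export
run_predict <- function(config, model, fasta, out_tsv) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(model)) model <- load_model(model)
  cl <- clean_transcripts(read_fasta(fasta), min_len = config$min_len,
                          max_len = config$max_len, drop_duplicates = FALSE,
                          enforce_length = FALSE)
  tx <- cl$transcripts
  if (nrow(tx) == 0L) {
    preds <- data.frame(id = character(0), noncoding_score = numeric(0),
                        predicted_class = character(0),
                        shortcut_applied = logical(0),
                        length_flag = logical(0))
  } else {
    fm <- feature_matrix(tx)
    preds <- predict(model, fm)
    preds <- cbind(preds[, 1:4], length_flag = tx$length_flag,
                   preds[, -(1:4), drop = FALSE])
  }
  write_report(preds, out_tsv)
  invisible(preds)
}

#' Evaluate a prediction report against known labels
#'
#' Joins the report and label table on transcript id, computes the confusion
#' counts (NONCODING positive), Sn/Sp/ACC/MCC, and rank-based AUC with
#' shortcut-flagged rows excluded from the ROC (their score of 1 is a rule,
#' not a forest vote).
#'
#' @param config A `run_config`.
#' @param report_tsv Prediction report path (from [run_predict()]).
#' @param labels_tsv Two-column TSV (`id`, `label`).
#' @param out_metrics Output metrics TSV path.
#' @return Invisibly, a list with `counts`, `metrics` (including `AUC`, `NA`
#'   when undefined), and the joined data.
#' @export
run_evaluate <- function(config, report_tsv, labels_tsv, out_metrics) {
  stopifnot(inherits(config, "run_config"))
  report <- utils::read.delim(report_tsv, check.names = FALSE,
                              stringsAsFactors = FALSE)
  labels <- utils::read.delim(labels_tsv, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "label") %in% names(labels)))
  missing_lab <- setdiff(report$id, labels$id)
  missing_rep <- setdiff(labels$id, report$id)
  if (length(missing_lab) || length(missing_rep)) {
    stop("id mismatch between report and labels; unlabelled: [",
         paste(utils::head(missing_lab, 5L), collapse = ", "),
         "], unpredicted: [",
         paste(utils::head(missing_rep, 5L), collapse = ", "), "]")
  }
  joined <- merge(report, labels, by = "id", sort = FALSE)
  counts <- confusion_counts(joined$label, joined$predicted_class)
  metrics <- classification_metrics(counts)
  keep_roc <- !joined$shortcut_applied
  metrics$AUC <- if (length(unique(joined$label[keep_roc])) == 2L) {
    roc_auc(joined$noncoding_score[keep_roc], joined$label[keep_roc])
  } else {
    NA_real_
  }
  out <- data.frame(metric = c("TP", "FP", "TN", "FN", "Sn", "Sp", "ACC",
                               "MCC", "AUC"),
                    value = c(counts$TP, counts$FP, counts$TN, counts$FN,
                              metrics$Sn, metrics$Sp, metrics$ACC,
                              metrics$MCC, metrics$AUC))
  utils::write.table(out, out_metrics, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(counts = counts, metrics = metrics, joined = joined))
}
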