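known_config_keys <- function() {
  list(
    top = c("seed", "sim", "split", "model", "train", "score"),
    sim = names(formals(sim_config)),
    split = c("test_fraction"),
    model = names(formals(model_config)),
    train = names(formals(train_control)),
    score = c("threshold")
  )
}

validate_run_config <- function(cfg) {
  keys <- known_config_keys()
  bad <- setdiff(names(cfg), keys$top)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (blk in c("sim", "split", "model", "train", "score")) {
    if (!is.null(cfg[[blk]])) {
      bad <- setdiff(names(cfg[[blk]]), keys[[blk]])
      if (length(bad)) {
        stop("unknown config key(s) in '", blk, "': ",
             paste(bad, collapse = ", "))
      }
    }
  }
  invisible(cfg)
}

stage_log <- function(stage, ...) {
  message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", ...)
}

#' Run the end-to-end pipeline
#'
#' Executes the requested stages in order -- `simulate` (write a synthetic
#' WFDB corpus), `preprocess` (build the window-pair sequence dataset),
#' `train` (patient-grouped split + fit), `predict` (per-segment scores) and
#' `evaluate` (metrics and AHI report) -- each stage reading its
#' predecessor's artifacts from `out_dir`. The resolved configuration is
#' written alongside the artifacts for auditability. With `resume = TRUE` a
#' stage whose artifact already exists is skipped.
#'
#' @param config path to a YAML file or a named list with blocks `sim`,
#'   `split`, `model`, `train`, `score` and a top-level `seed`; unknown keys
#'   are rejected before anything runs.
#' @param out_dir artifact directory.
#' @param stages subset of the five stages, in pipeline order.
#' @param seed overrides the config seed.
#' @param resume skip stages whose outputs already exist.
#' @param threshold classification threshold override for evaluation.
#' @return (invisibly) a list of the artifacts produced.
#' @export
run_pipeline <- function(config = list(), out_dir,
                         stages = c("simulate", "preprocess", "train",
                                    "predict", "evaluate"),
                         seed = NULL, resume = FALSE, threshold = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_run_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  if (!is.null(seed)) config$seed <- seed
  config$seed <- config$seed %||% 1L
  # fail on invalid stage settings before any computation
  sim_cfg <- do.call(sim_config, c(config$sim %||% list(),
                                   list(seed = config$seed)))
  mod_cfg <- do.call(model_config, config$model %||% list())
  ctl <- do.call(train_control, c(config$train %||% list(),
                                  list(seed = config$seed)))
  thr <- threshold %||% config$score$threshold %||% 0.5
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(out_dir, "config_resolved.yaml"))

  corpus_dir <- file.path(out_dir, "corpus")
  dataset_rds <- file.path(out_dir, "dataset.rds")
  fit_rds <- file.path(out_dir, "model.rds")
  scores_csv <- file.path(out_dir, "segment_scores.csv")
  artifacts <- list()

  if ("simulate" %in% stages &&
      !(resume && file.exists(file.path(corpus_dir, "manifest.json")))) {
    stage_log("simulate", sim_cfg$n_recordings, " recordings -> ", corpus_dir)
    simulate_corpus(sim_cfg, dir = corpus_dir)
  }
  artifacts$corpus <- corpus_dir

  if ("preprocess" %in% stages && !(resume && file.exists(dataset_rds))) {
    stage_log("preprocess", "building window-pair sequences")
    manifest <- unlist(jsonlite::read_json(file.path(corpus_dir,
                                                     "manifest.json")))
    recs <- lapply(names(manifest), function(rid) {
      read_wfdb_record(file.path(corpus_dir, rid))
    })
    names(recs) <- names(manifest)
    anns <- lapply(names(manifest), function(rid) {
      read_annotations(file.path(corpus_dir, paste0(rid, "_events.csv")))
    })
    names(anns) <- names(manifest)
    dataset <- build_sequences(recs, anns, manifest)
    saveRDS(list(dataset = dataset, annotations = anns,
                 manifest = manifest), dataset_rds)
  }
  artifacts$dataset <- dataset_rds

  if ("train" %in% stages && !(resume && file.exists(fit_rds))) {
    stage_log("train", "patient-grouped split + fit")
    dd <- readRDS(dataset_rds)
    sp <- split_train_test(dd$manifest,
                           config$split$test_fraction %||% (245 / 1465),
                           seed = config$seed)
    fit <- apnea_scorer(dd$dataset[sp$train], config = mod_cfg,
                        control = ctl)
    saveRDS(list(fit = fit, split = sp), fit_rds)
    write.csv(fit$history, file.path(out_dir, "history.csv"),
              row.names = FALSE)
  }
  artifacts$model <- fit_rds

  if ("predict" %in% stages && !(resume && file.exists(scores_csv))) {
    stage_log("predict", "scoring test recordings")
    dd <- readRDS(dataset_rds)
    mm <- readRDS(fit_rds)
    test <- dd$dataset[mm$split$test]
    sc <- predict(mm$fit, test)
    tab <- do.call(rbind, lapply(names(sc), function(rid) {
      data.frame(record_id = rid, t = seq_along(sc[[rid]]) - 1L,
                 label = test[[rid]]$labels, score = sc[[rid]])
    }))
    write.csv(tab, scores_csv, row.names = FALSE)
  }
  artifacts$scores <- scores_csv

  if ("evaluate" %in% stages) {
    stage_log("evaluate", "metrics and AHI report")
    dd <- readRDS(dataset_rds)
    mm <- readRDS(fit_rds)
    test <- dd$dataset[mm$split$test]
    sc <- predict(mm$fit, test)
    rep <- performance_report(test, sc, dd$annotations[mm$split$test], thr)
    write.csv(rep$ahi, file.path(out_dir, "ahi_report.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(segment = lapply(rep$segment, as.list), agreement = rep$agreement),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    artifacts$report <- rep
  }
  invisible(artifacts)
}
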