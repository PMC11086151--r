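#' Pipeline configuration
#'
#' Bundles the per-module configurations, the output directory and a
#' single global seed covering cohort generation, split assignment and
#' model initialisation. A fingerprint of the configuration is recorded
#' with every artifact.
#'
#' @param out_dir Run directory; stages write artifacts beneath it.
#' @param seed Global integer seed.
#' @param n_es,n_pnes Synthetic cohort event counts.
#' @param generator A [generator_config()].
#' @param filter A [filter_spec()].
#' @param render A [render_config()].
#' @param prep A [prep_config()].
#' @param train A [train_config()].
#' @param train_montages Montage names rendered for training events
#'   (training diversity); validation and test events are always rendered
#'   in `ap_bipolar` only, matching clinical evaluation practice.
#' @param stride_s Epoch stride in seconds (default: non-overlapping).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, n_es = 10, n_pnes = 10,
                            generator = generator_config(seed = seed),
                            filter = filter_spec(),
                            render = render_config(),
                            prep = prep_config(seed = seed),
                            train = train_config(seed = seed,
                                                 max_epochs = 20),
                            train_montages = c("ap_bipolar",
                                               "average_referential",
                                               "transverse_bipolar",
                                               "phase1"),
                            stride_s = NULL) {
  cfg <- structure(
    list(out_dir = out_dir, seed = as.integer(seed),
         n_es = n_es, n_pnes = n_pnes,
         generator = generator, filter = filter, render = render,
         prep = prep, train = train, train_montages = train_montages,
         stride_s = stride_s %||% render$epoch_s),
    class = "pipeline_config")
  cfg
}

stage_dir <- function(cfg, stage) file.path(cfg$out_dir, stage)

require_stage <- function(cfg, stage, file) {
  path <- file.path(stage_dir(cfg, stage), file)
  if (!file.exists(path))
    stop("missing artifact '", file, "': run stage '", stage, "' first")
  path
}

write_stage_log <- function(cfg, stage, lines) {
  dir.create(stage_dir(cfg, stage), recursive = TRUE, showWarnings = FALSE)
  writeLines(c(sprintf("stage: %s", stage),
               sprintf("time: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
               sprintf("seed: %d", cfg$seed),
               sprintf("config_hash: %s", pipeline_hash(cfg)),
               lines),
             file.path(stage_dir(cfg, stage), paste0(stage, ".log")))
}

pipeline_hash <- function(cfg) {
  config_hash(lapply(unclass(cfg)[setdiff(names(cfg), "out_dir")], unclass))
}

#' Check for event-level split leakage
#'
#' Verifies that no event identifier appears in more than one of the
#' train/validation/test splits; a violation aborts, since within-event
#' segments are highly correlated and would inflate evaluation scores.
#'
#' @param manifest data.frame with columns `event_id`, `split`.
#' @return Invisibly `TRUE`; stops on violation.
#' @export
check_no_leakage <- function(manifest) {
  tab <- unique(manifest[manifest$split != "none", c("event_id", "split")])
  dup <- tab$event_id[duplicated(tab$event_id)]
  if (length(dup))
    stop("event-level leakage: event(s) span multiple splits: ",
         paste(unique(dup), collapse = ", "))
  invisible(TRUE)
}

#' Run one pipeline stage
#'
#' Stages, in order: `simulate` (synthetic cohort + event-level split
#' assignment), `render` (band-pass, montage derivation, epoch tiling,
#' plot-image rendering), `prepare` (segment split, ictal-content and EMG
#' filters, pad/resize/normalise), `train` (classifier with
#' lowest-validation-loss checkpoint; aborts on split leakage),
#' `evaluate` (test-set confusion matrix, diagnostic metrics with Wilson
#' intervals, ROC/AUC), `report` (human-readable summary). Each stage
#' writes a manifest and a log beneath `cfg$out_dir` and is idempotent
#' given an identical configuration and seed.
#'
#' @param stage One of `"simulate"`, `"render"`, `"prepare"`, `"train"`,
#'   `"evaluate"`, `"report"`.
#' @param cfg A [pipeline_config()].
#' @return Invisibly, the stage's primary artifact path.
#' @export
run_stage <- function(stage, cfg) {
  stage <- match.arg(stage, c("simulate", "render", "prepare", "train",
                              "evaluate", "report"))
  switch(stage,
         simulate = stage_simulate(cfg),
         render = stage_render(cfg),
         prepare = stage_prepare(cfg),
         train = stage_train(cfg),
         evaluate = stage_evaluate(cfg),
         report = stage_report(cfg))
}

#' @rdname run_stage
#' @export
run_pipeline <- function(cfg) {
  for (s in c("simulate", "render", "prepare", "train", "evaluate",
              "report"))
    run_stage(s, cfg)
  invisible(file.path(stage_dir(cfg, "evaluate"), "metrics.json"))
}

stage_simulate <- function(cfg) {
  dir.create(stage_dir(cfg, "simulate"), recursive = TRUE,
             showWarnings = FALSE)
  cohort <- generate_cohort(cfg$generator, cfg$n_es, cfg$n_pnes)
  manifest <- cohort_manifest(cohort)
  splits <- assign_splits(manifest$event_id, cfg$prep$split_ratios,
                          seed = cfg$seed)
  manifest <- merge(manifest, splits, by = "event_id", sort = TRUE)
  saveRDS(cohort, file.path(stage_dir(cfg, "simulate"), "cohort.rds"))
  path <- file.path(stage_dir(cfg, "simulate"), "cohort_manifest.csv")
  utils::write.csv(manifest[order(manifest$event_id), ], path,
                   row.names = FALSE)
  write_stage_log(cfg, "simulate",
                  sprintf("events: %d ES, %d PNES", cfg$n_es, cfg$n_pnes))
  invisible(path)
}

stage_render <- function(cfg) {
  cohort <- readRDS(require_stage(cfg, "simulate", "cohort.rds"))
  manifest <- utils::read.csv(require_stage(cfg, "simulate",
                                            "cohort_manifest.csv"))
  img_dir <- file.path(stage_dir(cfg, "render"), "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  montages <- builtin_montages()
  rows <- list()
  for (ev in cohort) {
    rec <- apply_bandpass(ev$recording, cfg$filter)
    split <- manifest$split[manifest$event_id == rec$event_id]
    mnames <- if (identical(split, "train")) cfg$train_montages
              else "ap_bipolar"
    windows <- extract_epochs(recording_duration(rec), cfg$render$epoch_s,
                              cfg$stride_s)
    for (mn in mnames) {
      drec <- derive_montage(rec, montages[[mn]])
      for (k in seq_len(nrow(windows))) {
        img <- render_epoch(drec, windows[k, ], cfg$render)
        fname <- sprintf("%s_%s_%06.1f.png", rec$event_id, mn,
                         windows$start_s[k])
        write_plot_image(img, file.path(img_dir, fname))
        rows[[length(rows) + 1L]] <- data.frame(
          event_id = rec$event_id, subject_id = rec$subject_id,
          event_type = ev$annotation$event_type, split = split,
          montage = mn, start_s = windows$start_s[k],
          end_s = windows$end_s[k], path = file.path("images", fname),
          stringsAsFactors = FALSE)
      }
    }
  }
  rmanifest <- do.call(rbind, rows)
  path <- file.path(stage_dir(cfg, "render"), "render_manifest.csv")
  utils::write.csv(rmanifest, path, row.names = FALSE)
  write_stage_log(cfg, "render",
                  sprintf("images rendered: %d", nrow(rmanifest)))
  invisible(path)
}

stage_prepare <- function(cfg) {
  cohort <- readRDS(require_stage(cfg, "simulate", "cohort.rds"))
  rmanifest <- utils::read.csv(require_stage(cfg, "render",
                                             "render_manifest.csv"))
  anns <- stats::setNames(lapply(cohort, `[[`, "annotation"),
                          vapply(cohort, function(e) e$recording$event_id,
                                 character(1)))
  tensors <- list()
  records <- list()
  for (i in seq_len(nrow(rmanifest))) {
    row <- rmanifest[i, ]
    img <- read_plot_image(file.path(stage_dir(cfg, "render"), row$path))
    segs <- prepare_segments(img, anns[[row$event_id]], row$event_type,
                             cfg$prep)
    for (seg in segs) {
      rec <- seg$record
      rec$split <- row$split
      rec$segment_id <- sprintf("%s_%s_%06.1f_%s", row$event_id,
                                row$montage, row$start_s, rec$half)
      records[[length(records) + 1L]] <- rec
      if (rec$status == "kept") tensors[[rec$segment_id]] <- seg$tensor
    }
  }
  smanifest <- do.call(rbind, records)
  dir.create(stage_dir(cfg, "prepare"), recursive = TRUE,
             showWarnings = FALSE)
  saveRDS(tensors, file.path(stage_dir(cfg, "prepare"), "tensors.rds"))
  path <- file.path(stage_dir(cfg, "prepare"), "segment_manifest.csv")
  utils::write.csv(smanifest, path, row.names = FALSE)
  write_stage_log(cfg, "prepare", c(
    sprintf("segments: %d total, %d kept", nrow(smanifest),
            sum(smanifest$status == "kept")),
    sprintf("dropped_ictal_rule: %d",
            sum(smanifest$status == "dropped_ictal_rule")),
    sprintf("dropped_emg: %d", sum(smanifest$status == "dropped_emg"))))
  invisible(path)
}

prepared_dataset <- function(cfg, split, montage = NULL) {
  smanifest <- utils::read.csv(require_stage(cfg, "prepare",
                                             "segment_manifest.csv"))
  tensors <- readRDS(require_stage(cfg, "prepare", "tensors.rds"))
  keep <- smanifest$status == "kept" & smanifest$split == split
  if (!is.null(montage)) keep <- keep & smanifest$montage %in% montage
  rows <- smanifest[keep, ]
  list(images = tensors[rows$segment_id], labels = rows$label,
       event_id = rows$event_id, manifest = rows)
}

stage_train <- function(cfg) {
  smanifest <- utils::read.csv(require_stage(cfg, "prepare",
                                             "segment_manifest.csv"))
  check_no_leakage(smanifest)
  train_set <- prepared_dataset(cfg, "train")
  val_set <- prepared_dataset(cfg, "validation", montage = "ap_bipolar")
  model <- build_model(cfg$train)
  fit <- train_classifier(model, train_set$images, train_set$labels,
                          val_set$images, val_set$labels, cfg$train)
  dir.create(stage_dir(cfg, "train"), recursive = TRUE,
             showWarnings = FALSE)
  saveRDS(fit, file.path(stage_dir(cfg, "train"), "model.rds"))
  path <- file.path(stage_dir(cfg, "train"), "training_log.csv")
  utils::write.csv(fit$history, path, row.names = FALSE)
  write_stage_log(cfg, "train", c(
    sprintf("train images: %d, validation images: %d",
            length(train_set$images), length(val_set$images)),
    sprintf("best epoch: %d (val loss %.4f)", fit$best_epoch,
            fit$best_val_loss)))
  invisible(path)
}

stage_evaluate <- function(cfg) {
  fit <- readRDS(require_stage(cfg, "train", "model.rds"))
  test_set <- prepared_dataset(cfg, "test", montage = "ap_bipolar")
  if (length(test_set$images) == 0L) stop("no kept test segments")
  scores <- predict_scores(fit, test_set$images)
  pred <- classify_scores(scores)
  cm <- confusion(test_set$labels, pred)
  met <- seizure_metrics(cm)
  roc <- if (length(unique(test_set$labels)) == 2L)
    roc_auc(scores$p_es, test_set$labels) else NULL
  dir.create(stage_dir(cfg, "evaluate"), recursive = TRUE,
             showWarnings = FALSE)
  utils::write.csv(data.frame(tp = cm$tp, fp = cm$fp, fn = cm$fn,
                              tn = cm$tn),
                   file.path(stage_dir(cfg, "evaluate"), "confusion.csv"),
                   row.names = FALSE)
  if (!is.null(roc))
    utils::write.csv(roc$curve,
                     file.path(stage_dir(cfg, "evaluate"), "roc.csv"),
                     row.names = FALSE)
  metrics <- list(
    n_test_images = length(test_set$images),
    confusion = list(tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn),
    metrics = lapply(split(met, met$metric), function(r)
      list(estimate = r$estimate, lo = r$lo, hi = r$hi)),
    auc = if (!is.null(roc)) roc$auc else NA,
    seed = cfg$seed, config_hash = pipeline_hash(cfg))
  path <- file.path(stage_dir(cfg, "evaluate"), "metrics.json")
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  write_stage_log(cfg, "evaluate", c(
    sprintf("test images: %d", length(test_set$images)),
    sprintf("accuracy: %.3f", met["accuracy", "estimate"])))
  invisible(path)
}

stage_report <- function(cfg) {
  metrics <- jsonlite::read_json(require_stage(cfg, "evaluate",
                                               "metrics.json"),
                                 simplifyVector = TRUE)
  cm <- confusion_matrix(metrics$confusion$tp, metrics$confusion$fp,
                         metrics$confusion$fn, metrics$confusion$tn)
  met <- seizure_metrics(cm)
  lines <- c("Seizure classification report (synthetic cohort)",
             sprintf("seed: %d  config: %s", metrics$seed,
                     metrics$config_hash),
             sprintf("test images: %d", metrics$n_test_images),
             sprintf("confusion: tp=%d fp=%d fn=%d tn=%d", cm$tp, cm$fp,
                     cm$fn, cm$tn),
             utils::capture.output(print(met)),
             sprintf("AUC: %s",
                     ifelse(is.na(metrics$auc), "n/a",
                            sprintf("%.3f", as.numeric(metrics$auc)))))
  dir.create(stage_dir(cfg, "report"), recursive = TRUE,
             showWarnings = FALSE)
  path <- file.path(stage_dir(cfg, "report"), "report.txt")
  writeLines(lines, path)
  write_stage_log(cfg, "report", "report written")
  invisible(path)
}
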