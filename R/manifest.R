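#' Cohort manifests and experiment orchestration
#'
#' The manifest CSV is the package's exchange format: one row per scan
#' with columns subject_id, timepoint, path, days_since_baseline, event,
#' time_days, cause, site, split. Splits are by subject (cv1..cv5,
#' internal_test, external_test) and a subject appears in exactly one
#' split, so no scan ever crosses a train/validation boundary.
#'
#' @name cli-io
NULL

manifest_columns <- c("subject_id", "timepoint", "path",
                      "days_since_baseline", "event", "time_days",
                      "cause", "site", "split")
valid_splits <- c(paste0("cv", 1:5), "internal_test", "external_test")

#' Load and validate a cohort manifest
#'
#' @param path CSV file with the columns listed above.
#' @return validated data.frame of class `cohort_manifest`.
#' @export
load_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(manifest_columns, names(m))
  if (length(miss))
    stop_invalid("manifest lacks column(s): ", paste(miss, collapse = ", "))
  bad_split <- setdiff(unique(m$split), valid_splits)
  if (length(bad_split))
    stop_invalid("invalid split value(s): ", paste(bad_split, collapse = ", "))
  for (id in unique(m$subject_id)) {
    rows <- m[m$subject_id == id, ]
    if (length(unique(rows$split)) != 1)
      stop_invalid("subject ", id, " appears in multiple splits: ",
                   paste(unique(rows$split), collapse = ", "))
    if (any(diff(rows$days_since_baseline[order(rows$timepoint)]) <= 0))
      stop_invalid("subject ", id, " has non-increasing timepoints")
  }
  structure(m, class = c("cohort_manifest", "data.frame"))
}

#' Export a synthetic cohort as NIfTI volumes plus a manifest CSV
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @param gzip write `.nii.gz` instead of `.nii`.
#' @return path of the written manifest CSV.
#' @export
export_cohort <- function(cohort, dir, gzip = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  ext <- if (gzip) ".nii.gz" else ".nii"
  for (i in seq_len(nrow(cohort$subjects))) {
    s <- cohort$subjects[i, ]
    rend <- render_subject(cohort, i)
    days <- cohort$schedule[[i]]
    for (k in seq_along(rend$scans)) {
      fn <- file.path(dir, paste0(s$subject_id, "_T", k - 1, ext))
      write_nifti(rend$scans[[k]], fn)
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = s$subject_id, timepoint = paste0("T", k - 1),
        path = fn, days_since_baseline = days[k], event = s$event,
        time_days = s$time_days, cause = s$cause, site = s$site,
        split = s$split, stringsAsFactors = FALSE)
    }
  }
  man <- do.call(rbind, rows)
  out <- file.path(dir, "manifest.csv")
  write.csv(man, out, row.names = FALSE)
  out
}

#' Load and preprocess the scan series of each manifest subject
#'
#' @param manifest a `cohort_manifest`.
#' @param config a [preprocess_config()].
#' @return named list (by subject id) of `longitudinal_series`.
#' @export
manifest_series <- function(manifest, config = preprocess_config()) {
  ids <- unique(manifest$subject_id)
  out <- setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    rows <- manifest[manifest$subject_id == id, ]
    rows <- rows[order(rows$days_since_baseline), ]
    scans <- lapply(seq_len(nrow(rows)), function(k)
      read_nifti(rows$path[k], acquisition_day = rows$days_since_baseline[k]))
    out[[id]] <- preprocess_series(scans, config)
  }
  out
}

#' Run configuration for an experiment
#'
#' @param objective `"cross_entropy"` or `"cox"`.
#' @param cell_kind recurrent cell for the CRNN stage.
#' @param hx recurrent hidden size.
#' @param preset backbone preset.
#' @param cnn,crnn [optimiser_config()]s for the two phases.
#' @param folds number of CV folds to run (<= 5).
#' @param seed master seed.
#' @param ... stored as-is.
#' @export
run_config <- function(objective = "cross_entropy", cell_kind = "lstm",
                       hx = 16, preset = "tiny",
                       cnn = optimiser_config(lr = 0.01, epochs = 8,
                                              batch_size = 12),
                       crnn = optimiser_config(lr = 0.01, epochs = 20,
                                               batch_size = 12),
                       folds = 5, seed = 1, ...) {
  c(list(objective = objective, cell_kind = cell_kind, hx = hx,
         preset = preset, cnn = cnn, crnn = crnn, folds = folds,
         seed = seed), list(...))
}

eval_metrics <- function(objective, preds, records, labels,
                         train_records = NULL) {
  if (objective == "cross_entropy") {
    p <- vapply(preds, `[[`, numeric(1), "p_event")
    cls <- as.integer(p > 0.5)
    cm <- f1_mcc(sum(cls == 1 & labels == 1), sum(cls == 1 & labels == 0),
                 sum(cls == 0 & labels == 0), sum(cls == 0 & labels == 1))
    c(auc = roc_auc(p, labels), f1 = cm$f1, mcc = as.numeric(cm$mcc))
  } else {
    s <- vapply(preds, `[[`, numeric(1), "score")
    c(ipcw_cindex = as.numeric(
        ipcw_cindex(train_records %||% records, records, s, tau = Inf)),
      harrell = harrell_cindex(records, s))
  }
}

#' Run the staged cross-validated experiment
#'
#' For each fold: train the CNN on the latest scans of the other folds,
#' freeze the backbone, train the recurrent head on the full series, and
#' evaluate on the held-out fold; then evaluate each fold model on the
#' internal and external test splits. Reports per-cohort "mean (sd)"
#' across folds, mirroring a 5-fold cross-validation table.
#'
#' @param series named list of `longitudinal_series` per subject.
#' @param subjects data.frame with subject_id, event, time_days, cause,
#'   split (one row per subject, e.g. `cohort$subjects`).
#' @param config a [run_config()].
#' @return list: `fold_metrics`, `report` (list of [cv_report()] outputs
#'   keyed internal_cv / internal_test / external_test), `models`.
#' @export
run_experiment <- function(series, subjects, config = run_config()) {
  subjects <- subjects[match(names(series), subjects$subject_id), ]
  records <- survival_records(subjects$time_days, subjects$event,
                              subjects$cause)
  labels <- subjects$event
  feats_env <- new.env()

  latest_vol <- function(i) {
    v <- series[[i]]$volumes
    v[[length(v)]]
  }
  folds <- seq_len(config$folds)
  cvsplit <- subjects$split
  fold_of <- match(cvsplit, paste0("cv", 1:5))
  test_idx <- which(cvsplit == "internal_test")
  ext_idx <- which(cvsplit == "external_test")

  fold_rows <- list(test_rows = list(), ext_rows = list())
  cv_rows <- list(); test_rows <- list(); ext_rows <- list()
  models <- list()
  for (k in folds) {
    tr <- which(!is.na(fold_of) & fold_of != k)
    va <- which(fold_of == k)
    bb <- build_backbone(backbone_config(config$preset),
                         seed = config$seed + k)
    cnn <- cnn_model(bb, head = if (config$objective == "cox") "cox"
                     else "classification", seed = config$seed + k)
    cfg_cnn <- config$cnn; cfg_cnn$seed <- config$seed + 100 + k
    fit <- train_cnn(cnn, lapply(tr, latest_vol),
                     labels = labels[tr], records = records[tr, ],
                     objective = config$objective, config = cfg_cnn)
    cnn <- fit$model
    feats <- lapply(seq_along(series), function(i)
      series_features(cnn$backbone, series[[i]]))
    gaps <- lapply(series, `[[`, "gaps")
    crnn <- crnn_model(cnn$backbone, cell_kind = config$cell_kind,
                       hx = config$hx,
                       head = if (config$objective == "cox") "cox"
                       else "classification", seed = config$seed + k)
    cfg_crnn <- config$crnn; cfg_crnn$seed <- config$seed + 200 + k
    fitr <- train_crnn(crnn, feats[tr], gaps[tr], labels = labels[tr],
                       records = records[tr, ],
                       objective = config$objective, config = cfg_crnn)
    crnn <- fitr$model
    predict_set <- function(idx) lapply(idx, function(i)
      crnn_predict(crnn, list(features = feats[[i]], gaps = gaps[[i]])))
    cv_rows[[k]] <- eval_metrics(config$objective, predict_set(va),
                                 records[va, ], labels[va], records[tr, ])
    test_rows[[k]] <- eval_metrics(config$objective, predict_set(test_idx),
                                   records[test_idx, ], labels[test_idx],
                                   records[tr, ])
    ext_rows[[k]] <- eval_metrics(config$objective, predict_set(ext_idx),
                                  records[ext_idx, ], labels[ext_idx],
                                  records[tr, ])
    models[[k]] <- list(cnn = cnn, crnn = crnn)
  }
  list(fold_metrics = list(internal_cv = cv_rows,
                           internal_test = test_rows,
                           external_test = ext_rows),
       report = list(internal_cv = cv_report(cv_rows),
                     internal_test = cv_report(test_rows),
                     external_test = cv_report(ext_rows)),
       models = models)
}
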