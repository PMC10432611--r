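#' Desk-scale reference experiments
#'
#' End-to-end signal-recovery experiments on synthetic phantom cohorts,
#' sized for a single CPU: generate a cohort, run the preprocessing
#' pipeline, train the CNN on the latest scans, freeze the backbone,
#' train recurrent heads on the per-scan feature sequences (a 5-member
#' seed ensemble, mirroring the treatment of cross-validation models as
#' an ensemble), and evaluate on held-out subjects. Used by the test
#' suite and the acceptance report; also a worked example of the full
#' API.
#'
#' @name experiments
NULL

#' Desk-scale training defaults
#'
#' The CNN phase uses plain SGD with momentum (no SAM) purely for CPU
#' budget; the recurrent phase keeps SAM on. Learning rates are hotter
#' than the full-scale defaults because the tiny preset trains from
#' scratch in tens of epochs.
#'
#' @param seed master seed.
#' @export
desk_protocol <- function(seed = 1) {
  list(cnn = optimiser_config(lr = 0.05, epochs = 40, rho = 0,
                              batch_size = 12, patience = 8,
                              seed = seed + 100),
       crnn = optimiser_config(lr = 0.01, epochs = 250, rho = 0.05,
                               batch_size = 12, seed = seed + 200),
       n_members = 5,
       cnn_restarts = 1)
}

#' Standardise per-scan features with training-set statistics
#'
#' @param features list of per-subject feature matrices.
#' @param train_idx indices whose rows define the statistics.
#' @return list with standardised `features`, `center`, `scale`.
#' @export
standardize_features <- function(features, train_idx) {
  fm <- do.call(rbind, features[train_idx])
  mu <- colMeans(fm)
  sdv <- apply(fm, 2, sd)
  sdv[sdv == 0] <- 1
  list(features = lapply(features, function(f)
         sweep(sweep(f, 2, mu), 2, sdv, "/")),
       center = mu, scale = sdv)
}

#' Run the desk-scale end-to-end experiment on a phantom cohort
#'
#' @param seed cohort and training seed.
#' @param n cohort size.
#' @param shape phantom grid.
#' @param risk_covariate `"last"` (risk encoded in the latest scan's
#'   lesion burden) or `"slope"` (risk encoded in the burden growth rate,
#'   with the last-scan burden distribution identical across classes).
#' @param objectives character subset of `c("classification", "cox")`.
#' @param backbone optional pre-trained `backbone` used as the frozen
#'   feature extractor for *both* arms instead of training a CNN on this
#'   cohort. Used by the slope experiment: sharing one burden-sensitive
#'   extractor across the single-scan and temporal arms isolates exactly
#'   the architectural contrast (and avoids representation collapse when
#'   a cohort's labels are uninformative for single scans). The
#'   single-scan arm then gets a logistic head fitted to convergence on
#'   its training features.
#' @param verbose print stage progress.
#' @return list with held-out metrics (`auc_cnn`, `auc_crnn` ensemble,
#'   internal-test variants, `cindex` for cox), predictions, records and
#'   split indices.
#' @export
desk_experiment <- function(seed = 1, n = 120, shape = c(32, 32, 16),
                            risk_covariate = "last",
                            objectives = c("classification", "cox"),
                            backbone = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  proto <- desk_protocol(seed)
  cohort <- generate_cohort(n, shape = shape,
                            risk_covariate = risk_covariate, seed = seed)
  pc <- preprocess_config(target_shape = shape)
  say("preprocessing ", n, " subjects")
  series <- suppressWarnings(lapply(seq_len(n), function(i)
    preprocess_series(render_subject(cohort, i)$scans, pc)))
  s <- cohort$subjects
  trn <- grep("^cv", s$split)
  tst_int <- which(s$split == "internal_test")
  tst_all <- which(!grepl("^cv", s$split))
  latest <- lapply(series, function(x) x$volumes[[length(x$volumes)]])
  records <- cohort_records(cohort)

  if (is.null(backbone)) {
    # one seeded CNN run by default (cnn_restarts = 1), early-stopped at
    # the best validation checkpoint; with cnn_restarts > 1 the restarts
    # are prediction-ensembled and each contributes recurrent members
    say("training CNN (early stopping on a validation split)")
    set.seed(seed + 50)
    vi <- sample(seq_along(trn), max(8, round(length(trn) * 0.2)))
    cnns <- vector("list", proto$cnn_restarts)
    for (r in seq_len(proto$cnn_restarts)) {
      bb <- build_backbone(backbone_config("tiny"),
                           seed = seed + 1000 * (r - 1))
      cand <- cnn_model(bb, "classification", seed = seed + 1000 * (r - 1))
      cfg <- proto$cnn; cfg$seed <- cfg$seed + r - 1
      fit <- train_cnn(cand, latest[trn[-vi]], labels = s$event[trn[-vi]],
                       objective = "cross_entropy", config = cfg,
                       val = list(volumes = latest[trn[vi]],
                                  labels = s$event[trn[vi]]))
      cnns[[r]] <- fit$model
    }
    cnn <- cnns[[1]]
    p_cnn <- rowMeans(vapply(cnns, function(m) vapply(seq_len(n),
      function(i) cnn_predict(m, latest[[i]])$p_event, numeric(1)),
      numeric(n)))
    backbones <- lapply(cnns, `[[`, "backbone")
  } else {
    say("reusing supplied backbone(s); fitting logistic single-scan head")
    backbones <- if (inherits(backbone, "backbone")) list(backbone)
                 else backbone
    cnns <- NULL; cnn <- NULL
  }
  # per-backbone standardised feature sets
  feat_sets <- lapply(backbones, function(bb) {
    feats <- lapply(series, function(x) series_features(bb, x))
    standardize_features(feats, trn)$features
  })
  featsS <- feat_sets[[1]]
  gaps <- lapply(series, `[[`, "gaps")
  if (!is.null(backbone)) {
    # single-scan arm on frozen features: logistic head per backbone,
    # prediction averaged across backbones
    p_cnn <- rowMeans(vapply(feat_sets, function(fs) {
      flast <- t(vapply(fs, function(f) f[nrow(f), ],
                        numeric(ncol(fs[[1]]))))
      df <- data.frame(y = s$event[trn], flast[trn, , drop = FALSE])
      glmfit <- suppressWarnings(
        stats::glm(y ~ ., data = df, family = stats::binomial()))
      suppressWarnings(as.numeric(stats::predict(
        glmfit, newdata = data.frame(flast), type = "response")))
    }, numeric(n)))
  }

  out <- list(cohort = cohort, split = list(train = trn,
                internal_test = tst_int, test = tst_all),
              records = records, p_cnn = p_cnn,
              auc_cnn = roc_auc(p_cnn[tst_all], s$event[tst_all]),
              auc_cnn_internal = roc_auc(p_cnn[tst_int], s$event[tst_int]))

  # recurrent members are trained per backbone and pooled into one
  # ensemble (n_members per backbone, mirroring the ensemble treatment
  # of cross-validation models)
  train_pool <- function(head, base_seed) {
    preds <- matrix(0, n, 0)
    for (bi in seq_along(feat_sets)) {
      fs <- feat_sets[[bi]]
      for (k in seq_len(proto$n_members)) {
        cr <- crnn_model(backbones[[bi]], "lstm", hx = 16, head = head,
                         seed = seed + 10 * bi + k)
        cfg <- proto$crnn; cfg$seed <- base_seed + 10 * bi + k
        m <- if (head == "cox") {
          train_crnn(cr, fs[trn], gaps[trn], records = records[trn, ],
                     objective = "cox", config = cfg)$model
        } else {
          train_crnn(cr, fs[trn], gaps[trn], labels = s$event[trn],
                     objective = "cross_entropy", config = cfg)$model
        }
        p <- vapply(seq_len(n), function(i) {
          pr <- crnn_predict(m, list(features = fs[[i]], gaps = gaps[[i]]))
          if (head == "cox") pr$score else pr$p_event
        }, numeric(1))
        preds <- cbind(preds, p)
      }
    }
    rowMeans(preds)
  }

  if ("classification" %in% objectives) {
    say("training CRNN ensemble (classification)")
    p_crnn <- train_pool("classification", seed + 300)
    out$p_crnn <- p_crnn
    out$auc_crnn <- roc_auc(p_crnn[tst_all], s$event[tst_all])
    out$auc_crnn_internal <- roc_auc(p_crnn[tst_int], s$event[tst_int])
    out$km <- km_stratify(records[tst_all, ], p_crnn[tst_all])
  }

  if ("cox" %in% objectives) {
    say("training CRNN ensemble (cox)")
    sc <- train_pool("cox", seed + 400)
    out$cox_scores <- sc
    out$harrell <- harrell_cindex(records[tst_all, ], sc[tst_all])
    out$ipcw <- as.numeric(ipcw_cindex(records[trn, ], records[tst_all, ],
                                       sc[tst_all], tau = Inf))
  }
  out$cnn_model <- cnn
  out$backbones <- backbones
  out
}
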