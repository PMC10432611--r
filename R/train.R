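#' Training protocol
#'
#' Two-phase protocol: the CNN (backbone + head) is trained on each
#' subject's latest scan; the backbone is then frozen and the recurrent
#' side is trained on the per-scan feature sequences. Classification uses
#' cross-entropy with an inverse-class-size weighted sampler; the Cox
#' objective uses the batch-level negative partial log-likelihood
#' (degenerate all-censored batches are resampled). Optimisation is
#' SAM-wrapped SGD with momentum, decoupled L2 weight decay and a
#' triangular cyclic learning-rate schedule. All randomness flows from
#' the config seed, so runs are bit-reproducible single-threaded.
#'
#' @name training
NULL

#' Optimiser configuration
#'
#' Defaults follow the published protocol (initial learning rate 1e-3,
#' momentum 0.9, weight decay 5e-4, cyclic schedule, batch size 24);
#' desk-scale runs typically raise the learning rate and shrink the
#' epoch count.
#'
#' @param lr peak learning rate.
#' @param momentum SGD momentum.
#' @param weight_decay L2 coefficient.
#' @param rho SAM neighbourhood radius (0 disables SAM).
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param cycle cyclic learning-rate period in epochs.
#' @param patience early-stopping patience on the validation loss
#'   (`Inf` = never stop early).
#' @param seed integer seed; logged and applied at the start of training.
#' @export
optimiser_config <- function(lr = 1e-3, momentum = 0.9, weight_decay = 5e-4,
                             rho = 0.05, batch_size = 24, epochs = 10,
                             cycle = 10, patience = Inf, seed = 1) {
  if (lr <= 0 || batch_size < 1 || epochs < 1)
    stop_config("rates and sizes must be positive")
  list(lr = lr, momentum = momentum, weight_decay = weight_decay,
       rho = rho, batch_size = batch_size, epochs = epochs, cycle = cycle,
       patience = patience, seed = seed)
}

cnn_get_params <- function(model) {
  p <- list(head_W = model$head_W, head_b = model$head_b)
  for (k in names(model$backbone$params))
    p[[paste0("bb.", k)]] <- model$backbone$params[[k]]
  p
}

cnn_set_params <- function(model, p) {
  model$head_W <- p$head_W; model$head_b <- p$head_b
  for (k in names(model$backbone$params))
    model$backbone$params[[k]] <- p[[paste0("bb.", k)]]
  model
}

ce_dz <- function(z, label) {
  e <- exp(z - max(z)); pr <- e / sum(e)
  dz <- pr; dz[label + 1] <- dz[label + 1] - 1
  attr(dz, "loss") <- -log(max(pr[label + 1], 1e-12))
  dz
}

# one minibatch forward + backward through backbone and head; the loss
# head is cross-entropy (labels given) or the batch Cox partial
# likelihood (records given)
cnn_batch_grad <- function(model, vols, labels = NULL, records = NULL,
                           update_env = NULL) {
  fw <- backbone_forward_batch(model$backbone, vols, train = TRUE,
                               update_env = update_env)
  f <- fw$features
  B <- nrow(f)
  z <- f %*% model$head_W + rep(model$head_b, each = B)
  if (!is.null(labels)) {
    dz <- matrix(0, B, ncol(z)); loss <- 0
    for (i in seq_len(B)) {
      di <- ce_dz(z[i, ], labels[i])
      dz[i, ] <- di / B
      loss <- loss + attr(di, "loss") / B
    }
  } else {
    cl <- cox_partial_loss(drop(z), records, gradient = TRUE)
    dz <- matrix(cl$grad, ncol = 1)
    loss <- cl$loss
  }
  g <- list(head_W = crossprod(f, dz), head_b = colSums(dz))
  dfeats <- dz %*% t(model$head_W)
  bb <- backbone_backward_batch(model$backbone, fw$cache, dfeats)$grads
  for (k in names(bb)) g[[paste0("bb.", k)]] <- bb[[k]]
  attr(g, "loss") <- loss
  g
}

add_grads <- function(acc, g, w = 1) {
  if (is.null(acc)) return(lapply(g, function(x) x * w))
  for (k in names(g)) acc[[k]] <- acc[[k]] + g[[k]] * w
  acc
}

#' Train a CNN model (backbone + head) on single scans
#'
#' @param model a `cnn_model`.
#' @param volumes list of `thorax_volume` (each subject's latest scan).
#' @param labels integer 0/1 (or 0..K-1) class labels, classification
#'   objective only.
#' @param records `survival_records`, cox objective only.
#' @param objective `"cross_entropy"` or `"cox"`.
#' @param config an [optimiser_config()].
#' @param val optional list(volumes, labels/records) used for the
#'   early-stopping criterion.
#' @param verbose print per-epoch loss.
#' @return list `model` (trained), `log` (data.frame epoch/loss/lr, plus
#'   val_loss when a validation set is given).
#' @export
train_cnn <- function(model, volumes, labels = NULL, records = NULL,
                      objective = c("cross_entropy", "cox"),
                      config = optimiser_config(), val = NULL,
                      verbose = FALSE) {
  objective <- match.arg(objective)
  n <- length(volumes)
  set.seed(config$seed)
  params <- cnn_get_params(model)
  state <- NULL
  bnenv <- new.env()
  bnenv$bn <- model$backbone$bn
  log <- list()
  best <- list(loss = Inf, params = params, bn = bnenv$bn, epoch = 0)
  bad <- 0
  sample_probs <- if (objective == "cross_entropy")
    weighted_sampler_probs(labels) else NULL

  for (epoch in seq_len(config$epochs)) {
    lr <- cyclic_lr(epoch, config$lr, config$cycle)
    idx_epoch <- if (objective == "cross_entropy") {
      sample.int(n, n, replace = TRUE, prob = sample_probs)
    } else sample.int(n)
    nb <- max(1, floor(n / config$batch_size))
    ep_loss <- 0
    for (b in seq_len(nb)) {
      batch <- idx_epoch[((b - 1) * config$batch_size + 1):
                         min(b * config$batch_size, n)]
      if (objective == "cox") {
        tries <- 0
        while (sum(records$event[batch]) == 0 && tries < 50) {
          batch <- sample.int(n, length(batch))
          tries <- tries + 1
        }
        if (sum(records$event[batch]) == 0) next
      }
      batch_seed <- sample.int(.Machine$integer.max, 1)
      grad_fn <- function(p, update_bn = FALSE) {
        m <- cnn_set_params(model, p)
        m$backbone$bn <- bnenv$bn
        set.seed(batch_seed)  # same dropout masks for both SAM passes
        cnn_batch_grad(m, volumes[batch],
                       labels = if (objective == "cross_entropy")
                         labels[batch] else NULL,
                       records = if (objective == "cox")
                         records[batch, ] else NULL,
                       update_env = if (update_bn) bnenv else NULL)
      }
      g1 <- grad_fn(params, update_bn = TRUE)
      ep_loss <- ep_loss + attr(g1, "loss") / nb
      st <- sam_step_pre(params, g1, grad_fn, lr, config)
      upd <- sam_apply(params, st$g, lr, config, state)
      params <- upd$params; state <- upd$state
    }
    vloss <- NA_real_
    if (!is.null(val)) {
      m <- cnn_set_params(model, params)
      m$backbone$bn <- bnenv$bn
      vloss <- eval_cnn_loss(m, val, objective)
      if (vloss < best$loss - 1e-6) {
        best <- list(loss = vloss, params = params, bn = bnenv$bn,
                     epoch = epoch)
        bad <- 0
      } else bad <- bad + 1
    }
    log[[epoch]] <- data.frame(epoch = epoch, loss = ep_loss, lr = lr,
                               val_loss = vloss)
    if (verbose) message(sprintf("epoch %d loss %.4f val %.4f",
                                 epoch, ep_loss, vloss))
    if (!is.null(val) && bad >= config$patience) break
  }
  bn_final <- bnenv$bn
  if (!is.null(val) && is.finite(best$loss)) {
    params <- best$params
    bn_final <- best$bn
  }
  model <- cnn_set_params(model, params)
  model$backbone$bn <- bn_final
  list(model = model, log = do.call(rbind, log))
}

# SAM split into the perturbation (reusing the already-computed gradient)
# and the base update, so the first gradient is not computed twice.
sam_step_pre <- function(params, g1, grad_fn, lr, config) {
  gn <- sqrt(sum(vapply(names(params),
                        function(k) sum(g1[[k]]^2), numeric(1))))
  if (config$rho > 0 && gn > 0) {
    pert <- params
    for (k in names(params))
      pert[[k]] <- params[[k]] + config$rho * g1[[k]] / gn
    list(g = grad_fn(pert))
  } else list(g = g1)
}

sam_apply <- function(params, g, lr, config, state) {
  if (is.null(state)) state <- lapply(params, function(x) x * 0)
  # global gradient-norm clipping stabilises the norm-free backbone
  clip <- config$clip %||% 5
  gn <- sqrt(sum(vapply(names(params),
                        function(k) sum(g[[k]]^2), numeric(1))))
  sc <- if (gn > clip) clip / gn else 1
  for (k in names(params)) {
    gk <- g[[k]] * sc + config$weight_decay * params[[k]]
    state[[k]] <- config$momentum * state[[k]] + gk
    params[[k]] <- params[[k]] - lr * state[[k]]
  }
  list(params = params, state = state)
}

eval_cnn_loss <- function(model, val, objective) {
  if (objective == "cross_entropy") {
    tot <- 0
    for (i in seq_along(val$volumes)) {
      pr <- cnn_predict(model, val$volumes[[i]])$prob
      tot <- tot - log(max(pr[val$labels[i] + 1], 1e-12))
    }
    tot / length(val$volumes)
  } else {
    zs <- vapply(val$volumes, function(v) cnn_predict(model, v)$score,
                 numeric(1))
    cox_partial_loss(zs, val$records)
  }
}

#' Train the recurrent side of a CRNN on frozen-backbone features
#'
#' The backbone inside `model` is untouched (asserted by the test suite
#' to be bit-identical after training); only the cell, FC layer and head
#' are optimised.
#'
#' @param model a `crnn_model`.
#' @param features list of per-subject feature matrices (rows = scans),
#'   e.g. from [series_features()].
#' @param gaps list of per-subject gap data.frames ([encode_gaps()]).
#' @param labels,records,objective,config,val,verbose as in [train_cnn()];
#'   `val` is `list(features, gaps, labels/records)`.
#' @return list `model`, `log`.
#' @export
train_crnn <- function(model, features, gaps, labels = NULL, records = NULL,
                       objective = c("cross_entropy", "cox"),
                       config = optimiser_config(), val = NULL,
                       verbose = FALSE) {
  objective <- match.arg(objective)
  n <- length(features)
  set.seed(config$seed)
  params <- crnn_get_params(model)
  state <- NULL
  log <- list()
  best <- list(loss = Inf, params = params); bad <- 0
  sample_probs <- if (objective == "cross_entropy")
    weighted_sampler_probs(labels) else NULL

  for (epoch in seq_len(config$epochs)) {
    lr <- cyclic_lr(epoch, config$lr, config$cycle)
    idx_epoch <- if (objective == "cross_entropy")
      sample.int(n, n, replace = TRUE, prob = sample_probs)
    else sample.int(n)
    nb <- max(1, floor(n / config$batch_size))
    ep_loss <- 0
    for (b in seq_len(nb)) {
      batch <- idx_epoch[((b - 1) * config$batch_size + 1):
                         min(b * config$batch_size, n)]
      if (objective == "cox") {
        tries <- 0
        while (sum(records$event[batch]) == 0 && tries < 50) {
          batch <- sample.int(n, length(batch)); tries <- tries + 1
        }
        if (sum(records$event[batch]) == 0) next
      }
      batch_seed <- sample.int(.Machine$integer.max, 1)
      # group the batch by sequence length so each group can be
      # vectorised across subjects
      lens <- vapply(batch, function(i) nrow(features[[i]]), numeric(1))
      groups <- split(batch, lens)
      grad_fn <- function(p) {
        m <- crnn_set_params(model, p)
        set.seed(batch_seed)
        fwds <- lapply(groups, function(idx)
          crnn_batch_forward(m, features, gaps, idx, train = TRUE))
        acc <- NULL
        if (objective == "cross_entropy") {
          tot <- 0
          for (gi in seq_along(groups)) {
            idx <- groups[[gi]]; Z <- fwds[[gi]]$Z
            E <- exp(sweep(Z, 2, apply(Z, 2, max)))
            P <- sweep(E, 2, colSums(E), `/`)
            oneh <- matrix(0, nrow(Z), length(idx))
            oneh[cbind(labels[idx] + 1, seq_along(idx))] <- 1
            tot <- tot - sum(log(pmax(P[oneh == 1], 1e-12))) / length(batch)
            dZ <- (P - oneh) / length(batch)
            acc <- add_grads(acc, crnn_batch_backward(m, fwds[[gi]], dZ))
          }
          attr(acc, "loss") <- tot
        } else {
          ord <- unlist(groups)
          zs <- unlist(lapply(fwds, function(f) drop(f$Z)))
          cl <- cox_partial_loss(zs, records[ord, ], gradient = TRUE)
          pos <- 0
          for (gi in seq_along(groups)) {
            nB <- length(groups[[gi]])
            dZ <- matrix(cl$grad[pos + seq_len(nB)], nrow = 1)
            pos <- pos + nB
            acc <- add_grads(acc, crnn_batch_backward(m, fwds[[gi]], dZ))
          }
          attr(acc, "loss") <- cl$loss
        }
        acc
      }
      g1 <- grad_fn(params)
      ep_loss <- ep_loss + attr(g1, "loss") / nb
      st <- sam_step_pre(params, g1, grad_fn, lr, config)
      upd <- sam_apply(params, st$g, lr, config, state)
      params <- upd$params; state <- upd$state
    }
    vloss <- NA_real_
    if (!is.null(val)) {
      m <- crnn_set_params(model, params)
      vloss <- eval_crnn_loss(m, val, objective)
      if (vloss < best$loss - 1e-6) {
        best <- list(loss = vloss, params = params); bad <- 0
      } else bad <- bad + 1
    }
    log[[epoch]] <- data.frame(epoch = epoch, loss = ep_loss, lr = lr,
                               val_loss = vloss)
    if (verbose) message(sprintf("epoch %d loss %.4f val %.4f",
                                 epoch, ep_loss, vloss))
    if (!is.null(val) && bad >= config$patience) break
  }
  if (!is.null(val) && is.finite(best$loss)) params <- best$params
  list(model = crnn_set_params(model, params), log = do.call(rbind, log))
}

eval_crnn_loss <- function(model, val, objective) {
  preds <- lapply(seq_along(val$features), function(i)
    crnn_predict(model, list(features = val$features[[i]],
                             gaps = val$gaps[[i]])))
  if (objective == "cross_entropy") {
    -mean(vapply(seq_along(preds), function(i)
      log(max(preds[[i]]$prob[val$labels[i] + 1], 1e-12)), numeric(1)))
  } else {
    zs <- vapply(preds, `[[`, numeric(1), "score")
    cox_partial_loss(zs, val$records)
  }
}
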