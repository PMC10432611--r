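#' CRNN assembly: frozen backbone + recurrent head
#'
#' The two sides of the hybrid model are trained independently: the 3D
#' backbone is trained as a CNN on the latest scan, then frozen; the
#' recurrent side consumes the per-scan feature vectors and the
#' inter-scan gaps, and only its parameters (cell, fully-connected layer,
#' head) are optimised during CRNN training.
#'
#' @name crnn
NULL

#' Build a CRNN model around a (frozen) backbone
#'
#' @param backbone a trained `backbone` (its parameters are not touched
#'   by CRNN training).
#' @param cell_kind `"lstm"`, `"tlstm"` or `"talstm"`.
#' @param hx hidden size of the recurrent cell (paper-scale values 32/64;
#'   the tiny preset uses 16).
#' @param head `"classification"` or `"cox"`.
#' @param n_classes logits for a classification head.
#' @param dropout dropout rate of the post-recurrent FC layer.
#' @param seed initialisation seed.
#' @return list of class `crnn_model`.
#' @export
crnn_model <- function(backbone, cell_kind = c("lstm", "tlstm", "talstm"),
                       hx = 16, head = c("classification", "cox"),
                       n_classes = 2, dropout = 0.3, seed = 1) {
  cell_kind <- match.arg(cell_kind)
  head <- match.arg(head)
  nf <- backbone$config$feat_dim
  cell <- cell_params(nf, hx, kind = cell_kind, seed = seed + 2)
  set.seed(seed + 3)
  nout <- if (head == "cox") 1L else as.integer(n_classes)
  structure(list(backbone = backbone, cell = cell, hx = hx,
                 cell_kind = cell_kind, head = head, n_classes = nout,
                 dropout = dropout,
                 fc_W = matrix(rnorm(hx * hx, 0, sqrt(2 / hx)), hx, hx),
                 fc_b = numeric(hx),
                 head_W = matrix(rnorm(hx * nout, 0, 0.1), hx, nout),
                 head_b = numeric(nout)),
            class = "crnn_model")
}

#' Extract per-scan backbone features from a longitudinal series
#'
#' @param backbone a `backbone`.
#' @param series a `longitudinal_series` (or list of `thorax_volume`).
#' @return matrix, one row per scan.
#' @export
series_features <- function(backbone, series) {
  vols <- if (inherits(series, "longitudinal_series")) series$volumes
          else series
  t(vapply(vols, function(v)
    backbone_forward(backbone, v, train = FALSE)$feature,
    numeric(backbone$config$feat_dim)))
}

crnn_head_forward <- function(model, h_last, train = FALSE) {
  u <- drop(crossprod(model$fc_W, h_last)) + model$fc_b
  r <- pmax(u, 0)
  m <- if (train && model$dropout > 0)
    (runif(length(r)) > model$dropout) / (1 - model$dropout)
  else rep(1, length(r))
  rd <- r * m
  z <- drop(crossprod(model$head_W, rd)) + model$head_b
  list(u = u, m = m, rd = rd, z = z)
}

#' Predict risk for a longitudinal series with a CRNN model
#'
#' Per-scan features are extracted with the frozen backbone, unrolled by
#' the recurrent cell (any series length >= 1), and the final hidden
#' state is passed through the FC layer and the prediction head.
#'
#' @param model a `crnn_model`.
#' @param series a `longitudinal_series`, or a list with `features`
#'   (matrix, rows = scans) and `gaps` (from [encode_gaps()]) for
#'   pre-extracted features.
#' @return risk prediction as in [cnn_predict()].
#' @export
crnn_predict <- function(model, series) {
  if (!is.null(series$features)) {
    feats <- series$features; gaps <- series$gaps
  } else {
    feats <- series_features(model$backbone, series)
    gaps <- series$gaps
  }
  st <- unroll(feats, gaps, model$cell)
  hf <- crnn_head_forward(model, st$h, train = FALSE)
  z <- hf$z
  if (model$head == "cox") {
    list(mode = "cox", score = unname(z))
  } else {
    e <- exp(z - max(z))
    prob <- e / sum(e)
    list(mode = "classification", prob = prob, p_event = unname(prob[2]),
         logits = z)
  }
}

crnn_get_params <- function(model) {
  p <- list(fc_W = model$fc_W, fc_b = model$fc_b,
            head_W = model$head_W, head_b = model$head_b)
  for (k in names(model$cell)) p[[paste0("cell.", k)]] <- model$cell[[k]]
  p
}

crnn_set_params <- function(model, p) {
  model$fc_W <- p$fc_W; model$fc_b <- p$fc_b
  model$head_W <- p$head_W; model$head_b <- p$head_b
  for (k in names(model$cell)) model$cell[[k]] <- p[[paste0("cell.", k)]]
  model
}
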