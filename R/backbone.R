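#' 3D residual convolutional backbone
#'
#' A compact 3D ResNet: a strided convolutional stem, four residual
#' stages (one basic block each) with batch normalisation, global
#' adaptive average pooling, and a two-layer fully-connected head (ReLU +
#' dropout) ending in a fixed-size feature vector. Adaptive pooling makes
#' the feature dimension independent of the input grid. Everything —
#' convolution via im2col/GEMM, batch normalisation, the residual blocks,
#' the heads, and all gradients — is implemented in the package, since no
#' deep-learning framework is available in this R stack. Training runs
#' batched (batch statistics); inference uses running statistics and is
#' deterministic.
#'
#' @name crnn-model
NULL

#' Backbone configuration
#'
#' @param preset `"tiny"` (widths 8/16/32/64, 32-unit FC, 16-d features;
#'   sized for CPU training on 32x32x16 phantoms) or `"full"` (widths
#'   64/128/256/512, 512-unit FC, 32-d features, for 256x256x128 input).
#' @param ... field overrides (`widths`, `fc_hidden`, `feat_dim`,
#'   `dropout`, `input_scale`).
#' @return list of class `backbone_config`.
#' @export
backbone_config <- function(preset = c("tiny", "full"), ...) {
  preset <- match.arg(preset)
  cfg <- if (preset == "tiny") {
    list(widths = c(8, 16, 32, 64), fc_hidden = 32, feat_dim = 16)
  } else {
    list(widths = c(64, 128, 256, 512), fc_hidden = 512, feat_dim = 32)
  }
  cfg$dropout <- 0.5
  cfg$stem_stride <- 2
  # thorax volumes arrive in [0, 255] with fill 170; centre and scale
  cfg$input_scale <- c(center = 170, scale = 64)
  over <- list(...)
  cfg[names(over)] <- over
  cfg$preset <- preset
  structure(cfg, class = "backbone_config")
}

conv_init <- function(cin, cout, k) {
  fan_in <- cin * k^3
  matrix(rnorm(fan_in * cout, 0, sqrt(2 / fan_in)), fan_in, cout)
}

bn_layers <- function() {
  c("stem", paste0("s", 1:4, "_c1"), paste0("s", 1:4, "_c2"),
    paste0("s", 2:4, "_sc"))
}

#' Build a randomly initialised backbone
#'
#' @param config a [backbone_config()].
#' @param seed integer seed for the initialisation.
#' @return list of class `backbone`: `config`, `params` (named list of
#'   weight matrices in im2col layout `(Cin*k^3) x Cout`, plus per-layer
#'   batch-norm gain/shift `*_nG`/`*_nB`), and `bn` (running statistics
#'   used at inference).
#' @export
build_backbone <- function(config = backbone_config(), seed = 1) {
  if (length(config$widths) != 4)
    stop_config("backbone expects 4 residual stage widths")
  if (config$dropout < 0 || config$dropout >= 1)
    stop_config("dropout must lie in [0, 1)")
  set.seed(seed)
  w <- config$widths
  p <- list()
  p$stem_W <- conv_init(1, w[1], 3)
  cin <- w[1]
  for (s in 1:4) {
    nm <- paste0("s", s, "_")
    p[[paste0(nm, "c1_W")]] <- conv_init(cin, w[s], 3)
    p[[paste0(nm, "c2_W")]] <- conv_init(w[s], w[s], 3)
    if (s > 1) p[[paste0(nm, "sc_W")]] <- conv_init(cin, w[s], 1)
    cin <- w[s]
  }
  width_of <- function(layer) w[as.integer(substr(layer, 2, 2))]
  bn <- list()
  for (layer in bn_layers()) {
    cw <- if (layer == "stem") w[1] else width_of(layer)
    p[[paste0(layer, "_nG")]] <- rep(1, cw)
    p[[paste0(layer, "_nB")]] <- numeric(cw)
    bn[[layer]] <- list(mean = numeric(cw), var = rep(1, cw))
  }
  p$fc1_W <- matrix(rnorm(w[4] * config$fc_hidden, 0, sqrt(2 / w[4])),
                    w[4], config$fc_hidden)
  p$fc1_b <- numeric(config$fc_hidden)
  p$fc2_W <- matrix(rnorm(config$fc_hidden * config$feat_dim, 0,
                          sqrt(2 / config$fc_hidden)),
                    config$fc_hidden, config$feat_dim)
  p$fc2_b <- numeric(config$feat_dim)
  structure(list(config = config, params = p, bn = bn, seed = seed),
            class = "backbone")
}

conv_fwd <- function(x, W, stride, k, pad) {
  d <- dim(x)
  cols <- cpp_im2col3(x, d[1], d[2], d[3], d[4], k, stride, pad)
  out <- crossprod(W, cols)
  xo <- (d[2] + 2 * pad - k) %/% stride + 1
  yo <- (d[3] + 2 * pad - k) %/% stride + 1
  zo <- (d[4] + 2 * pad - k) %/% stride + 1
  dim(out) <- c(ncol(W), xo, yo, zo)
  out
}

conv_bwd <- function(x, W, dout, stride, k, pad, need_dx = TRUE) {
  d <- dim(x)
  cols <- cpp_im2col3(x, d[1], d[2], d[3], d[4], k, stride, pad)
  dm <- matrix(dout, nrow = dim(dout)[1])
  dW <- cols %*% t(dm)
  dx <- if (need_dx)
    cpp_col2im3(W %*% dm, d[1], d[2], d[3], d[4], k, stride, pad)
  else NULL
  list(dW = dW, dx = dx)
}

scale_input <- function(x, cfg) {
  v <- if (is.list(x)) x$voxels else x
  v <- (v - cfg$input_scale[["center"]]) / cfg$input_scale[["scale"]]
  dim(v) <- c(1, dim(if (is.list(x)) x$voxels else x))
  v
}

bn_eps <- 1e-5

# batch normalisation across a list of per-sample activations
# (C, X, Y, Z). In train mode the batch statistics are used (and
# optionally pushed into the running stats); in eval mode the running
# stats are used, making the layer a fixed per-channel affine map.
bn_fwd <- function(zs, gamma, beta, stats, train, update_env = NULL,
                   layer = NULL) {
  d <- dim(zs[[1]])
  M <- do.call(cbind, lapply(zs, function(z) matrix(z, nrow = d[1])))
  if (train) {
    mu <- rowMeans(M)
    va <- rowMeans(M^2) - mu^2
    if (!is.null(update_env)) {
      mom <- 0.1
      old <- update_env$bn[[layer]]
      update_env$bn[[layer]] <- list(mean = (1 - mom) * old$mean + mom * mu,
                                     var = (1 - mom) * old$var + mom * va)
    }
  } else {
    mu <- stats$mean; va <- stats$var
  }
  sig <- sqrt(pmax(va, 0) + bn_eps)
  xhat <- (M - mu) / sig
  Y <- xhat * gamma + beta
  P <- prod(d[2:4])
  ys <- lapply(seq_along(zs), function(i) {
    y <- Y[, ((i - 1) * P + 1):(i * P), drop = FALSE]
    dim(y) <- d
    y
  })
  list(ys = ys, xhat = xhat, sig = sig, d = d, P = P, train = train)
}

bn_bwd <- function(cache, dys, gamma) {
  d <- cache$d
  DM <- do.call(cbind, lapply(dys, function(z) matrix(z, nrow = d[1])))
  dgamma <- rowSums(DM * cache$xhat)
  dbeta <- rowSums(DM)
  dxhat <- DM * gamma
  dx <- if (cache$train) {
    (dxhat - rowMeans(dxhat) -
       cache$xhat * rowMeans(dxhat * cache$xhat)) / cache$sig
  } else {
    dxhat / cache$sig
  }
  P <- cache$P
  dxs <- lapply(seq_along(dys), function(i) {
    v <- dx[, ((i - 1) * P + 1):(i * P), drop = FALSE]
    dim(v) <- d
    v
  })
  list(dxs = dxs, dgamma = dgamma, dbeta = dbeta)
}

relu_list <- function(zs) lapply(zs, function(z) pmax(z, 0))

#' Batched backbone forward pass
#'
#' @param backbone a `backbone`.
#' @param xs list of `thorax_volume`s (or 3D arrays on the \[0,255\]
#'   scale) forming one minibatch.
#' @param train use batch statistics and dropout (TRUE) or running
#'   statistics (FALSE).
#' @param update_env environment whose `bn` field receives updated
#'   running statistics (training only).
#' @return list `features` (B x feat_dim matrix) and `cache`.
#' @export
backbone_forward_batch <- function(backbone, xs, train = TRUE,
                                   update_env = NULL) {
  p <- backbone$params; cfg <- backbone$config
  as <- lapply(xs, scale_input, cfg = cfg)
  cache <- list(x0 = as)
  zs <- lapply(as, conv_fwd, W = p$stem_W, stride = cfg$stem_stride,
               k = 3, pad = 1)
  bn0 <- bn_fwd(zs, p$stem_nG, p$stem_nB, backbone$bn$stem, train,
                update_env, "stem")
  a <- relu_list(bn0$ys)
  cache$stem_bn <- bn0
  for (s in 1:4) {
    nm <- paste0("s", s, "_")
    stride <- if (s == 1) 1 else 2
    z1 <- lapply(a, conv_fwd, W = p[[paste0(nm, "c1_W")]], stride = stride,
                 k = 3, pad = 1)
    b1 <- bn_fwd(z1, p[[paste0(nm, "c1_nG")]], p[[paste0(nm, "c1_nB")]],
                 backbone$bn[[paste0("s", s, "_c1")]], train, update_env,
                 paste0("s", s, "_c1"))
    r1 <- relu_list(b1$ys)
    z2 <- lapply(r1, conv_fwd, W = p[[paste0(nm, "c2_W")]], stride = 1,
                 k = 3, pad = 1)
    b2 <- bn_fwd(z2, p[[paste0(nm, "c2_nG")]], p[[paste0(nm, "c2_nB")]],
                 backbone$bn[[paste0("s", s, "_c2")]], train, update_env,
                 paste0("s", s, "_c2"))
    if (s == 1) {
      sc <- a; bsc <- NULL
    } else {
      zsc <- lapply(a, conv_fwd, W = p[[paste0(nm, "sc_W")]],
                    stride = stride, k = 1, pad = 0)
      bsc <- bn_fwd(zsc, p[[paste0(nm, "sc_nG")]], p[[paste0(nm, "sc_nB")]],
                    backbone$bn[[paste0("s", s, "_sc")]], train, update_env,
                    paste0("s", s, "_sc"))
      sc <- bsc$ys
    }
    z <- mapply(function(u, v) u + v, b2$ys, sc, SIMPLIFY = FALSE)
    out <- relu_list(z)
    cache[[paste0(nm, "in")]] <- a
    cache[[paste0(nm, "b1")]] <- b1
    cache[[paste0(nm, "r1")]] <- r1
    cache[[paste0(nm, "b2")]] <- b2
    cache[[paste0(nm, "bsc")]] <- bsc
    cache[[paste0(nm, "z")]] <- z
    cache[[paste0(nm, "out")]] <- out
    a <- out
  }
  d <- dim(a[[1]])
  nvox <- prod(d[2:4])
  g <- t(vapply(a, function(v) rowMeans(matrix(v, nrow = d[1])),
                numeric(d[1])))
  u1 <- g %*% p$fc1_W + rep(p$fc1_b, each = nrow(g))
  r <- pmax(u1, 0)
  m1 <- if (train && cfg$dropout > 0)
    matrix((runif(length(r)) > cfg$dropout) / (1 - cfg$dropout), nrow(r))
  else matrix(1, nrow(r), ncol(r))
  rd <- r * m1
  f <- rd %*% p$fc2_W + rep(p$fc2_b, each = nrow(rd))
  cache$gap_dim <- d; cache$g <- g; cache$u1 <- u1; cache$m1 <- m1
  cache$rd <- rd
  list(features = f, cache = cache)
}

#' Batched backbone backward pass
#'
#' @param backbone a `backbone`.
#' @param cache cache from [backbone_forward_batch()].
#' @param dfeats gradient of the loss w.r.t. the feature matrix
#'   (B x feat_dim).
#' @param upto optional stage name (`"s1"`..`"s4"`): stop there and also
#'   return `d_act`, the per-sample gradient w.r.t. that stage's output
#'   (used by Grad-CAM).
#' @return list `grads` (summed over the batch) and optionally `d_act`.
#' @export
backbone_backward_batch <- function(backbone, cache, dfeats, upto = NULL) {
  p <- backbone$params
  g <- list()
  g$fc2_W <- crossprod(cache$rd, dfeats)
  g$fc2_b <- colSums(dfeats)
  drd <- dfeats %*% t(p$fc2_W)
  dr <- drd * cache$m1
  du1 <- dr * (cache$u1 > 0)
  g$fc1_W <- crossprod(cache$g, du1)
  g$fc1_b <- colSums(du1)
  dg <- du1 %*% t(p$fc1_W)
  d <- cache$gap_dim
  nvox <- prod(d[2:4])
  B <- nrow(dfeats)
  da <- lapply(seq_len(B), function(i)
    array(rep(dg[i, ] / nvox, nvox), dim = d))
  for (s in 4:1) {
    nm <- paste0("s", s, "_")
    if (!is.null(upto) && upto == paste0("s", s))
      return(list(grads = g, d_act = da))
    dz <- mapply(function(dd, z) dd * (z > 0), da, cache[[paste0(nm, "z")]],
                 SIMPLIFY = FALSE)
    stride <- if (s == 1) 1 else 2
    bn2 <- bn_bwd(cache[[paste0(nm, "b2")]], dz, p[[paste0(nm, "c2_nG")]])
    g[[paste0(nm, "c2_nG")]] <- bn2$dgamma
    g[[paste0(nm, "c2_nB")]] <- bn2$dbeta
    dW2 <- NULL; dr1 <- vector("list", B)
    for (i in seq_len(B)) {
      b <- conv_bwd(cache[[paste0(nm, "r1")]][[i]], p[[paste0(nm, "c2_W")]],
                    bn2$dxs[[i]], 1, 3, 1)
      dW2 <- if (is.null(dW2)) b$dW else dW2 + b$dW
      dr1[[i]] <- b$dx
    }
    g[[paste0(nm, "c2_W")]] <- dW2
    dn1 <- mapply(function(dd, bb) dd * (bb > 0), dr1,
                  cache[[paste0(nm, "b1")]]$ys, SIMPLIFY = FALSE)
    bn1 <- bn_bwd(cache[[paste0(nm, "b1")]], dn1, p[[paste0(nm, "c1_nG")]])
    g[[paste0(nm, "c1_nG")]] <- bn1$dgamma
    g[[paste0(nm, "c1_nB")]] <- bn1$dbeta
    dW1 <- NULL; din <- vector("list", B)
    for (i in seq_len(B)) {
      b <- conv_bwd(cache[[paste0(nm, "in")]][[i]], p[[paste0(nm, "c1_W")]],
                    bn1$dxs[[i]], stride, 3, 1)
      dW1 <- if (is.null(dW1)) b$dW else dW1 + b$dW
      din[[i]] <- b$dx
    }
    g[[paste0(nm, "c1_W")]] <- dW1
    if (s == 1) {
      da <- mapply(function(u, v) u + v, din, dz, SIMPLIFY = FALSE)
    } else {
      bns <- bn_bwd(cache[[paste0(nm, "bsc")]], dz, p[[paste0(nm, "sc_nG")]])
      g[[paste0(nm, "sc_nG")]] <- bns$dgamma
      g[[paste0(nm, "sc_nB")]] <- bns$dbeta
      dWs <- NULL
      for (i in seq_len(B)) {
        b <- conv_bwd(cache[[paste0(nm, "in")]][[i]],
                      p[[paste0(nm, "sc_W")]], bns$dxs[[i]], stride, 1, 0)
        dWs <- if (is.null(dWs)) b$dW else dWs + b$dW
        din[[i]] <- din[[i]] + b$dx
      }
      g[[paste0(nm, "sc_W")]] <- dWs
      da <- din
    }
  }
  dn0 <- mapply(function(dd, bb) dd * (bb > 0), da, cache$stem_bn$ys,
                SIMPLIFY = FALSE)
  bn0 <- bn_bwd(cache$stem_bn, dn0, p$stem_nG)
  g$stem_nG <- bn0$dgamma; g$stem_nB <- bn0$dbeta
  dW0 <- NULL
  for (i in seq_along(dn0)) {
    b <- conv_bwd(cache$x0[[i]], p$stem_W, bn0$dxs[[i]],
                  backbone$config$stem_stride, 3, 1, need_dx = FALSE)
    dW0 <- if (is.null(dW0)) b$dW else dW0 + b$dW
  }
  g$stem_W <- dW0
  list(grads = g)
}

#' Single-volume backbone forward pass (inference)
#'
#' Evaluation mode: running batch-norm statistics, no dropout, so fixed
#' weights and a fixed input give a fixed output.
#'
#' @param backbone a `backbone`.
#' @param x a `thorax_volume` (or 3D array on the \[0, 255\] scale).
#' @param train kept for compatibility; `TRUE` only enables the cache.
#' @return list with `feature` (length `feat_dim`) and `cache`.
#' @export
backbone_forward <- function(backbone, x, train = FALSE) {
  fw <- backbone_forward_batch(backbone, list(x), train = FALSE)
  list(feature = drop(fw$features), cache = fw$cache)
}

#' Attach a prediction head to a backbone
#'
#' @param backbone a `backbone`.
#' @param head `"classification"` (2 softmax logits; the reported
#'   mortality probability is the non-survivor class) or `"cox"` (a
#'   single unbounded log-hazard score). `n_classes` overrides the logit
#'   count for the cause-specific classifier.
#' @param n_classes number of classes for a classification head.
#' @param seed head initialisation seed.
#' @return list of class `cnn_model`.
#' @export
cnn_model <- function(backbone, head = c("classification", "cox"),
                      n_classes = 2, seed = 1) {
  head <- match.arg(head)
  set.seed(seed + 1)
  nf <- backbone$config$feat_dim
  nout <- if (head == "cox") 1L else as.integer(n_classes)
  structure(list(backbone = backbone,
                 head = head, n_classes = nout,
                 head_W = matrix(rnorm(nf * nout, 0, 0.1), nf, nout),
                 head_b = numeric(nout)),
            class = "cnn_model")
}

head_forward <- function(model, feature) {
  z <- drop(crossprod(model$head_W, feature)) + model$head_b
  if (model$head == "cox") {
    list(mode = "cox", score = unname(z))
  } else {
    e <- exp(z - max(z))
    prob <- e / sum(e)
    list(mode = "classification", prob = prob,
         p_event = unname(prob[2]), logits = z)
  }
}

#' Predict risk for a single scan with a CNN model
#'
#' @param model a `cnn_model`.
#' @param volume a `thorax_volume`.
#' @return a risk prediction: list with `mode` and either `prob` /
#'   `p_event` (classification; probabilities sum to 1) or `score` (cox,
#'   unbounded log-hazard).
#' @export
cnn_predict <- function(model, volume) {
  f <- backbone_forward(model$backbone, volume)$feature
  head_forward(model, f)
}

#' Average an ensemble of predictions
#'
#' @param models list of models of the same mode (`cnn_model` or
#'   `crnn_model`).
#' @param input a `thorax_volume` (CNN) or `longitudinal_series` (CRNN).
#' @return risk prediction with member probabilities (or scores)
#'   arithmetically averaged.
#' @export
ensemble_predict <- function(models, input) {
  if (length(models) < 1) stop_config("need at least one model")
  preds <- lapply(models, function(m) {
    if (inherits(m, "crnn_model")) crnn_predict(m, input)
    else cnn_predict(m, input)
  })
  modes <- unique(vapply(preds, `[[`, "", "mode"))
  if (length(modes) != 1) stop_config("ensemble members have mixed modes")
  if (modes == "cox") {
    list(mode = "cox",
         score = mean(vapply(preds, `[[`, numeric(1), "score")))
  } else {
    pr <- Reduce(`+`, lapply(preds, `[[`, "prob")) / length(preds)
    list(mode = "classification", prob = pr, p_event = unname(pr[2]))
  }
}

#' 3D Grad-CAM saliency volume
#'
#' Gradient-weighted class-activation mapping: the gradient of the target
#' (a class logit, or the Cox score) with respect to a chosen backbone
#' stage's feature maps is averaged per channel, the channel-weighted sum
#' of the feature maps is rectified, upsampled to the input shape, and
#' min-max scaled to \[0, 1\]. Computed in evaluation mode.
#'
#' @param model a `cnn_model`.
#' @param volume a `thorax_volume`.
#' @param target class index for classification heads (default: the
#'   non-survivor class), ignored for cox.
#' @param layer backbone stage name, `"s1"`..`"s4"` (default `"s4"`).
#' @return 3D saliency array with the input's shape, values in \[0, 1\].
#'   All-zero gradients yield an all-zero map with a warning.
#' @export
gradcam <- function(model, volume, target = 2, layer = "s4") {
  if (!layer %in% paste0("s", 1:4)) stop_config("unknown layer ", layer)
  bb <- model$backbone
  fw <- backbone_forward_batch(bb, list(volume), train = FALSE)
  dfeat <- if (model$head == "cox") drop(model$head_W)
           else model$head_W[, target]
  bk <- backbone_backward_batch(bb, fw$cache, matrix(dfeat, nrow = 1),
                                upto = layer)
  act <- fw$cache[[paste0(layer, "_out")]][[1]]
  dact <- bk$d_act[[1]]
  d <- dim(act)
  w <- rowMeans(matrix(dact, nrow = d[1]))      # channel weights
  cam <- array(colSums(matrix(act, nrow = d[1]) * w), dim = d[2:4])
  cam <- pmax(cam, 0)
  inshape <- dim(if (is.list(volume)) volume$voxels else volume)
  cam <- resample(cam, inshape, order = 1)
  mx <- max(cam)
  if (mx <= 0) {
    warning("zero gradient everywhere: all-zero saliency map")
    return(array(0, dim = inshape))
  }
  (cam - min(cam)) / (mx - min(cam))
}
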