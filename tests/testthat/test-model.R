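test_that("backbone produces fixed-size features for any input grid", {
  bb <- build_backbone(backbone_config("tiny"), seed = 1)
  f1 <- backbone_forward(bb, tiny_volume(1, c(32, 32, 16)))$feature
  f2 <- backbone_forward(bb, tiny_volume(2, c(16, 16, 8)))$feature
  expect_length(f1, 16)
  expect_length(f2, 16)
  # full preset contract: 32-d features
  cfg <- backbone_config("full")
  expect_equal(cfg$feat_dim, 32)
  expect_equal(cfg$fc_hidden, 512)
  expect_error(build_backbone(backbone_config("tiny", dropout = 1)),
               "dropout")
})

test_that("evaluation mode is deterministic and heads behave", {
  bb <- build_backbone(backbone_config("tiny"), seed = 2)
  v <- tiny_volume(3, c(16, 16, 8))
  m <- cnn_model(bb, "classification", seed = 2)
  p1 <- cnn_predict(m, v); p2 <- cnn_predict(m, v)
  expect_identical(p1, p2)
  expect_equal(sum(p1$prob), 1)
  expect_equal(p1$p_event, p1$prob[2])
  # cox head: adding b to the bias shifts every score by exactly b
  mx <- cnn_model(bb, "cox", seed = 2)
  s0 <- cnn_predict(mx, v)$score
  mx$head_b <- mx$head_b + 1.25
  expect_equal(cnn_predict(mx, v)$score, s0 + 1.25, tolerance = 1e-12)
  # and rank metrics are unchanged under that shift
  vs <- lapply(1:8, tiny_volume, shape = c(16, 16, 8))
  sc <- vapply(vs, function(vv) cnn_predict(mx, vv)$score, numeric(1))
  rec <- survival_records(8:1, rep(1, 8))
  expect_equal(harrell_cindex(rec, sc + 3), harrell_cindex(rec, sc))
})

test_that("crnn_predict consumes variable-length series", {
  bb <- build_backbone(backbone_config("tiny"), seed = 3)
  m <- crnn_model(bb, "lstm", hx = 8, head = "classification", seed = 3)
  feats <- matrix(rnorm(48), 3, 16)
  gaps <- encode_gaps(c(0, 370, 740))
  p3 <- crnn_predict(m, list(features = feats, gaps = gaps))
  expect_equal(sum(p3$prob), 1)
  # a length-1 series equals a single recurrent step on that scan
  p1 <- crnn_predict(m, list(features = feats[1, , drop = FALSE],
                             gaps = gaps[1, , drop = FALSE]))
  st <- lstm_step(feats[1, ], zero_state(8), m$cell)
  hf <- longisurv:::crnn_head_forward(m, st$h, train = FALSE)
  expect_equal(p1$logits, hf$z, tolerance = 1e-12)
  # permuting scan order changes the prediction for generic weights
  pp <- crnn_predict(m, list(features = feats[c(3, 1, 2), ], gaps = gaps))
  expect_false(isTRUE(all.equal(p3$prob, pp$prob)))
  expect_error(crnn_model(bb, "gru"), "arg")
})

test_that("ensemble averaging follows the arithmetic-mean contract", {
  m1 <- fixed_prob_model(0.2); m2 <- fixed_prob_model(0.6)
  v <- tiny_volume(5, c(16, 16, 8))
  e <- ensemble_predict(list(m1, m2), v)
  expect_equal(e$p_event, 0.4, tolerance = 1e-12)
  same <- ensemble_predict(list(m1, m1, m1), v)
  expect_equal(same$p_event, cnn_predict(m1, v)$p_event)
  bb <- build_backbone(backbone_config("tiny", widths = c(2, 2, 2, 2),
                                       fc_hidden = 4, feat_dim = 2),
                       seed = 1)
  mx <- cnn_model(bb, "cox", seed = 1)
  expect_error(ensemble_predict(list(m1, mx), v), "mixed modes")
})

test_that("gradcam saliency is a unit-scaled map over the input grid", {
  bb <- build_backbone(backbone_config("tiny"), seed = 4)
  m <- cnn_model(bb, "cox", seed = 4)
  v <- tiny_volume(6, c(32, 32, 16))
  g <- gradcam(m, v)
  expect_equal(dim(g), c(32, 32, 16))
  expect_gte(min(g), 0); expect_lte(max(g), 1)
  # constant target (zero head weights) has zero gradient everywhere
  m0 <- m; m0$head_W[] <- 0
  expect_warning(g0 <- gradcam(m0, v), "zero gradient")
  expect_true(all(g0 == 0))
  expect_error(gradcam(m, v, layer = "s9"), "unknown layer")
})

test_that("gradcam localises a planted hyperdense blob", {
  # single-channel averaging network: saliency must peak where the
  # (positively weighted) input is brightest
  cfg <- backbone_config("tiny", widths = c(1, 1, 1, 1), fc_hidden = 2,
                         feat_dim = 1, dropout = 0)
  bb <- build_backbone(cfg, seed = 5)
  for (nm in grep("_W$", names(bb$params), value = TRUE))
    bb$params[[nm]][] <- abs(bb$params[[nm]]) + 0.2
  for (nm in grep("_nG$", names(bb$params), value = TRUE))
    bb$params[[nm]][] <- 1
  for (nm in grep("_nB$", names(bb$params), value = TRUE))
    bb$params[[nm]][] <- 2           # keep every relu active
  m <- cnn_model(bb, "cox", seed = 5)
  m$head_W[] <- 1
  v <- array(100, c(32, 32, 16))
  v[9:14, 17:22, 5:8] <- 255         # the blob
  g <- gradcam(m, list(voxels = v), layer = "s2")
  peak <- which(g == max(g), arr.ind = TRUE)[1, ]
  pad <- 6                           # stride-4 receptive-field slack
  expect_true(peak[1] >= 9 - pad && peak[1] <= 14 + pad)
  expect_true(peak[2] >= 17 - pad && peak[2] <= 22 + pad)
  expect_true(peak[3] >= 5 - pad && peak[3] <= 8 + pad)
})

test_that("crnn training leaves every backbone parameter bit-identical", {
  set.seed(9)
  bb <- build_backbone(backbone_config("tiny"), seed = 9)
  m <- crnn_model(bb, "lstm", hx = 8, head = "classification", seed = 9)
  before <- serialize(m$backbone, NULL)
  feats <- lapply(1:10, function(i) matrix(rnorm(48), 3, 16))
  gaps <- lapply(1:10, function(i) encode_gaps(c(0, 360, 720)))
  labels <- rep(0:1, 5)
  fit <- train_crnn(m, feats, gaps, labels = labels,
                    objective = "cross_entropy",
                    config = optimiser_config(lr = 0.05, epochs = 3,
                                              batch_size = 5, seed = 1))
  expect_identical(serialize(fit$model$backbone, NULL), before)
})

test_that("training reduces the objective on learnable toy problems", {
  set.seed(10)
  # linearly separable embeddings, full-batch plain SGD: strictly
  # decreasing cross-entropy over the first 10 epochs
  labels <- rep(0:1, each = 8)
  feats <- lapply(seq_along(labels), function(i)
    matrix(rnorm(48, mean = 2 * labels[i]), 3, 16))
  gaps <- lapply(seq_along(labels), function(i) encode_gaps(c(0, 365, 730)))
  bb <- build_backbone(backbone_config("tiny"), seed = 10)
  m <- crnn_model(bb, "lstm", hx = 8, head = "classification", seed = 10)
  m$dropout <- 0
  # the training loss is measured on the full training set after each
  # epoch (the per-epoch batch loss is computed on resampled batches and
  # is noisy by construction)
  fit <- train_crnn(m, feats, gaps, labels = labels,
                    objective = "cross_entropy",
                    config = optimiser_config(lr = 0.05, epochs = 10,
                                              batch_size = 16, rho = 0,
                                              seed = 2),
                    val = list(features = feats, gaps = gaps,
                               labels = labels))
  expect_true(all(diff(fit$log$val_loss) < 0))
  # cox objective beats the all-equal-scores baseline
  rec <- survival_records(rexp(16, 0.02 * exp(labels)), rep(1, 16))
  mx <- crnn_model(bb, "lstm", hx = 8, head = "cox", seed = 10)
  mx$dropout <- 0
  fitx <- train_crnn(mx, feats, gaps, records = rec, objective = "cox",
                     config = optimiser_config(lr = 0.05, epochs = 30,
                                               batch_size = 16, rho = 0,
                                               seed = 3))
  base <- cox_partial_loss(rep(0, 16), rec)
  expect_lt(tail(fitx$log$loss, 1), base)
  # 1 epoch -> loss log of length 1
  fit1 <- train_crnn(m, feats, gaps, labels = labels,
                     objective = "cross_entropy",
                     config = optimiser_config(lr = 0.01, epochs = 1,
                                               batch_size = 8, seed = 4))
  expect_equal(nrow(fit1$log), 1)
})

test_that("train_cnn learns a planted intensity signal end to end", {
  set.seed(11)
  labels <- rep(0:1, each = 8)
  vols <- lapply(seq_along(labels), function(i) {
    v <- array(rnorm(16 * 16 * 8, 170 + 30 * labels[i], 20), c(16, 16, 8))
    list(voxels = pmin(pmax(v, 0), 255))
  })
  bb <- build_backbone(backbone_config("tiny"), seed = 11)
  m <- cnn_model(bb, "classification", seed = 11)
  fit <- train_cnn(m, vols, labels = labels, objective = "cross_entropy",
                   config = optimiser_config(lr = 0.05, epochs = 8,
                                             batch_size = 8, rho = 0,
                                             seed = 5))
  p <- vapply(vols, function(v) cnn_predict(fit$model, v)$p_event,
              numeric(1))
  expect_gt(roc_auc(p, labels), 0.9)
  # determinism: same config and data, same result
  fit2 <- train_cnn(m, vols, labels = labels, objective = "cross_entropy",
                    config = optimiser_config(lr = 0.05, epochs = 8,
                                              batch_size = 8, rho = 0,
                                              seed = 5))
  expect_equal(fit$model$head_W, fit2$model$head_W, tolerance = 1e-12)
})
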