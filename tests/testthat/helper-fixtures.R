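# shared fixtures: everything is generated in code at test time

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# small raw-HU phantom for preprocessing tests (64x64x32 default grid)
fixture_phantom <- function(seed = 3, ...) {
  make_thorax_phantom(thorax_phantom_spec(), seed = seed, ...)
}

# a ct_volume with a single hypodense ellipsoid inside a soft-tissue body
two_region_phantom <- function(shape = c(96, 96, 48), noise_sd = 15,
                               seed = 7) {
  set.seed(seed)
  x <- seq_len(shape[1]); y <- seq_len(shape[2]); z <- seq_len(shape[3])
  c0 <- (shape + 1) / 2
  ell <- outer(outer(((x - c0[1]) / (shape[1] * 0.3))^2,
                     ((y - c0[2]) / (shape[2] * 0.3))^2, `+`),
               ((z - c0[3]) / (shape[3] * 0.35))^2, `+`) <= 1
  v <- array(40, dim = shape)
  v[ell] <- -850
  v <- v + array(rnorm(prod(shape), 0, noise_sd), dim = shape)
  list(volume = ct_volume(v, spacing = c(4, 4, 8)), truth = ell)
}

# scalar cell params with every weight set to `w` and biases to 0
scalar_cell <- function(kind, w = 1) {
  p <- cell_params(1, 1, kind, seed = 1)
  for (nm in names(p)) p[[nm]][] <- w
  for (nm in grep("^b_", names(p), value = TRUE)) p[[nm]][] <- 0
  if (!is.null(p$b_d)) p$b_d[] <- 0
  p
}

# a classification model whose probability is fixed via the head bias
# (head weights zeroed), so two_step_predict can be tested exactly
fixed_prob_model <- function(p_event, n_classes = 2) {
  bb <- build_backbone(backbone_config("tiny", widths = c(2, 2, 2, 2),
                                       fc_hidden = 4, feat_dim = 2),
                       seed = 1)
  m <- cnn_model(bb, "classification", n_classes = n_classes, seed = 1)
  m$head_W[] <- 0
  if (length(p_event) == 1) {
    m$head_b <- c(log(1 - p_event), log(p_event))
  } else {
    m$head_b <- log(p_event)    # full probability vector supplied
  }
  m
}

tiny_volume <- function(seed = 1, shape = c(16, 16, 8)) {
  set.seed(seed)
  list(voxels = array(runif(prod(shape), 0, 255), shape))
}

# brute-force IPCW concordance oracle (independent of the implementation)
ipcw_oracle <- function(train, test, risk, tau) {
  cens <- train; cens$event <- 1 - cens$event
  g <- km_fit(cens)   # shared KM estimator; weights assembled independently
  num <- den <- 0
  n <- nrow(test)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (test$event[i] != 1) next
    if (!(test$time[i] < test$time[j]) || test$time[i] >= tau) next
    w <- 1 / km_surv(g, test$time[i], left = TRUE)^2
    den <- den + w
    num <- num + w * ((risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j]))
  }
  num / den
}
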