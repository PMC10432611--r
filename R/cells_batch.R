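# Minibatch-vectorised recurrent forward/backward used by train_crnn.
# States are (hx x B) matrices and inputs (nx x B); the per-sequence step
# functions in cells.R remain the reference implementation (the test
# suite asserts batched and sequential paths agree to machine precision).
# All sequences in one batch must share a length; the trainer groups
# subjects accordingly.

cell_seq_forward_b <- function(X, gaps_days, gaps_value, params) {
  # X: list over timepoints of (nx x B); gaps_*: (T x B) matrices
  kind <- attr(params, "kind")
  hx <- attr(params, "hx")
  B <- ncol(X[[1]])
  H <- matrix(0, hx, B); C <- matrix(0, hx, B)
  Tn <- length(X)
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    x <- X[[t]]
    h_prev <- H; c_prev <- C
    if (kind == "talstm") {
      cs <- tanh(params$W_d %*% c_prev + params$b_d)
      gd <- talstm_discount(gaps_days[t, ])           # length B
      cstar <- c_prev + sweep(cs, 2, gd - 1, `*`)
    } else {
      cs <- NULL; gd <- NULL; cstar <- c_prev
    }
    dtv <- if (kind == "tlstm") gaps_value[t, ] else NULL
    gate <- function(g, act) {
      a <- params[[paste0("W_i", g)]] %*% x +
           params[[paste0("W_h", g)]] %*% h_prev + params[[paste0("b_", g)]]
      if (!is.null(dtv)) a <- a + outer(params[[paste0("w_t", g)]], dtv)
      act(a)
    }
    f <- gate("f", sigmoid); i <- gate("i", sigmoid)
    g <- gate("g", tanh); o <- gate("o", sigmoid)
    C <- f * cstar + i * g
    H <- o * tanh(C)
    cache[[t]] <- list(x = x, h_prev = h_prev, c_prev = c_prev,
                       cstar = cstar, cs = cs, gd = gd, dtv = dtv,
                       f = f, i = i, g = g, o = o, tc = tanh(C))
  }
  list(H = H, C = C, cache = cache)
}

cell_seq_backward_b <- function(cache, dH_last, params) {
  kind <- attr(params, "kind")
  grads <- lapply(params, function(p) p * 0)
  dH <- dH_last
  dC <- dH * 0
  for (t in rev(seq_along(cache))) {
    cc <- cache[[t]]
    do_ <- dH * cc$tc
    dCn <- dC + dH * cc$o * (1 - cc$tc^2)
    df <- dCn * cc$cstar
    di <- dCn * cc$g
    dg <- dCn * cc$i
    dcstar <- dCn * cc$f
    das <- list(f = df * cc$f * (1 - cc$f),
                i = di * cc$i * (1 - cc$i),
                g = dg * (1 - cc$g^2),
                o = do_ * cc$o * (1 - cc$o))
    dH <- dH * 0
    for (g in c("f", "i", "g", "o")) {
      da <- das[[g]]
      grads[[paste0("W_i", g)]] <- grads[[paste0("W_i", g)]] +
        tcrossprod(da, cc$x)
      grads[[paste0("W_h", g)]] <- grads[[paste0("W_h", g)]] +
        tcrossprod(da, cc$h_prev)
      grads[[paste0("b_", g)]] <- grads[[paste0("b_", g)]] + rowSums(da)
      if (kind == "tlstm")
        grads[[paste0("w_t", g)]] <- grads[[paste0("w_t", g)]] +
          drop(da %*% cc$dtv)
      dH <- dH + crossprod(params[[paste0("W_h", g)]], da)
    }
    if (kind == "talstm") {
      dcs <- sweep(dcstar, 2, cc$gd - 1, `*`)
      dad <- dcs * (1 - cc$cs^2)
      grads$W_d <- grads$W_d + tcrossprod(dad, cc$c_prev)
      grads$b_d <- grads$b_d + rowSums(dad)
      dC <- dcstar + crossprod(params$W_d, dad)
    } else {
      dC <- dcstar
    }
  }
  grads
}

# forward + backward of the whole recurrent side for one equal-length
# batch; dz is supplied per sample after the forward (closure over the
# loss). Returns grads summed over the batch plus the head outputs.
crnn_batch_forward <- function(model, features, gaps, idx, train = TRUE) {
  Tn <- nrow(features[[idx[1]]])
  X <- lapply(seq_len(Tn), function(t)
    vapply(idx, function(i) features[[i]][t, ],
           numeric(ncol(features[[idx[1]]]))))
  gd <- vapply(idx, function(i) gaps[[i]]$days, numeric(Tn))
  gv <- vapply(idx, function(i) gaps[[i]]$value, numeric(Tn))
  if (Tn == 1) { gd <- matrix(gd, 1); gv <- matrix(gv, 1) }
  X <- lapply(X, function(m) if (is.matrix(m)) m else matrix(m, nrow = 1))
  fw <- cell_seq_forward_b(X, gd, gv, model$cell)
  U <- crossprod(model$fc_W, fw$H) + model$fc_b      # hx x B
  R <- pmax(U, 0)
  Mk <- if (train && model$dropout > 0)
    matrix((runif(length(R)) > model$dropout) / (1 - model$dropout),
           nrow(R))
  else matrix(1, nrow(R), ncol(R))
  RD <- R * Mk
  Z <- crossprod(model$head_W, RD) + model$head_b    # nout x B
  list(fw = fw, U = U, Mk = Mk, RD = RD, Z = Z)
}

crnn_batch_backward <- function(model, fwd, dZ) {
  g <- list()
  g$head_W <- tcrossprod(fwd$RD, dZ)                 # hx x nout
  g$head_b <- rowSums(dZ)
  dRD <- model$head_W %*% dZ
  dU <- dRD * fwd$Mk * (fwd$U > 0)
  g$fc_W <- tcrossprod(fwd$fw$H, dU)
  g$fc_b <- rowSums(dU)
  dH <- model$fc_W %*% dU
  cellg <- cell_seq_backward_b(fwd$fw$cache, dH, model$cell)
  for (k in names(cellg)) g[[paste0("cell.", k)]] <- cellg[[k]]
  g
}
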