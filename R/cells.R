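#' Recurrent cells for irregular follow-up intervals
#'
#' Three step-compatible recurrent cells: the vanilla LSTM, the
#' time-modulated LSTM (tLSTM) whose four gates each receive an extra
#' weighted elapsed-time term \eqn{W_t \delta t}, and the time-aware LSTM
#' (TALSTM) which decomposes the carried cell memory into long- and
#' short-term parts and discounts the short-term part by a monotone
#' function of the elapsed time before the standard update. All cells
#' share one state contract (`list(h, c)`) and one analytic backward pass,
#' so they are interchangeable inside the recurrent head.
#'
#' @name recurrent-cells
NULL

#' Initialise parameters for a recurrent cell
#'
#' Weights are drawn uniformly from \eqn{\pm 1/\sqrt{hx}}; the forget-gate
#' bias starts at 1 (standard practice so early training does not flush
#' the cell memory).
#'
#' @param nx input feature size.
#' @param hx hidden size.
#' @param kind `"lstm"`, `"tlstm"` or `"talstm"`.
#' @param seed optional integer seed for reproducible initialisation.
#' @return named list of parameter arrays; class `cell_params` with
#'   attributes `nx`, `hx`, `kind`.
#' @export
cell_params <- function(nx, hx, kind = c("lstm", "tlstm", "talstm"),
                        seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  s <- 1 / sqrt(hx)
  mk <- function(nr, nc) matrix(runif(nr * nc, -s, s), nr, nc)
  p <- list()
  for (g in c("f", "i", "g", "o")) {
    p[[paste0("W_i", g)]] <- mk(hx, nx)
    p[[paste0("W_h", g)]] <- mk(hx, hx)
    p[[paste0("b_", g)]] <- if (g == "f") rep(1, hx) else rep(0, hx)
    if (kind == "tlstm") p[[paste0("w_t", g)]] <- runif(hx, -s, s)
  }
  if (kind == "talstm") {
    p$W_d <- mk(hx, hx)
    p$b_d <- rep(0, hx)
  }
  structure(p, nx = nx, hx = hx, kind = kind, class = "cell_params")
}

#' Zero initial cell state
#' @param hx hidden size.
#' @export
zero_state <- function(hx) list(h = numeric(hx), c = numeric(hx))

#' TALSTM elapsed-time discount
#'
#' \eqn{g(\delta t) = 1/\log(e + \delta t)} with \eqn{\delta t} in days:
#' monotone non-increasing with \eqn{g(0) = 1}.
#'
#' @param dt_days elapsed time in days, non-negative.
#' @export
talstm_discount <- function(dt_days) 1 / log(exp(1) + dt_days)

check_cell_shapes <- function(x, state, params) {
  nx <- attr(params, "nx"); hx <- attr(params, "hx")
  if (length(x) != nx)
    stop_invalid("input size ", length(x), " != expected ", nx)
  if (length(state$h) != hx || length(state$c) != hx)
    stop_invalid("state size mismatch (expected hx = ", hx, ")")
  if (any(!is.finite(state$h)) || any(!is.finite(state$c)))
    stop_invalid("non-finite cell state")
}

# shared gate + state computation; dt enters as w_t * dt when time weights
# are present (tLSTM) and is 0 otherwise.
lstm_core <- function(x, h, c, params, dt = 0, timed = FALSE) {
  gate <- function(g) {
    a <- drop(params[[paste0("W_i", g)]] %*% x) +
         drop(params[[paste0("W_h", g)]] %*% h) +
         params[[paste0("b_", g)]]
    if (timed) a <- a + params[[paste0("w_t", g)]] * dt
    a
  }
  af <- gate("f"); ai <- gate("i"); ag <- gate("g"); ao <- gate("o")
  f <- sigmoid(af); i <- sigmoid(ai); g <- tanh(ag); o <- sigmoid(ao)
  cn <- f * c + i * g
  hn <- o * tanh(cn)
  list(h = hn, c = cn, f = f, i = i, g = g, o = o, tc = tanh(cn))
}

#' One vanilla LSTM step
#'
#' Standard gates from the input and previous hidden state:
#' `c' = f*c + i*g`, `h' = o*tanh(c')`.
#'
#' @param x input feature vector.
#' @param state `list(h, c)` from [zero_state()] or a previous step.
#' @param params a `cell_params` object.
#' @return new `list(h, c)`.
#' @export
lstm_step <- function(x, state, params) {
  check_cell_shapes(x, state, params)
  out <- lstm_core(x, state$h, state$c, params)
  list(h = out$h, c = out$c)
}

#' One time-modulated LSTM step
#'
#' As [lstm_step()] but every gate pre-activation gains an extra
#' \eqn{W_t \delta t} term, injecting the (scaled) elapsed time since the
#' previous observation into the gate computation.
#'
#' @inheritParams lstm_step
#' @param dt encoded elapsed time since the previous input (the package
#'   default encoding is years, i.e. days/365; see [encode_gaps()]).
#' @export
tlstm_step <- function(x, state, dt, params) {
  if (is.null(params$w_tf))
    stop_config("cell params lack time weights; build with kind = 'tlstm'")
  if (dt < 0) stop_invalid("elapsed time must be non-negative")
  check_cell_shapes(x, state, params)
  out <- lstm_core(x, state$h, state$c, params, dt = dt, timed = TRUE)
  list(h = out$h, c = out$c)
}

#' One time-aware LSTM step
#'
#' The carried cell memory is split into a short-term part
#' \eqn{c_S = \tanh(W_d c + b_d)} and the long-term remainder
#' \eqn{c_T = c - c_S}; the short-term part is discounted by
#' [talstm_discount()] and the adjusted memory
#' \eqn{c^* = c_T + g(\delta t) c_S} feeds a standard LSTM step. At
#' \eqn{\delta t = 0} the decomposition is the identity.
#'
#' @inheritParams lstm_step
#' @param dt_days elapsed time in days since the previous input.
#' @export
talstm_step <- function(x, state, dt_days, params) {
  if (is.null(params$W_d))
    stop_config("cell params lack decomposition weights; build with kind = 'talstm'")
  if (dt_days < 0) stop_invalid("elapsed time must be non-negative")
  check_cell_shapes(x, state, params)
  cs <- tanh(drop(params$W_d %*% state$c) + params$b_d)
  cstar <- state$c + (talstm_discount(dt_days) - 1) * cs
  out <- lstm_core(x, state$h, cstar, params)
  list(h = out$h, c = out$c)
}

#' Encode acquisition days into inter-scan gaps
#'
#' @param acquisition_days strictly increasing integer days since the
#'   subject's baseline scan.
#' @param mode `"years"` (default: days/365), `"days"` (identity), or
#'   `"log"` (`log1p(days)`).
#' @return data.frame with columns `days` (raw gap; first element 0) and
#'   `value` (encoded gap).
#' @export
encode_gaps <- function(acquisition_days, mode = c("years", "days", "log")) {
  mode <- match.arg(mode)
  if (length(acquisition_days) == 0) stop_invalid("empty day sequence")
  if (any(diff(acquisition_days) <= 0))
    stop_invalid("acquisition days must be strictly increasing")
  gaps <- c(0, diff(acquisition_days))
  value <- switch(mode, years = gaps / 365, days = gaps, log = log1p(gaps))
  data.frame(days = gaps, value = value)
}

#' Unroll a recurrent cell over a feature sequence
#'
#' Folds the chosen step function over the sequence from the zero state
#' and returns the final state. Sequence length is arbitrary (>= 1).
#'
#' @param features matrix with one row per timepoint (columns = input
#'   features), or a list of vectors.
#' @param gaps data.frame from [encode_gaps()] with one row per timepoint.
#' @param params `cell_params` (its `kind` attribute selects the cell).
#' @param state optional initial state (defaults to zeros).
#' @return final `list(h, c)`.
#' @export
unroll <- function(features, gaps, params, state = NULL) {
  if (is.list(features) && !is.matrix(features))
    features <- do.call(rbind, features)
  if (is.vector(features)) features <- matrix(features, nrow = 1)
  Tn <- nrow(features)
  if (Tn < 1) stop_invalid("empty sequence")
  if (nrow(gaps) != Tn) stop_invalid("features and gaps length mismatch")
  kind <- attr(params, "kind")
  if (is.null(state)) state <- zero_state(attr(params, "hx"))
  for (t in seq_len(Tn)) {
    x <- features[t, ]
    state <- switch(kind,
      lstm = lstm_step(x, state, params),
      tlstm = tlstm_step(x, state, gaps$value[t], params),
      talstm = talstm_step(x, state, gaps$days[t], params))
  }
  state
}

# ---- forward with cache + analytic backward (used by CRNN training and
# ---- the finite-difference gradient tests) -------------------------------

cell_seq_forward <- function(features, gaps, params) {
  kind <- attr(params, "kind")
  hx <- attr(params, "hx")
  Tn <- nrow(features)
  state <- zero_state(hx)
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    x <- features[t, ]
    h_prev <- state$h; c_prev <- state$c
    if (kind == "talstm") {
      cs <- tanh(drop(params$W_d %*% c_prev) + params$b_d)
      gd <- talstm_discount(gaps$days[t])
      cstar <- c_prev + (gd - 1) * cs
    } else {
      cs <- NULL; gd <- NULL; cstar <- c_prev
    }
    dt <- if (kind == "tlstm") gaps$value[t] else 0
    out <- lstm_core(x, h_prev, cstar, params, dt = dt,
                     timed = (kind == "tlstm"))
    cache[[t]] <- list(x = x, h_prev = h_prev, c_prev = c_prev,
                       cstar = cstar, cs = cs, gd = gd, dt = dt, out = out)
    state <- list(h = out$h, c = out$c)
  }
  list(state = state, cache = cache)
}

cell_seq_backward <- function(cache, dh_last, params, dc_last = NULL) {
  kind <- attr(params, "kind")
  hx <- attr(params, "hx")
  grads <- lapply(params, function(p) p * 0)
  dh <- dh_last
  dc <- if (is.null(dc_last)) numeric(hx) else dc_last
  dxs <- vector("list", length(cache))
  for (t in rev(seq_along(cache))) {
    cc <- cache[[t]]; o <- cc$out
    do_ <- dh * o$tc
    dcn <- dc + dh * o$o * (1 - o$tc^2)
    df <- dcn * cc$cstar
    di <- dcn * o$g
    dg <- dcn * o$i
    dcstar <- dcn * o$f
    daf <- df * o$f * (1 - o$f)
    dai <- di * o$i * (1 - o$i)
    dag <- dg * (1 - o$g^2)
    dao <- do_ * o$o * (1 - o$o)
    das <- list(f = daf, i = dai, g = dag, o = dao)
    dh_prev <- numeric(hx)
    dx <- numeric(length(cc$x))
    for (g in c("f", "i", "g", "o")) {
      da <- das[[g]]
      grads[[paste0("W_i", g)]] <- grads[[paste0("W_i", g)]] +
        da %o% cc$x
      grads[[paste0("W_h", g)]] <- grads[[paste0("W_h", g)]] +
        da %o% cc$h_prev
      grads[[paste0("b_", g)]] <- grads[[paste0("b_", g)]] + da
      if (kind == "tlstm")
        grads[[paste0("w_t", g)]] <- grads[[paste0("w_t", g)]] + da * cc$dt
      dh_prev <- dh_prev + drop(crossprod(params[[paste0("W_h", g)]], da))
      dx <- dx + drop(crossprod(params[[paste0("W_i", g)]], da))
    }
    if (kind == "talstm") {
      dcs <- (cc$gd - 1) * dcstar
      dad <- dcs * (1 - cc$cs^2)
      grads$W_d <- grads$W_d + dad %o% cc$c_prev
      grads$b_d <- grads$b_d + dad
      dc <- dcstar + drop(crossprod(params$W_d, dad))
    } else {
      dc <- dcstar
    }
    dh <- dh_prev
    dxs[[t]] <- dx
  }
  list(dparams = grads, dxs = do.call(rbind, dxs))
}
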