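test_that("scalar worked examples match independent gate evaluation", {
  # vanilla: unit weights, x=1, zero state: f=i=o=sigma(1), g=tanh(1)
  p <- scalar_cell("lstm")
  st <- lstm_step(1, zero_state(1), p)
  sig1 <- 1 / (1 + exp(-1))
  expect_equal(st$c, sig1 * tanh(1), tolerance = 1e-12)
  expect_equal(st$h, sig1 * tanh(sig1 * tanh(1)), tolerance = 1e-12)
  expect_equal(round(st$c, 4), 0.5568)
  # time-modulated: gate pre-activations gain + W_t * dt = 1
  pt <- scalar_cell("tlstm")
  stt <- tlstm_step(1, zero_state(1), 1, pt)
  sig2 <- 1 / (1 + exp(-2))
  expect_equal(stt$c, sig2 * tanh(2), tolerance = 1e-12)
  expect_equal(round(stt$c, 4), 0.8491)
  expect_equal(round(stt$h, 3), 0.608)
  # zero everything -> zero state out
  pz <- cell_params(2, 3, "lstm", seed = 1)
  for (nm in names(pz)) pz[[nm]][] <- 0
  stz <- lstm_step(c(0, 0), zero_state(3), pz)
  expect_equal(stz$h, rep(0, 3)); expect_equal(stz$c, rep(0, 3))
})

test_that("talstm decomposition matches the closed form", {
  # W_d = 1, b_d = 0, c = 1, discount 0.5: c* = 1 - tanh(1) + 0.5 tanh(1)
  pa <- scalar_cell("talstm")
  dt_half <- exp(2) - exp(1)       # g(dt) = 1/log(e + dt) = 0.5
  expect_equal(talstm_discount(dt_half), 0.5)
  expect_equal(talstm_discount(0), 1)
  st_in <- list(h = 0, c = 1)
  out <- talstm_step(0, st_in, dt_half, pa)
  cstar <- 1 + (0.5 - 1) * tanh(1)
  expect_equal(round(cstar, 4), 0.6192)
  # feed the same cstar through a vanilla step to cross-check
  pl <- scalar_cell("lstm")
  ref <- lstm_step(0, list(h = 0, c = cstar), pl)
  expect_equal(out$h, ref$h, tolerance = 1e-12)
  # monotone discount: larger dt never increases |discounted short-term|
  d1 <- talstm_discount(100); d2 <- talstm_discount(500)
  expect_true(d2 <= d1)
})

test_that("reduction chain: tLSTM and TALSTM degenerate to vanilla", {
  set.seed(10)
  for (rep in 1:100) {
    nx <- sample(2:5, 1); hx <- sample(2:6, 1)
    x <- rnorm(nx)
    st <- list(h = rnorm(hx), c = rnorm(hx))
    pt <- cell_params(nx, hx, "tlstm", seed = rep)
    pl <- pt; attr(pl, "kind") <- "lstm"
    # W_t = 0 -> vanilla for any dt
    pt0 <- pt
    for (nm in grep("^w_t", names(pt0), value = TRUE)) pt0[[nm]][] <- 0
    expect_equal(tlstm_step(x, st, runif(1, 0, 5), pt0),
                 lstm_step(x, st, pl))
    # dt = 0 with nonzero W_t -> vanilla
    expect_equal(tlstm_step(x, st, 0, pt), lstm_step(x, st, pl))
    pa <- cell_params(nx, hx, "talstm", seed = rep + 500)
    pal <- pa; attr(pal, "kind") <- "lstm"
    expect_equal(talstm_step(x, st, 0, pa), lstm_step(x, st, pal))
  }
})

test_that("constant-gap tLSTM equals vanilla with absorbed biases", {
  set.seed(2)
  pt <- cell_params(3, 4, "tlstm", seed = 6)
  dt <- 1.3
  pl <- pt; attr(pl, "kind") <- "lstm"
  for (g in c("f", "i", "g", "o"))
    pl[[paste0("b_", g)]] <- pl[[paste0("b_", g)]] +
      pt[[paste0("w_t", g)]] * dt
  xs <- matrix(rnorm(9), 3)
  gaps <- data.frame(days = c(dt, dt, dt) * 365, value = rep(dt, 3))
  a <- unroll(xs, gaps, pt)
  b <- unroll(xs, gaps, pl)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("gate activations stay in range and cell growth is bounded", {
  set.seed(3)
  p <- cell_params(4, 5, "lstm", seed = 9)
  st <- list(h = rnorm(5), c = runif(5, -2, 2))
  B <- max(abs(st$c))
  out <- lstm_step(rnorm(4), st, p)
  expect_true(all(abs(out$c) <= B + 1 + 1e-12))
  expect_true(all(abs(out$h) <= 1))
})

test_that("encode_gaps encodes schedules and rejects bad input", {
  g <- encode_gaps(c(0, 365, 731))
  expect_equal(g$days, c(0, 365, 366))
  expect_equal(encode_gaps(c(0, 365), mode = "years")$value[2], 1)
  expect_error(encode_gaps(c(0, 365, 365)), "strictly increasing")
  # phantom generator schedules: realised gap IQR near 40 days
  co <- generate_cohort(1000, ratio = NULL, shape = c(16, 16, 8), seed = 5)
  gaps <- unlist(lapply(co$schedule, diff))
  expect_gt(IQR(gaps), 30)
  expect_lt(IQR(gaps), 50)
})

test_that("unroll equals manual chaining and threads state associatively", {
  set.seed(7)
  for (kind in c("lstm", "tlstm", "talstm")) {
    p <- cell_params(3, 4, kind, seed = 11)
    xs <- matrix(rnorm(15), 5)
    gaps <- encode_gaps(cumsum(c(0, sample(200:500, 4))) + 1)
    full <- unroll(xs, gaps, p)
    # manual chaining
    st <- zero_state(4)
    for (t in 1:5) {
      st <- switch(kind,
        lstm = lstm_step(xs[t, ], st, p),
        tlstm = tlstm_step(xs[t, ], st, gaps$value[t], p),
        talstm = talstm_step(xs[t, ], st, gaps$days[t], p))
    }
    expect_equal(full, st, tolerance = 1e-12)
    # unroll(a ++ b) == unroll(b from unroll(a))
    head_st <- unroll(xs[1:2, ], gaps[1:2, ], p)
    tail_st <- unroll(xs[3:5, ], gaps[3:5, ], p, state = head_st)
    expect_equal(full, tail_st, tolerance = 1e-12)
  }
  p <- cell_params(2, 3, "lstm", seed = 1)
  expect_error(unroll(matrix(numeric(0), 0, 2), data.frame(), p), "empty")
})

test_that("analytic step gradients match finite differences", {
  set.seed(14)
  for (kind in c("lstm", "tlstm", "talstm")) {
    p <- cell_params(3, 4, kind, seed = 15)
    xs <- matrix(rnorm(9), 3)
    gaps <- encode_gaps(c(1, 380, 700))
    fw <- longisurv:::cell_seq_forward(xs, gaps, p)
    dh <- rnorm(4)
    bk <- longisurv:::cell_seq_backward(fw$cache, dh, p)
    loss <- function(pp)
      sum(longisurv:::cell_seq_forward(xs, gaps, pp)$state$h * dh)
    for (nm in names(p)) {
      fd <- p[[nm]] * 0
      for (j in seq_along(p[[nm]])) {
        e <- 1e-6
        pp <- p; pp[[nm]][j] <- pp[[nm]][j] + e; lp <- loss(pp)
        pp[[nm]][j] <- pp[[nm]][j] - 2 * e; lm <- loss(pp)
        fd[j] <- (lp - lm) / (2 * e)
      }
      expect_lt(max(abs(bk$dparams[[nm]] - fd)) /
                  max(max(abs(fd)), 1e-8), 1e-5)
    }
  }
})

test_that("configuration errors are raised for missing weights", {
  pl <- cell_params(2, 3, "lstm", seed = 1)
  expect_error(tlstm_step(rnorm(2), zero_state(3), 1, pl), "time weights")
  expect_error(talstm_step(rnorm(2), zero_state(3), 1, pl),
               "decomposition")
  expect_error(lstm_step(rnorm(5), zero_state(3), pl), "input size")
})
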