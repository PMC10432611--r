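#' Training objectives and optimisation primitives
#'
#' The Cox proportional-hazards negative partial log-likelihood (Breslow
#' tie handling, with Efron as an option), risk-set construction,
#' inverse-class-size sampling weights, and sharpness-aware minimisation
#' (SAM) wrapped around an SGD-with-momentum base update.
#'
#' @name training-losses
NULL

#' Risk set of a subject
#'
#' The set of subjects still at risk at the anchor's event time:
#' all `j` with `T_j >= T_i` (the anchor is always a member).
#'
#' @param records `survival_records`.
#' @param i anchor index; must have `event == 1`.
#' @return integer vector of member indices.
#' @export
risk_set <- function(records, i) {
  if (records$event[i] != 1)
    stop_invalid("anchor subject ", i, " is censored")
  which(records$time >= records$time[i])
}

#' Cox negative partial log-likelihood
#'
#' \deqn{L = -\frac{1}{N_{E=1}} \sum_{i: E_i = 1}
#'   \left[ h(x_i) - \log \sum_{j \in R(T_i)} e^{h(x_j)} \right]}
#' with risk sets \eqn{R(T_i) = \{j : T_j \ge T_i\}} (Breslow convention:
#' tied event times share a risk set). The log-sum-exp is computed stably.
#'
#' @param scores per-subject log-hazard scores h(x).
#' @param records `survival_records` for the same subjects.
#' @param ties `"breslow"` (default, the form above) or `"efron"`.
#' @param gradient if `TRUE`, return `list(loss, grad)` with the exact
#'   analytic gradient with respect to `scores`.
#' @return scalar loss, or a list when `gradient = TRUE`.
#' @export
cox_partial_loss <- function(scores, records, ties = c("breslow", "efron"),
                             gradient = FALSE) {
  ties <- match.arg(ties)
  if (length(scores) != nrow(records))
    stop_invalid("scores and records must have equal length")
  ev <- which(records$event == 1)
  if (length(ev) == 0)
    stop_invalid("degenerate batch: no events; resample the batch")
  time <- records$time
  n <- length(scores)
  nev <- length(ev)
  loss <- 0
  grad <- numeric(n)
  if (ties == "breslow") {
    for (i in ev) {
      rs <- which(time >= time[i])
      m <- max(scores[rs])
      lse <- m + log(sum(exp(scores[rs] - m)))
      loss <- loss - (scores[i] - lse)
      if (gradient) {
        p <- exp(scores[rs] - lse)
        grad[rs] <- grad[rs] + p
        grad[i] <- grad[i] - 1
      }
    }
  } else {
    # Efron: within a tie group of d events, the k-th term removes
    # (k-1)/d of the tied events' hazard mass from the denominator.
    for (t in sort(unique(time[ev]))) {
      tied <- ev[time[ev] == t]
      d <- length(tied)
      rs <- which(time >= t)
      m <- max(scores[rs])
      srs <- sum(exp(scores[rs] - m))
      std <- sum(exp(scores[tied] - m))
      for (k in seq_len(d)) {
        denom <- srs - (k - 1) / d * std
        lse <- m + log(denom)
        loss <- loss - (scores[tied[k]] - lse)
        if (gradient) {
          grad[rs] <- grad[rs] + exp(scores[rs] - m) / denom
          grad[tied] <- grad[tied] - (k - 1) / d * exp(scores[tied] - m) / denom
          grad[tied[k]] <- grad[tied[k]] - 1
        }
      }
    }
  }
  loss <- loss / nev
  if (!gradient) return(loss)
  list(loss = loss, grad = grad / nev)
}

#' Inverse-class-size sampling probabilities
#'
#' Assigns each sample a probability proportional to the reciprocal of its
#' class size, so a random draw is class-balanced in expectation.
#'
#' @param labels class labels (any atomic type).
#' @return numeric vector of probabilities summing to 1.
#' @export
weighted_sampler_probs <- function(labels) {
  tab <- table(labels)
  if (any(tab == 0) || length(tab) == 0)
    stop_config("every class must be non-empty")
  w <- 1 / as.numeric(tab[as.character(labels)])
  w / sum(w)
}

#' One sharpness-aware minimisation (SAM) step
#'
#' Non-adaptive SAM: evaluate the gradient at the current parameters,
#' climb to the adversarial point \eqn{\tilde w = w + \rho g / \|g\|},
#' re-evaluate the gradient there, and apply the base update at `w` using
#' the re-evaluated gradient. The base rule is SGD with optional momentum
#' and decoupled L2 weight decay. A zero gradient norm falls back to a
#' plain base step.
#'
#' @param params named list of numeric arrays (the flattened model).
#' @param grad_fn function(params) -> named list of gradients (same
#'   shapes), typically closing over a minibatch.
#' @param lr learning rate.
#' @param rho SAM neighbourhood radius (global L2 norm across all
#'   parameters). `rho = 0` gives plain SGD.
#' @param momentum momentum coefficient; `state` carries velocities.
#' @param weight_decay L2 coefficient added to the gradient.
#' @param state optional optimiser state from the previous call.
#' @return list `params`, `state`.
#' @export
sam_step <- function(params, grad_fn, lr, rho = 0.05, momentum = 0,
                     weight_decay = 0, state = NULL) {
  g <- grad_fn(params)
  gn <- sqrt(sum(vapply(names(params),
                        function(k) sum(g[[k]]^2), numeric(1))))
  if (rho > 0 && gn > 0) {
    pert <- params
    for (k in names(params))
      pert[[k]] <- params[[k]] + rho * g[[k]] / gn
    g <- grad_fn(pert)
  }
  if (is.null(state)) state <- lapply(params, function(x) x * 0)
  for (k in names(params)) {
    gk <- g[[k]] + weight_decay * params[[k]]
    state[[k]] <- momentum * state[[k]] + gk
    params[[k]] <- params[[k]] - lr * state[[k]]
  }
  list(params = params, state = state)
}

#' Triangular cyclic learning-rate schedule
#'
#' Oscillates linearly between `lr/10` and `lr` with the given cycle
#' length (in epochs), starting at the top of the cycle.
#'
#' @param epoch 1-based epoch number.
#' @param lr peak learning rate.
#' @param cycle cycle length in epochs.
#' @export
cyclic_lr <- function(epoch, lr, cycle = 10) {
  lo <- lr / 10
  phase <- ((epoch - 1) %% cycle) / cycle       # 0 .. <1
  tri <- 1 - abs(2 * phase - 1)                  # 0 -> 1 -> 0
  lo + (lr - lo) * (1 - tri)
}
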