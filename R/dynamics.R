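## Firing-rate dynamics.
##
## Every unit in the network obeys the first-order rate equation
##   tau * dr/dt = -r + f(b + W %*% r_pre)
## integrated with the forward Euler method at a fixed step dt. Decision and
## motor units are normalized within competing pairs (exponentiated
## log-softmax, i.e. softmax), so their rates live in (0, 1) and the fixed
## 0.55 decision threshold is attainable; all other units are rectified
## linear.

#' Rate-unit parameters
#'
#' @param tau Membrane time constant in seconds (default 0.1 s).
#' @param dt Euler step in seconds (default 0.01 s). Must satisfy `dt <= tau`
#'   for stability.
#' @param activation One of `"relu"`, `"softmax"` (normalized decision pair),
#'   `"identity"`, `"bounded_relu"` (relu clipped at 1, used by
#'   self-sustaining cue neurons).
#' @return A list of validated parameters.
#' @export
rate_params <- function(tau = 0.1, dt = 0.01,
                        activation = c("relu", "softmax", "identity",
                                       "bounded_relu")) {
  activation <- match.arg(activation)
  stopifnot(tau > 0, dt > 0, dt <= tau)
  list(tau = tau, dt = dt, activation = activation)
}

#' Apply an activation function
#'
#' `"relu"` is elementwise `max(0, x)`; `"softmax"` is the exponentiated
#' log-softmax over the whole vector (one normalized decision group), so the
#' result lies in (0, 1) and sums to 1; `"identity"` returns its input;
#' `"bounded_relu"` is `min(max(x, 0), 1)`.
#'
#' @param kind Activation name.
#' @param x Numeric preactivation vector.
#' @return Numeric vector of the same length.
#' @export
apply_activation <- function(kind, x) {
  stopifnot(length(x) >= 1)
  switch(kind,
    relu = pmax(x, 0),
    softmax = {
      e <- exp(x - max(x))
      e / sum(e)
    },
    identity = x,
    bounded_relu = pmin(pmax(x, 0), 1),
    stop("unknown activation kind: ", kind)
  )
}

## Bare Euler update used in the inner trial loops: r, target drive u
## (already through f), both plain vectors.
.euler <- function(r, fu, dt, tau) r + (dt / tau) * (fu - r)

#' One Euler step of a rate population
#'
#' Advances `state$rates` by one step of
#' `r <- r + dt/tau * (-r + f(bias + W %*% r_pre))` and `state$time` by `dt`.
#' The input state is not modified.
#'
#' @param state List with `rates` (numeric vector) and `time` (seconds).
#' @param drive List with `bias` (vector or scalar), `W` (matrix or NULL),
#'   and `r_pre` (presynaptic rate vector; ignored when `W` is NULL).
#' @param params From [rate_params()].
#' @return Updated state.
#' @export
euler_step <- function(state, drive, params) {
  u <- drive$bias
  if (!is.null(drive$W)) {
    if (ncol(drive$W) != length(drive$r_pre) ||
        nrow(drive$W) != length(state$rates))
      stop("weight matrix shape does not match source/target dimensions")
    u <- u + as.vector(drive$W %*% drive$r_pre)
  }
  if (any(!is.finite(u))) stop("non-finite drive")
  list(rates = .euler(state$rates, apply_activation(params$activation, u),
                      params$dt, params$tau),
       time = state$time + params$dt)
}

#' Simulate a wired set of rate populations
#'
#' All populations are advanced synchronously: every update at step k reads
#' presynaptic rates from step k. Each population is a list with elements
#' `rates` (initial rates), `params` ([rate_params()]), `bias` (vector or
#' scalar), and `inputs`, a list of `list(from = <population name>,
#' W = <matrix>)` connections.
#'
#' @param populations Named list of population definitions.
#' @param duration Simulated time in seconds.
#' @return Named list of trajectory matrices (steps x units), with the state
#'   after each step; `attr(,"time")` gives the time grid.
#' @export
simulate <- function(populations, duration) {
  stopifnot(duration > 0, length(names(populations)) == length(populations))
  nm <- names(populations)
  rates <- lapply(populations, function(p) p$rates)
  nsteps <- round(duration / populations[[1]]$params$dt)
  out <- lapply(populations, function(p)
    matrix(NA_real_, nsteps, length(p$rates)))
  for (k in seq_len(nsteps)) {
    new <- rates
    for (i in seq_along(populations)) {
      p <- populations[[i]]
      u <- rep_len(if (is.null(p$bias)) 0 else p$bias, length(rates[[i]]))
      for (cn in p$inputs) {
        if (is.null(rates[[cn$from]]))
          stop("dangling population reference: ", cn$from)
        u <- u + as.vector(cn$W %*% rates[[cn$from]])
      }
      new[[i]] <- .euler(rates[[i]],
                         apply_activation(p$params$activation, u),
                         p$params$dt, p$params$tau)
      out[[i]][k, ] <- new[[i]]
    }
    rates <- new
  }
  names(out) <- nm
  attr(out, "time") <- seq_len(nsteps) * populations[[1]]$params$dt
  out
}

#' First threshold-crossing time of a rate trace
#'
#' @param trace Numeric vector of rates sampled at `dt` intervals, first
#'   element being the state after one step.
#' @param threshold Decision threshold (default 0.55).
#' @param dt Step size in seconds.
#' @return Crossing time in seconds, or `NA` if never crossed.
#' @export
crossing_time <- function(trace, threshold = 0.55, dt = 0.01) {
  k <- which(trace >= threshold)
  if (length(k) == 0) return(NA_real_)
  k[1] * dt
}
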