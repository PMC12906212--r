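## Shallow subcortical pathway. Two variants share the same receptive-field
## front end (each decision population sees only its own 4x4 square window):
## a trained 2 -> 16 -> 2 perceptron (feedforward model), and a non-plastic
## recurrent network of two 128-unit excitatory populations competing
## through a 32-unit inhibitory population (predictive-coding model). The
## antisaccade rule neuron suppresses the pathway either by direct
## subtractive inhibition of the decision pair (FF) or by exciting the
## inhibitory population (PC).

#' Receptive-field brightness readout
#'
#' Mean intensity over the fixed left and right 4x4 square windows. The cue
#' bar lies outside both windows, so cue screens read out as (0, 0): the
#' subcortex responds to brightness stimuli but not to rule cues.
#'
#' @param frame A 16x32 screen (possibly noised).
#' @return Named vector `c(left = , right = )`.
#' @export
readout_receptive_fields <- function(frame) {
  c(left = mean(frame[.left_rows, .left_cols]),
    right = mean(frame[.right_rows, .right_cols]))
}

#' Train the feedforward subcortical perceptron
#'
#' A single-hidden-layer perceptron (2 input units carrying the left/right
#' window readouts, 16 rectified hidden units, 2 softmax outputs S_L and
#' S_R), trained by backpropagation to report the brighter side on the
#' non-equal training pairs. The net is deliberately bias-free, so a zero
#' readout (any cue screen) maps to exactly symmetric output probabilities
#' (0.5, 0.5): the pathway is structurally silent without stimulus
#' evidence.
#'
#' @param train Training set from [make_training_set()].
#' @param seed Integer seed.
#' @param epochs,lr Full-batch Adam settings.
#' @return Object of class `subcortex_ff` with weights `W1` (16 x 2), `W2`
#'   (2 x 16), and training accuracy.
#' @export
train_subcortex_ff <- function(train = make_training_set(), seed = 1,
                               epochs = 1500, lr = 5e-3) {
  stim <- train[train$x_left != train$x_right, ]
  X <- rbind(stim$x_left, stim$x_right)              # 2 x n
  y <- ifelse(stim$x_left > stim$x_right, 1L, 2L)    # S_L, S_R
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  par <- list(W1 = matrix(stats::rnorm(32, 0, 1), 16, 2),
              W2 = matrix(stats::rnorm(32, 0, 0.5), 2, 16))
  st <- .adam_new(par)
  n <- ncol(X)
  for (ep in seq_len(epochs)) {
    H <- pmax(par$W1 %*% X, 0)
    logits <- par$W2 %*% H
    ce <- .xent(logits, y, rep(1, n))
    dH <- (t(par$W2) %*% ce$dlogits) * (H > 0)
    g <- list(W1 = dH %*% t(X), W2 = ce$dlogits %*% t(H))
    up <- .adam_step(par, g, st, lr)
    par <- up$par; st <- up$st
  }
  probs <- .mlp2_probs(par, X)
  acc <- mean(max.col(t(probs)) == y)
  if (acc < 0.99)
    warning(sprintf("subcortex perceptron training accuracy %.3f < 0.99", acc))
  structure(list(W1 = par$W1, W2 = par$W2, train_accuracy = acc,
                 seed = seed), class = "subcortex_ff")
}

## Class probabilities (2 x n, rows S_L, S_R) from a 2 x n readout matrix.
.mlp2_probs <- function(par, X) {
  logits <- par$W2 %*% pmax(par$W1 %*% X, 0)
  e <- exp(sweep(logits, 2, apply(logits, 2, max)))
  sweep(e, 2, colSums(e), "/")
}

## Batched probabilities (2 x n) from an n x 2 readout matrix.
.subcortex_ff_probs <- function(sub, readout) {
  t(.mlp2_probs(list(W1 = sub$W1, W2 = sub$W2), t(readout)))
}

#' Sample the recurrent subcortical network
#'
#' Draws the non-plastic connectivity of the recurrent decision network: two
#' excitatory populations of 128 units (S_L, S_R) and one inhibitory
#' population of 32 units (S_I). Every projection is an independent
#' Bernoulli mask at its stated connection probability with uniform(0, 1)
#' magnitudes: excitatory E->I at p = 0.3, inhibitory I->E at p = 0.8,
#' self-recurrent E->E at p = 0.4, stimulus input at p = 0.4, and output to
#' the motor units at p = 0.8. Signs are fixed by projection type
#' (inhibitory weights enter the drive negatively); weights are frozen after
#' sampling.
#'
#' @param seed Integer seed.
#' @param n_exc,n_inh Population sizes (defaults 128 and 32).
#' @return Object of class `subcortex_rnn` holding the weight matrices.
#' @export
sample_subcortex_rnn <- function(seed = 1, n_exc = 128L, n_inh = 32L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  draw <- function(nr, nc, p)
    matrix(stats::runif(nr * nc) * (stats::runif(nr * nc) < p), nr, nc)
  structure(list(
    n_exc = n_exc, n_inh = n_inh, seed = seed,
    W_IL = draw(n_inh, n_exc, 0.3),   # S_L -> S_I (excitatory)
    W_IR = draw(n_inh, n_exc, 0.3),   # S_R -> S_I (excitatory)
    W_LI = draw(n_exc, n_inh, 0.8),   # S_I -> S_L (inhibitory)
    W_RI = draw(n_exc, n_inh, 0.8),   # S_I -> S_R (inhibitory)
    W_LL = draw(n_exc, n_exc, 0.4),   # self-recurrent
    W_RR = draw(n_exc, n_exc, 0.4),
    w_in_L = draw(n_exc, 1L, 0.4)[, 1],   # stimulus input
    w_in_R = draw(n_exc, 1L, 0.4)[, 1],
    w_out_L = draw(1L, n_exc, 0.8)[1, ],  # output to motor
    w_out_R = draw(1L, n_exc, 0.8)[1, ]
  ), class = "subcortex_rnn")
}

#' Realized connection densities of a sampled network
#'
#' @param rnn A `subcortex_rnn`.
#' @return Named vector of nonzero-entry fractions per projection.
#' @export
rnn_densities <- function(rnn) {
  dens <- function(w) mean(w != 0)
  c(exc_IL = dens(rnn$W_IL), exc_IR = dens(rnn$W_IR),
    inh_LI = dens(rnn$W_LI), inh_RI = dens(rnn$W_RI),
    self_LL = dens(rnn$W_LL), self_RR = dens(rnn$W_RR),
    in_L = dens(rnn$w_in_L), in_R = dens(rnn$w_in_R),
    out_L = dens(rnn$w_out_L), out_R = dens(rnn$w_out_R))
}

#' Export sampled connectivity as a sparse triplet table
#'
#' @param rnn A `subcortex_rnn`.
#' @return Data frame with columns `projection`, `pre`, `post`, `weight`
#'   (nonzero entries only; inhibitory projections carry negative weights).
#' @export
rnn_triplets <- function(rnn) {
  one <- function(w, name, sign = 1) {
    nz <- which(w != 0, arr.ind = TRUE)
    if (is.null(dim(w))) {
      nz <- which(w != 0)
      return(data.frame(projection = name, pre = nz, post = 1L,
                        weight = sign * w[nz]))
    }
    data.frame(projection = name, pre = nz[, 2], post = nz[, 1],
               weight = sign * w[nz])
  }
  rbind(one(rnn$W_IL, "SL->SI"), one(rnn$W_IR, "SR->SI"),
        one(rnn$W_LI, "SI->SL", -1), one(rnn$W_RI, "SI->SR", -1),
        one(rnn$W_LL, "SL->SL"), one(rnn$W_RR, "SR->SR"),
        one(rnn$w_in_L, "X->SL"), one(rnn$w_in_R, "X->SR"),
        one(rnn$w_out_L, "SL->M"), one(rnn$w_out_R, "SR->M"))
}

#' One Euler step of the recurrent subcortical network (batched)
#'
#' Advances the three populations synchronously for a batch of trials.
#' Drives are normalized by presynaptic population size so the sampled
#' uniform weights act as population averages; gains set the operating
#' point. The antisaccade rule activity `a` excites the inhibitory
#' population, which in turn suppresses both excitatory populations.
#'
#' @param rnn A `subcortex_rnn`.
#' @param state List with matrices `R_L`, `R_R` (n_exc x n) and `R_I`
#'   (n_inh x n), or NULL to start from zero rates for `n` trials.
#' @param x_left,x_right Length-n window readouts.
#' @param a Length-n antisaccade rule activity in [0, 1].
#' @param gains From [pc_gains()].
#' @param params From [rate_params()].
#' @param n Number of trials (used when `state` is NULL).
#' @return Updated state (same shape), with the per-trial output drives
#'   `o_L`, `o_R` attached.
#' @export
step_subcortex_rnn <- function(rnn, state, x_left, x_right, a, gains,
                               params = rate_params(), n = length(x_left)) {
  if (is.null(state))
    state <- list(R_L = matrix(0, rnn$n_exc, n),
                  R_R = matrix(0, rnn$n_exc, n),
                  R_I = matrix(0, rnn$n_inh, n))
  g <- gains
  bg <- function(nr) if (g$sigma_bg > 0)
    matrix(stats::rnorm(nr * n, 0, g$sigma_bg), nr, n) else 0
  u_L <- g$self * (rnn$W_LL %*% state$R_L) / rnn$n_exc -
    g$inh * (rnn$W_LI %*% state$R_I) / rnn$n_inh +
    g$input * outer(rnn$w_in_L, x_left) - g$theta_e + bg(rnn$n_exc)
  u_R <- g$self * (rnn$W_RR %*% state$R_R) / rnn$n_exc -
    g$inh * (rnn$W_RI %*% state$R_I) / rnn$n_inh +
    g$input * outer(rnn$w_in_R, x_right) - g$theta_e + bg(rnn$n_exc)
  u_I <- g$exc * (rnn$W_IL %*% state$R_L + rnn$W_IR %*% state$R_R) /
    (2 * rnn$n_exc) - g$theta_i +
    matrix(g$anti * a, rnn$n_inh, n, byrow = TRUE) + bg(rnn$n_inh)
  dtau <- params$dt / params$tau
  ## excitatory rates saturate at 1 (bounded rectifier); the inhibitory
  ## population is plain rectified-linear
  state$R_L <- state$R_L + dtau * (pmin(pmax(u_L, 0), 1) - state$R_L)
  state$R_R <- state$R_R + dtau * (pmin(pmax(u_R, 0), 1) - state$R_R)
  state$R_I <- state$R_I + dtau * (pmax(u_I, 0) - state$R_I)
  raw_L <- colMeans(rnn$w_out_L * state$R_L)
  raw_R <- colMeans(rnn$w_out_R * state$R_R)
  cal <- g$out_cal
  if (is.null(cal)) {
    state$o_L <- g$output * raw_L
    state$o_R <- g$output * raw_R
  } else {
    state$o_L <- g$output * (cal$scale[1] * (raw_L - cal$rest[1]) + cal$base)
    state$o_R <- g$output * (cal$scale[2] * (raw_R - cal$rest[2]) + cal$base)
  }
  state
}

#' Homeostatic output calibration of the recurrent subcortex
#'
#' The left and right pathways are independent random samples, so both
#' their resting output drives and their stimulus-response gains differ;
#' uncorrected, this static asymmetry would bias every race. Mimicking slow
#' homeostatic synaptic scaling, each pathway's output is affinely
#' normalized at two operating points: the resting (cue-phase) state and
#' the response to a full-contrast stimulus in its own receptive field,
#' making the two output transfer curves match at rest and at full drive.
#'
#' @param rnn A `subcortex_rnn`.
#' @param gains From [pc_gains()].
#' @param params From [rate_params()].
#' @return List with per-side `scale`, raw `rest` outputs, and the common
#'   resting level `base`, consumed by [step_subcortex_rnn()].
#' @export
calibrate_rnn_output <- function(rnn, gains, params = rate_params()) {
  g <- gains; g$sigma_bg <- 0; g$out_cal <- NULL; g$output <- 1
  run <- function(xl, xr) {
    st <- NULL
    for (k in seq_len(150))
      st <- step_subcortex_rnn(rnn, st, xl, xr, 0, g, params, n = 1)
    c(st$o_L, st$o_R)
  }
  rest <- run(g$in_base, g$in_base)
  ## multiplicative scaling matched at the resting point: zero output maps
  ## to zero, so a suppressed pathway stays neutral rather than
  ## extrapolating to a spurious offset
  scale <- mean(rest) / rest
  ## calibrated output difference for a full-contrast stimulus pair, used
  ## to normalize the decision drive to this realization's dynamic range
  hi <- run(g$in_base + g$in_slope, g$in_base)
  list(scale = scale, rest = c(0, 0), base = 0,
       ref_do = scale[1] * hi[1] - scale[2] * hi[2],
       o_rest = mean(rest))
}
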