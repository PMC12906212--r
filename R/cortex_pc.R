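## Rao-Ballard predictive-coding cortical pathway. A three-layer linear
## generative hierarchy (512 input units = the flattened 16x32 screen, 144
## and 16 latent units) is trained with local Hebbian-style updates to
## minimize squared prediction error; a post-hoc linear (softmax) classifier
## reads the task classes from the top latents; two self-recurrent cue
## neurons hold the rule across the cue-stimulus gap.

#' Predictive-coding hyperparameters
#'
#' @param inference_rate Gradient step size for latent inference.
#' @param inference_iters Fixed number of inference iterations per frame
#'   presentation (fixed count keeps trial timing deterministic).
#' @param learning_rate Step size for the local weight updates.
#' @param prior_decay Quadratic decay (ridge prior) on the latents.
#' @param weight_decay Weight shrinkage per learning update.
#' @param epochs Training epochs over the frame set.
#' @return List of validated hyperparameters.
#' @export
pc_hyper <- function(inference_rate = 0.05, inference_iters = 40,
                     learning_rate = 0.03, prior_decay = 0.01,
                     weight_decay = 1e-4, epochs = 400) {
  stopifnot(inference_rate > 0, inference_iters > 0, learning_rate > 0,
            prior_decay >= 0, weight_decay >= 0, epochs > 0)
  list(inference_rate = inference_rate, inference_iters = inference_iters,
       learning_rate = learning_rate, prior_decay = prior_decay,
       weight_decay = weight_decay, epochs = epochs)
}

#' Initialize predictive-coding weights
#'
#' @param seed Integer seed.
#' @return List with generative maps `U1` (512 x 144) and `U2` (144 x 16).
#' @export
pc_init_weights <- function(seed = 1) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  list(U1 = matrix(stats::rnorm(512 * 144, 0, 0.1), 512, 144),
       U2 = matrix(stats::rnorm(144 * 16, 0, 0.1), 144, 16))
}

.frames_to_x <- function(frames, n_in = 512L) {
  if (is.list(frames)) vapply(frames, as.numeric, numeric(n_in))
  else matrix(as.numeric(frames), n_in)
}

#' Infer latent states for one or more frames
#'
#' Runs gradient descent on the total squared prediction error
#' `E = ||x - U1 r1||^2 + ||r1 - U2 r2||^2 + prior_decay (||r1||^2 + ||r2||^2)`
#' for a fixed number of iterations, from zero-initialized latents.
#'
#' @param weights From [pc_init_weights()] or [pc_learn()].
#' @param frames A single 16x32 frame or a list of frames.
#' @param hyper From [pc_hyper()].
#' @return List with `r1` (144 x n), `r2` (16 x n), `x` (512 x n), and
#'   `energy`, the per-iteration total energy summed over frames (length
#'   `inference_iters + 1`, starting at iteration 0).
#' @export
pc_infer <- function(weights, frames, hyper = pc_hyper()) {
  x <- .frames_to_x(frames, nrow(weights$U1))
  n <- ncol(x)
  r1 <- matrix(0, ncol(weights$U1), n)
  r2 <- matrix(0, ncol(weights$U2), n)
  a <- hyper$inference_rate; lam <- hyper$prior_decay
  energy <- numeric(hyper$inference_iters + 1)
  e0 <- x - weights$U1 %*% r1
  e1 <- r1 - weights$U2 %*% r2
  energy[1] <- sum(e0^2) + sum(e1^2) + lam * (sum(r1^2) + sum(r2^2))
  for (k in seq_len(hyper$inference_iters)) {
    g1 <- crossprod(weights$U1, e0) - e1 - lam * r1
    g2 <- crossprod(weights$U2, e1) - lam * r2
    r1 <- r1 + a * g1
    r2 <- r2 + a * g2
    e0 <- x - weights$U1 %*% r1
    e1 <- r1 - weights$U2 %*% r2
    energy[k + 1] <- sum(e0^2) + sum(e1^2) + lam * (sum(r1^2) + sum(r2^2))
  }
  bad <- sum(diff(energy) > 1e-9)
  if (bad > 3)
    warning(sprintf("inference energy increased on %d iterations; ", bad),
            "inference_rate may be too large")
  list(r1 = r1, r2 = r2, x = x, energy = energy)
}

#' Train the predictive-coding hierarchy
#'
#' Alternates latent inference over all training frames (the two cue screens
#' and the 121 brightness screens) with the local delta-rule weight updates
#' `U1 <- U1 + lr * e0 r1' / n` and `U2 <- U2 + lr * e1 r2' / n`, where `e0`
#' and `e1` are the layer prediction errors at the inferred states.
#'
#' The two cue screens are replicated `cue_oversample` times in the learning
#' set. With only 2 cue frames among 121 brightness frames, the squared-error
#' objective would otherwise devote almost no generative capacity to the
#' faint two-pixel cue patterns; replication balances the objective so the
#' hierarchy retains a discriminable cue representation (this sets how well
#' the rule survives input noise downstream).
#'
#' @param train Training set from [make_training_set()].
#' @param hyper From [pc_hyper()].
#' @param seed Integer seed (weight initialization).
#' @param cue_oversample Replication factor for the two cue screens
#'   (default 60).
#' @return Object of class `pc_weights`: `U1`, `U2`, `hyper`, and a training
#'   `log` (epoch, mean squared reconstruction error per pixel).
#' @export
pc_learn <- function(train = make_training_set(), hyper = pc_hyper(),
                     seed = 1, cue_oversample = 60) {
  frames <- c(rep(list(render_cue("pro"), render_cue("anti")),
                  cue_oversample),
              Map(render_stimulus, train$x_left, train$x_right))
  x <- .frames_to_x(frames)
  n <- ncol(x)
  w <- pc_init_weights(seed)
  st0 <- pc_infer(w, frames, hyper)
  log <- data.frame(epoch = 0L,
                    recon_mse = mean((x - w$U1 %*% st0$r1)^2))
  for (ep in seq_len(hyper$epochs)) {
    st <- pc_infer(w, frames, hyper)
    e0 <- x - w$U1 %*% st$r1
    e1 <- st$r1 - w$U2 %*% st$r2
    if (any(!is.finite(e0)))
      stop("non-finite prediction errors at epoch ", ep,
           " (learning diverged; reduce learning_rate)")
    w$U1 <- (1 - hyper$weight_decay) * w$U1 +
      hyper$learning_rate * (e0 %*% t(st$r1)) / n
    w$U2 <- (1 - hyper$weight_decay) * w$U2 +
      hyper$learning_rate * (e1 %*% t(st$r2)) / n
    if (ep %% 10 == 0 || ep == hyper$epochs)
      log <- rbind(log, data.frame(epoch = ep,
                                   recon_mse = mean(e0^2)))
  }
  structure(list(U1 = w$U1, U2 = w$U2, hyper = hyper, seed = seed,
                 log = log), class = "pc_weights")
}

#' Reconstruct a frame from a latent layer
#'
#' Layer 1 reconstructs through `U1 r1`; layer 2 hierarchically through
#' `U1 (U2 r2)`.
#'
#' @param weights `pc_weights`.
#' @param states Output of [pc_infer()] for a single frame.
#' @param layer 1 or 2.
#' @return A 16x32 `saccadia_frame`.
#' @export
reconstruct_from_layer <- function(weights, states, layer) {
  if (!layer %in% c(1, 2)) stop("layer must be 1 or 2")
  v <- if (layer == 1) weights$U1 %*% states$r1[, 1]
       else weights$U1 %*% (weights$U2 %*% states$r2[, 1])
  structure(matrix(v, .screen_rows, .screen_cols),
            phase = "reconstruction", class = c("saccadia_frame",
                                                "matrix", "array"))
}

#' Train the linear latent classifier
#'
#' Fits a 4-class softmax regression (via [nnet::multinom()]) from the
#' 16-dimensional top-layer latents to the task classes (L, R, P, A). The
#' fit is post-hoc (the hierarchy is frozen). Because inference is linear
#' in the input, pixel noise maps to a fixed latent noise distribution; the
#' classifier is therefore trained on latents of noise-jittered training
#' screens (`n_aug` replicas per screen, noise s.d. drawn uniformly from
#' `aug_sigma`), which lets the linear readout place its boundaries with
#' respect to that distribution. Classes are balanced by replication.
#'
#' @param weights Trained `pc_weights`.
#' @param train Training set from [make_training_set()].
#' @param hyper From [pc_hyper()] (inference settings used to compute
#'   latents).
#' @param n_aug Noisy replicas per side class (cue screens are replicated
#'   to the same class mass); default 440 per class.
#' @param aug_sigma Noise levels sampled during augmentation.
#' @param seed Seed for the augmentation noise.
#' @return Object of class `latent_classifier`.
#' @export
train_latent_classifier <- function(weights, train = make_training_set(),
                                    hyper = weights$hyper, n_aug = 440,
                                    aug_sigma = seq(0, 0.2, 0.01),
                                    seed = 1) {
  stim <- train[train$x_left != train$x_right, ]
  reps_stim <- ceiling(n_aug / (nrow(stim) / 2))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  frames <- list(); lab <- character()
  for (k in seq_len(n_aug)) for (cu in c("pro", "anti")) {
    frames[[length(frames) + 1L]] <-
      add_noise(render_cue(cu), sample(aug_sigma, 1))
    lab <- c(lab, if (cu == "pro") "P" else "A")
  }
  for (k in seq_len(reps_stim)) for (i in seq_len(nrow(stim))) {
    frames[[length(frames) + 1L]] <-
      add_noise(render_stimulus(stim$x_left[i], stim$x_right[i]),
                sample(aug_sigma, 1))
    lab <- c(lab, if (stim$x_left[i] > stim$x_right[i]) "L" else "R")
  }
  lab <- factor(lab, levels = .ff_classes)
  st <- pc_infer(weights, frames, hyper)
  d <- as.data.frame(t(st$r2))
  d$class <- lab
  fit <- nnet::multinom(class ~ ., data = d, maxit = 400, trace = FALSE,
                        MaxNWts = 2000)
  ## report noiseless training accuracy
  base <- c(list(render_cue("pro"), render_cue("anti")),
            Map(render_stimulus, stim$x_left, stim$x_right))
  base_lab <- c("P", "A", ifelse(stim$x_left > stim$x_right, "L", "R"))
  bd <- as.data.frame(t(pc_infer(weights, base, hyper)$r2))
  acc <- mean(as.character(stats::predict(fit, bd)) == base_lab)
  structure(list(fit = fit, classes = .ff_classes, train_accuracy = acc),
            class = "latent_classifier")
}

#' Class scores from a top-layer latent
#'
#' @param classifier From [train_latent_classifier()].
#' @param r2 A 16-vector, or 16 x n matrix of latents.
#' @return Named score (probability) vector over `(L, R, P, A)`, or an
#'   n x 4 matrix for batches.
#' @export
classify_latent <- function(classifier, r2) {
  if (is.matrix(r2)) {
    if (nrow(r2) != 16) stop("latents must have 16 rows")
    d <- as.data.frame(t(r2))
  } else {
    if (length(r2) != 16) stop("latent must have length 16")
    d <- as.data.frame(matrix(r2, 1, 16))
  }
  names(d) <- paste0("V", 1:16)
  p <- stats::predict(classifier$fit, d, type = "probs")
  if (is.null(dim(p))) p[classifier$classes]
  else p[, classifier$classes, drop = FALSE]
}

## Linear class scores (logits) from the fitted multinomial coefficients;
## returns the L-vs-R score margin (positive = evidence for L). Unlike the
## softmaxed probabilities, the linear scores do not saturate, so the margin
## grades with stimulus contrast across the whole brightness range.
.latent_margin_lr <- function(classifier, r2) {
  B <- stats::coef(classifier$fit)            # (K-1) x 17, baseline = "L"
  if (is.null(dim(B))) B <- matrix(B, 1)
  x <- rbind(1, r2)
  -as.vector(B["R", , drop = FALSE] %*% x)    # s_L - s_R with s_L = 0
}

#' Self-recurrent cue neurons
#'
#' Two rate units (P and A) with excitatory self-connections and a
#' saturating rectified-linear activation `min(max(x, 0), 1)`. With
#' `w_self` above the sustain bifurcation (1 for this piecewise-linear
#' unit), a transiently driven neuron latches near its saturated rate and
#' holds it after the drive is removed; the activation threshold `theta`
#' keeps the undriven neuron silent against weak spurious input.
#'
#' @param w_self Self-connection weight (default 1.2).
#' @param theta Activation threshold subtracted from the drive (default 0.1).
#' @return Object of class `cue_neurons` with `p_rate` and `a_rate` at 0.
#' @export
cue_neurons <- function(w_self = 1.2, theta = 0.1) {
  structure(list(p_rate = 0, a_rate = 0, w_self = w_self, theta = theta),
            class = "cue_neurons")
}

#' Advance the cue neurons by one Euler step
#'
#' @param neurons A `cue_neurons` object.
#' @param drive Length-2 numeric vector of external drive to (P, A).
#' @param params From [rate_params()] (its `tau` and `dt` are used; the
#'   activation is the saturating rectifier described in [cue_neurons()]).
#' @return Updated `cue_neurons`.
#' @export
sustain_cue <- function(neurons, drive = c(0, 0), params = rate_params()) {
  r <- c(neurons$p_rate, neurons$a_rate)
  u <- neurons$w_self * r + drive - neurons$theta
  f <- apply_activation("bounded_relu", u)
  r <- .euler(r, f, params$dt, params$tau)
  neurons$p_rate <- r[1]; neurons$a_rate <- r[2]
  neurons
}
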