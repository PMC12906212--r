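## Convolutional feedforward cortical pathway: a single four-way classifier
## over task screens (classes L, R, P, A), a cue-memory latch, and a
## hard-wired XOR gate that combines the remembered rule with the
## brighter-side classification into a choice drive.

.ff_classes <- c("L", "R", "P", "A")

.frames_to_array <- function(frames) {
  N <- length(frames)
  A <- array(0, c(.screen_rows, .screen_cols, 1L, N))
  for (i in seq_len(N)) A[, , 1L, i] <- frames[[i]]
  A
}

#' Train the feedforward cortical classifier
#'
#' Trains the small convolutional network (two valid 4x4 convolutions with 8
#' and 16 channels, each followed by 3x3 non-overlapping max pooling, then a
#' 16-unit dense layer and 4 output units) jointly on the noiseless training
#' screens: the two cue screens (classes P, A) and the non-equal brightness
#' screens (classes L, R; the brighter side). Training is full-batch Adam on
#' class-balanced cross-entropy. Equal-brightness pairs carry no side label
#' and are excluded.
#'
#' Training runs to two criteria. First, at least 99% accuracy on the
#' noiseless training screens. Second, a generalization check: the trained
#' network must keep rule (P/A) and side (L/R) discrimination above 80%
#' on screens carrying heavy pixel noise (s.d. 0.2). Cross-entropy training
#' on the small noiseless set occasionally converges to solutions whose
#' clean-data margins are fine but whose noise response is degenerate;
#' such runs are restarted from a shifted initialization (up to
#' `max_restarts` times, deterministically), and a run that never meets
#' criterion is reported with a warning rather than silently accepted.
#'
#' @param train Training set from [make_training_set()].
#' @param hyper List of training settings: `epochs` (default 500), `lr`
#'   (default 2e-3), `weight_decay` (default 2e-3, decoupled),
#'   `max_restarts` (default 4).
#' @param seed Integer seed; training is deterministic given the seed.
#' @return An object of class `ff_classifier` with the learned parameters,
#'   geometry tables, training log, final training accuracy, the noise
#'   check result, and the number of restarts used.
#' @export
train_ff_classifier <- function(train = make_training_set(),
                                hyper = list(), seed = 1) {
  epochs <- if (is.null(hyper$epochs)) 500L else hyper$epochs
  lr <- if (is.null(hyper$lr)) 2e-3 else hyper$lr
  wd <- if (is.null(hyper$weight_decay)) 2e-3 else hyper$weight_decay
  max_restarts <- if (is.null(hyper$max_restarts)) 4L else hyper$max_restarts

  stim <- train[train$x_left != train$x_right, ]
  frames <- c(list(render_cue("pro"), render_cue("anti")),
              Map(render_stimulus, stim$x_left, stim$x_right))
  y <- c(match(c("P", "A"), .ff_classes),
         match(ifelse(stim$x_left > stim$x_right, "L", "R"), .ff_classes))
  ## Balance class mass: the two cue screens together get the same weight as
  ## each 55-frame side class.
  w <- c(rep(55, 2), rep(1, nrow(stim)))

  geom <- .cnn_geometry()
  A <- .frames_to_array(frames)
  best <- NULL
  for (attempt in 0:max_restarts) {
    par <- .cnn_init(seed + 101L * attempt, geom)
    st <- .adam_new(par)
    log <- data.frame(epoch = integer(), loss = numeric(),
                      accuracy = numeric())
    for (ep in seq_len(epochs)) {
      fw <- .cnn_forward(par, geom, A, keep = TRUE)
      ce <- .xent(fw$logits, y, w)
      g <- .cnn_backward(par, geom, fw, ce$dlogits)
      up <- .adam_step(par, g, st, lr, wd = wd)
      par <- up$par; st <- up$st
      if (ep %% 25 == 0 || ep == epochs) {
        acc <- mean(max.col(t(fw$logits), ties.method = "first") == y)
        log <- rbind(log, data.frame(epoch = ep, loss = ce$loss,
                                     accuracy = acc))
      }
    }
    logits <- .cnn_forward(par, geom, A)
    acc <- mean(max.col(t(logits), ties.method = "first") == y)
    clf <- structure(list(par = par, geom = geom, classes = .ff_classes,
                          train_accuracy = acc, log = log, seed = seed,
                          restarts = attempt),
                     class = "ff_classifier")
    clf$noise_check <- .ff_noise_check(clf, seed)
    if (is.null(best) || min(clf$noise_check) > min(best$noise_check))
      best <- clf
    if (acc >= 0.99 && all(clf$noise_check >= 0.8)) break
  }
  if (best$train_accuracy < 0.99)
    warning(sprintf(
      "classifier reached %.1f%% training accuracy (< 99%% criterion)",
      100 * best$train_accuracy))
  if (any(best$noise_check < 0.8))
    warning(sprintf(
      "classifier noise check below criterion (cue %.2f, side %.2f)",
      best$noise_check["cue"], best$noise_check["side"]))
  best
}

## Rule and side discrimination accuracy on screens noised at s.d. 0.2,
## with the argmax restricted to the relevant class pair (as used by the
## trial dynamics). Deterministic given the training seed.
.ff_noise_check <- function(clf, seed, n = 100, sigma = 0.2) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed + 77L)
  cues <- rep(c("pro", "anti"), length.out = n)
  cue_ok <- vapply(cues, function(cu) {
    sc <- classify_frame(clf, add_noise(render_cue(cu), sigma))
    c("P", "A")[which.max(sc[c("P", "A")])] ==
      (if (cu == "pro") "P" else "A")
  }, logical(1))
  xl <- stats::runif(n); xr <- stats::runif(n)
  flip <- abs(xl - xr) < 0.05
  xr[flip] <- (xl[flip] + 0.5) %% 1   # keep pairs decisively separated
  side_ok <- vapply(seq_len(n), function(i) {
    sc <- classify_frame(clf, add_noise(render_stimulus(xl[i], xr[i]),
                                        sigma))
    c("L", "R")[which.max(sc[c("L", "R")])] ==
      (if (xl[i] > xr[i]) "L" else "R")
  }, logical(1))
  c(cue = mean(cue_ok), side = mean(side_ok))
}

#' Classify a task screen
#'
#' @param weights A trained `ff_classifier`.
#' @param frame A 16x32 screen (possibly noised).
#' @return Named numeric vector of class scores (logits) over
#'   `(L, R, P, A)`; the argmax is the classification.
#' @export
classify_frame <- function(weights, frame) {
  if (!all(dim(frame) == c(.screen_rows, .screen_cols)))
    stop("frame must be 16 x 32")
  A <- array(as.numeric(frame), c(.screen_rows, .screen_cols, 1L, 1L))
  sc <- as.vector(.cnn_forward(weights$par, weights$geom, A))
  names(sc) <- weights$classes
  sc
}

#' Hard-wired XOR gate weights
#'
#' Fixed, untrained weights implementing the rule-integration gate. Inputs
#' are the four classifier-unit rates in order `(P, A, L, R)`; four hidden
#' rectified units compute the conjunctions `PL, PR, AL, AR` (AND gates with
#' bias -1); the output layer maps `PL + AR -> C_L` and `PR + AL -> C_R`.
#'
#' @return List with `W_in` (4x4), `b_in` (length 4), `W_out` (2x4).
#' @export
xor_gate_weights <- function() {
  W_in <- rbind(PL = c(1, 0, 1, 0),
                PR = c(1, 0, 0, 1),
                AL = c(0, 1, 1, 0),
                AR = c(0, 1, 0, 1))
  colnames(W_in) <- c("P", "A", "L", "R")
  W_out <- rbind(C_L = c(1, 0, 0, 1),
                 C_R = c(0, 1, 1, 0))
  colnames(W_out) <- rownames(W_in)
  list(W_in = W_in, b_in = rep(-1, 4), W_out = W_out)
}

#' Combine cue and stimulus classifications through the XOR gate
#'
#' @param cue_class `"P"` or `"A"` (the remembered rule).
#' @param stim_class `"L"` or `"R"` (the brighter side).
#' @return Named vector `c(C_L = , C_R = )`; exactly one entry is 1.
#' @export
xor_combine <- function(cue_class, stim_class) {
  if (is.na(cue_class) || !cue_class %in% c("P", "A"))
    stop("cue memory is empty or invalid at stimulus time")
  stopifnot(stim_class %in% c("L", "R"))
  gw <- xor_gate_weights()
  x <- c(P = 0, A = 0, L = 0, R = 0)
  x[cue_class] <- 1; x[stim_class] <- 1
  h <- pmax(gw$W_in %*% x + gw$b_in, 0)
  drop(gw$W_out %*% h)
}

## Latch the cue: argmax restricted to the P/A scores.
.latch_cue <- function(scores) c("P", "A")[which.max(scores[c("P", "A")])]
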