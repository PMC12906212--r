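## Motor integration, trial orchestration, and reaction-time readout.
##
## Both model variants share the same decision scaffold: a four-unit
## classifier stage (L, R, P, A), the hard-wired XOR gate, a normalized
## cortical choice pair (C_L, C_R), a subcortical decision pair, and a
## normalized motor pair (M_L, M_R) driven by the sum of the two pathway
## outputs. The reaction time of a trial is the first time after stimulus
## onset at which either motor rate crosses the fixed 0.55 threshold; the
## winner is the pathway whose own normalized output pair crossed first.

#' Pathway gains for the feedforward model
#'
#' Single calibration point for the mapping from classifier outputs to rate
#' drives. `class` drives the winning classifier unit; `cortex` scales the
#' XOR-gate output into the cortical choice pair; `sub_beta` scales the
#' perceptron probabilities into the subcortical pair; `inhib` is the direct
#' cortico-subcortical inhibition gain; `motor` scales the summed pathway
#' outputs into the motor pair. Defaults are calibrated so the model's mean
#' reaction times reproduce the pro/antisaccade pattern (about 189 ms and
#' 241 ms; see the methods vignette).
#'
#' @param class,cortex,sub_beta,inhib,motor Positive gains.
#' @return List of gains.
#' @export
ff_gains <- function(class = 1, cortex = 2.3, sub_beta = 0.5, inhib = 5,
                     motor = 0.9) {
  list(class = class, cortex = cortex, sub_beta = sub_beta, inhib = inhib,
       motor = motor)
}

#' Pathway and population gains for the predictive-coding model
#'
#' `class`, `cortex`, and `motor` play the same roles as in [ff_gains()].
#' `margin` scales the graded part of the side-unit drive: the side units
#' receive the categorical classification plus the (clipped) linear score
#' margin, so cortical commitment speed grades with stimulus contrast.
#' `self`, `inh`, `exc`, `input`, `output` scale the recurrent network's
#' projections (drives are normalized by presynaptic population size);
#' `anti` is the rule-neuron excitation of the inhibitory population;
#' `sigma_bg` is the per-unit background-noise s.d. per step. `norm` maps
#' the two population output drives onto the normalized subcortical
#' decision pair; when a model is built, it is set per realization to
#' `norm_target / ref_do` so a full-contrast stimulus always produces the
#' same decision-drive separation (see [calibrate_rnn_output()]).
#' `race_noise` is the s.d. (in decision-drive units) of the background
#' input to the subcortical decision pair, scaled by the pathway's own
#' output level so a silenced pathway is also noise-free; it makes the
#' subcortical race stochastic, with near-contrast-independent timing.
#'
#' @param class,cue,cortex,motor,margin,self,inh,exc,input,output,anti,norm
#'   Positive gains (`class` is the categorical baseline drive of the side
#'   units, `cue` the drive of the rule neurons).
#' @param sigma_bg Background noise s.d. (>= 0).
#' @return List of gains.
#' @export
pc_gains <- function(class = 0.08, cue = 1, cortex = 6, motor = 1.5,
                     margin = 24, margin_floor = 0.5, self = 0.6,
                     inh = 1.6, exc = 1.2, input = 4, output = 1.0,
                     anti = 12, theta_e = 0, theta_i = 0, in_base = 0.45,
                     in_slope = 0.16, sigma_bg = 0.01, norm = 130,
                     norm_target = 2.2, race_noise = 0.5) {
  list(class = class, cue = cue, cortex = cortex, motor = motor,
       margin = margin, margin_floor = margin_floor, self = self,
       inh = inh, exc = exc, input = input, output = output, anti = anti,
       theta_e = theta_e, theta_i = theta_i, in_base = in_base,
       in_slope = in_slope, sigma_bg = sigma_bg, norm = norm,
       norm_target = norm_target, race_noise = race_noise,
       out_cal = NULL)
}

#' Trial protocol
#'
#' @param cue_duration Cue presentation in seconds (default 0.5).
#' @param delay Cue-stimulus gap in seconds (default 0).
#' @param stim_duration Maximum decision window after stimulus onset
#'   (default 1).
#' @param threshold Decision threshold on normalized rates (default 0.55).
#' @param dt,tau Euler step and membrane time constant in seconds.
#' @return List of protocol settings.
#' @export
trial_protocol <- function(cue_duration = 0.5, delay = 0,
                           stim_duration = 1, threshold = 0.55,
                           dt = 0.01, tau = 0.1) {
  stopifnot(cue_duration > 0, delay >= 0, stim_duration > 0,
            threshold > 0.5, threshold < 1, dt > 0, dt <= tau)
  list(cue_duration = cue_duration, delay = delay,
       stim_duration = stim_duration, threshold = threshold,
       dt = dt, tau = tau)
}

#' Build the complete feedforward model
#'
#' Trains the convolutional cortical classifier and the subcortical
#' perceptron and wires them with the XOR gate and calibrated gains.
#'
#' @param seed Integer seed for both trained components.
#' @param train Training set from [make_training_set()].
#' @param gains From [ff_gains()].
#' @param hyper Training settings passed to [train_ff_classifier()].
#' @return Object of class `saccadia_model` with `variant = "ff"`.
#' @export
build_ff_model <- function(seed = 1, train = make_training_set(),
                           gains = ff_gains(), hyper = list()) {
  structure(list(variant = "ff",
                 classifier = train_ff_classifier(train, hyper, seed),
                 subcortex = train_subcortex_ff(train, seed + 1L),
                 gains = gains, seed = seed),
            class = "saccadia_model")
}

#' Build the complete predictive-coding model
#'
#' Trains the Rao-Ballard hierarchy and its latent classifier, samples the
#' non-plastic recurrent subcortical network, and wires them with the XOR
#' gate, self-recurrent cue neurons, and calibrated gains.
#'
#' @param seed Integer seed (hierarchy init and network sampling).
#' @param train Training set from [make_training_set()].
#' @param gains From [pc_gains()].
#' @param hyper From [pc_hyper()].
#' @return Object of class `saccadia_model` with `variant = "pc"`.
#' @export
build_pc_model <- function(seed = 1, train = make_training_set(),
                           gains = pc_gains(), hyper = pc_hyper()) {
  pcw <- pc_learn(train, hyper, seed)
  clf <- train_latent_classifier(pcw, train, hyper, seed = seed + 2L)
  ## reference margin of a full-contrast stimulus, used to normalize the
  ## graded side drive
  ref <- pc_infer(pcw, render_stimulus(1, 0), hyper)$r2
  rnn <- sample_subcortex_rnn(seed + 1L)
  gains$out_cal <- calibrate_rnn_output(rnn, gains)
  gains$norm <- gains$norm_target / gains$out_cal$ref_do
  structure(list(variant = "pc", pc = pcw, classifier = clf, rnn = rnn,
                 margin_scale = abs(.latent_margin_lr(clf, ref)),
                 gains = gains, seed = seed),
            class = "saccadia_model")
}

## Column-wise softmax of a 2-row matrix (one normalized decision pair per
## trial), computed as a logistic of the drive difference.
.softmax2 <- function(u) {
  p1 <- 1 / (1 + exp(u[2, ] - u[1, ]))
  rbind(p1, 1 - p1, deparse.level = 0)
}

## Crossing bookkeeping: given a 2 x n pair matrix at step k (within the
## stimulus window), update first-crossing records in env `bk` under name
## `nm` (fields <nm>_step, <nm>_unit).
.track <- function(bk, nm, pair, k, thr) {
  step <- bk[[paste0(nm, "_step")]]
  unit <- bk[[paste0(nm, "_unit")]]
  hit <- is.na(step) & (pair[1, ] >= thr | pair[2, ] >= thr)
  if (any(hit)) {
    step[hit] <- k
    u <- ifelse(pair[1, hit] > pair[2, hit], 1L,
                ifelse(pair[2, hit] > pair[1, hit], 2L, 0L))
    unit[hit] <- u
    bk[[paste0(nm, "_step")]] <- step
    bk[[paste0(nm, "_unit")]] <- unit
  }
  invisible(bk)
}

## Shared finishing step: assemble the per-trial result table.
.assemble_results <- function(trials, sigma, bk, dt) {
  n <- nrow(trials)
  choice <- rep("none", n)
  choice[!is.na(bk$M_step) & bk$M_unit == 1L] <- "left"
  choice[!is.na(bk$M_step) & bk$M_unit == 2L] <- "right"
  rt_ms <- ifelse(is.na(bk$M_step), NA_real_, bk$M_step * dt * 1000)
  cs <- ifelse(is.na(bk$C_step), Inf, bk$C_step)
  ss <- ifelse(is.na(bk$S_step), Inf, bk$S_step)
  winner <- rep("none", n)
  winner[choice != "none" & cs < ss] <- "cortex"
  winner[choice != "none" & ss < cs] <- "subcortex"
  winner[choice != "none" & ss == cs & is.finite(ss)] <- "cortex"
  correct <- ifelse(choice == "none" | trials$correct_side == "undefined",
                    NA, choice == trials$correct_side)
  data.frame(trial_id = trials$trial_id, cue = trials$cue,
             x_left = trials$x_left, x_right = trials$x_right,
             sigma = sigma, choice = choice, rt_ms = rt_ms,
             winner = winner, correct = correct,
             difficulty = trials$difficulty,
             rt_cortex_ms = ifelse(is.finite(cs), cs * dt * 1000,
                                   NA_real_),
             rt_subcortex_ms = ifelse(is.finite(ss), ss * dt * 1000,
                                      NA_real_))
}

.new_bookkeeping <- function(n) {
  as.environment(list(
    M_step = rep(NA_integer_, n), M_unit = rep(NA_integer_, n),
    C_step = rep(NA_integer_, n), C_unit = rep(NA_integer_, n),
    S_step = rep(NA_integer_, n), S_unit = rep(NA_integer_, n)))
}

## ---- feedforward variant ---------------------------------------------

.run_ff_batch <- function(model, trials, sigma, protocol, record = FALSE) {
  n <- nrow(trials)
  g <- model$gains
  dt <- protocol$dt; dtau <- dt / protocol$tau; thr <- protocol$threshold
  cue_steps <- round((protocol$cue_duration + protocol$delay) / dt)
  stim_steps <- round(protocol$stim_duration / dt)

  ## Phase inputs: classify each (noised) screen once per presentation.
  xc <- vapply(seq_len(n), function(i)
    as.numeric(add_noise(render_cue(trials$cue[i]), sigma)), numeric(512))
  xs <- vapply(seq_len(n), function(i)
    as.numeric(add_noise(render_stimulus(trials$x_left[i],
                                         trials$x_right[i]), sigma)),
    numeric(512))
  geom <- model$classifier$geom
  sc_cue <- .cnn_forward(model$classifier$par, geom,
                         array(xc, c(16, 32, 1, n)))   # 4 x n (L,R,P,A)
  sc_stim <- .cnn_forward(model$classifier$par, geom,
                          array(xs, c(16, 32, 1, n)))
  latch <- ifelse(sc_cue[3, ] >= sc_cue[4, ], 3L, 4L)  # P or A row
  side <- ifelse(sc_stim[1, ] >= sc_stim[2, ], 1L, 2L) # L or R row
  D_cue <- matrix(0, 4, n); D_cue[cbind(latch, seq_len(n))] <- 1
  D_stim <- matrix(0, 4, n)
  D_stim[cbind(side, seq_len(n))] <- 1
  D_stim[cbind(latch, seq_len(n))] <- 1
  ro_cue <- t(vapply(seq_len(n), function(i) {
    f <- matrix(xc[, i], 16, 32)
    readout_receptive_fields(f)
  }, numeric(2)))
  ro_stim <- t(vapply(seq_len(n), function(i) {
    f <- matrix(xs[, i], 16, 32)
    readout_receptive_fields(f)
  }, numeric(2)))
  p_cue <- t(.subcortex_ff_probs(model$subcortex, ro_cue))    # 2 x n
  p_stim <- t(.subcortex_ff_probs(model$subcortex, ro_stim))

  gw <- xor_gate_weights()
  cls <- matrix(0, 4, n); gate <- matrix(0, 4, n)
  Cr <- matrix(0, 2, n); S <- matrix(0, 2, n); M <- matrix(0, 2, n)
  bk <- .new_bookkeeping(n)
  traces <- if (record) vector("list", cue_steps + stim_steps) else NULL

  step_once <- function(D, probs, k_global) {
    a <- cls[4, ]
    u_cls <- g$class * D
    u_gate <- gw$W_in %*% cls[c(3, 4, 1, 2), , drop = FALSE] + gw$b_in
    u_C <- g$cortex * (gw$W_out %*% gate)
    u_S <- pmax(g$sub_beta * probs -
                  matrix(g$inhib * a, 2, n, byrow = TRUE), 0)
    u_M <- g$motor * (Cr + S)
    cls <<- cls + dtau * (pmax(u_cls, 0) - cls)
    gate <<- gate + dtau * (pmax(u_gate, 0) - gate)
    Cr <<- Cr + dtau * (.softmax2(u_C) - Cr)
    S <<- S + dtau * (.softmax2(u_S) - S)
    M <<- M + dtau * (.softmax2(u_M) - M)
    if (record)
      traces[[k_global]] <<- c(M = M[, 1], C = Cr[, 1], S = S[, 1],
                               cls = cls[, 1], gate = gate[, 1])
  }

  for (k in seq_len(cue_steps)) step_once(D_cue, p_cue, k)
  for (k in seq_len(stim_steps)) {
    step_once(D_stim, p_stim, cue_steps + k)
    .track(bk, "M", M, k, thr)
    .track(bk, "C", Cr, k, thr)
    .track(bk, "S", S, k, thr)
  }
  res <- .assemble_results(trials, sigma, bk, dt)
  if (record) {
    tr <- do.call(rbind, traces)
    attr(res, "traces") <- data.frame(
      time = (seq_len(nrow(tr)) - cue_steps) * dt, tr)
  }
  res
}

## ---- predictive-coding variant ---------------------------------------

.run_pc_batch <- function(model, trials, sigma, protocol, record = FALSE) {
  n <- nrow(trials)
  g <- model$gains
  dt <- protocol$dt; dtau <- dt / protocol$tau; thr <- protocol$threshold
  params <- rate_params(protocol$tau, dt)
  cue_steps <- round((protocol$cue_duration + protocol$delay) / dt)
  stim_steps <- round(protocol$stim_duration / dt)

  xc <- vapply(seq_len(n), function(i)
    as.numeric(add_noise(render_cue(trials$cue[i]), sigma)), numeric(512))
  xs <- vapply(seq_len(n), function(i)
    as.numeric(add_noise(render_stimulus(trials$x_left[i],
                                         trials$x_right[i]), sigma)),
    numeric(512))
  frames_c <- lapply(seq_len(n), function(i) matrix(xc[, i], 16, 32))
  frames_s <- lapply(seq_len(n), function(i) matrix(xs[, i], 16, 32))
  st_c <- pc_infer(model$pc, frames_c, model$pc$hyper)
  st_s <- pc_infer(model$pc, frames_s, model$pc$hyper)
  pr_c <- classify_latent(model$classifier, st_c$r2)  # n x 4 (L,R,P,A)
  pr_s <- classify_latent(model$classifier, st_s$r2)
  if (is.null(dim(pr_c))) pr_c <- matrix(pr_c, 1, 4,
                                         dimnames = list(NULL, names(pr_c)))
  if (is.null(dim(pr_s))) pr_s <- matrix(pr_s, 1, 4,
                                         dimnames = list(NULL, names(pr_s)))
  cue_is_a <- pr_c[, "A"] > pr_c[, "P"]
  side <- ifelse(pr_s[, "L"] >= pr_s[, "R"], 1L, 2L)
  D_cue_pa <- rbind(ifelse(cue_is_a, 0, 1), ifelse(cue_is_a, 1, 0))
  ## Side-unit drive: categorical baseline plus the graded (clipped) linear
  ## score margin, normalized by the margin of a full-contrast stimulus, so
  ## cortical commitment speed scales with stimulus contrast.
  mm <- .latent_margin_lr(model$classifier, st_s$r2) / model$margin_scale
  mm <- pmax(pmin(mm, 1), -1)
  ## confidence-gated graded drive: evidence below the criterion
  ## `margin_floor` contributes nothing, so cortical commitment is slow for
  ## subtle contrasts and steeply faster for strong ones
  gr <- sign(mm) * pmax(abs(mm) - g$margin_floor, 0) / (1 - g$margin_floor)
  D_side <- matrix(0, 2, n); D_side[cbind(side, seq_len(n))] <- g$class
  D_side[1, ] <- D_side[1, ] + g$margin * pmax(gr, 0)
  D_side[2, ] <- D_side[2, ] + g$margin * pmax(-gr, 0)
  ## Luminance-adapted afferent: the subcortical input operates on a
  ## compressed intensity range, which (with rate saturation) flattens the
  ## race dynamics across stimulus contrasts.
  ro_c <- g$in_base + g$in_slope *
    t(vapply(frames_c, readout_receptive_fields, numeric(2)))
  ro_s <- g$in_base + g$in_slope *
    t(vapply(frames_s, readout_receptive_fields, numeric(2)))

  gw <- xor_gate_weights()
  cue_u <- matrix(0, 2, n)   # P, A self-recurrent cue neurons
  sideu <- matrix(0, 2, n)   # L, R classifier units
  gate <- matrix(0, 4, n)
  Cr <- matrix(0, 2, n); M <- matrix(0, 2, n)
  S <- matrix(0, 2, n)       # normalized subcortical decision pair
  rnn_state <- NULL
  bk <- .new_bookkeeping(n)
  traces <- if (record) vector("list", cue_steps + stim_steps) else NULL
  w_self <- 1.2; theta <- 0.1

  step_once <- function(Dpa, Dside, ro, k_global) {
    a <- cue_u[2, ]
    u_cue <- w_self * cue_u + g$cue * Dpa - theta
    u_side <- Dside
    u_gate <- gw$W_in %*% rbind(cue_u, sideu) + gw$b_in
    u_C <- g$cortex * (gw$W_out %*% gate)
    rnn_state <<- step_subcortex_rnn(model$rnn, rnn_state,
                                     ro[, 1], ro[, 2], a, g, params, n)
    u_S <- g$norm * rbind(rnn_state$o_L, rnn_state$o_R)
    if (g$race_noise > 0) {
      ## background drive from other subcortical populations, carried by
      ## the pathway's own activity: a silenced pathway is also noise-free
      amp <- pmin((rnn_state$o_L + rnn_state$o_R) /
                    (2 * g$output * g$out_cal$o_rest), 1)
      u_S <- u_S + matrix(stats::rnorm(2 * n, 0, g$race_noise), 2, n) *
        rep(amp, each = 2)
    }
    u_M <- g$motor * (Cr + S)
    cue_u <<- cue_u + dtau * (pmin(pmax(u_cue, 0), 1) - cue_u)
    sideu <<- sideu + dtau * (pmax(u_side, 0) - sideu)
    gate <<- gate + dtau * (pmax(u_gate, 0) - gate)
    Cr <<- Cr + dtau * (.softmax2(u_C) - Cr)
    S <<- S + dtau * (.softmax2(u_S) - S)
    M <<- M + dtau * (.softmax2(u_M) - M)
    if (record)
      traces[[k_global]] <<- c(M = M[, 1], C = Cr[, 1], S = S[, 1],
                               cue = cue_u[, 1], side = sideu[, 1],
                               SL = mean(rnn_state$R_L[, 1]),
                               SR = mean(rnn_state$R_R[, 1]),
                               SI = mean(rnn_state$R_I[, 1]))
  }

  for (k in seq_len(cue_steps))
    step_once(D_cue_pa, matrix(0, 2, n), ro_c, k)
  for (k in seq_len(stim_steps)) {
    step_once(matrix(0, 2, n), D_side, ro_s, cue_steps + k)
    .track(bk, "M", M, k, thr)
    .track(bk, "C", Cr, k, thr)
    .track(bk, "S", S, k, thr)
  }
  res <- .assemble_results(trials, sigma, bk, dt)
  if (record) {
    tr <- do.call(rbind, traces)
    attr(res, "traces") <- data.frame(
      time = (seq_len(nrow(tr)) - cue_steps) * dt, tr)
  }
  res
}

#' Run a batch of trials
#'
#' Executes the cue -> (delay) -> stimulus protocol for every trial,
#' integrating all rate units synchronously with the Euler method, and
#' extracts choice, reaction time, winner pathway, and correctness.
#'
#' @param model From [build_ff_model()] or [build_pc_model()].
#' @param trials Trial table from [as_trials()].
#' @param sigma Gaussian pixel-noise s.d. applied to every screen.
#' @param protocol From [trial_protocol()].
#' @param seed Optional seed for the noise streams.
#' @return Data frame with one row per trial: `trial_id`, `cue`, `x_left`,
#'   `x_right`, `sigma`, `choice` (`left`/`right`/`none`), `rt_ms`,
#'   `winner` (`cortex`/`subcortex`/`none`), `correct`, `difficulty`.
#' @export
run_trials <- function(model, trials, sigma = 0,
                       protocol = trial_protocol(), seed = NULL) {
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  fn <- if (model$variant == "ff") .run_ff_batch else .run_pc_batch
  fn(model, trials, sigma, protocol, record = FALSE)
}

#' Run a single trial with full rate trajectories
#'
#' @inheritParams run_trials
#' @param trial One-row trial table (see [as_trials()]).
#' @return List with `result` (one-row data frame as in [run_trials()]) and
#'   `traces` (data frame of unit rates by time; time 0 is stimulus onset).
#' @export
run_trial <- function(model, trial, sigma = 0, protocol = trial_protocol(),
                      seed = NULL) {
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  fn <- if (model$variant == "ff") .run_ff_batch else .run_pc_batch
  res <- fn(model, trial[1, , drop = FALSE], sigma, protocol, record = TRUE)
  list(result = res, traces = attr(res, "traces"))
}

#' Reaction-time summary per cue condition
#'
#' @param results Trial results from [run_trials()].
#' @return Data frame with `cue`, `mean_rt_ms`, `sd_rt_ms`, `n` (unresolved
#'   trials excluded).
#' @export
rt_summary <- function(results) {
  ok <- results[results$choice != "none", ]
  if (nrow(ok) == 0) stop("no resolved trials")
  out <- do.call(rbind, lapply(split(ok, ok$cue), function(d)
    data.frame(cue = d$cue[1], mean_rt_ms = mean(d$rt_ms),
               sd_rt_ms = stats::sd(d$rt_ms), n = nrow(d))))
  rownames(out) <- NULL
  out
}

#' Winner-versus-difficulty analysis (prosaccade trials)
#'
#' Bins prosaccade trials by stimulus difficulty `|x_left - x_right|` and
#' tabulates which pathway drove each decision. The choice ratio is
#' cortex-driven over subcortex-driven choices (undefined when no
#' subcortex-driven choice falls in a bin).
#'
#' @param results Trial results from [run_trials()]; prosaccade trials only.
#' @param breaks Difficulty bin edges (default width 0.1 over `[0, 1]`).
#' @return Data frame per bin: counts, choice ratio, and mean RT per winner.
#' @export
difficulty_analysis <- function(results, breaks = seq(0, 1, 0.1)) {
  if (any(results$cue != "pro"))
    stop("difficulty analysis is defined for prosaccade trials only")
  bin <- cut(results$difficulty, breaks, include.lowest = TRUE)
  out <- do.call(rbind, lapply(levels(bin), function(b) {
    d <- results[!is.na(bin) & bin == b, ]
    ncx <- sum(d$winner == "cortex")
    nsx <- sum(d$winner == "subcortex")
    data.frame(bin = b, n = nrow(d), cortex_wins = ncx,
               subcortex_wins = nsx,
               choice_ratio = if (nsx > 0) ncx / nsx else NA_real_,
               rt_cortex_ms = if (ncx > 0)
                 mean(d$rt_ms[d$winner == "cortex"]) else NA_real_,
               rt_subcortex_ms = if (nsx > 0)
                 mean(d$rt_ms[d$winner == "subcortex"]) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
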