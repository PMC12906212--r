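test_that("inference descends the prediction-error energy", {
  w <- pc_init_weights(3)
  # zero frame with decay prior: latents stay at the origin
  st0 <- pc_infer(w, matrix(0, 16, 32))
  expect_equal(max(abs(st0$r1)), 0)
  expect_equal(max(abs(st0$r2)), 0)

  set.seed(9)
  frames <- lapply(1:20, function(i) matrix(runif(512), 16, 32))
  st <- pc_infer(w, frames)
  expect_true(all(diff(st$energy) <= 1e-9))
  expect_lt(st$energy[length(st$energy)], st$energy[1])
})

test_that("the 1-D fixed point matches the normal equations", {
  # scalar layers, U1 = U2 = 1, no decay:
  # E = (x - r1)^2 + (r1 - r2)^2; grad = 0 gives the 2x2 system
  #   2 r1 - r2 = x ; -r1 + r2 = 0
  w <- list(U1 = matrix(1, 1, 1), U2 = matrix(1, 1, 1))
  x <- 0.73
  exact <- solve(rbind(c(2, -1), c(-1, 1)), c(x, 0))
  hy <- pc_hyper(inference_rate = 0.2, inference_iters = 200,
                 prior_decay = 0)
  st <- pc_infer(w, matrix(x, 1, 1), hy)
  expect_equal(as.numeric(st$r1), exact[1], tolerance = 1e-6)
  expect_equal(as.numeric(st$r2), exact[2], tolerance = 1e-6)
})

test_that("local learning shrinks reconstruction error and is seeded", {
  pcw <- get_pc_model()$pc
  log <- pcw$log
  expect_lt(log$recon_mse[nrow(log)], 0.1 * log$recon_mse[1])

  a <- pc_learn(hyper = pc_hyper(epochs = 3), seed = 8)
  b <- pc_learn(hyper = pc_hyper(epochs = 3), seed = 8)
  expect_identical(a$U1, b$U1)
  expect_identical(a$U2, b$U2)
})

test_that("a single repeated frame is reconstructed almost exactly", {
  one <- data.frame(x_left = 0.7, x_right = 0.2, difficulty = 0.5)
  w <- pc_learn(one, pc_hyper(epochs = 300, learning_rate = 0.05),
                seed = 2, cue_oversample = 0)
  f <- render_stimulus(0.7, 0.2)
  st <- pc_infer(w, f, w$hyper)
  rec <- reconstruct_from_layer(w, st, 1)
  expect_lt(max(abs(as.numeric(f) - as.numeric(rec))), 0.05)
})

test_that("hierarchical reconstructions recover held-out stimuli", {
  m <- get_pc_model()
  ts <- get_test_pairs(20, 13)
  r1s <- numeric(0); r2s <- numeric(0)
  for (i in seq_len(10)) {
    f <- render_stimulus(ts$x_left[i], ts$x_right[i])
    st <- pc_infer(m$pc, f, m$pc$hyper)
    rec1 <- reconstruct_from_layer(m$pc, st, 1)
    rec2 <- reconstruct_from_layer(m$pc, st, 2)
    expect_equal(dim(rec2), c(16L, 32L))
    r1s <- c(r1s, cor(as.numeric(f), as.numeric(rec1)))
    r2s <- c(r2s, cor(as.numeric(f), as.numeric(rec2)))
  }
  expect_true(all(r1s > 0.5))
  expect_true(all(r2s > 0.5))
  expect_error(reconstruct_from_layer(m$pc, st, 3), "layer")

  # the layer-1 reconstruction of a cue screen peaks on the cue bar
  cue <- render_cue("pro")
  stc <- pc_infer(m$pc, cue, m$pc$hyper)
  recc <- reconstruct_from_layer(m$pc, stc, 1)
  top2 <- order(as.numeric(recc), decreasing = TRUE)[1:2]
  expect_setequal(top2, which(as.numeric(cue) > 0))
})

test_that("the latent classifier reads rule and side from top latents", {
  m <- get_pc_model()
  sc <- classify_latent(m$classifier,
                        pc_infer(m$pc, render_cue("pro"),
                                 m$pc$hyper)$r2[, 1])
  expect_equal(names(which.max(sc)), "P")
  sc <- classify_latent(m$classifier,
                        pc_infer(m$pc, render_stimulus(0.2, 0.9),
                                 m$pc$hyper)$r2[, 1])
  expect_equal(names(which.max(sc)), "R")
  z <- classify_latent(m$classifier, rep(0, 16))
  expect_true(all(is.finite(z)))
  expect_error(classify_latent(m$classifier, rep(0, 5)), "16")
})

test_that("side classification stays above 0.75 under noise", {
  m <- get_pc_model()
  ts <- get_test_pairs(200, 7)
  truth <- ifelse(ts$x_left > ts$x_right, "L", "R")
  set.seed(55)
  for (sg in c(0, 0.1, 0.2)) {
    frames <- Map(function(l, r) add_noise(render_stimulus(l, r), sg),
                  ts$x_left, ts$x_right)
    p <- classify_latent(m$classifier,
                         pc_infer(m$pc, frames, m$pc$hyper)$r2)
    expect_gt(mean(colnames(p)[max.col(p)] == truth), 0.75)
  }
  for (sg in c(0, 0.1, 0.2)) {
    cues <- rep(c("pro", "anti"), 50)
    fc <- lapply(cues, function(cu) add_noise(render_cue(cu), sg))
    p <- classify_latent(m$classifier,
                         pc_infer(m$pc, fc, m$pc$hyper)$r2)
    expect_gt(mean(colnames(p)[max.col(p)] ==
                     ifelse(cues == "pro", "P", "A")), 0.75)
  }
})

test_that("self-recurrent cue neurons latch, sustain, and gate correctly", {
  p <- rate_params()
  run_protocol <- function(w_self, drive_ms = 200, after_ms = 500) {
    cn <- cue_neurons(w_self = w_self)
    for (k in seq_len(drive_ms / 10)) cn <- sustain_cue(cn, c(1, 0), p)
    peak <- cn$p_rate
    for (k in seq_len(after_ms / 10)) cn <- sustain_cue(cn, c(0, 0), p)
    c(peak = peak, later = cn$p_rate, other = cn$a_rate)
  }
  r <- run_protocol(1.2)
  expect_gte(r["later"], 0.5 * r["peak"])  # sustained after drive removal
  expect_lt(r["other"], 1e-6)              # undriven neuron stays silent

  # below the sustain bifurcation the latch decays (negative control)
  r0 <- run_protocol(0.8)
  expect_lt(r0["later"], 0.1 * r0["peak"])

  # never driven: stays at zero
  cn <- cue_neurons()
  for (k in 1:100) cn <- sustain_cue(cn, c(0, 0), p)
  expect_equal(cn$p_rate, 0)
  expect_equal(cn$a_rate, 0)

  # the sustain/decay boundary sits at the piecewise-linear bifurcation:
  # scan w_self and locate the transition numerically
  sustained <- vapply(c(0.7, 0.9, 1.1, 1.3), function(w)
    run_protocol(w)["later"] > 0.25, logical(1))
  expect_equal(unname(sustained), c(FALSE, FALSE, TRUE, TRUE))
})
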