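test_that("activation functions behave as specified", {
  expect_equal(apply_activation("relu", c(-1, 2)), c(0, 2))
  expect_equal(apply_activation("softmax", c(5, 5)), c(0.5, 0.5))
  sm <- apply_activation("softmax", c(2, 0))
  expect_equal(sm, c(exp(2), 1) / (exp(2) + 1))
  expect_equal(round(sm, 3), c(0.881, 0.119))
  expect_equal(sum(sm), 1)
  expect_equal(apply_activation("identity", c(-3, 7)), c(-3, 7))
  expect_equal(apply_activation("bounded_relu", c(-1, 0.4, 3)),
               c(0, 0.4, 1))
  expect_error(apply_activation("tanh", 1), "unknown")
})

test_that("a single Euler step matches the update rule", {
  p <- rate_params(tau = 0.1, dt = 0.01, activation = "identity")
  st <- list(rates = 0, time = 0)
  # constant unit drive: r' = 0 + (0.01/0.1) * (1 - 0) = 0.1
  out <- euler_step(st, list(bias = 1), p)
  expect_equal(out$rates, 0.1)
  expect_equal(out$time, 0.01)
  expect_equal(st$rates, 0)  # input unmodified

  # a state at its fixed point stays there
  fp <- euler_step(list(rates = 1, time = 0), list(bias = 1), p)
  expect_equal(fp$rates, 1)

  expect_error(euler_step(list(rates = c(0, 0), time = 0),
                          list(bias = 0, W = matrix(1, 2, 3),
                               r_pre = c(1, 1)), p),
               "shape")
  expect_error(euler_step(st, list(bias = Inf), p), "finite")
  expect_error(rate_params(tau = 0.05, dt = 0.1))
})

test_that("Euler integration converges to the linear ODE at order 1", {
  # constant drive u, identity activation: r(t) = u (1 - exp(-t / tau))
  relax <- function(dt, t_end = 0.5, u = 1, tau = 0.1) {
    r <- 0
    for (k in seq_len(round(t_end / dt))) r <- r + (dt / tau) * (u - r)
    r
  }
  exact <- 1 - exp(-0.5 / 0.1)
  e1 <- abs(relax(0.01) - exact)
  e2 <- abs(relax(0.005) - exact)
  e3 <- abs(relax(0.0025) - exact)
  expect_lt(e1, 0.05)
  expect_gt(e1 / e2, 1.5); expect_lt(e1 / e2, 3)
  expect_gt(e2 / e3, 1.5); expect_lt(e2 / e3, 3)
})

test_that("simulate advances populations synchronously and records steps", {
  p <- rate_params(activation = "relu")
  pops <- list(a = list(rates = 0, params = p, bias = 2, inputs = list()))
  tr <- simulate(pops, duration = 0.5)
  expect_equal(nrow(tr$a), 50L)
  expect_true(all(diff(tr$a[, 1]) > 0))        # monotone relaxation
  expect_lt(abs(tr$a[50, 1] - 2 * (1 - exp(-5))), 0.05)

  # determinism: bit-identical repeat
  expect_identical(simulate(pops, 0.2), simulate(pops, 0.2))
  expect_error(simulate(list(a = list(rates = 0, params = p, bias = 0,
                                      inputs = list(list(from = "ghost",
                                                         W = matrix(1))))),
                        0.1), "dangling")
})

test_that("mutual inhibition resolves toward the analytic fixed point", {
  # two linear units with symmetric inhibition: r = b - w * r_other,
  # solved exactly by a 2x2 linear system (independent of the integrator)
  b <- c(1.0, 0.8); w <- 0.5
  A <- rbind(c(1, w), c(w, 1))
  fp <- solve(A, b)
  p <- rate_params(activation = "identity")
  W <- matrix(c(0, -w, -w, 0), 2, 2, byrow = TRUE)
  pops <- list(duo = list(rates = c(0, 0), params = p, bias = b,
                          inputs = list(list(from = "duo", W = W))))
  tr <- simulate(pops, duration = 2)
  expect_equal(unname(tr$duo[200, ]), unname(fp), tolerance = 1e-3)
  expect_gt(tr$duo[200, 1], tr$duo[200, 2])  # larger input wins
})

test_that("normalized pairs stay in (0,1) and bounded activations bound rates", {
  p <- rate_params(activation = "softmax")
  set.seed(21)
  for (rep in 1:10) {
    b <- rnorm(2, 0, 3)
    pops <- list(pair = list(rates = runif(2), params = p, bias = b,
                             inputs = list()))
    tr <- simulate(pops, 1)
    expect_true(all(tr$pair >= 0 & tr$pair <= 1))
  }
})

test_that("threshold crossing matches the closed-form relaxation time", {
  # a normalized pair relaxing from 0 toward constant output p crosses
  # 0.55 at t = -tau * log(1 - 0.55 / p)
  p_act <- rate_params(activation = "softmax")
  for (ptarget in c(1, 0.8, 0.7)) {
    drive <- if (ptarget == 1) c(50, 0)
             else c(log(ptarget / (1 - ptarget)), 0)
    pops <- list(pair = list(rates = c(0, 0), params = p_act, bias = drive,
                             inputs = list()))
    tr <- simulate(pops, 1)
    t_obs <- crossing_time(tr$pair[, 1], 0.55, 0.01)
    t_exact <- -0.1 * log(1 - 0.55 / ptarget)
    expect_lt(abs(t_obs - t_exact), 0.011)
  }
  # p = 1 crossing near 79.9 ms
  pops <- list(pair = list(rates = c(0, 0), params = p_act, bias = c(50, 0),
                           inputs = list()))
  tr <- simulate(pops, 0.5)
  expect_equal(crossing_time(tr$pair[, 1]), 0.08, tolerance = 0.02)
  expect_true(is.na(crossing_time(c(0.1, 0.2, 0.3))))
})
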