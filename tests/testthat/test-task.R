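test_that("cue and stimulus screens are pixel-exact", {
  pro <- render_cue("pro")
  anti <- render_cue("anti")
  expect_equal(dim(pro), c(16L, 32L))
  expect_equal(sum(pro), 2)
  expect_equal(sum(anti), 2)
  expect_equal(sum(pro > 0), 2L)
  expect_equal(sum(anti > 0), 2L)
  # horizontal bar: both lit pixels on one row; vertical: one column
  expect_equal(length(unique(which(pro > 0, arr.ind = TRUE)[, "row"])), 1L)
  expect_equal(length(unique(which(anti > 0, arr.ind = TRUE)[, "col"])), 1L)

  f <- render_stimulus(1, 0)
  expect_equal(sum(f == 1), 16L)
  expect_equal(sum(f), 16)
  f2 <- render_stimulus(0.5, 0.5)
  expect_equal(sum(f2 > 0), 32L)
  expect_equal(sum(f2), 16)
  expect_error(render_stimulus(1.2, 0), "\\[0, 1\\]")
  # rendering is idempotent / deterministic
  expect_identical(render_stimulus(0.3, 0.7), render_stimulus(0.3, 0.7))
})

test_that("training set enumerates the 0.1 grid with side labels", {
  tr <- make_training_set()
  expect_equal(nrow(tr), 121L)
  expect_equal(sum(tr$correct_pro == "undefined"), 11L)
  expect_equal(sum(tr$correct_pro == "left"), 55L)
  expect_equal(sum(tr$correct_pro == "right"), 55L)
  expect_true(all(abs(tr$x_left * 10 - round(tr$x_left * 10)) < 1e-12))
  expect_equal(tr$difficulty, abs(tr$x_left - tr$x_right))
  # flipping the cue flips the correct side on every non-diagonal pair
  nd <- tr[tr$correct_pro != "undefined", ]
  expect_true(all(ifelse(nd$correct_pro == "left", "right", "left") ==
                    nd$correct_anti))
  expect_true(all(tr$correct_anti[tr$correct_pro == "undefined"] ==
                    "undefined"))
})

test_that("test sets are balanced, tie-free, and reproducible", {
  for (n in c(2L, 100L, 1000L)) {
    ts <- make_test_set(n, seed = 3)
    expect_equal(nrow(ts), n)
    expect_equal(sum(ts$correct_pro == "left"), n / 2)
    expect_equal(sum(ts$correct_pro == "right"), n / 2)
    expect_true(all(ts$x_left != ts$x_right))
  }
  expect_identical(make_test_set(50, 9), make_test_set(50, 9))
  expect_false(identical(make_test_set(50, 9), make_test_set(50, 10)))
  expect_error(make_test_set(7, 1), "even")
  # the 0.01 grid holds 101^2 - 101 = 10100 off-diagonal pairs
  expect_equal(nrow(make_test_set(10100, 1)), 10100L)
  expect_error(make_test_set(10102, 1), "exceeds")
})

test_that("as_trials resolves correct side under the given cue", {
  pairs <- data.frame(x_left = c(0.9, 0.2, 0.5),
                      x_right = c(0.1, 0.8, 0.5),
                      difficulty = c(0.8, 0.6, 0))
  pro <- as_trials(pairs, "pro")
  anti <- as_trials(pairs, "anti")
  expect_equal(pro$correct_side, c("left", "right", "undefined"))
  expect_equal(anti$correct_side, c("right", "left", "undefined"))
  expect_error(as_trials(pairs, "sideways"))
})

test_that("additive noise is Gaussian, unclipped, and seed-reproducible", {
  f <- render_stimulus(0.5, 0.5)
  expect_identical(add_noise(f, 0), f)
  expect_error(add_noise(f, -0.1), "nonnegative")

  z <- render_stimulus(0, 0)
  set.seed(11)
  big <- replicate(40, add_noise(z, 0.1))
  n <- length(big)
  expect_lt(abs(sd(big) - 0.1), 3 * 0.1 / sqrt(2 * n))
  expect_lt(min(big), 0)  # not clipped at zero

  set.seed(5); a <- add_noise(f, 0.05)
  set.seed(5); b <- add_noise(f, 0.05)
  expect_identical(a, b)
})

test_that("frames and trial tables round-trip through CSV", {
  f <- render_stimulus(0.25, 0.75)
  p <- tempfile(fileext = ".csv")
  write_frame_csv(f, p)
  back <- as.matrix(utils::read.csv(p, header = FALSE))
  expect_equal(unname(back), matrix(as.numeric(f), 16, 32))

  trl <- as_trials(make_test_set(10, 2), "pro")
  p2 <- tempfile(fileext = ".csv")
  write_trials_csv(trl, p2)
  back2 <- utils::read.csv(p2)
  expect_equal(back2$x_left, trl$x_left)
  expect_equal(back2$correct_side, trl$correct_side)
})
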