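test_that("easy prosaccades are subcortex-led and antisaccades cortex-led", {
  m <- get_ff_model()
  pair <- data.frame(x_left = 0.9, x_right = 0.1, difficulty = 0.8)
  pro <- run_trial(m, as_trials(pair, "pro"))
  expect_equal(pro$result$choice, "left")
  expect_equal(pro$result$winner, "subcortex")
  expect_true(pro$result$correct)

  anti <- run_trial(m, as_trials(pair, "anti"))
  expect_equal(anti$result$choice, "right")
  expect_equal(anti$result$winner, "cortex")
  expect_true(anti$result$correct)

  # traces are aligned to stimulus onset and stay in (0,1) for pairs
  expect_equal(min(pro$traces$time), -0.49)
  expect_true(all(pro$traces[, c("M1", "M2")] >= 0 &
                    pro$traces[, c("M1", "M2")] <= 1))
})

test_that("with both pathways silenced no motor unit ever crosses", {
  m <- get_ff_model()
  m$gains <- ff_gains(class = 0, cortex = 0, sub_beta = 0, inhib = 0,
                      motor = 0)
  res <- run_trials(m, as_trials(
    data.frame(x_left = 0.9, x_right = 0.1, difficulty = 0.8), "pro"))
  expect_equal(res$choice, "none")
  expect_true(is.na(res$rt_ms))
  expect_equal(res$winner, "none")
})

test_that("reaction times are positive multiples of the Euler step", {
  m <- get_ff_model()
  ts <- get_test_pairs(60, 5)
  res <- run_trials(m, as_trials(ts, c("pro", "anti")))
  rt <- res$rt_ms[!is.na(res$rt_ms)]
  expect_true(all(rt >= 10))
  expect_true(all(abs(rt / 10 - round(rt / 10)) < 1e-9))
})

test_that("prosaccades are faster than antisaccades in both variants", {
  ts <- get_test_pairs(200, 41)
  for (m in list(get_ff_model(), get_pc_model())) {
    res <- rbind(run_trials(m, as_trials(ts, "pro"), seed = 1),
                 run_trials(m, as_trials(ts, "anti"), seed = 2))
    s <- rt_summary(res)
    expect_lt(s$mean_rt_ms[s$cue == "pro"], s$mean_rt_ms[s$cue == "anti"])
    expect_gte(min(s$n), 190)
  }
})

test_that("rt_summary excludes unresolved trials and handles single trials", {
  res <- data.frame(cue = c("pro", "pro", "anti"),
                    choice = c("left", "none", "right"),
                    rt_ms = c(100, NA, 140))
  s <- rt_summary(res)
  expect_equal(s$mean_rt_ms[s$cue == "pro"], 100)
  expect_equal(s$sd_rt_ms[s$cue == "pro"], NA_real_)
  expect_equal(s$n, c(1L, 1L))
  expect_error(rt_summary(res[res$choice == "none", ]), "resolved")
})

test_that("winner attribution is consistent with module crossing order", {
  m <- get_pc_model()
  ts <- get_test_pairs(200, 41)
  res <- run_trials(m, as_trials(ts, "pro"), sigma = 0.05, seed = 3)
  sub <- res[res$winner == "subcortex", ]
  expect_true(all(is.na(sub$rt_cortex_ms) |
                    sub$rt_subcortex_ms <= sub$rt_cortex_ms))
  cx <- res[res$winner == "cortex", ]
  expect_true(all(is.na(cx$rt_subcortex_ms) |
                    cx$rt_cortex_ms <= cx$rt_subcortex_ms))
})

test_that("difficulty analysis bins, guards, and ratio conventions hold", {
  fake <- data.frame(cue = "pro",
                     difficulty = c(0.05, 0.05, 0.55, 0.95),
                     winner = c("subcortex", "subcortex", "subcortex",
                                "cortex"),
                     rt_ms = c(100, 110, 120, 130))
  da <- difficulty_analysis(fake)
  expect_equal(nrow(da), 10L)
  expect_equal(da$n[1], 2L)
  expect_equal(da$choice_ratio[1], 0)          # all subcortex: ratio 0
  expect_true(is.na(da$choice_ratio[10]))      # zero denominator: undefined
  expect_equal(da$n[3], 0L)                    # empty bin reported as n = 0
  expect_error(difficulty_analysis(transform(fake, cue = "anti")),
               "prosaccade")
})
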