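pd <- pd_params(360)

test_that("pd_params derives sample-count constants from ms definitions", {
  expect_equal(pd$window_samples, 93L)
  expect_equal(pd$refractory_samples, 93L)
  expect_equal(pd$search_radius, 15L)
  p250 <- pd_params(250)
  expect_equal(p250$window_samples, 65L)        # floor(0.26 * 250)
  expect_equal(p250$search_radius, 10L)         # round(15 * 250/360)
  expect_error(pd_params(360, a = 1.5), "a")
  expect_error(pd_params(360, th_min = 0), "th_min")
})

test_that("init_state follows the startup rule", {
  s <- c(rep(0.2, 100), 2.0, rep(0.2, 1000))    # first-2-s max is 2.0
  st <- init_state(s, pd)
  expect_equal(st$th_prev, 1.0)
  expect_equal(st$th_cur, 1.0)
  expect_equal(st$th_next, 1.0 - 0.5 * (1.0 - 0.15))  # one recursion step

  flat <- init_state(numeric(500), pd)          # all-zero s floors at th_min
  expect_equal(flat$th_prev, 0.15)
  expect_equal(flat$th_cur, 0.15)
})

test_that("advance_threshold mirrors the per-window recursion tail", {
  # the floor is a fixed point
  floor_st <- init_state(numeric(500), pd)
  adv <- advance_threshold(floor_st, pd)
  expect_equal(c(adv$th_prev, adv$th_cur, adv$th_next), rep(0.15, 3))

  # hand-evaluated step: (1, 1, 0.575) -> (1, 0.575, 0.405)
  st <- structure(list(th_prev = 1, th_cur = 1, th_next = 0.575),
                  class = "threshold_state")
  st2 <- advance_threshold(st, pd)
  expect_equal(st2$th_prev, 1)
  expect_equal(st2$th_cur, 0.575)
  expect_equal(st2$th_next, 0.575 - 0.5 * 0.425 - 0.1 * (-0.425))
})

test_that("recursion matches the literal oracle and decays to the floor", {
  th <- oracle_pd_iterate(30)
  st <- structure(list(th_prev = th[1, "th1"], th_cur = th[1, "th2"],
                       th_next = th[1, "th3"]),
                  class = "threshold_state")
  for (w in 1:30) {
    st <- advance_threshold(st, pd)
    expect_equal(unname(unlist(st[c("th_prev", "th_cur", "th_next")])),
                 unname(th[w + 1, ]), tolerance = 1e-12)
  }
  # within 0.01 of the floor in at most 20 windows, never below it
  expect_true(all(th >= 0.15 - 1e-15))
  expect_lt(abs(th[20 + 1, "th2"] - 0.15), 0.01)
})

test_that("the floor and boundedness survive randomized state machines", {
  set.seed(2024)
  for (trial in 1:50) {
    st <- structure(as.list(setNames(0.15 + runif(3, 0, 4),
                                     c("th_prev", "th_cur", "th_next"))),
                    class = "threshold_state")
    for (step in 1:40) {
      before <- unlist(st[c("th_prev", "th_cur", "th_next")])
      if (runif(1) < 0.3) {
        st <- register_detection(st, runif(1, 0.15, 6), pd)
      }
      st <- advance_threshold(st, pd)
      expect_true(all(unlist(st[c("th_prev", "th_cur", "th_next")]) >=
                        0.15 - 1e-12))
      expect_lte(st$th_next, max(before, st$th_cur, 0.15) + 1e-12)
    }
  }
})

test_that("point_threshold interpolates linearly across the window", {
  st <- structure(list(th_prev = 2, th_cur = 1.0, th_next = 0.5),
                  class = "threshold_state")
  expect_equal(point_threshold(st, 0, 93), 1.0)
  expect_equal(point_threshold(st, 93, 93), 0.5)
  expect_equal(point_threshold(st, 46.5, 93), 0.75)
  expect_error(point_threshold(st, -1, 93), ">= 0")
})

test_that("screen_window applies the M-times test and picks the largest s", {
  st <- structure(list(th_prev = 1, th_cur = 1, th_next = 1),
                  class = "threshold_state")

  none <- screen_window(integer(0), numeric(100), st, pd)
  expect_false(none$detected)

  s <- numeric(200)
  s[51] <- 10
  one <- screen_window(50L, s, st, pd, window_origin = 40L)
  expect_true(one$detected)                     # 10 > 1.5 * ~1
  expect_equal(one$peak_index, 50L)
  expect_equal(one$peak_feature, 10)

  s[121] <- 5                                   # two qualifying extremes:
  s[51] <- 3                                    # s 3.0 and 5.0
  two <- screen_window(c(50L, 120L), s, st, pd, window_origin = 40L)
  expect_equal(two$peak_index, 120L)            # the larger s wins
  expect_equal(two$peak_feature, 5)

  # the +/-15 search: s peak sits 12 samples after the extreme point
  s2 <- numeric(200)
  s2[63] <- 10
  off <- screen_window(50L, s2, st, pd, window_origin = 40L)
  expect_true(off$detected)
  expect_equal(off$peak_feature, 10)
})

test_that("register_detection reproduces the detection-branch arithmetic", {
  st <- structure(list(th_prev = 1, th_cur = 0.5, th_next = 0.3),
                  class = "threshold_state")
  reg <- register_detection(st, 4.0, pd)
  expect_equal(reg$th_cur, 4.0)
  expect_equal(reg$th_next, 4.0 - 0.5 * (4.0 - 0.15) - 0.1 * (4.0 - 1.0))

  reg2 <- register_detection(st, 0.15, pd)      # peak at the floor
  expect_equal(reg2$th_next, 0.15 - 0.1 * (0.15 - 1.0))

  st3 <- structure(list(th_prev = 2, th_cur = 2, th_next = 1),
                   class = "threshold_state")
  reg3 <- register_detection(st3, 2, pd)        # b-term vanishes
  expect_equal(reg3$th_next, 2 - 0.5 * (2 - 0.15))

  expect_error(register_detection(st, 0, pd), "positive")
})
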