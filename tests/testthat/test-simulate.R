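test_that("signal constructors produce the documented shapes", {
  expect_equal(make_signal("teeth", 10, jump = 1, segment_length = 5),
               c(rep(0, 5), rep(1, 5)))
  expect_equal(true_changepoints(make_signal("teeth", 10, jump = 1,
                                             segment_length = 5)), 5L)
  expect_equal(make_signal("constant", 5, level = 2), rep(2, 5))
  expect_equal(make_signal("custom", 5, breakpoints = 3, levels = c(0, 2)),
               c(0, 0, 0, 2, 2))
  # teeth with spacing L has floor((T-1)/L) change-points at multiples of L
  f <- make_signal("teeth", 500, jump = 4, segment_length = 5)
  cp <- true_changepoints(f)
  expect_equal(length(cp), 99L)
  expect_equal(cp, seq(5L, 495L, by = 5L))
  expect_equal(make_signal("extreme_teeth", 12)[6], 1)
  expect_error(make_signal("custom", 5, breakpoints = c(3, 2),
                           levels = c(0, 1, 2)), class = "wbs2sdll_input_error")
  expect_error(make_signal("custom", 5, breakpoints = 3, levels = 0),
               class = "wbs2sdll_input_error")
})

test_that("noise generation is seeded, scaled and median-centred", {
  f <- make_signal("constant", 1e4)
  expect_equal(add_noise(f, "gaussian", sigma = 0), f)
  expect_identical(add_noise(f, "student_t", df = 2, seed = 5),
                   add_noise(f, "student_t", df = 2, seed = 5))
  sd_hat <- sd(add_noise(f, "gaussian", sigma = 1, seed = 6) - f)
  expect_gt(sd_hat, 0.95); expect_lt(sd_hat, 1.05)
  # heavy-tailed families still have median ~0
  expect_lt(abs(median(add_noise(f, "cauchy", seed = 7))), 0.05)
  # heteroskedastic schedule must be positive and full length
  sched <- seq(0.5, 2, length.out = 1e4)
  x <- add_noise(f, "heteroskedastic_gaussian", sigma = sched, seed = 8)
  expect_gt(sd(x[9001:10000]), sd(x[1:1000]))
  expect_error(add_noise(f, "heteroskedastic_gaussian", sigma = 1),
               class = "wbs2sdll_input_error")
})

test_that("simulate_series returns a tidy frame pairing signal and data", {
  d <- simulate_series("teeth", 100, segment_length = 10, jump = 3, seed = 1)
  expect_s3_class(d, "tbl_df")
  expect_named(d, c("t", "signal", "value"))
  expect_equal(nrow(d), 100L)
  expect_identical(d, simulate_series("teeth", 100, segment_length = 10,
                                      jump = 3, seed = 1))
})

test_that("SETAR paths are stationary-regime, seeded and regime-switching", {
  # noiseless path started at 0 falls to the lower-regime fixed point c1/(1-a1)
  x0 <- setar_path(50, noise_sd = 0)
  expect_equal(x0[50], -2, tolerance = 1e-9)
  expect_identical(setar_path(500, seed = 3), setar_path(500, seed = 3))
  # with defaults both regimes are visited a nontrivial fraction of the time
  occ <- vapply(1:20, function(i) mean(setar_path(500, seed = i) <= 0),
                numeric(1))
  expect_gt(mean(occ), 0.2); expect_lt(mean(occ), 0.8)
  expect_error(setar_path(100, a1 = 1.2), class = "wbs2sdll_input_error")
})

test_that("random walks cumulate seeded Gaussian steps", {
  expect_equal(random_walk(10, step_sd = 0), rep(0, 10))
  expect_identical(random_walk(100, seed = 4), random_walk(100, seed = 4))
  v <- var(diff(random_walk(1e4, step_sd = 1, seed = 5)))
  expect_gt(v, 0.95); expect_lt(v, 1.05)
})

test_that("the synthetic epidemic series peaks then decays with weekly pattern", {
  d <- sim_epidemic_series(150, seed = 11)
  expect_equal(nrow(d), 150L)
  expect_true(all(d$value >= 0))
  peak <- which.max(d$trend)
  expect_gte(peak, 25); expect_lte(peak, 40)
  expect_gt(mean(d$value[25:40]), mean(d$value[130:150]))
  # period-7 structure: day-of-week means differ markedly around the peak
  dw <- tapply(d$value[15:112], ((15:112 - 1) %% 7), mean)
  expect_gt(max(dw) / min(dw), 1.2)
})
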