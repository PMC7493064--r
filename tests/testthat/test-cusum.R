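test_that("cusum_at matches hand-computed contrasts", {
  expect_equal(cusum_at(c(0, 0, 1, 1), 1, 4, 2), -1.0)
  expect_equal(cusum_at(c(0, 2), 1, 2, 1), -sqrt(2))
  expect_equal(cusum_at(rep(7.3, 6), 1, 6, 3), 0)
  # vectorised over splits, against the mean-form oracle
  x <- c(2, -1, 0.5, 4, 4, -3, 1)
  expect_equal(cusum_at(x, 2, 7, 2:6),
               vapply(2:6, function(b) oracle_cusum(x, 2, 7, b), numeric(1)))
})

test_that("cusum_at is location invariant and scale equivariant", {
  withr::local_seed(11)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    x <- rnorm(n)
    s <- sample1(seq_len(n - 1))
    e <- sample1((s + 1):n)
    b <- sample1(s:(e - 1))
    cc <- rnorm(1, sd = 10)
    aa <- rnorm(1, sd = 3)
    base <- cusum_at(x, s, e, b)
    expect_equal(cusum_at(x + cc, s, e, b), base, tolerance = 1e-10)
    expect_equal(cusum_at(aa * x, s, e, b), aa * base, tolerance = 1e-10)
  }
})

test_that("cusum_at rejects splits outside the interval", {
  expect_error(cusum_at(1:5, 2, 4, 4), class = "wbs2sdll_input_error")
  expect_error(cusum_at(1:5, 2, 4, 1), class = "wbs2sdll_input_error")
  expect_error(cusum_at(1:5, 4, 4, 4), class = "wbs2sdll_input_error")
})

test_that("max_cusum finds the exhaustive maximiser with smallest-b ties", {
  res <- max_cusum(c(0, 0, 1, 1), 1, 4)
  expect_equal(res$b, 2L)
  expect_equal(res$magnitude, 1.0)
  # constant segment: all contrasts zero, tie resolved to b = start
  res0 <- max_cusum(rep(2, 8), 2, 7)
  expect_equal(res0$b, 2L)
  expect_equal(res0$magnitude, 0)
  # length-2 interval has a single candidate
  expect_equal(max_cusum(rnorm(10), 4, 5)$b, 4L)
  # splits 2 and 4 tie exactly (|mean difference| 0.5 both sides); smaller wins
  tie <- max_cusum(c(0, 0, 1, 1, 0, 0), 1, 6)
  expect_equal(tie$b, 2L)
  expect_equal(tie$magnitude, sqrt(8 / 6) * 0.5)
})

test_that("max_cusum agrees with brute force for both variants", {
  withr::local_seed(21)
  for (rep in 1:40) {
    n <- sample(4:30, 1)
    x <- round(rnorm(n), 2)  # rounding induces frequent exact ties
    for (variant in c("standard", "robust")) {
      got <- max_cusum(x, 1, n, variant = variant)
      want <- oracle_max_cusum(x, 1, n, robust = variant == "robust")
      expect_equal(got$b, want$b)
      expect_equal(got$contrast, want$contrast, tolerance = 1e-12)
    }
  }
})

test_that("sign_transform applies the median-centred sign convention", {
  expect_equal(sign_transform(c(3, 1, 2), 1, 3), c(1, -1, 0))
  expect_equal(sign_transform(rep(4, 5), 1, 5), rep(0, 5))
  expect_equal(sign_transform(c(1, 2, 3, 4), 1, 4), c(-1, -1, 1, 1))
})

test_that("sign transform bounds every robust CUSUM magnitude by sqrt(n)", {
  withr::local_seed(31)
  for (rep in 1:20) {
    n <- sample(3:50, 1)
    x <- rcauchy(n)  # arbitrarily heavy tails
    expect_true(all(sign_transform(x, 1, n) %in% c(-1, 0, 1)))
    expect_lte(max_cusum(x, 1, n, variant = "robust")$magnitude, sqrt(n) + 1e-12)
  }
})

test_that("sharpness score separates decaying peaks from flat profiles", {
  # |CUSUM| of (0,0,1,1) increases from b=1 to b=2: no decay to the right of b=1
  expect_equal(sharpness_score(c(0, 0, 1, 1), 1, 4, 1, 1), 0)
  # zero contrast is defined as score 0
  expect_equal(sharpness_score(rep(1, 10), 1, 10, 5, 3), 0)
  # exact single step scores 1 at the change with the full offset window
  x <- c(rep(0, 10), rep(1, 10))
  expect_equal(sharpness_score(x, 1, 20, 10, 10), 1)
  # and stays high for smaller windows while a mid-noise-free split elsewhere decays
  expect_gt(sharpness_score(x, 1, 20, 10, 5), 0.5)
  expect_error(sharpness_score(x, 1, 20, 10, 11), class = "wbs2sdll_input_error")
  expect_error(sharpness_score(x, 1, 20, 18, 3), class = "wbs2sdll_input_error")
})

test_that("max_cusum_batch reproduces per-interval calls", {
  withr::local_seed(41)
  x <- rnorm(60)
  ivs <- random_intervals(1, 60, 25)
  batch <- max_cusum_batch(x, ivs)
  for (i in c(1, 7, 25)) {
    single <- max_cusum(x, ivs$start[i], ivs$end[i])
    expect_equal(batch$b[i], single$b)
    expect_equal(batch$contrast[i], single$contrast)
  }
  expect_error(max_cusum_batch(x, data.frame(start = 1, end = 61)),
               class = "wbs2sdll_input_error")
})
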