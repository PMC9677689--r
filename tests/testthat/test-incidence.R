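test_that("Garwood intervals match their chi-square construction", {
  ci0 <- poisson_ci(0, 100)
  expect_identical(ci0$rate, 0)
  expect_identical(ci0$ci_low, 0)
  expect_equal(ci0$ci_high, 3.68888 / 100, tolerance = 1e-5)

  ci10 <- poisson_ci(10, 100)
  expect_equal(ci10$rate, 0.10)
  expect_equal(ci10$ci_low, 0.0479539, tolerance = 1e-5)
  expect_equal(ci10$ci_high, 0.1839036, tolerance = 1e-5)

  expect_equal(poisson_ci(2, 100)$rate, 0.02)
  expect_error(poisson_ci(3, 0), class = "lynchcohort_domain_error")
  expect_error(poisson_ci(2.5, 10), class = "lynchcohort_domain_error")
})

test_that("interval ordering and level monotonicity hold", {
  d <- c(0L, 1L, 5L, 40L)
  y <- c(10, 100, 33, 2000)
  for (lev in c(0.8, 0.95, 0.99)) {
    ci <- poisson_ci(d, y, level = lev)
    expect_true(all(ci$ci_low <= ci$rate + 1e-15))
    expect_true(all(ci$rate <= ci$ci_high + 1e-15))
  }
  narrow <- poisson_ci(d, y, level = 0.90)
  wide <- poisson_ci(d, y, level = 0.99)
  expect_true(all(wide$ci_low <= narrow$ci_low))
  expect_true(all(wide$ci_high >= narrow$ci_high))
})

test_that("constant-rate cumulative incidence matches the closed form", {
  tab <- data.frame(bin_start = 25, bin_end = 75, r = 0.01)
  cc <- cumulative_incidence(tab, 25, 75)
  expect_identical(cc$Q[1], 0)
  expect_equal(cc$Q[cc$age == 75], 1 - 0.99^50, tolerance = 1e-12)
  expect_equal(cc$Q, 1 - 0.99^(cc$age - 25), tolerance = 1e-12)

  # all rates zero and one-year single bins
  z <- data.frame(bin_start = 25, bin_end = 75, r = 0)
  expect_true(all(cumulative_incidence(z, 25, 75)$Q == 0))
  one <- data.frame(bin_start = 40, bin_end = 41, r = 0.5)
  expect_equal(cumulative_incidence(one, 40, 41)$Q, c(0, 0.5))
})

test_that("Q is monotone, bounded, and rates above 1 are clamped", {
  for (s in 1:20) {
    set.seed(s)
    nb <- sample(3:10, 1)
    tab <- data.frame(bin_start = 25 + 5 * (seq_len(nb) - 1),
                      bin_end = 25 + 5 * seq_len(nb),
                      r = stats::runif(nb, 0, 0.3))
    cc <- cumulative_incidence(tab, 25, max(tab$bin_end))
    expect_true(all(diff(cc$Q) >= -1e-15))
    expect_true(all(cc$Q >= 0 & cc$Q <= 1))
  }
  hot <- data.frame(bin_start = 30, bin_end = 31, r = 2)
  expect_warning(cc <- cumulative_incidence(hot, 30, 31), "clamped")
  expect_identical(cc$Q[2], 1)
})

test_that("the conditional curve obeys the conditioning identity", {
  set.seed(99)
  tab <- data.frame(bin_start = seq(25, 70, 5), bin_end = seq(30, 75, 5),
                    r = stats::runif(10, 0, 0.05))
  q0 <- cumulative_incidence(tab, 25, 75)
  for (cur in c(25L, 40L, 50L, 60L)) {
    qc <- conditional_curve(tab, cur, 75)
    expect_identical(qc$Q[1], 0)
    ref <- (q0$Q[q0$age %in% cur:75] - q0$Q[q0$age == cur]) /
      (1 - q0$Q[q0$age == cur])
    expect_equal(qc$Q, ref, tolerance = 1e-12)
  }
  expect_equal(conditional_curve(tab, 25, 75)$Q, q0$Q, tolerance = 1e-15)
  expect_warning(conditional_curve(tab, 25, 75), NA)
})

test_that("uncovered ages raise a coverage error naming the first one", {
  tab <- data.frame(bin_start = c(25, 35), bin_end = c(30, 40),
                    r = c(0.01, 0.01))
  err <- expect_error(cumulative_incidence(tab, 25, 40),
                      class = "lynchcohort_coverage_error")
  expect_equal(err$age, 30)
  err <- expect_error(cumulative_incidence(tab, 20, 30),
                      class = "lynchcohort_coverage_error")
  expect_equal(err$age, 20)
})

test_that("zero person-time bins carry the previous rate forward, with warning", {
  tab <- data.frame(bin_start = c(25, 30, 35), bin_end = c(30, 35, 40),
                    d = c(1L, 0L, 2L), y = c(100, 0, 100),
                    r = c(0.01, NA, 0.02))
  expect_warning(cc <- cumulative_incidence(tab, 25, 40), "carry")
  ref <- 1 - cumprod(1 - rep(c(0.01, 0.01, 0.02), each = 5))
  expect_equal(cc$Q[-1], ref, tolerance = 1e-12)
  # leading undefined bin cannot be carried into
  tab0 <- data.frame(bin_start = 25, bin_end = 30, d = 0L, y = 0, r = NA)
  expect_error(cumulative_incidence(tab0, 25, 30),
               class = "lynchcohort_coverage_error")
})

test_that("bootstrap bands are reproducible, contain the estimate, and widen with level", {
  tab <- data.frame(bin_start = seq(25, 70, 5), bin_end = seq(30, 75, 5),
                    d = c(2L, 4L, 3L, 6L, 8L, 5L, 9L, 7L, 4L, 2L),
                    y = rep(400, 10))
  tab$r <- tab$d / tab$y
  b1 <- cumulative_ci(tab, 25, 75, reps = 500, seed = 42)
  b2 <- cumulative_ci(tab, 25, 75, reps = 500, seed = 42)
  expect_identical(as.data.frame(b1), as.data.frame(b2))
  b3 <- cumulative_ci(tab, 25, 75, reps = 500, seed = 43)
  expect_false(identical(b1$ci_high, b3$ci_high))

  expect_true(all(b1$ci_low <= b1$Q + 1e-12))
  expect_true(all(b1$Q <= b1$ci_high + 1e-12))

  wide <- cumulative_ci(tab, 25, 75, level = 0.99, reps = 500, seed = 42)
  expect_true(all(wide$ci_low <= b1$ci_low + 1e-12))
  expect_true(all(wide$ci_high >= b1$ci_high - 1e-12))

  expect_error(cumulative_ci(tab, 25, 75, reps = 50, seed = 1),
               class = "lynchcohort_domain_error")
  expect_error(cumulative_ci(tab, 25, 75, reps = 500),
               class = "lynchcohort_domain_error")
})

test_that("an all-zero table collapses the band to zero", {
  tab <- data.frame(bin_start = seq(25, 70, 5), bin_end = seq(30, 75, 5),
                    d = 0L, y = 100)
  tab$r <- 0
  b <- cumulative_ci(tab, 25, 75, reps = 200, seed = 1)
  expect_true(all(b$Q == 0))
  expect_true(all(b$ci_low == 0))
  expect_true(all(b$ci_high == 0))
})

test_that("the bootstrap band covers a known truth at close to nominal rate", {
  true_r <- seq(0.002, 0.02, length.out = 10)
  tab0 <- data.frame(bin_start = seq(25, 70, 5), bin_end = seq(30, 75, 5))
  trueQ <- 1 - prod((1 - true_r)^5)
  y <- 2000
  hits <- vapply(1:500, function(i) {
    set.seed(1000 + i)
    d <- stats::rpois(10, y * true_r)
    tab <- cbind(tab0, d = d, y = y, r = d / y)
    b <- cumulative_ci(tab, 25, 75, reps = 500, seed = i)
    last <- nrow(b)
    b$ci_low[last] <= trueQ && trueQ <= b$ci_high[last]
  }, logical(1))
  expect_gte(mean(hits), 0.93)
  expect_lte(mean(hits), 0.97)
})

test_that("the per-year Bernoulli convention nests the exponential form exactly", {
  # with per-year event probability p = 1 - exp(-h), the discrete product
  # over k years reproduces the continuous-time exponential risk exactly,
  # so estimates from simulated cohorts are comparable to truth with no
  # discretisation error; approximating p by h itself is close but inexact
  for (h in c(0.005, 0.01, 0.02)) {
    k <- 50
    tab <- data.frame(bin_start = 25, bin_end = 75, r = 1 - exp(-h))
    cc <- cumulative_incidence(tab, 25, 75)
    expect_equal(cc$Q[cc$age == 75], 1 - exp(-h * k), tolerance = 1e-12)
    expect_lt(abs((1 - (1 - h)^k) - (1 - exp(-h * k))), 5e-3)
  }
})
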