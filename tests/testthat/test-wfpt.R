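# First-passage density and hitting probabilities

wfpt_both <- function(rt, a, v, t0 = 0, w = 0.5) {
  wfpt_density(rt, "upper", a = a, v = v, t0 = t0, w = w) +
    wfpt_density(rt, "lower", a = a, v = v, t0 = t0, w = w)
}

test_that("density integrates to the closed-form hitting probability", {
  grid <- expand.grid(a = c(0.8, 1.5, 2.5), v = c(-1, 0, 0.8), w = c(0.3, 0.5, 0.7))
  rt <- seq(1e-5, 30, by = 1e-3)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    up <- sum(wfpt_density(rt, "upper", a = g$a, v = g$v, w = g$w)) * 1e-3
    lo <- sum(wfpt_density(rt, "lower", a = g$a, v = g$v, w = g$w)) * 1e-3
    expect_equal(up, wfpt_hit_prob(g$a, g$v, g$w)[["upper"]], tolerance = 1e-4)
    expect_equal(up + lo, 1, tolerance = 1e-4)
  }
})

test_that("density is zero at or below the non-decision time and never negative", {
  rt <- seq(0, 5, by = 0.01)
  d <- wfpt_density(rt, "upper", a = 1.5, v = 0.5, t0 = 0.3)
  expect_true(all(d[rt <= 0.3] == 0))
  expect_true(all(d >= 0))
  expect_true(all(is.finite(d)))
})

test_that("hitting probability limits are correct", {
  # zero drift: probability of the upper boundary equals the start point
  expect_equal(wfpt_hit_prob(2, 0, 0.25)[["upper"]], 0.25, tolerance = 1e-12)
  expect_equal(wfpt_hit_prob(1.3, 0, 0.5)[["upper"]], 0.5, tolerance = 1e-12)
  # start at the top: upper boundary is certain
  expect_equal(wfpt_hit_prob(2, -1, 1 - 1e-12)[["upper"]], 1, tolerance = 1e-9)
  # strong positive drift dominates
  expect_gt(wfpt_hit_prob(2, 3, 0.5)[["upper"]], 0.99)
  # monotone in drift
  p <- vapply(seq(-2, 2, by = 0.25), function(v) wfpt_hit_prob(1.8, v)[["upper"]], 0)
  expect_true(all(diff(p) > 0))
})

test_that("hitting probability matches large-sample simulation", {
  sim <- sample_ddm(2e4, a = 1.6, v = 0.5, t0 = 0.25, seed = 42)
  p_hat <- mean(sim$boundary == "upper")
  p <- wfpt_hit_prob(1.6, 0.5)[["upper"]]
  se <- sqrt(p * (1 - p) / 2e4)
  expect_lt(abs(p_hat - p), 4 * se)
})

test_that("simulated first-passage times agree with the density (KS)", {
  a <- 1.8; v <- 0.4; t0 <- 0.3
  sim <- sample_ddm(4000, a = a, v = v, t0 = t0, seed = 7)
  rt_up <- sim$rt[sim$boundary == "upper"]
  # theoretical conditional CDF of upper-boundary times by fine quadrature
  grid <- seq(t0 + 5e-4, 12, by = 1e-3)
  dens <- wfpt_density(grid, "upper", a = a, v = v, t0 = t0)
  cdf <- cumsum(dens) * 1e-3
  cdf <- cdf / wfpt_hit_prob(a, v)[["upper"]]
  theo <- stats::approxfun(grid, pmin(cdf, 1), yleft = 0, yright = 1)
  ks <- suppressWarnings(stats::ks.test(rt_up, theo))
  expect_gt(ks$p.value, 0.01)
})

test_that("mean decision time grows with boundary separation", {
  rt <- seq(1e-4, 40, by = 1e-3)
  m <- vapply(c(0.8, 1.2, 1.8, 2.4, 3), function(a) {
    d <- wfpt_both(rt, a = a, v = 0.5)
    sum(rt * d) / sum(d)
  }, 0)
  expect_true(all(diff(m) > 0))
})

test_that("accuracy grows with boundary separation under positive drift", {
  p <- vapply(c(0.8, 1.2, 1.8, 2.4, 3), function(a) wfpt_hit_prob(a, 0.5)[["upper"]], 0)
  expect_true(all(diff(p) > 0))
})

test_that("sample_ddm is reproducible and validates inputs", {
  s1 <- sample_ddm(50, a = 1.5, v = 0.3, seed = 3)
  s2 <- sample_ddm(50, a = 1.5, v = 0.3, seed = 3)
  expect_identical(s1, s2)
  s3 <- sample_ddm(50, a = 1.5, v = 0.3, seed = 4)
  expect_false(identical(s1$rt, s3$rt))
  expect_error(wfpt_density(1, "upper", a = -1, v = 0))
  expect_error(sample_ddm(10, a = 0, v = 0))
})
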