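# Shared numeric utilities

test_that("credible intervals behave on known samples", {
  set.seed(1)
  x <- rnorm(2e5)
  ci <- cri(x, 0.95)
  expect_equal(unname(ci[["lower"]]), -1.96, tolerance = 0.03)
  expect_equal(unname(ci[["upper"]]), 1.96, tolerance = 0.03)
  # HDI of a skewed sample is shorter than the central interval
  y <- rexp(2e5)
  hdi <- cri(y, 0.9, method = "hdi")
  qi <- cri(y, 0.9, method = "quantile")
  expect_lt(hdi[["upper"]] - hdi[["lower"]], qi[["upper"]] - qi[["lower"]])
  expect_equal(unname(hdi[["lower"]]), 0, tolerance = 0.01)
})

test_that("split R-hat separates stationary from drifting chains", {
  set.seed(2)
  stationary <- matrix(rnorm(4000), ncol = 2)
  expect_lt(split_rhat(stationary), 1.02)
  drifting <- cbind(rnorm(2000), rnorm(2000, mean = 3))
  expect_gt(split_rhat(drifting), 1.5)
})

test_that("per-subject z-scoring centers and scales within subject", {
  d <- tibble::tibble(subject = rep(c("a", "b"), each = 50),
                      x = c(rnorm(50, 10, 2), rnorm(50, -5, 7)))
  z <- zscore_by_subject(d, "x")
  expect_true("x_z" %in% names(z))
  by <- dplyr::summarise(dplyr::group_by(z, subject),
                         m = mean(x_z), s = sd(x_z))
  expect_equal(by$m, c(0, 0), tolerance = 1e-12)
  expect_equal(by$s, c(1, 1), tolerance = 1e-12)
})
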