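# Hierarchical drift-diffusion model

ddm_fixture <- function() fixture("ddm_fit", function() {
  ds <- simulate_experiment(
    gt = ground_truth(n_subjects = 6, seed = 13, a_trial_sd = 0,
                      double_response_p = 0),
    config = task_config(n_trials = 150), scenario = "nostim",
    seed = 13, components = character())
  pb <- dplyr::filter(prepare_behavior(filter_trials(ds$trials)), included)
  fit <- fit_hddm(pb, a = ~instr_c, chains = 2, iter = 1500, burn = 400, seed = 1)
  list(gt = ds$ground_truth, data = pb, fit = fit)
})

test_that("the hierarchical fit recovers group-level truth", {
  fx <- ddm_fixture()
  td <- tidy(fx$fit)
  est <- function(tm) td[td$term == tm, ]
  subj <- fx$gt$subjects
  # group threshold mean (average of the two instruction levels)
  tr_mu <- mean((subj$a_accuracy + subj$a_speed) / 2)
  expect_lt(abs(est("mu_a")$estimate - tr_mu), 0.25)
  # instruction contrast on the threshold: negative and covering truth
  tr_i <- mean(subj$a_speed - subj$a_accuracy)
  ii <- est("a_instr_c")
  expect_lt(ii$conf.high, 0)
  expect_lt(abs(ii$estimate - tr_i), 0.15)
  # drift and non-decision time near truth
  expect_lt(abs(est("mu_v")$estimate - mean(subj$v)), 0.2)
  expect_lt(abs(est("mu_t")$estimate - mean(subj$t0)), 0.05)
  expect_true(all(is.finite(td$rhat)))
  expect_lte(max(fx$fit$rhat[fx$fit$terms], na.rm = TRUE), 1.1)
})

test_that("dispersed chains agree (split R-hat on core terms)", {
  fx <- ddm_fixture()
  expect_true(fx$fit$converged)
  g <- glance(fx$fit)
  expect_equal(g$chains, 2)
  expect_lte(g$rhat_max, 1.1)
})

test_that("the fit is reproducible given a seed", {
  fx <- ddm_fixture()
  refit <- fit_hddm(fx$data, a = ~instr_c, chains = 2, iter = 300, burn = 100, seed = 9)
  refit2 <- fit_hddm(fx$data, a = ~instr_c, chains = 2, iter = 300, burn = 100, seed = 9)
  expect_identical(refit$draws, refit2$draws)
})

test_that("quantile-probability summaries compare observed and predicted RTs", {
  fx <- ddm_fixture()
  qp <- quantile_probability_check(fx$fit, fx$data, n_draws = 20, seed = 1)
  expect_true(all(c("response", "prob", "quantile", "rt_obs",
                    "condition", "prob_pred", "rt_pred") %in% names(qp)))
  expect_setequal(unique(qp$condition), c("accuracy", "speed"))
  # predicted response probabilities close to observed ones
  agg <- dplyr::distinct(qp, response, condition, prob, prob_pred)
  expect_lt(max(abs(agg$prob - agg$prob_pred)), 0.1)
  # predicted RT quantiles within a reasonable band of observed
  expect_lt(stats::median(abs(qp$rt_pred - qp$rt_obs) / qp$rt_obs), 0.15)
  p <- plot_quantile_probability(qp)
  expect_s3_class(p, "ggplot")
})

test_that("regression wrapper builds the documented design", {
  fx <- ddm_fixture()
  set.seed(4)
  d <- fx$data
  d$cov <- rnorm(nrow(d))
  fit <- fit_hddm_regression(d, covariate = "cov", chains = 2,
                             iter = 600, burn = 200, seed = 2)
  td <- tidy(fit)
  expect_true(all(c("a_instr_c", "a_cov_z", "a_instr_c:cov_z",
                    "v_cov_z", "t_cov_z") %in% td$term))
  # a pure-noise covariate is not significant on the threshold path
  cc <- td[td$term == "a_cov_z", ]
  expect_true(cc$conf.low < 0 & cc$conf.high > 0)
})

test_that("invalid inputs abort cleanly", {
  fx <- ddm_fixture()
  bad <- fx$data
  bad$rt[1] <- -1
  expect_error(fit_hddm(bad, chains = 1, iter = 50, burn = 10))
  expect_error(fit_hddm(fx$data, a = ~nonexistent_column,
                        chains = 1, iter = 50, burn = 10))
})
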