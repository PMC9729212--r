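# Force-trace measures, trial exclusions, hierarchical regressions

test_that("movement onset is detected on a clean synthetic ramp", {
  tr <- synthesize_force_trace(rt = 0.8, mt = 0.4, peak_force = 26,
                               noise_sd = 0.02, seed = 2)
  onset <- detect_movement_onset(tr, response_time = min(tr$time[tr$force >= 20]))
  expect_equal(onset, 0.8, tolerance = 0.05)
})

test_that("derived trial measures recover the generating parameters", {
  tr <- synthesize_force_trace(rt = 0.7, mt = 0.35, peak_force = 30,
                               noise_sd = 0.02, seed = 5)
  resp <- min(tr$time[tr$force >= 20])
  m <- derive_trial_measures(tr, response_time = resp)
  expect_equal(m$rt, 0.7, tolerance = 0.05)
  expect_equal(m$mt, 0.35, tolerance = 0.08)
  expect_equal(m$peak_force, 30, tolerance = 1.5)
})

test_that("exclusion flags follow the documented rules", {
  tr <- tibble::tibble(trial = 1:4, subject = "S01", instruction = "speed",
                       rt = c(0.2, 0.6, NA, 0.7), mt = c(0.3, 0.3, NA, 0.3),
                       accuracy = c(1, 1, NA, 0),
                       omission = c(FALSE, FALSE, TRUE, FALSE),
                       double_response = c(FALSE, FALSE, FALSE, TRUE))
  ft <- filter_trials(tr)
  expect_equal(nrow(ft), 4)
  expect_identical(ft$included, c(FALSE, TRUE, FALSE, FALSE))
  expect_identical(ft$excl_fast, c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(ft$excl_omission, c(FALSE, FALSE, TRUE, FALSE))
  expect_identical(ft$excl_double, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("a fully clean table is fully included", {
  tr <- tibble::tibble(trial = 1:3, subject = "S01", instruction = "accuracy",
                       rt = c(0.5, 0.6, 0.7), mt = 0.3, accuracy = 1,
                       omission = FALSE, double_response = FALSE)
  ft <- filter_trials(tr)
  expect_true(all(ft$included))
})

test_that("an all-omission table warns", {
  tr <- tibble::tibble(trial = 1:3, subject = "S01", instruction = "speed",
                       rt = NA_real_, mt = NA_real_, accuracy = NA_real_,
                       omission = TRUE, double_response = FALSE)
  expect_warning(ft <- filter_trials(tr), "no trials remain")
  expect_false(any(ft$included))
})

test_that("prepared behavior has sum-coded conditions and log outcomes", {
  pb <- prepare_behavior(filter_trials(small_nostim()$trials))
  expect_setequal(unique(pb$instr_c), c(-0.5, 0.5))
  ok <- pb$included
  expect_equal(pb$log_rt[ok], log(pb$rt[ok]))
  expect_equal(pb$log_mt[ok], log(pb$mt[ok]))
})

test_that("the linear hierarchy recovers the instruction effect on log RT", {
  pb <- dplyr::filter(prepare_behavior(filter_trials(small_nostim()$trials)),
                      included)
  fit <- fit_hlm(pb, log_rt ~ instr_c + (1 | subject),
                 chains = 2, iter = 1500, burn = 300, seed = 1)
  expect_s3_class(fit, "stn_posterior")
  d <- decide_significance(fit, "instr_c")
  expect_true(d$significant)
  expect_identical(d$direction, "negative")
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "conf.low", "conf.high", "rhat") %in% names(td)))
  g <- glance(fit)
  expect_identical(g$family, "gaussian")
  expect_lte(g$rhat_max, 1.1)
})

test_that("the logistic hierarchy recovers the instruction effect on accuracy", {
  pb <- dplyr::filter(prepare_behavior(filter_trials(beh_nostim()$trials)),
                      included)
  fit <- fit_hlogit(pb, accuracy ~ instr_c + (1 | subject),
                    chains = 2, iter = 1500, burn = 300, seed = 2)
  d <- decide_significance(fit, "instr_c")
  expect_true(d$significant)
  expect_identical(d$direction, "negative")
})

test_that("a permuted predictor is not called significant", {
  pb <- dplyr::filter(prepare_behavior(filter_trials(small_nostim()$trials)),
                      included)
  set.seed(11)
  pb$noise_c <- sample(pb$instr_c)
  fit <- fit_hlm(pb, log_rt ~ noise_c + (1 | subject),
                 chains = 2, iter = 1500, burn = 300, seed = 3)
  d <- decide_significance(fit, "noise_c")
  expect_false(d$significant)
})

test_that("one-tailed decisions respect the stated direction", {
  draws <- matrix(rnorm(4000, mean = 0.12, sd = 0.05), ncol = 1,
                  dimnames = list(NULL, "x"))
  fake <- structure(list(draws = draws, terms = "x", re_terms = character(),
                         rhat = c(x = 1), n_obs = 10L, n_subjects = 2L,
                         chains = 2L, iter = 2000L, burn = 0L,
                         family = "gaussian", converged = TRUE),
                    class = "stn_posterior")
  pos <- decide_significance(fake, "x", tail = "one", direction = "positive")
  neg <- decide_significance(fake, "x", tail = "one", direction = "negative")
  expect_true(pos$significant)
  expect_false(neg$significant)
})
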