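# Morlet time-frequency pipeline

test_that("the FFT-based transform matches brute-force convolution", {
  set.seed(1)
  rate <- 200; n <- 5 * rate
  x <- rnorm(n)
  tf <- morlet_tfr(x, rate, freqs = c(20), step = 0.02)
  w <- stnsat:::morlet_wavelet(20, rate, 7)
  half <- (length(w) - 1) / 2
  direct <- vapply(seq(1, n, by = 4), function(i) {
    lo <- i - half; hi <- i + half
    if (lo < 1 || hi > n) return(NA_real_)
    Mod(sum(x[lo:hi] * rev(w)))^2
  }, 0)
  a <- tf$power[, "20"]
  ok <- is.finite(a) & is.finite(direct)
  expect_gt(sum(ok), 100)
  expect_lt(max(abs(a[ok] - direct[ok]) / abs(direct[ok])), 1e-6)
})

test_that("a pure tone peaks at its own frequency and power scales as amplitude squared", {
  rate <- 200; n <- 8 * rate
  tone <- sin(2 * pi * 20 * (0:(n - 1)) / rate)
  tt <- morlet_tfr(tone, rate, freqs = c(10, 20, 40))
  cm <- colMeans(tt$power, na.rm = TRUE)
  expect_identical(names(which.max(cm)), "20")
  tt2 <- morlet_tfr(2 * tone, rate, freqs = 20)
  expect_equal(mean(tt2$power[, 1], na.rm = TRUE) / cm[["20"]], 4,
               tolerance = 1e-10)
  # interior response to a stationary tone is itself stationary
  mid <- tt$power[, "20"]
  mid <- mid[is.finite(mid)]
  expect_lt(sd(mid) / mean(mid), 1e-3)
})

test_that("edges within three temporal SDs of the wavelet are masked", {
  rate <- 200; n <- 4 * rate
  tf <- morlet_tfr(rnorm(n), rate, freqs = c(5, 40), step = 0.02)
  sd5 <- 7 / (2 * pi * 5)
  expect_true(all(is.na(tf$power[tf$times < 3 * sd5, "5"])))
  expect_true(all(is.finite(tf$power[tf$times > 3 * sd5 + 0.1 &
                                     tf$times < max(tf$times) - 3 * sd5 - 0.1, "5"])))
  # higher frequencies have narrower masks
  expect_lt(sum(is.na(tf$power[, "40"])), sum(is.na(tf$power[, "5"])))
})

test_that("percent-change normalization has an exact zero time-mean", {
  set.seed(3)
  tf <- morlet_tfr(rnorm(1200), 200, freqs = c(10, 25), step = 0.02)
  nz <- normalize_power(tf)
  expect_true(nz$normalized)
  expect_lt(max(abs(colMeans(nz$power, na.rm = TRUE))), 1e-10)
})

test_that("preprocessing removes line noise and DC and resamples", {
  rate <- 1024; n <- 10 * rate
  t <- (0:(n - 1)) / rate
  x <- 5 + sin(2 * pi * 50 * t) + 0.5 * sin(2 * pi * 20 * t)
  lfp <- make_lfp(cbind(x), rate)
  pp <- preprocess_lfp(lfp)
  expect_equal(pp$rate, 200)
  expect_lt(abs(mean(pp$data[, 1])), 0.05)
  spec <- function(f) {
    m <- nrow(pp$data)
    Mod(sum(pp$data[, 1] * exp(-2i * pi * f * (0:(m - 1)) / 200))) / m
  }
  expect_lt(spec(50), 0.05 * spec(20))  # line component suppressed
  expect_gt(spec(20), 0.15)             # signal band preserved
})

test_that("bipolar montage counts follow the electrode geometry", {
  mk <- function(chs) make_lfp(matrix(rnorm(400 * length(chs)), ncol = length(chs)),
                               200, channels = chs)
  expect_length(bipolar_montage(mk(c("0", "1", "2", "3")))$channels, 3)
  expect_length(bipolar_montage(mk(c("1", "2a", "2b", "2c", "3a", "3b", "3c", "4")))$channels, 9)
  expect_length(bipolar_montage(mk(c("0", "1", "2", "3")), scheme = "wide")$channels, 2)
  # common-mode activity cancels exactly
  common <- rnorm(400)
  lfp <- make_lfp(cbind(common, common, common), 200, channels = c("0", "1", "2"))
  bm <- bipolar_montage(lfp)
  expect_lt(max(abs(bm$data)), 1e-12)
})

test_that("the cue-beta feature on a constructed -20% step equals +20", {
  times <- seq(0, 30, by = 0.02)
  freqs <- c(4:8, 13:30, 55:80)
  events <- tibble::tibble(trial = 1:3, t_cue = c(8, 14, 20),
                           t_onset = c(8.6, 14.6, 20.6),
                           rt = 0.6, response_side = "left")
  power <- matrix(0, length(times), length(freqs))
  for (a in events$t_cue) power[times >= a, ] <- -20
  # reset each pre-cue baseline to zero for the next trial
  for (a in events$t_cue) power[times >= a - 2 & times < a, ] <- 0
  tfr <- make_tfr(power, times, freqs)
  ft <- extract_features(tfr, events, zscore = FALSE)
  expect_equal(ft$beta_cue, rep(20, 3), tolerance = 1e-12)
  expect_equal(ft$beta_move, rep(-20, 3), tolerance = 1e-12)
})

test_that("contact selection prefers gamma and falls back to beta", {
  times <- seq(0, 10, by = 0.02)
  freqs <- c(13:30, 55:80)
  events <- tibble::tibble(trial = 1, t_onset = 5)
  mk <- function(gamma, beta) {
    p <- matrix(0, length(times), length(freqs))
    win <- times >= 5 & times <= 5.3
    p[win, as.character(freqs) %in% as.character(55:80)] <- gamma
    p[win, as.character(freqs) %in% as.character(13:30)] <- beta
    make_tfr(p, times, freqs)
  }
  sel <- select_contact(list(c12 = mk(5, 0), c23 = mk(12, 0)), events)
  expect_identical(sel$channel, "c23")
  expect_identical(sel$criterion, "gamma")
  # no gamma increase anywhere: strongest beta suppression wins
  sel2 <- select_contact(list(c12 = mk(-1, -4), c23 = mk(-2, -9)), events)
  expect_identical(sel2$channel, "c23")
  expect_identical(sel2$criterion, "beta")
  # ties resolve to the first (dorsal-most) channel
  sel3 <- select_contact(list(c12 = mk(7, 0), c23 = mk(7, 0)), events)
  expect_identical(sel3$channel, "c12")
})

test_that("epoching tags laterality and drops out-of-range trials", {
  times <- seq(0, 10, by = 0.02)
  power <- matrix(rnorm(length(times) * 2), ncol = 2)
  power[times > 9.5, ] <- NA_real_  # masked edge, as in a real map
  tfr <- make_tfr(power, times, c(20, 21))
  events <- tibble::tibble(trial = 1:3, t_cue = c(2, 5, 9.9),
                           t_onset = c(2.5, 5.5, 10.2),
                           response_side = c("left", "right", "left"))
  ep <- epoch_and_lateralize(tfr, events, hemisphere = "left",
                             alignment = "cue", window = c(-0.5, 1))
  expect_equal(ep$trial, c(1, 2))  # trial 3 reaches into the masked edge
  expect_identical(ep$laterality, c("ipsilateral", "contralateral"))
  m <- ep$map[[1]]
  expect_equal(range(attr(m, "times")), c(-0.5, 1), tolerance = 0.02)
})

test_that("identical events at different times yield identical epochs of a tone", {
  rate <- 200; n <- 30 * rate
  tone <- sin(2 * pi * 20 * (0:(n - 1)) / rate)
  tf <- normalize_power(morlet_tfr(tone, rate, freqs = c(19, 20, 21), step = 0.02))
  events <- tibble::tibble(trial = 1:2, t_cue = c(10, 20.00),
                           t_onset = c(10, 20.00), response_side = "left")
  ep <- epoch_and_lateralize(tf, events, hemisphere = "left", window = c(-0.5, 0.5))
  expect_equal(ep$map[[1]][], ep$map[[2]][], tolerance = 1e-8)
})

test_that("the full feature pipeline produces sane single-trial features", {
  ds <- small_lfp()
  ft <- extract_lfp_features(ds)
  expect_true(all(c("subject", "trial", "hemisphere", "channel",
                    "beta_cue", "beta_move", "gamma_move", "theta_cue") %in% names(ft)))
  expect_gt(nrow(ft), 10)
  # generated couplings: cue-related suppression positive, movement beta
  # suppressed, movement gamma increased
  expect_gt(mean(ft$beta_cue, na.rm = TRUE), 0)
  expect_lt(mean(ft$beta_move, na.rm = TRUE), 0)
  expect_gt(mean(ft$gamma_move, na.rm = TRUE), 0)
})

test_that("condition contrasts validate their inputs", {
  d <- tibble::tibble(subject = rep(c("a", "b", "c"), each = 4),
                      instruction = rep(c("accuracy", "speed"), 6),
                      f = rnorm(12))
  cc <- condition_contrast(d, "f")
  expect_identical(cc$n_subjects, 3L)
  expect_error(condition_contrast(dplyr::mutate(d, instruction = "speed"), "f"),
               "two levels")
})

test_that("time-frequency maps plot", {
  tf <- morlet_tfr(rnorm(800), 200, freqs = c(10, 20), step = 0.02)
  expect_s3_class(autoplot(normalize_power(tf)), "ggplot")
})
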