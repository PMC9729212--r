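# Sliding-window stimulation analysis

make_binary <- function(left, right = left, rate = 200) {
  structure(list(left = left, right = right, rate = rate, ramp_inclusion = 0),
            class = "stn_stim_binary")
}

simple_events <- function(t_cue, subject = "S01") {
  tibble::tibble(trial = seq_along(t_cue), subject = subject, t_cue = t_cue,
                 t_onset = t_cue + 0.6, response_side = "left",
                 instruction = rep(c("accuracy", "speed"),
                                   length.out = length(t_cue)),
                 rt = 0.6, mt = 0.3, accuracy = 1)
}

test_that("both alignments produce the documented 141-window grid", {
  bin <- make_binary(rep(FALSE, 2000))
  ev <- simple_events(c(3, 5))
  wc <- assign_windows(bin, ev, alignment = "cue")
  expect_identical(dim(wc$flags), c(2L, 141L))
  expect_equal(wc$starts[1], -0.5)
  expect_equal(wc$starts[141], 0.9)
  wm <- assign_windows(bin, ev, alignment = "movement")
  expect_equal(wm$starts[1], -1)
  expect_equal(wm$starts[141], 0.4)
})

test_that("window membership uses half-open intervals on the sample clock", {
  # one stimulated sample at exactly 3.0 s (sample index 601 at 200 Hz)
  left <- rep(FALSE, 2000); left[601] <- TRUE
  bin <- make_binary(left)
  w <- assign_windows(bin, simple_events(3), alignment = "cue")
  onset <- w$starts
  hit <- which(w$flags[1, ])
  # the sample at offset 0 belongs to windows [t, t + 0.1) with t in (-0.1, 0]
  expect_identical(onset[hit], onset[onset > -0.1 + 1e-9 & onset <= 0 + 1e-9])
})

test_that("window flags are translation-equivariant", {
  set.seed(5)
  left <- rep(FALSE, 4000)
  left[sample.int(2000, 150) + 500] <- TRUE
  shift <- 400  # exactly 2 s at 200 Hz
  bin1 <- make_binary(left)
  bin2 <- make_binary(c(rep(FALSE, shift), left)[seq_along(left)])
  w1 <- assign_windows(bin1, simple_events(c(4, 6, 8)))
  w2 <- assign_windows(bin2, simple_events(c(4, 6, 8) + shift / 200))
  expect_identical(w1$flags, w2$flags)
})

test_that("hemisphere selection routes through response side", {
  left <- rep(FALSE, 2000); left[500:700] <- TRUE
  bin <- make_binary(left, right = rep(FALSE, 2000))
  ev <- simple_events(3)  # response with the left hand
  # left hand -> contralateral is the right hemisphere (no stim there)
  wc <- assign_windows(bin, ev, hemisphere = "contralateral")
  expect_false(any(wc$flags))
  wi <- assign_windows(bin, ev, hemisphere = "ipsilateral")
  expect_true(any(wi$flags))
  expect_identical(assign_windows(bin, ev, hemisphere = "left")$flags, wi$flags)
})

test_that("coverage is exact in the trivial cases", {
  ev <- simple_events(c(3, 5, 7))
  all_on <- make_binary(rep(TRUE, 2000))
  expect_true(all(stim_coverage(assign_windows(all_on, ev))$fraction == 1))
  all_off <- make_binary(rep(FALSE, 2000))
  expect_true(all(stim_coverage(assign_windows(all_off, ev))$fraction == 0))
})

test_that("small cohorts enumerate the sign-flip null exactly", {
  set.seed(1)
  X <- matrix(rnorm(8 * 141), 8)
  ct <- cluster_permutation(X, n_perm = 500, seed = 2)
  expect_true(ct$exact)
  expect_identical(ct$n_perm, 256L)
  # exchangeable null data should not produce significant clusters here
  expect_false(any(ct$clusters$significant))
})

test_that("an exact p-value for an overwhelming common effect is 1/2^J", {
  set.seed(2)
  X <- matrix(rnorm(8 * 141, sd = 0.1), 8)
  X[, 60:80] <- X[, 60:80] + 3
  ct <- cluster_permutation(X, n_perm = 500, seed = 3)
  sig <- ct$clusters[ct$clusters$significant, ]
  expect_equal(nrow(sig), 1)
  expect_lte(sig$from, 62)
  expect_gte(sig$to, 78)
  # the max statistic is sign-symmetric: the identity flip and the global
  # flip both reach the observed mass, so the exact two-sided p is 2/2^J
  expect_equal(sig$p, 2 / 256)
})

test_that("random permutation p-values use the add-one rule", {
  set.seed(3)
  X <- matrix(rnorm(12 * 141, sd = 0.1), 12)  # 2^12 > 500 -> random flips
  X[, 30:45] <- X[, 30:45] + 3
  ct <- cluster_permutation(X, n_perm = 500, seed = 4)
  expect_false(ct$exact)
  sig <- ct$clusters[ct$clusters$significant, ]
  expect_equal(min(sig$p), 1 / 501)
})

test_that("fewer than five subjects abort", {
  X <- matrix(rnorm(4 * 141), 4)
  expect_error(cluster_permutation(X), "subject")
})

test_that("per-window effects measure what was injected", {
  set.seed(7)
  n <- 60
  ev <- simple_events(seq(3, by = 2, length.out = n))
  flags <- matrix(FALSE, n, 141)
  flags[1:30, 50:70] <- TRUE
  ev$rt <- rnorm(n, 0.6, 0.01) - 0.2 * (seq_len(n) <= 30)
  w <- structure(list(flags = flags, starts = stnsat:::window_grid("cue"),
                      width = 0.1, step = 0.01, alignment = "cue",
                      hemisphere = "either", events = ev),
                 class = "stn_stim_windows")
  eff <- effect_per_window(w, outcome = "rt", mode = "stim")
  expect_equal(dim(eff$effects), c(1L, 141L))
  expect_lt(eff$effects[1, 60], -0.15)
  expect_true(all(is.na(eff$effects[1, c(1:49, 71:141)]) |
                  abs(eff$effects[1, c(1:49, 71:141)]) < 0.05))
})

test_that("post-hoc window tests separate the two instructions", {
  set.seed(8)
  parts <- lapply(1:8, function(s) {
    ev <- simple_events(seq(3, by = 2, length.out = 80),
                        subject = sprintf("S%02d", s))
    flags <- matrix(FALSE, 80, 141)
    stim_rows <- sample.int(80, 40)
    flags[stim_rows, 45:75] <- TRUE
    ev$rt <- rnorm(80, 0.7, 0.02)
    sel <- seq_len(80) %in% stim_rows & ev$instruction == "accuracy"
    ev$rt[sel] <- ev$rt[sel] - 0.1
    list(flags = flags, events = ev)
  })
  w <- structure(list(flags = do.call(rbind, lapply(parts, `[[`, "flags")),
                      starts = stnsat:::window_grid("cue"),
                      width = 0.1, step = 0.01, alignment = "cue",
                      hemisphere = "either",
                      events = dplyr::bind_rows(lapply(parts, `[[`, "events"))),
                 class = "stn_stim_windows")
  ph <- posthoc_window(w, span = c(-0.06, 0.1), outcome = "rt")
  acc <- ph[ph$condition == "accuracy" & ph$outcome == "rt", ]
  spd <- ph[ph$condition == "speed" & ph$outcome == "rt", ]
  expect_lt(acc$mean_difference, -0.05)
  expect_lt(acc$p_corrected, 0.05)
  expect_gt(spd$p_corrected, 0.05)
})

test_that("artifact removal is near-identity on clean signals", {
  rate <- 1024; n <- 6 * rate
  t <- (0:(n - 1)) / rate
  x <- 2 * sin(2 * pi * 20 * t)
  lfp <- make_lfp(cbind(x), rate)
  cln <- remove_stim_artifact(lfp)
  expect_equal(max(cln$interpolated), 0)
  expect_equal(cln$rate, 200)
  # band content preserved after the removal chain
  m <- nrow(cln$data)
  amp <- Mod(sum(cln$data[, 1] * exp(-2i * pi * 20 * (0:(m - 1)) / 200))) / m * 2
  expect_equal(amp, 2, tolerance = 0.1)
})

test_that("isolated large spikes are interpolated away", {
  rate <- 1024; n <- 6 * rate
  t <- (0:(n - 1)) / rate
  x <- sin(2 * pi * 18 * t)
  spikes <- seq(2048, n - 2048, by = 1024)
  x[spikes] <- x[spikes] + 500
  lfp <- make_lfp(cbind(x), rate)
  cln <- remove_stim_artifact(lfp)
  expect_gt(max(cln$interpolated), 0)
  expect_lt(max(cln$interpolated), 0.05)
  # every surviving or interpolated sample is bounded by the threshold
  expect_lt(max(abs(cln$data[, 1])), 10 + 1e-9)
})

test_that("overwhelmed recordings abort rather than fabricate data", {
  rate <- 1024
  x <- rnorm(4 * rate, sd = 500)
  expect_error(remove_stim_artifact(make_lfp(cbind(x), rate)),
               "exceed the artifact threshold")
})

test_that("cluster tests tidy, glance and plot", {
  set.seed(9)
  X <- matrix(rnorm(8 * 141, sd = 0.1), 8)
  X[, 100:115] <- X[, 100:115] + 2
  ct <- cluster_permutation(X, n_perm = 500, seed = 1)
  td <- tidy(ct)
  expect_true(all(c("from", "to", "mass", "p", "significant") %in% names(td)))
  g <- glance(ct)
  expect_identical(g$n_windows, 141L)
  expect_s3_class(autoplot(ct), "ggplot")
})
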