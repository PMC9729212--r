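# Synthetic experiment generator

test_that("simulation is deterministic given a seed", {
  a <- simulate_experiment(gt = ground_truth(n_subjects = 2),
                           config = task_config(n_trials = 30),
                           scenario = "bilateral", seed = 9,
                           components = character())
  b <- simulate_experiment(gt = ground_truth(n_subjects = 2),
                           config = task_config(n_trials = 30),
                           scenario = "bilateral", seed = 9,
                           components = character())
  expect_identical(a$trials, b$trials)
  expect_identical(a$stim, b$stim)
  c <- simulate_experiment(gt = ground_truth(n_subjects = 2),
                           config = task_config(n_trials = 30),
                           scenario = "bilateral", seed = 10,
                           components = character())
  expect_false(identical(a$trials$rt, c$trials$rt))
})

test_that("optional components draw from independent sub-streams", {
  base <- simulate_experiment(gt = ground_truth(n_subjects = 1),
                              config = task_config(n_trials = 20),
                              scenario = "bilateral", seed = 31,
                              components = character())
  with_force <- simulate_experiment(gt = ground_truth(n_subjects = 1),
                                    config = task_config(n_trials = 20),
                                    scenario = "bilateral", seed = 31,
                                    components = "force")
  expect_identical(base$trials, with_force$trials)
  expect_false(is.null(with_force$force))
})

test_that("trial schedules respect the configured timing", {
  sch <- generate_trial_schedule(task_config(n_trials = 100), seed = 3)
  expect_equal(nrow(sch), 100)
  # balanced instruction conditions
  expect_equal(unname(abs(diff(table(sch$instruction)))), 0)
  # cue follows the instruction by the configured jitter
  expect_true(all(sch$cue_jitter >= 0.75 & sch$cue_jitter <= 1.25))
  expect_equal(sch$t_cue, sch$t_instruction + sch$cue_jitter)
  expect_true(all(diff(sch$t_instruction) > 0))
})

test_that("burst schedules have valid segment structure", {
  sch <- generate_burst_schedule(120, "bilateral", seed = 8)
  for (h in c("left", "right")) {
    st <- sch[[h]]$state
    r <- rle(st)
    # plateaus only ever follow a ramp-up and precede a ramp-down
    plat <- which(r$values == 2)
    expect_true(all(r$values[plat - 1] == 1))
    expect_true(all(r$values[plat + 1] == 3, na.rm = TRUE))
    # segment durations in the configured ranges (at the schedule rate);
    # the final run may be truncated by the end of the session
    k <- length(r$lengths)
    ramps <- setdiff(which(r$values %in% c(1, 3)), k)
    expect_true(all(abs(r$lengths[ramps] - 0.15 * sch$rate) <= 1))
    pl <- r$lengths[setdiff(plat, k)] / sch$rate
    expect_true(all(pl >= 0.15 - 1e-9 & pl <= 0.35 + 1e-9))
    iv <- r$lengths[r$values == 0] / sch$rate
    # interior off-segments follow the interval distribution
    interior <- iv[-c(1, length(iv))]
    expect_true(all(interior >= 0.075 - 1e-9 & interior <= 0.225 + 1e-9))
    # intensity is zero exactly when off, maximal on the plateau
    expect_true(all(sch[[h]]$intensity[st == 0] == 0))
    expect_true(all(sch[[h]]$intensity[st == 2] == max(sch[[h]]$intensity)))
  }
})

test_that("unilateral schedules stimulate one hemisphere only", {
  sch <- generate_burst_schedule(60, "unilateral-left", seed = 2)
  expect_true(any(sch$left$state > 0))
  expect_true(all(sch$right$state == 0))
})

test_that("binarization marks exactly the plateau by default", {
  sch <- generate_burst_schedule(60, "bilateral", seed = 4)
  bin <- binarize_stimulation(sch)
  expect_s3_class(bin, "stn_stim_binary")
  expect_identical(bin$left, sch$left$state == 2L)
  # including ramps marks strictly more samples
  bin_r <- binarize_stimulation(sch, ramp_inclusion = 1)
  expect_true(all(bin$left <= bin_r$left))
  expect_identical(bin_r$left, sch$left$state %in% c(1L, 2L, 3L))
})

test_that("omissions and responses are internally consistent", {
  ds <- small_bilateral()
  tr <- ds$trials
  expect_true(all(is.na(tr$rt[tr$omission])))
  ok <- !tr$omission
  expect_true(all(is.finite(tr$rt[ok])))
  expect_true(all(tr$rt[ok] > 0))
  expect_true(all(tr$mt[ok] > 0))
  expect_true(all(tr$accuracy[ok] %in% c(0, 1)))
  # correct responses land on the cued side
  expect_true(all((tr$response_side[ok] == tr$side[ok]) == (tr$accuracy[ok] == 1)))
  # speed instructions shorten both decision and movement
  m <- dplyr::summarise(dplyr::group_by(dplyr::filter(tr, !omission), instruction),
                        rt = mean(rt), mt = mean(mt), acc = mean(accuracy))
  expect_lt(m$rt[m$instruction == "speed"], m$rt[m$instruction == "accuracy"])
  expect_lt(m$mt[m$instruction == "speed"], m$mt[m$instruction == "accuracy"])
  expect_lt(m$acc[m$instruction == "speed"], m$acc[m$instruction == "accuracy"])
})

test_that("force traces cross the trigger at the recorded response time", {
  tr <- synthesize_force_trace(rt = 0.6, mt = 0.3, peak_force = 26, seed = 1)
  expect_true(is.numeric(tr$force) && is.numeric(tr$time))
  above <- tr$time[tr$force >= 20]
  # trigger threshold reached between movement onset and the peak
  expect_gt(min(above), 0.6)
  expect_lt(min(above), 0.6 + 0.3)
})

test_that("zero-effect stimulation injection leaves behavior unchanged", {
  ds <- simulate_experiment(
    gt = ground_truth(n_subjects = 2,
                      stim = stim_truth(effect_a_accuracy = 0,
                                        effect_a_speed = 0, effect_mt = 0)),
    config = task_config(n_trials = 30), scenario = "bilateral",
    seed = 21, components = character())
  ref <- simulate_experiment(
    gt = ground_truth(n_subjects = 2,
                      stim = stim_truth(effect_a_accuracy = 0,
                                        effect_a_speed = 0, effect_mt = 0)),
    config = task_config(n_trials = 30), scenario = "nostim",
    seed = 21, components = character())
  expect_equal(ds$trials$rt, ref$trials$rt)
  expect_equal(ds$trials$mt, ref$trials$mt)
})

test_that("stimulation flags in trials agree with a from-scratch recount", {
  ds <- small_bilateral()
  s <- names(ds$stim)[1]
  ev <- dplyr::filter(ds$trials, subject == s, !omission)
  bin <- binarize_stimulation(ds$stim[[s]])
  tt <- (seq_along(bin$left) - 1) / bin$rate
  recount <- vapply(seq_len(nrow(ev)), function(i) {
    lo <- ev$t_cue[i] - 0.18; hi <- ev$t_cue[i] - 0.01
    sel <- tt >= lo & tt < hi
    any(bin$left[sel]) || any(bin$right[sel])
  }, logical(1))
  expect_identical(unname(ev$stim_rt_window), unname(recount))
})
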