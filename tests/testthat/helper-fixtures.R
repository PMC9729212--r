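# Shared fixtures, built lazily and cached for the duration of the test run so
# that expensive simulations are only generated once.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small bilateral behavior-only dataset (3 subjects x 40 trials)
small_bilateral <- function() fixture("small_bilateral", function() {
  simulate_experiment(gt = ground_truth(n_subjects = 3),
                      config = task_config(n_trials = 40),
                      scenario = "bilateral", seed = 101,
                      components = character())
})

# small no-stimulation behavior-only dataset (4 subjects x 60 trials)
small_nostim <- function() fixture("small_nostim", function() {
  simulate_experiment(gt = ground_truth(n_subjects = 4),
                      config = task_config(n_trials = 60),
                      scenario = "nostim", seed = 5,
                      components = character())
})

# larger no-stimulation behavior-only dataset for the accuracy model, which
# needs more trials per condition than the continuous outcomes
beh_nostim <- function() fixture("beh_nostim", function() {
  simulate_experiment(gt = ground_truth(n_subjects = 12),
                      config = task_config(n_trials = 360),
                      scenario = "nostim", seed = 5,
                      components = character())
})

# one subject with LFP at a reduced rate (used by spectral tests)
small_lfp <- function() fixture("small_lfp", function() {
  simulate_experiment(gt = ground_truth(n_subjects = 1),
                      config = task_config(n_trials = 20),
                      scenario = "nostim", seed = 7,
                      components = "lfp", lfp_rate = 512)
})

# a hand-built stn_lfp container around an arbitrary signal matrix
make_lfp <- function(data, rate, channels = paste0("c", seq_len(ncol(data))),
                     hemisphere = "left", events = NULL) {
  events <- events %||% tibble::tibble(trial = integer(), t_cue = numeric())
  structure(list(data = data, rate = rate, channels = channels,
                 hemisphere = hemisphere, events = events),
            class = "stn_lfp")
}

# a hand-built stn_tfr container around an arbitrary power matrix
make_tfr <- function(power, times, freqs, rate = 200, step = 0.02,
                     normalized = TRUE) {
  dimnames(power) <- list(NULL, as.character(freqs))
  structure(list(power = power, times = times, freqs = freqs, rate = rate,
                 step = step, cycles = 7, normalized = normalized),
            class = "stn_tfr")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
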