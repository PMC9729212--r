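#' Task configuration for the synthetic speed-accuracy experiment
#'
#' Encodes the timing and response-device constants of the moving-dots
#' speed-accuracy task: a written instruction cue (jittered duration),
#' a dots cue, a grip-force response with a fixed ~20 N trigger, and
#' instruction-dependent response deadlines (2 s speed, 3 s accuracy).
#'
#' @param n_trials trials per session (default 200).
#' @param instruction_jitter instruction-cue duration bounds (s), uniform.
#' @param deadline_speed,deadline_accuracy response deadlines (s).
#' @param coherence fraction of coherently moving dots.
#' @param force_trigger response trigger threshold (N).
#' @param lfp_rate LFP sampling rate (Hz).
#' @param force_rate force channel sampling rate (Hz), defaults to `lfp_rate`.
#' @param iti inter-trial interval after feedback (s).
#' @param feedback feedback duration (s).
#' @param lead_in quiet recording time before the first trial (s).
#' @return an object of class `stn_task_config`.
#' @export
task_config <- function(n_trials = 200, instruction_jitter = c(0.75, 1.25),
                        deadline_speed = 2, deadline_accuracy = 3,
                        coherence = 0.08, force_trigger = 20,
                        lfp_rate = 2048, force_rate = NULL,
                        iti = 0.4, feedback = 0.5, lead_in = 2) {
  if (n_trials < 1) abort("`n_trials` must be positive")
  if (deadline_speed <= 0 || deadline_accuracy <= 0) abort("deadlines must be positive")
  if (deadline_speed >= deadline_accuracy)
    abort("the speed deadline must be shorter than the accuracy deadline")
  if (instruction_jitter[1] > instruction_jitter[2]) abort("jitter bounds must be ordered")
  structure(list(
    n_trials = as.integer(n_trials), instruction_jitter = instruction_jitter,
    deadline_speed = deadline_speed, deadline_accuracy = deadline_accuracy,
    coherence = coherence, force_trigger = force_trigger,
    lfp_rate = lfp_rate, force_rate = force_rate %||% lfp_rate,
    iti = iti, feedback = feedback, lead_in = lead_in
  ), class = "stn_task_config")
}

#' Ground-truth model for a synthetic cohort
#'
#' Draws per-subject drift-diffusion parameters and fixes the generative
#' couplings that the downstream analyses are meant to recover: the
#' instruction-dependent threshold shift (log scale), the negative coupling
#' between trial thresholds and movement times, the LFP band-power couplings
#' and the timing-specific behavioral effects of burst stimulation.
#'
#' Defaults emulate the study conditions: thresholds around 2 evidence
#' units under accuracy instructions with a -0.26 log-unit shift under
#' speed, drift rates around 0.6 (about 70% correct at 8% coherence),
#' non-decision times around 0.30 s, and movement times of ~0.3 s coupled
#' negatively to the trial-level threshold jitter.
#'
#' @param n_subjects cohort size.
#' @param group `"PD"` or `"HC"`.
#' @param seed RNG seed for the subject-level draws.
#' @param a_accuracy_mean,a_accuracy_sd group distribution of accuracy-trial
#'   thresholds.
#' @param instruction_shift log-scale threshold shift for speed instructions
#'   (negative = lower threshold under speed).
#' @param v_mean,v_sd group distribution of drift rates.
#' @param t0_mean,t0_sd group distribution of non-decision times (s).
#' @param w relative starting point.
#' @param a_trial_sd SD of the trial-to-trial threshold jitter.
#' @param mt_accuracy,mt_speed movement-time baselines (s) per instruction.
#' @param mt_slope coupling of movement time (s) to the within-instruction
#'   standardized trial threshold; negative = higher thresholds give faster
#'   movements.
#' @param mt_sd residual movement-time SD (s).
#' @param peak_force_mean,peak_force_sd peak grip force distribution (N).
#' @param covariate_beta_a effect (evidence units per SD) of a synthetic
#'   standard-normal trial covariate on the threshold; 0 disables it.
#' @param double_response_p probability that a trial is flagged as a double
#'   response.
#' @param lfp list of LFP generative settings, see [lfp_truth()].
#' @param stim list of stimulation-effect settings, see [stim_truth()].
#' @return an object of class `stn_ground_truth`.
#' @export
ground_truth <- function(n_subjects = 13, group = "PD", seed = 1,
                         a_accuracy_mean = 2.0, a_accuracy_sd = 0.25,
                         instruction_shift = -0.26,
                         v_mean = 0.6, v_sd = 0.2,
                         t0_mean = 0.30, t0_sd = 0.04, w = 0.5,
                         a_trial_sd = 0.15,
                         mt_accuracy = 0.35, mt_speed = 0.29,
                         mt_slope = -0.03, mt_sd = 0.05,
                         peak_force_mean = 26, peak_force_sd = 2,
                         covariate_beta_a = 0, double_response_p = 0.01,
                         lfp = lfp_truth(), stim = stim_truth()) {
  set.seed(seed)
  a_acc <- pmax(0.8, rnorm(n_subjects, a_accuracy_mean, a_accuracy_sd))
  subjects <- tibble(
    subject = sprintf("S%02d", seq_len(n_subjects)),
    group = group,
    a_accuracy = a_acc,
    a_speed = a_acc * exp(instruction_shift),
    v = pmax(0.15, rnorm(n_subjects, v_mean, v_sd)),
    t0 = pmax(0.12, rnorm(n_subjects, t0_mean, t0_sd)),
    w = w,
    mt_accuracy = pmax(0.15, rnorm(n_subjects, mt_accuracy, 0.03)),
    mt_speed = pmax(0.12, rnorm(n_subjects, mt_speed, 0.03))
  )
  structure(list(
    subjects = subjects, instruction_shift = instruction_shift,
    a_trial_sd = a_trial_sd, mt_slope = mt_slope, mt_sd = mt_sd,
    peak_force_mean = peak_force_mean, peak_force_sd = peak_force_sd,
    covariate_beta_a = covariate_beta_a, double_response_p = double_response_p,
    lfp = lfp, stim = stim, seed = seed
  ), class = "stn_ground_truth")
}

#' LFP generative settings
#'
#' Parameters of the synthetic subthalamic LFP: 1/f background, 50 Hz line,
#' tonic beta with cue-locked and movement-locked suppression, a
#' movement-locked gamma burst and a cue-locked theta response. Amplitudes
#' are in microvolts (SD of the band-limited component).
#'
#' @param amp_beta,amp_gamma,amp_theta tonic band amplitudes (uV).
#' @param background_sd 1/f background SD (uV).
#' @param line_amp 50 Hz line amplitude (uV).
#' @param cue_sup_base baseline fractional beta suppression after the cue.
#' @param cue_sup_coupling extra suppression per SD decrease of the trial
#'   threshold (deeper suppression on low-threshold trials).
#' @param ipsi_factor multiplier on cue suppression for the hemisphere
#'   ipsilateral to the responding hand (< 1 makes contralateral deeper).
#' @param move_sup_base fractional beta suppression around movement.
#' @param move_sup_coupling_speed extra movement suppression per SD decrease
#'   of movement time on speed trials (faster movement, deeper suppression).
#' @param gamma_burst fractional gamma increase on the best contact 0-300 ms
#'   after movement onset; other contacts get `gamma_other` of it.
#' @param gamma_other relative gamma modulation on non-best contacts.
#' @param theta_burst fractional theta increase 0-750 ms after the cue.
#' @param best_contact index of the contact carrying the largest gamma
#'   modulation.
#' @param n_contacts bipolar channels per subthalamic nucleus.
#' @param artifact_amp stimulation pulse-train artifact amplitude (uV).
#' @return a list of settings.
#' @export
lfp_truth <- function(amp_beta = 1.6, amp_gamma = 0.5, amp_theta = 0.9,
                      background_sd = 1.5, line_amp = 1.0,
                      cue_sup_base = 0.40, cue_sup_coupling = 0.42,
                      ipsi_factor = 0.6,
                      move_sup_base = 0.55, move_sup_coupling_speed = 0.18,
                      gamma_burst = 1.4, gamma_other = 0.35, theta_burst = 0.9,
                      best_contact = 2, n_contacts = 3, artifact_amp = 400) {
  as.list(environment())
}

#' Stimulation-effect settings
#'
#' Timing-specific behavioral effects of burst stimulation: trials whose
#' plateau stimulation overlaps a pre-cue window get a threshold change
#' (separately per instruction), trials with stimulation in a post-cue
#' window get a movement-time change. In unilateral sessions the effects
#' apply only when the stimulated hemisphere is contralateral to the
#' responding hand.
#'
#' @param window_rt pre-cue effect window (s relative to cue onset).
#' @param effect_a_accuracy,effect_a_speed threshold change (evidence units)
#'   on stimulated accuracy / speed trials.
#' @param window_mt post-cue effect window (s relative to cue onset).
#' @param effect_mt movement-time change (s) on stimulated trials.
#' @return a list of settings.
#' @export
stim_truth <- function(window_rt = c(-0.180, -0.010),
                       effect_a_accuracy = -0.20, effect_a_speed = 0.10,
                       window_mt = c(0.330, 0.460), effect_mt = -0.03) {
  as.list(environment())
}

#' Generate a randomized trial schedule
#'
#' Lays out a session of trials with a randomized (balanced) instruction
#' sequence, balanced left/right coherent motion directions, jittered
#' instruction-cue durations and provisional cue times on the session clock
#' (a nominal response slot is assumed; actual event times are recomputed
#' once behavior is simulated).
#'
#' @param config a [task_config()].
#' @param seed RNG seed.
#' @param nominal_response nominal response duration used for the
#'   provisional clock (s).
#' @return tibble with one row per trial.
#' @export
generate_trial_schedule <- function(config = task_config(), seed = 1,
                                    nominal_response = 1.4) {
  if (config$n_trials < 1) abort("non-positive trial count")
  set.seed(seed)
  n <- config$n_trials
  instruction <- sample(rep(c("speed", "accuracy"), length.out = n))
  side <- sample(rep(c("left", "right"), length.out = n))
  jitter <- runif(n, config$instruction_jitter[1], config$instruction_jitter[2])
  slot <- jitter + nominal_response + config$feedback + config$iti
  t_instruction <- config$lead_in + c(0, cumsum(slot[-n]))
  tibble(
    trial = seq_len(n), instruction = instruction, side = side,
    cue_jitter = jitter,
    t_instruction = t_instruction,
    t_cue = t_instruction + jitter
  )
}

# raised-cosine force profile: 0 at onset, peak at onset + mt, exponential
# decay afterwards; crosses the trigger threshold during the rise
force_profile <- function(tau, mt, peak, decay = 0.15) {
  f <- numeric(length(tau))
  rise <- tau >= 0 & tau <= mt
  f[rise] <- peak * (1 - cos(pi * tau[rise] / mt)) / 2
  post <- tau > mt
  f[post] <- peak * exp(-(tau[post] - mt) / decay)
  f
}

# time from movement onset until the force trace crosses `trigger`
trigger_latency <- function(mt, peak, trigger) {
  frac <- pmin(0.999, trigger / peak)
  (mt / pi) * acos(1 - 2 * frac)
}

#' Synthesize a single-trial grip-force trace
#'
#' Flat (noisy) baseline, a raised-cosine rise from movement onset reaching
#' peak force at onset + movement time, then an exponential decay. Time 0 is
#' the dots-cue onset; movement onset is at `rt`. An optional tremor
#' oscillation can be superimposed to stress-test threshold-based onset
#' detection.
#'
#' @param rt reaction time (s): cue to movement onset.
#' @param mt movement time (s): onset to peak force; must be positive.
#' @param peak_force peak force above baseline (N).
#' @param rate sampling rate (Hz).
#' @param baseline baseline force level (N).
#' @param noise_sd baseline/measurement noise SD (N).
#' @param tremor_amp,tremor_freq optional tremor amplitude (N) and
#'   frequency (Hz).
#' @param pre,post trace extent before the cue / after the peak (s).
#' @param seed optional RNG seed.
#' @return tibble with columns `time` (s relative to cue) and `force` (N).
#' @export
synthesize_force_trace <- function(rt, mt, peak_force, rate = 2048,
                                   baseline = 0, noise_sd = 0.15,
                                   tremor_amp = 0, tremor_freq = 5,
                                   pre = 1.5, post = 0.5, seed = NULL) {
  if (!is.finite(mt) || mt <= 0) abort("movement time must be positive")
  if (!is.null(seed)) set.seed(seed)
  time <- seq(-pre, rt + mt + post, by = 1 / rate)
  force <- baseline + force_profile(time - rt, mt, peak_force)
  if (noise_sd > 0) force <- force + rnorm(length(time), 0, noise_sd)
  if (tremor_amp > 0)
    force <- force + tremor_amp * sin(2 * pi * tremor_freq * time + runif(1, 0, 2 * pi))
  tibble(time = time, force = force)
}

#' Generate a ramped burst-stimulation schedule
#'
#' Alternating cycles of ramp-up, plateau, ramp-down and interval, with
#' plateau durations drawn from U(150, 350) ms and intervals from
#' U(75, 225) ms. Each sample is labeled with its state; intensity ramps
#' linearly from 0 to 1 during ramps. Pulse parameters (130 Hz, 60 us) are
#' carried as metadata.
#'
#' @param session_length session duration (s).
#' @param mode `"bilateral"`, `"unilateral-left"` or `"unilateral-right"`.
#' @param ramp ramp duration per side (s).
#' @param plateau,interval uniform bounds (s) for plateau and interval
#'   durations.
#' @param rate schedule sampling rate (Hz).
#' @param seed RNG seed.
#' @return object of class `stn_burst_schedule`: per-hemisphere integer
#'   state vectors (0 off, 1 ramp-up, 2 plateau, 3 ramp-down) and intensity
#'   vectors, plus metadata.
#' @export
generate_burst_schedule <- function(session_length,
                                    mode = c("bilateral", "unilateral-left",
                                             "unilateral-right"),
                                    ramp = 0.150, plateau = c(0.150, 0.350),
                                    interval = c(0.075, 0.225), rate = 200,
                                    seed = 1) {
  mode <- match.arg(mode)
  if (session_length < 0) abort("session length must be non-negative")
  if (session_length > 0 && 2 * ramp > session_length)
    abort("ramp duration exceeds the session length")
  set.seed(seed)
  n <- floor(session_length * rate)
  state <- integer(n)
  intensity <- numeric(n)
  if (n > 0) {
    pos <- 1L + floor(runif(1, interval[1], interval[2]) * rate)
    fill <- function(dur, code, ramp_dir) {
      len <- max(1L, round(dur * rate))
      if (pos <= n) {
        idx <- pos:min(n, pos + len - 1L)
        state[idx] <<- code
        intensity[idx] <<- switch(as.character(ramp_dir),
          "0" = 1,
          "1" = (seq_along(idx)) / len,
          "-1" = 1 - seq_along(idx) / len)
      }
      pos <<- pos + len
    }
    while (pos <= n) {
      fill(ramp, 1L, 1)
      fill(runif(1, plateau[1], plateau[2]), 2L, 0)
      fill(ramp, 3L, -1)
      pos <- pos + max(1L, round(runif(1, interval[1], interval[2]) * rate))
    }
  }
  off <- list(state = integer(n), intensity = numeric(n))
  on <- list(state = state, intensity = intensity)
  hemis <- switch(mode,
    "bilateral" = list(left = on, right = on),
    "unilateral-left" = list(left = on, right = off),
    "unilateral-right" = list(left = off, right = on))
  structure(c(hemis, list(
    rate = rate, mode = mode, ramp = ramp,
    pulse = list(freq_hz = 130, width_us = 60)
  )), class = "stn_burst_schedule")
}

# does any plateau sample on `hemi` fall inside [from, to] (s, session clock)?
stim_in_window <- function(schedule, hemi, from, to) {
  st <- schedule[[hemi]]$state
  i1 <- max(1L, floor(from * schedule$rate) + 1L)
  i2 <- min(length(st), ceiling(to * schedule$rate))
  i1 <= i2 && any(st[i1:i2] == 2L)
}

#' Simulate drift-diffusion behavior for one subject's session
#'
#' Sequentially simulates choices, reaction times, movement times and peak
#' forces for a trial schedule, laying actual event times on the session
#' clock as responses unfold. Trial thresholds are the instruction-specific
#' subject threshold plus trial jitter (plus an optional synthetic covariate
#' effect); movement times couple to the within-instruction standardized
#' trial threshold. When a burst schedule is supplied, trials with plateau
#' stimulation in the pre-cue window get a threshold change and trials with
#' stimulation in the post-cue window get a movement-time change (in
#' unilateral sessions only when the stimulated hemisphere is contralateral
#' to the hand cued by the coherent motion).
#'
#' @param schedule trial schedule from [generate_trial_schedule()].
#' @param params one row of `ground_truth$subjects`.
#' @param gt a [ground_truth()] object.
#' @param config a [task_config()].
#' @param seed RNG seed.
#' @param stim optional [generate_burst_schedule()] result.
#' @param dt Euler step (s).
#' @return tibble of per-trial records including event times.
#' @export
simulate_ddm_trials <- function(schedule, params, gt, config = task_config(),
                                seed = 1, stim = NULL, dt = 0.001) {
  if (any(c(params$a_accuracy, params$a_speed) <= 0) || params$t0 < 0 ||
      params$w <= 0 || params$w >= 1)
    abort("invalid drift-diffusion parameters")
  set.seed(seed)
  n <- nrow(schedule)
  inst <- schedule$instruction
  a_base <- ifelse(inst == "speed", params$a_speed, params$a_accuracy)
  a_jit <- rnorm(n, 0, gt$a_trial_sd)
  cov_z <- rnorm(n)
  a_trial <- a_base + a_jit + gt$covariate_beta_a * cov_z
  deadline <- ifelse(inst == "speed", config$deadline_speed, config$deadline_accuracy)
  # within-instruction standardized threshold jitter drives movement time
  jit_z <- ave(a_jit, inst, FUN = zscore)
  mt_base <- ifelse(inst == "speed", params$mt_speed, params$mt_accuracy)
  mt_noise <- rnorm(n, 0, gt$mt_sd)
  peak <- pmax(config$force_trigger + 2,
               rnorm(n, gt$peak_force_mean, gt$peak_force_sd))
  dbl <- runif(n) < gt$double_response_p

  stim_rt <- logical(n); stim_mt <- logical(n); stim_lat <- logical(n)
  rt <- mt <- t_cue <- t_onset <- t_peak <- t_resp <- rep(NA_real_, n)
  correct <- rep(NA_integer_, n)
  clock <- config$lead_in
  swin <- gt$stim

  for (i in seq_len(n)) {
    t_instr <- clock
    tc <- t_instr + schedule$cue_jitter[i]
    t_cue[i] <- tc
    a_i <- a_trial[i]
    mt_i <- max(0.05, mt_base[i] + gt$mt_slope * jit_z[i] + mt_noise[i])
    if (!is.null(stim)) {
      hemi_stim <- switch(stim$mode, "bilateral" = NA_character_,
                          "unilateral-left" = "left", "unilateral-right" = "right")
      # the stimulated hemisphere acts on the contralateral hand
      lateral_ok <- is.na(hemi_stim) ||
        (hemi_stim == "left" && schedule$side[i] == "right") ||
        (hemi_stim == "right" && schedule$side[i] == "left")
      hemi_chk <- if (is.na(hemi_stim)) "left" else hemi_stim
      s_rt <- stim_in_window(stim, hemi_chk, tc + swin$window_rt[1], tc + swin$window_rt[2])
      s_mt <- stim_in_window(stim, hemi_chk, tc + swin$window_mt[1], tc + swin$window_mt[2])
      stim_rt[i] <- s_rt; stim_mt[i] <- s_mt; stim_lat[i] <- lateral_ok
      if (s_rt && lateral_ok)
        a_i <- a_i + if (inst[i] == "speed") swin$effect_a_speed else swin$effect_a_accuracy
      if (s_mt && lateral_ok) mt_i <- max(0.05, mt_i + swin$effect_mt)
    }
    a_i <- max(0.3, a_i)
    a_trial[i] <- a_i
    sim <- sample_ddm_cpp(a_i, params$v, params$t0, params$w, deadline[i], dt)
    if (is.na(sim$rt)) {                       # omission
      clock <- tc + deadline[i] + config$feedback + config$iti
    } else {
      rt[i] <- sim$rt
      correct[i] <- sim$boundary
      mt[i] <- mt_i
      t_onset[i] <- tc + rt[i]
      t_peak[i] <- t_onset[i] + mt_i
      t_resp[i] <- t_onset[i] + trigger_latency(mt_i, peak[i], config$force_trigger)
      clock <- t_resp[i] + config$feedback + config$iti
    }
  }

  response_side <- ifelse(is.na(correct), NA_character_,
                          ifelse(correct == 1L, schedule$side,
                                 ifelse(schedule$side == "left", "right", "left")))
  # `!!` forces the local vectors: the schedule already carries provisional
  # t_instruction/t_cue columns that must be replaced by the realized clock
  schedule %>%
    mutate(
      subject = params$subject, group = params$group,
      t_instruction = !!t_cue - .data$cue_jitter,
      t_cue = !!t_cue, rt = rt, mt = mt,
      peak_force = ifelse(is.na(rt), NA_real_, peak),
      accuracy = correct, omission = is.na(rt),
      double_response = dbl & !is.na(rt),
      response_side = response_side,
      a_trial = a_trial, cov_z = cov_z,
      t_onset = t_onset, t_peak = t_peak, t_response = t_resp,
      stim_rt_window = stim_rt, stim_mt_window = stim_mt,
      stim_lateral = stim_lat
    )
}

# 1/f-shaped gaussian background noise, unit SD
pink_noise <- function(n, rate) {
  nf <- nextn(n, 2)
  x <- fft(rnorm(nf))
  f <- c(1, seq_len(nf - 1))
  f <- pmin(f, nf - f + 1) * rate / nf
  x <- x / sqrt(pmax(f, 0.5))
  y <- Re(fft(x, inverse = TRUE))[seq_len(n)]
  y / sd(y)
}

# band-limited gaussian carrier, unit SD
band_noise <- function(n, rate, lo, hi) {
  bf <- signal::butter(3, c(lo, hi) / (rate / 2), type = "pass")
  y <- signal::filtfilt(bf, rnorm(n + 2 * rate))
  y <- y[(rate + 1):(rate + n)]
  y / sd(y)
}

# add a raised-cosine bump (edges `edge` s) into envelope `env` over [from, to]
add_bump <- function(env, rate, from, to, height, edge = 0.05) {
  n <- length(env)
  i1 <- max(1L, floor(from * rate) + 1L)
  i2 <- min(n, ceiling(to * rate))
  if (i1 > i2) return(env)
  idx <- i1:i2
  len <- length(idx)
  ne <- min(floor(edge * rate), floor(len / 2))
  shape <- rep(1, len)
  if (ne > 0) {
    ramp <- (1 - cos(pi * seq_len(ne) / ne)) / 2
    shape[seq_len(ne)] <- ramp
    shape[(len - ne + 1):len] <- rev(ramp)
  }
  env[idx] <- env[idx] + height * shape
  env
}

#' Synthesize bilateral subthalamic LFP for one subject's session
#'
#' Per hemisphere and contact: 1/f background, 50 Hz line noise, tonic beta
#' (13-30 Hz) with cue-locked suppression (depth coupled to the trial
#' threshold, deeper contralateral to the responding hand) and
#' movement-locked suppression (depth coupled to movement time on speed
#' trials), a gamma (55-80 Hz) burst 0-300 ms after movement onset (largest
#' on the designated best contact) and a theta (4-8 Hz) cue response.
#' When a burst schedule is supplied, a biphasic 130 Hz pulse-train artifact
#' scaled by the ramped intensity plus broadband onset transients are added.
#'
#' @param trials simulated trial table for this subject.
#' @param gt a [ground_truth()] object (uses its `$lfp` settings).
#' @param rate sampling rate (Hz).
#' @param stim optional burst schedule whose artifact should contaminate the
#'   recording.
#' @param seed RNG seed.
#' @return object of class `stn_lfp_session`: per-hemisphere `stn_lfp`
#'   recordings (samples x contacts, dorsal-most contact first) plus the
#'   event table.
#' @export
synthesize_lfp <- function(trials, gt, rate = 2048, stim = NULL, seed = 1) {
  set.seed(seed)
  p <- gt$lfp
  ses_len <- max(trials$t_cue, trials$t_response, na.rm = TRUE) + 2
  n <- ceiling(ses_len * rate)
  jit_z <- ave(trials$a_trial, trials$instruction, FUN = zscore)
  mt_z <- zscore(trials$mt)
  contra <- ifelse(is.na(trials$response_side), NA_character_,
                   ifelse(trials$response_side == "left", "right", "left"))

  make_hemi <- function(hemi) {
    env_beta <- rep(1, n)
    env_gamma_best <- rep(0.15, n)
    env_theta <- rep(0.2, n)
    for (i in seq_len(nrow(trials))) {
      tc <- trials$t_cue[i]
      lat <- if (!is.na(contra[i]) && contra[i] == hemi) 1 else p$ipsi_factor
      d_cue <- p$cue_sup_base - p$cue_sup_coupling * jit_z[i]
      d_cue <- min(0.95, max(0, d_cue)) * lat
      env_beta <- add_bump(env_beta, rate, tc + 0.10, tc + 0.50, -d_cue)
      if (!is.na(trials$t_onset[i])) {
        d_mv <- p$move_sup_base
        if (trials$instruction[i] == "speed" && is.finite(mt_z[i]))
          d_mv <- d_mv - p$move_sup_coupling_speed * mt_z[i]
        d_mv <- min(0.95, max(0, d_mv)) * lat
        tm <- trials$t_onset[i]
        env_beta <- add_bump(env_beta, rate, tm - 0.05, tm + 0.35, -d_mv)
        env_gamma_best <- add_bump(env_gamma_best, rate, tm, tm + 0.30, p$gamma_burst)
      }
      env_theta <- add_bump(env_theta, rate, tc, tc + 0.75, p$theta_burst)
    }
    env_beta <- pmax(env_beta, 0.05)

    dat <- matrix(0, n, p$n_contacts)
    for (k in seq_len(p$n_contacts)) {
      g_k <- if (k == p$best_contact) env_gamma_best else
        0.15 + (env_gamma_best - 0.15) * p$gamma_other
      dat[, k] <- p$background_sd * pink_noise(n, rate) +
        p$line_amp * sin(2 * pi * 50 * seq_len(n) / rate) +
        p$amp_beta * env_beta * band_noise(n, rate, 13, 30) +
        p$amp_gamma * g_k * band_noise(n, rate, 55, 80) +
        p$amp_theta * env_theta * band_noise(n, rate, 4, 8)
    }
    if (!is.null(stim)) dat <- dat + stim_artifact(stim, hemi, n, rate, p$artifact_amp)
    structure(list(
      data = dat, rate = rate,
      channels = sprintf("c%d", seq_len(p$n_contacts)),
      hemisphere = hemi,
      events = trials %>% select(all_of(c("trial", "instruction", "response_side",
                                          "t_cue", "t_onset", "rt", "mt")))
    ), class = "stn_lfp")
  }

  structure(list(left = make_hemi("left"), right = make_hemi("right"),
                 rate = rate, events = trials),
            class = "stn_lfp_session")
}

# biphasic pulse-train + broadband onset-transient artifact on one hemisphere
stim_artifact <- function(stim, hemi, n, rate, amp) {
  sc <- stim[[hemi]]
  if (!any(sc$state != 0L)) return(0)
  intensity <- approx(seq_along(sc$intensity) / stim$rate, sc$intensity,
                      xout = seq_len(n) / rate, rule = 2)$y
  art <- numeric(n)
  pulse_idx <- seq(1, n, by = max(1L, round(rate / stim$pulse$freq_hz)))
  art[pulse_idx] <- 1
  nx <- pulse_idx + 1L
  nx <- nx[nx <= n]
  art[nx] <- art[nx] - 0.8
  art <- art * intensity * amp
  # broadband transient at each ramp-up onset
  on_idx <- which(diff(c(0L, as.integer(sc$state == 1L))) == 1L)
  for (o in on_idx) {
    i0 <- max(1L, round(o / stim$rate * rate))
    if (i0 > n) next
    idx <- i0:min(n, i0 + round(0.05 * rate))
    art[idx] <- art[idx] + rnorm(length(idx), 0, amp / 4) *
      exp(-seq_along(idx) / (0.015 * rate))
  }
  art
}

#' Re-simulate a dataset with stimulation effects injected
#'
#' Takes a simulated dataset and regenerates the behavioral records with the
#' configured timing-specific stimulation effects applied, reusing the same
#' per-subject behavioral random streams: with zero effect sizes the
#' original trials are reproduced exactly, so stimulated and unstimulated
#' trials are statistically exchangeable.
#'
#' @param dataset an `stn_dataset` from [simulate_experiment()].
#' @param gt optional replacement ground truth (e.g., different effect
#'   sizes); defaults to the dataset's own.
#' @return the dataset with updated trials and ground truth.
#' @export
inject_stim_effects <- function(dataset, gt = NULL) {
  gt <- gt %||% dataset$ground_truth
  if (gt$stim$window_rt[1] < -2 || gt$stim$window_mt[2] > 3)
    abort("stimulation effect windows fall outside the trial")
  seeds <- dataset$seeds
  trials <- purrr::map_dfr(seq_len(nrow(gt$subjects)), function(j) {
    params <- gt$subjects[j, ]
    simulate_ddm_trials(dataset$schedules[[j]], params, gt, dataset$config,
                        seed = seeds$behavior[j], stim = dataset$stim[[j]])
  })
  dataset$trials <- trials
  dataset$ground_truth <- gt
  dataset
}

#' Simulate a complete synthetic experiment
#'
#' End-to-end generator: trial schedules, drift-diffusion behavior, force
#' traces, bilateral LFP and burst-stimulation schedules for a whole cohort,
#' fully determined by one master seed. Independent sub-streams are derived
#' per component and subject, so e.g. regenerating LFP noise leaves the
#' behavioral draws unchanged.
#'
#' @param gt a [ground_truth()] cohort.
#' @param config a [task_config()].
#' @param scenario `"nostim"`, `"bilateral"`, `"unilateral-left"` or
#'   `"unilateral-right"`.
#' @param seed master seed.
#' @param components which signals to generate besides the trial table:
#'   subset of `c("force", "lfp")`. Omitting `"lfp"` keeps memory small for
#'   behavior-only studies.
#' @param lfp_rate,stim_rate sampling rates (Hz) for the LFP and the
#'   stimulation schedule; default to the task configuration's LFP rate and
#'   200 Hz respectively.
#' @return object of class `stn_dataset` with elements `trials`,
#'   `schedules`, `stim`, `force`, `lfp`, `ground_truth`, `config`,
#'   `scenario`, `seed`, `seeds`.
#' @export
simulate_experiment <- function(gt = ground_truth(), config = task_config(),
                                scenario = c("nostim", "bilateral",
                                             "unilateral-left", "unilateral-right"),
                                seed = 1, components = c("force", "lfp"),
                                lfp_rate = NULL, stim_rate = 200) {
  scenario <- match.arg(scenario)
  lfp_rate <- lfp_rate %||% config$lfp_rate
  nsub <- nrow(gt$subjects)
  master <- derive_seeds(seed, c("schedule", "behavior", "force", "lfp", "stim"))
  seeds <- lapply(master, function(s) unlist(derive_seeds(s, gt$subjects$subject)))

  # generous provisional session length for the stimulation schedule
  nominal_len <- config$lead_in +
    config$n_trials * (mean(config$instruction_jitter) +
                         config$deadline_accuracy + config$feedback + config$iti) + 10

  schedules <- stims <- trials <- vector("list", nsub)
  force <- if ("force" %in% components) vector("list", nsub) else NULL
  lfp <- if ("lfp" %in% components) vector("list", nsub) else NULL

  for (j in seq_len(nsub)) {
    params <- gt$subjects[j, ]
    schedules[[j]] <- generate_trial_schedule(config, seed = seeds$schedule[j])
    stim_j <- if (scenario == "nostim") NULL else
      generate_burst_schedule(nominal_len, mode = scenario, rate = stim_rate,
                              seed = seeds$stim[j])
    stims[j] <- list(stim_j)
    trials[[j]] <- simulate_ddm_trials(schedules[[j]], params, gt, config,
                                       seed = seeds$behavior[j], stim = stim_j)
    if (!is.null(force)) {
      tr <- trials[[j]]
      set.seed(seeds$force[j])
      force[[j]] <- purrr::map(seq_len(nrow(tr)), function(i) {
        if (is.na(tr$rt[i])) return(NULL)
        synthesize_force_trace(tr$rt[i], tr$mt[i], tr$peak_force[i],
                               rate = config$force_rate)
      })
    }
    if (!is.null(lfp))
      lfp[[j]] <- synthesize_lfp(trials[[j]], gt, rate = lfp_rate,
                                 stim = stim_j, seed = seeds$lfp[j])
  }
  names(schedules) <- names(stims) <- names(trials) <- gt$subjects$subject
  if (!is.null(force)) names(force) <- gt$subjects$subject
  if (!is.null(lfp)) names(lfp) <- gt$subjects$subject

  structure(list(
    trials = bind_rows(trials), schedules = schedules, stim = stims,
    force = force, lfp = lfp, ground_truth = gt, config = config,
    scenario = scenario, seed = seed, seeds = seeds
  ), class = "stn_dataset")
}
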