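# ---------------------------------------------------------------------------
# Orchestration, configuration and I/O.
#
# Unit convention: all times stored in files are seconds; window
# specifications in configs carry an explicit `_ms` suffix when given in
# milliseconds.
# ---------------------------------------------------------------------------

#' Pipeline run configuration
#'
#' Defaults are the scaled-down continuous-integration profile (8 subjects,
#' 120 trials, 500 permutations, 2000 retained MCMC draws);
#' `paper_scale = TRUE` switches to the study-scale profile (13 subjects,
#' 200 trials, 1000 permutations, 10000 iterations with 2000 burn-in).
#'
#' @param seed master seed; every stage derives its own sub-stream.
#' @param scenario `"nostim"`, `"bilateral"`, `"unilateral-left"` or
#'   `"unilateral-right"`.
#' @param n_subjects,n_trials synthetic cohort size.
#' @param n_perm cluster-permutation count.
#' @param chains,iter,burn MCMC settings (behavior and drift-diffusion).
#' @param components signal components to synthesize (`"force"`, `"lfp"`).
#' @param lfp_rate LFP sampling rate (Hz).
#' @param paper_scale use the study-scale profile.
#' @param out_dir optional directory for artifacts.
#' @return a `stn_config` list.
#' @export
pipeline_config <- function(seed = 1, scenario = "bilateral",
                            n_subjects = 8, n_trials = 120, n_perm = 500,
                            chains = 2, iter = 2500, burn = 500,
                            components = "force", lfp_rate = 512,
                            paper_scale = FALSE, out_dir = NULL) {
  cfg <- as.list(environment())
  if (paper_scale) {
    cfg$n_subjects <- 13; cfg$n_trials <- 200; cfg$n_perm <- 1000
    cfg$chains <- 3; cfg$iter <- 10000; cfg$burn <- 2000
  }
  structure(cfg, class = "stn_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_config()] returns an `stn_config`; [write_config()]
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) abort(paste0("unknown config fields: ", paste(bad, collapse = ", ")))
  # YAML has no empty character vector; an empty sequence reads as list()
  if (!is.null(raw$components)) raw$components <- as.character(unlist(raw$components))
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @param config an `stn_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes, in dependency order: experiment synthesis, behavioral
#' exclusions and hierarchical regressions, LFP feature extraction (when
#' `"lfp"` is among the components), the hierarchical drift-diffusion
#' instruction model, and the sliding-window stimulation analysis (skipped
#' for the `"nostim"` scenario). Returns a structured report; identical
#' config and seed give an identical report.
#'
#' @param config an `stn_config` (or YAML path).
#' @return `stn_report`: nested list of per-stage metrics plus provenance.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "stn_config"))
  seeds <- derive_seeds(config$seed, c("truth", "experiment", "models", "perm"))
  report <- list()

  # --- synthesis ----------------------------------------------------------
  gt <- ground_truth(n_subjects = config$n_subjects, seed = seeds$truth)
  task <- task_config(n_trials = config$n_trials, lfp_rate = config$lfp_rate)
  ds <- simulate_experiment(gt, task, scenario = config$scenario,
                            seed = seeds$experiment,
                            components = config$components)
  report$synthio <- list(
    scenario = config$scenario, n_subjects = config$n_subjects,
    n_trials_total = nrow(ds$trials),
    omission_rate = mean(ds$trials$omission)
  )

  # --- behavior -----------------------------------------------------------
  flt <- filter_trials(ds$trials)
  excl <- attr(flt, "exclusion_report")
  beh <- prepare_behavior(flt[flt$included, , drop = FALSE])
  fit_rt <- fit_hlm(beh, log_rt ~ instr_c + (1 | subject),
                    chains = config$chains, iter = config$iter,
                    burn = config$burn, seed = seeds$models)
  fit_mt <- fit_hlm(beh, log_mt ~ instr_c + (1 | subject),
                    chains = config$chains, iter = config$iter,
                    burn = config$burn, seed = seeds$models + 1)
  fit_acc <- fit_hlogit(beh, accuracy ~ instr_c + (1 | subject),
                        chains = config$chains, iter = config$iter,
                        burn = config$burn, seed = seeds$models + 2)
  report$behavior <- list(
    exclusions = excl,
    n_included = nrow(beh),
    rt_instruction = decide_significance(fit_rt, "instr_c"),
    mt_instruction = decide_significance(fit_mt, "instr_c"),
    accuracy_instruction = decide_significance(fit_acc, "instr_c"),
    converged = c(rt = fit_rt$converged, mt = fit_mt$converged,
                  accuracy = fit_acc$converged)
  )

  # --- spectral -----------------------------------------------------------
  features <- NULL
  if ("lfp" %in% config$components && config$scenario == "nostim") {
    features <- extract_lfp_features(ds)
    beh <- left_join(beh, features, by = c("subject", "trial"))
    report$spectral <- list(
      n_feature_trials = nrow(features),
      beta_cue_contrast = condition_contrast(
        left_join(features, ds$trials[, c("subject", "trial", "instruction")],
                  by = c("subject", "trial")), "beta_cue")
    )
  }

  # --- drift diffusion ----------------------------------------------------
  fit_ddm <- fit_hddm(beh, a = ~instr_c, chains = config$chains,
                      iter = config$iter, burn = config$burn,
                      seed = seeds$models + 3)
  ci <- cri(fit_ddm$draws[, "a_instr_c"])
  report$ddm <- list(
    threshold_instruction = tibble(term = "a_instr_c",
                                   mean = mean(fit_ddm$draws[, "a_instr_c"]),
                                   lower = ci[["lower"]], upper = ci[["upper"]],
                                   significant = ci[["upper"]] < 0 | ci[["lower"]] > 0),
    rhat_max = max(fit_ddm$rhat[fit_ddm$terms]),
    converged = fit_ddm$converged
  )
  if (!is.null(features)) {
    reg <- fit_hddm_regression(beh[!is.na(beh$beta_cue) & beh$ok_beta_cue, ],
                               covariate = "beta_cue",
                               chains = config$chains, iter = config$iter,
                               burn = config$burn, seed = seeds$models + 4)
    cib <- cri(reg$draws[, "a_beta_cue_z"])
    report$ddm$beta_cue_threshold <- tibble(
      term = "a_beta_cue_z", mean = mean(reg$draws[, "a_beta_cue_z"]),
      lower = cib[["lower"]], upper = cib[["upper"]],
      significant = cib[["upper"]] < 0 | cib[["lower"]] > 0)
  }

  # --- stimulation windows ------------------------------------------------
  if (config$scenario != "nostim") {
    trr <- beh
    effs <- do.call(rbind, lapply(unique(trr$subject), function(s) {
      w <- assign_windows(binarize_stimulation(ds$stim[[s]]),
                          trr[trr$subject == s, , drop = FALSE])
      sat_effect_per_window(w)$effects
    }))
    ct <- cluster_permutation(effs, n_perm = config$n_perm, seed = seeds$perm)
    report$stimwin <- list(
      coverage_mean = {
        s1 <- unique(trr$subject)[1]
        w1 <- assign_windows(binarize_stimulation(ds$stim[[s1]]),
                             trr[trr$subject == s1, , drop = FALSE])
        mean(stim_coverage(w1)$fraction)
      },
      clusters = ct$clusters,
      n_significant = sum(ct$clusters$significant)
    )
  }

  report$provenance <- list(
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("stnsat")),
    timestamp = NULL  # kept NULL so reports are bit-identical per config+seed
  )
  structure(report, class = "stn_report")
}

#' Write / read a synthetic dataset container
#'
#' Serializes an `stn_dataset` to a directory: trial table and schedules as
#' Feather (lossless for doubles), LFP signals as Feather (one file per
#' subject and hemisphere, one column per contact plus `time`), force
#' traces as Feather, events as CSV for interoperability, and ground truth,
#' configuration and seeds as maximum-precision JSON.
#'
#' @param dataset an `stn_dataset`.
#' @param path output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "stn_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  arrow::write_feather(dataset$trials, file.path(path, "trials.feather"))
  write.csv(dataset$trials, file.path(path, "trials.csv"), row.names = FALSE)
  js <- function(x, f) jsonlite::write_json(
    x, file.path(path, f), auto_unbox = TRUE, digits = NA, null = "null")
  js(list(ground_truth = unclass_deep(dataset$ground_truth),
          config = unclass(dataset$config),
          scenario = dataset$scenario, seed = dataset$seed,
          seeds = dataset$seeds), "meta.json")
  for (s in names(dataset$schedules)) {
    arrow::write_feather(dataset$schedules[[s]],
                         file.path(path, paste0("schedule_", s, ".feather")))
    if (!is.null(dataset$stim[[s]])) {
      st <- dataset$stim[[s]]
      arrow::write_feather(
        tibble(left_state = st$left$state, left_intensity = st$left$intensity,
               right_state = st$right$state, right_intensity = st$right$intensity),
        file.path(path, paste0("stim_", s, ".feather")))
      js(list(rate = st$rate, mode = st$mode, ramp = st$ramp, pulse = st$pulse),
         paste0("stim_", s, ".json"))
    }
    if (!is.null(dataset$lfp[[s]])) {
      for (h in c("left", "right")) {
        l <- dataset$lfp[[s]][[h]]
        d <- as_tibble(as.data.frame(l$data))
        names(d) <- l$channels
        d$time <- (seq_len(nrow(d)) - 1) / l$rate
        arrow::write_feather(d, file.path(path, paste0("lfp_", s, "_", h, ".feather")))
        write.csv(l$events, file.path(path, paste0("events_", s, "_", h, ".csv")),
                  row.names = FALSE)
        js(list(rate = l$rate, channels = l$channels, hemisphere = h),
           paste0("lfp_", s, "_", h, ".json"))
      }
    }
    if (!is.null(dataset$force[[s]])) {
      tr <- purrr::imap_dfr(dataset$force[[s]], function(f, i) {
        if (is.null(f)) return(NULL)
        f$trial <- as.integer(i); f
      })
      arrow::write_feather(tr, file.path(path, paste0("force_", s, ".feather")))
    }
  }
  invisible(path)
}

# strip S3 classes recursively so jsonlite serializes plain structures
unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_deep)
  } else x
}

#' @rdname write_dataset
#' @return [read_dataset()] returns the reconstructed `stn_dataset`
#'   (signal components included when present in the container).
#' @export
read_dataset <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  trials <- arrow::read_feather(file.path(path, "trials.feather"))
  subs <- unique(trials$subject)
  gt <- meta$ground_truth
  gt$subjects <- as_tibble(gt$subjects)
  class(gt) <- "stn_ground_truth"
  config <- meta$config
  schedules <- stims <- lfp <- force <- setNames(vector("list", length(subs)), subs)
  has_lfp <- FALSE
  for (s in subs) {
    schedules[[s]] <- arrow::read_feather(file.path(path, paste0("schedule_", s, ".feather")))
    fs <- file.path(path, paste0("stim_", s, ".feather"))
    if (file.exists(fs)) {
      d <- arrow::read_feather(fs)
      m <- jsonlite::read_json(file.path(path, paste0("stim_", s, ".json")),
                               simplifyVector = TRUE)
      stims[[s]] <- structure(list(
        left = list(state = as.integer(d$left_state), intensity = d$left_intensity),
        right = list(state = as.integer(d$right_state), intensity = d$right_intensity),
        rate = m$rate, mode = m$mode, ramp = m$ramp, pulse = as.list(m$pulse)
      ), class = "stn_burst_schedule")
    }
    fl <- file.path(path, paste0("lfp_", s, "_left.feather"))
    if (file.exists(fl)) {
      has_lfp <- TRUE
      lfp[[s]] <- structure(list(
        left = import_recording(path, s, "left"),
        right = import_recording(path, s, "right"),
        rate = NA, events = NULL), class = "stn_lfp_session")
      lfp[[s]]$rate <- lfp[[s]]$left$rate
    }
    ff <- file.path(path, paste0("force_", s, ".feather"))
    if (file.exists(ff)) {
      d <- arrow::read_feather(ff)
      force[[s]] <- lapply(seq_len(max(d$trial)), function(i) {
        out <- d[d$trial == i, setdiff(names(d), "trial"), drop = FALSE]
        if (nrow(out)) out else NULL
      })
    }
  }
  structure(list(
    trials = trials, schedules = schedules, stim = stims,
    force = if (any(!vapply(force, is.null, TRUE))) force else NULL,
    lfp = if (has_lfp) lfp else NULL,
    ground_truth = gt, config = config,
    scenario = meta$scenario, seed = meta$seed, seeds = meta$seeds
  ), class = "stn_dataset")
}

#' Import one LFP recording from a dataset container
#'
#' Reads the Feather signal file and CSV event table of one subject and
#' hemisphere, validating that event markers fall within the recording.
#'
#' @param path container directory.
#' @param subject subject id (e.g. `"S01"`).
#' @param hemisphere `"left"` or `"right"`.
#' @return an `stn_lfp`.
#' @export
import_recording <- function(path, subject, hemisphere) {
  f <- file.path(path, paste0("lfp_", subject, "_", hemisphere, ".feather"))
  if (!file.exists(f)) abort(paste0("no recording at ", f))
  d <- arrow::read_feather(f)
  m <- jsonlite::read_json(sub("feather$", "json", f), simplifyVector = TRUE)
  ev <- read.csv(file.path(path, paste0("events_", subject, "_", hemisphere, ".csv")))
  dur <- nrow(d) / m$rate
  tt <- ev$t_cue[is.finite(ev$t_cue)]
  if (length(tt) && (min(tt) < 0 || max(tt) > dur))
    abort("event markers fall outside the recording")
  structure(list(
    data = as.matrix(d[, m$channels, drop = FALSE]),
    rate = m$rate, channels = m$channels, hemisphere = m$hemisphere,
    events = as_tibble(ev)
  ), class = "stn_lfp")
}

#' Assemble a run report from stage artifacts
#'
#' @param artifacts named list of per-stage metric lists (non-empty).
#' @param config the `stn_config` used, for provenance.
#' @return `stn_report`.
#' @export
make_report <- function(artifacts, config = NULL) {
  if (!length(artifacts)) abort("empty artifact set")
  if (is.null(names(artifacts)) || any(names(artifacts) == ""))
    abort("artifacts must be a fully named list")
  rep <- artifacts
  rep$provenance <- list(
    config = if (!is.null(config)) unclass(config),
    config_hash = if (!is.null(config)) rlang::hash(unclass(config)),
    package_version = as.character(utils::packageVersion("stnsat"))
  )
  structure(rep, class = "stn_report")
}

#' @export
print.stn_report <- function(x, ...) {
  cat("<stn_report>", paste(setdiff(names(x), "provenance"), collapse = ", "), "\n")
  s <- x$synthio
  cat(sprintf("synthio:  scenario '%s', %d subjects, %d trials (%.1f%% omissions)\n",
              s$scenario, s$n_subjects, s$n_trials_total, 100 * s$omission_rate))
  dec_line <- function(label, d)
    cat(sprintf("  %-22s [%7.3f, %7.3f]  %s\n", label, d$lower, d$upper,
                if (d$significant) paste0("significant, ", d$direction) else "n.s."))
  cat(sprintf("behavior: %d trials included\n", x$behavior$n_included))
  dec_line("rt ~ instruction", x$behavior$rt_instruction)
  dec_line("mt ~ instruction", x$behavior$mt_instruction)
  dec_line("accuracy ~ instruction", x$behavior$accuracy_instruction)
  if (!is.null(x$ddm)) {
    ti <- x$ddm$threshold_instruction
    cat(sprintf("ddm:      threshold ~ instruction: %.3f [%.3f, %.3f]  %s (max R-hat %.2f)\n",
                ti$mean, ti$lower, ti$upper,
                if (ti$significant) "significant" else "n.s.", x$ddm$rhat_max))
  }
  if (!is.null(x$stimwin)) {
    cat(sprintf("stimwin:  mean plateau coverage %.1f%%; %d significant cluster(s)\n",
                100 * x$stimwin$coverage_mean, x$stimwin$n_significant))
    sig <- x$stimwin$clusters[x$stimwin$clusters$significant, , drop = FALSE]
    if (nrow(sig))
      for (i in seq_len(nrow(sig)))
        cat(sprintf("  windows %d-%d (mass %.1f, p = %.3f)\n",
                    sig$from[i], sig$to[i], sig$mass[i], sig$p[i]))
  }
  invisible(x)
}
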