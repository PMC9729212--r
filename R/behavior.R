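#' Detect movement onset in a grip-force trace
#'
#' Threshold-based automatic onset detection: the baseline is taken 1 s to
#' 0.5 s before the response trigger, and onset is the first sample at or
#' after the dots cue where force exceeds baseline mean + `k` baseline SDs.
#' Returns `NA` when the trace never crosses the threshold (e.g., a flat
#' trace). High-amplitude tremor can defeat the fixed threshold, which is
#' why annotated onsets can be supplied downstream instead.
#'
#' @param trace tibble with columns `time` (s, 0 = dots-cue onset) and
#'   `force` (N).
#' @param response_time trigger time (s relative to cue).
#' @param k threshold in baseline SDs (default 5).
#' @param baseline_window window relative to the response used as baseline
#'   (default 1 to 0.5 s before).
#' @return onset time in seconds relative to the cue, or `NA`.
#' @export
detect_movement_onset <- function(trace, response_time, k = 5,
                                  baseline_window = c(-1, -0.5)) {
  bl <- trace$force[trace$time >= response_time + baseline_window[1] &
                    trace$time <= response_time + baseline_window[2]]
  if (length(bl) < 2) abort("trace does not cover the baseline window")
  thr <- mean(bl) + k * sd(bl)
  post <- trace$time >= 0
  hit <- which(post & trace$force > thr)
  if (length(hit) == 0) return(NA_real_)
  trace$time[hit[1]]
}

#' Derive trial measures from a force trace
#'
#' Reaction time (cue to movement onset), movement time (onset to peak
#' force) and peak force (maximum minus baseline force), using either an
#' annotated onset or the automatic detector.
#'
#' @inheritParams detect_movement_onset
#' @param onset optional annotated onset time (s relative to cue); when
#'   `NULL` the automatic detector is used.
#' @return one-row tibble with `rt`, `mt`, `peak_force`, `onset`.
#' @export
derive_trial_measures <- function(trace, response_time, onset = NULL, k = 5,
                                  baseline_window = c(-1, -0.5)) {
  onset <- onset %||% detect_movement_onset(trace, response_time, k, baseline_window)
  if (is.na(onset))
    return(tibble(rt = NA_real_, mt = NA_real_, peak_force = NA_real_,
                  onset = NA_real_))
  bl <- trace$force[trace$time >= response_time + baseline_window[1] &
                    trace$time <= response_time + baseline_window[2]]
  ipk <- which.max(trace$force)
  t_peak <- trace$time[ipk]
  if (t_peak < onset) abort("peak force occurs before movement onset")
  tibble(rt = onset, mt = t_peak - onset,
         peak_force = max(trace$force) - mean(bl), onset = onset)
}

#' Apply the trial exclusion rules
#'
#' Marks omissions, double responses and responses faster than `rt_min`
#' (default 0.25 s) as excluded. Flags are conjunctive, so the order of
#' application is irrelevant. An exclusion report is attached as the
#' `"exclusion_report"` attribute.
#'
#' @param trials trial tibble with columns `rt`, `omission`,
#'   `double_response`.
#' @param rt_min fastest admissible reaction time (s).
#' @return the tibble with added `excl_omission`, `excl_double`,
#'   `excl_fast` and `included` columns.
#' @export
filter_trials <- function(trials, rt_min = 0.25) {
  out <- trials
  if (!"omission" %in% names(out)) out$omission <- is.na(out$rt)
  if (!"double_response" %in% names(out)) out$double_response <- FALSE
  out <- out %>%
    mutate(
      excl_omission = .data$omission,
      excl_double = .data$double_response,
      excl_fast = !is.na(.data$rt) & .data$rt < rt_min,
      included = !.data$excl_omission & !.data$excl_double & !.data$excl_fast
    )
  report <- tibble(
    n = nrow(out),
    omission = sum(out$excl_omission),
    double_response = sum(out$excl_double),
    fast = sum(out$excl_fast),
    included = sum(out$included)
  )
  if (report$included == 0 && report$n > 0)
    warn("no trials remain after exclusion")
  attr(out, "exclusion_report") <- report
  out
}

#' Add model-ready predictor codings to a trial table
#'
#' Sum-codes Instruction (+0.5 speed, -0.5 accuracy) and Group (+0.5 PD,
#' -0.5 HC) so main effects stay interpretable in the presence of
#' interactions, log-transforms the skewed reaction-time, movement-time and
#' peak-force measures, and standardizes movement time within subject.
#'
#' @param trials trial tibble (typically after [filter_trials()]).
#' @return the tibble with added `instr_c`, `group_c`, `log_rt`, `log_mt`,
#'   `log_force`, `mt_z` columns.
#' @export
prepare_behavior <- function(trials) {
  out <- trials %>%
    mutate(
      instr_c = ifelse(.data$instruction == "speed", 0.5, -0.5),
      group_c = ifelse(.data$group == "PD", 0.5, -0.5),
      side_c = ifelse(.data$response_side == "right", 0.5, -0.5),
      log_rt = log(.data$rt),
      log_mt = log(.data$mt),
      log_force = log(.data$peak_force)
    )
  zscore_by_subject(out, "mt", suffix = "_z")
}

# pull (expr | group) terms out of an lme4-style formula
split_bars <- function(formula) {
  bars <- list()
  strip <- function(e) {
    if (is.call(e)) {
      if (identical(e[[1]], as.name("+"))) {
        l <- strip(e[[2]]); r <- strip(e[[3]])
        if (is.null(l)) return(r)
        if (is.null(r)) return(l)
        return(call("+", l, r))
      }
      if (identical(e[[1]], as.name("(")) && is.call(e[[2]]) &&
          identical(e[[2]][[1]], as.name("|"))) {
        bars[[length(bars) + 1]] <<- e[[2]]
        return(NULL)
      }
    }
    e
  }
  fixed_rhs <- strip(formula[[3]]) %||% 1
  list(fixed = as.formula(call("~", formula[[2]], fixed_rhs),
                          env = environment(formula)),
       bars = bars)
}

jags_hlm_string <- function(family) {
  lik <- if (family == "gaussian") "
    y[i] ~ dnorm(mu[i], tau)
    mu[i] <- inprod(X[i,], beta) + inprod(Z[i,], u[subj[i],])" else "
    y[i] ~ dbern(p[i])
    logit(p[i]) <- inprod(X[i,], beta) + inprod(Z[i,], u[subj[i],])"
  extra <- if (family == "gaussian")
    "tau <- pow(sigma, -2)\n  sigma ~ dt(0, 1, 3) T(0,)" else ""
  sprintf("model {
  for (i in 1:N) {%s
  }
  for (j in 1:J) { for (k in 1:K) { u[j,k] ~ dnorm(0, tau_u[k]) } }
  for (p in 1:P) { beta[p] ~ dnorm(0, 0.16) }
  for (k in 1:K) { tau_u[k] <- pow(sigma_u[k], -2)\n    sigma_u[k] ~ dt(0, 1, 3) T(0,) }
  %s
}", lik, extra)
}

fit_jags_hier <- function(formula, data, family, chains, iter, burn, seed) {
  parts <- split_bars(formula)
  if (length(parts$bars) != 1)
    abort("exactly one random-effects term `( ... | subject )` is required")
  bar <- parts$bars[[1]]
  grp <- all.vars(bar[[3]])
  stopifnot(length(grp) == 1)
  mf <- stats::model.frame(parts$fixed, data = data, na.action = na.omit)
  keep <- as.integer(rownames(mf))
  X <- model.matrix(attr(mf, "terms"), mf)
  y <- stats::model.response(mf)
  Z <- model.matrix(as.formula(call("~", bar[[2]])), data[keep, , drop = FALSE])
  subj <- as.integer(factor(data[[grp]][keep]))
  jd <- list(y = as.numeric(y), N = length(y), X = X, P = ncol(X),
             Z = Z, K = ncol(Z), subj = subj, J = max(subj))
  inits <- lapply(seq_len(chains), function(c) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (seed + 1000L * c) %% .Machine$integer.max)
  })
  monitors <- c("beta", "sigma_u", if (family == "gaussian") "sigma")
  mod <- rjags::jags.model(textConnection(jags_hlm_string(family)), data = jd,
                           inits = inits, n.chains = chains, quiet = TRUE)
  update(mod, burn, progress.bar = "none")
  samp <- rjags::coda.samples(mod, monitors, n.iter = iter - burn,
                              progress.bar = "none")
  term_names <- colnames(X)
  re_names <- paste0("sd_", colnames(Z), "|", grp)
  draws_by_chain <- lapply(samp, function(ch) {
    m <- as.matrix(ch)
    cn <- colnames(m)
    # JAGS drops the index on length-one vectors
    cn[cn == "beta"] <- term_names[1]
    cn[cn == "sigma_u"] <- re_names[1]
    for (p in seq_along(term_names))
      cn[cn == sprintf("beta[%d]", p)] <- term_names[p]
    for (k in seq_along(re_names))
      cn[cn == sprintf("sigma_u[%d]", k)] <- re_names[k]
    colnames(m) <- cn
    m
  })
  all_draws <- do.call(rbind, draws_by_chain)
  rhat <- vapply(colnames(all_draws), function(cn) {
    split_rhat(do.call(cbind, lapply(draws_by_chain, function(m) m[, cn])))
  }, numeric(1))
  structure(list(
    draws = all_draws, draws_by_chain = draws_by_chain,
    terms = term_names, re_terms = re_names, family = family,
    formula = formula, rhat = rhat, n_obs = length(y), n_subjects = max(subj),
    chains = chains, iter = iter, burn = burn,
    converged = all(rhat < 1.1, na.rm = TRUE)
  ), class = "stn_posterior")
}

#' Fit a hierarchical Bayesian linear regression
#'
#' Hierarchical (linear mixed) regression of a continuous, typically
#' log-transformed, trial measure on sum-coded predictors, with
#' subject-level random deviations for the terms named in the single
#' `( ... | subject )` component of the formula (independent random
#' effects). Coefficients get weakly informative normal(0, 2.5) priors,
#' standard deviations half-t(3) priors. Sampling runs `chains` MCMC chains
#' of `iter` iterations, discarding `burn` as burn-in; convergence is
#' assessed by split-R-hat and flagged (not silently accepted) when any
#' R-hat exceeds 1.1.
#'
#' @param data trial tibble ([prepare_behavior()] supplies codings).
#' @param formula lme4-style formula, e.g.
#'   `log_rt ~ instr_c * group_c + (instr_c | subject)`.
#' @param chains,iter,burn sampler settings (defaults 3 chains x 5000
#'   iterations, 500 burn-in).
#' @param seed RNG seed.
#' @return an `stn_posterior` object; see [tidy.stn_posterior()].
#' @export
fit_hlm <- function(data, formula, chains = 3, iter = 5000, burn = 500,
                    seed = 1) {
  fit <- fit_jags_hier(formula, data, "gaussian", chains, iter, burn, seed)
  if (!fit$converged)
    warn(sprintf("convergence not reached: max R-hat = %.3f", max(fit$rhat)))
  fit
}

#' Fit a hierarchical Bayesian logistic regression
#'
#' As [fit_hlm()] but with a Bernoulli likelihood and logit link, for
#' response accuracy; coefficients are changes in the log-odds that a trial
#' is correct. The weakly informative priors regularize separation (e.g., a
#' subject with all-correct responses).
#'
#' @inheritParams fit_hlm
#' @return an `stn_posterior` object.
#' @export
fit_hlogit <- function(data, formula, chains = 3, iter = 5000, burn = 500,
                       seed = 1) {
  fit <- fit_jags_hier(formula, data, "binomial", chains, iter, burn, seed)
  if (!fit$converged)
    warn(sprintf("convergence not reached: max R-hat = %.3f", max(fit$rhat)))
  fit
}

#' Posterior significance decision for one coefficient
#'
#' Two-tailed decisions use the 95% credible interval; one-tailed decisions
#' use the 90% interval together with a check that the posterior mass lies
#' on the hypothesized side. An effect is significant when the interval
#' excludes zero.
#'
#' @param fit an `stn_posterior` or `stn_ddm_fit` object.
#' @param term coefficient name (see `tidy(fit)`).
#' @param tail `"two"` or `"one"`.
#' @param direction for one-tailed tests, the hypothesized sign
#'   (`"negative"` or `"positive"`).
#' @return one-row tibble with the interval, decision and direction.
#' @export
decide_significance <- function(fit, term, tail = c("two", "one"),
                                direction = c("negative", "positive")) {
  tail <- match.arg(tail)
  direction <- match.arg(direction)
  draws <- if (inherits(fit, "stn_posterior") || inherits(fit, "stn_ddm_fit"))
    fit$draws[, term] else fit[[term]] %||% abort("term not found")
  level <- if (tail == "two") 0.95 else 0.90
  ci <- cri(draws, level)
  sig <- ci["lower"] > 0 || ci["upper"] < 0
  if (tail == "one") {
    ok_dir <- if (direction == "negative") median(draws) < 0 else median(draws) > 0
    sig <- sig && ok_dir
  }
  tibble(term = term, tail = tail, level = level,
         lower = unname(ci["lower"]), upper = unname(ci["upper"]),
         significant = unname(sig),
         direction = ifelse(median(draws) < 0, "negative", "positive"))
}
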