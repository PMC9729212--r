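# closed-form method-of-moments starting values (EZ-style) per subject,
# used only to initialize the chains
ez_init <- function(rt, correct) {
  acc <- min(0.95, max(0.55, mean(correct)))
  vrt <- max(1e-4, var(rt))
  L <- qlogis(acc)
  x <- L * (L * acc^2 - L * acc + acc - 0.5) / vrt
  v <- sign(acc - 0.5) * abs(x)^0.25
  v <- min(3, max(0.2, v))
  a <- min(4, max(0.6, L / v))
  mdt <- (a / (2 * v)) * (1 - exp(-v * a)) / (1 + exp(-v * a))
  t0 <- mean(rt) - mdt
  t0 <- min(max(0.05, t0), 0.9 * min(rt))
  c(a = a, v = v, t0 = max(0.05, t0))
}

#' Default priors for the hierarchical drift-diffusion model
#'
#' Weakly informative priors on the group-level means (normal), group-level
#' standard deviations (half-normal scales) and fixed-effect coefficients.
#' Pass a modified copy to [fit_hddm()] via its `prior` argument; omitted
#' entries keep their defaults.
#'
#' @return a named list of prior hyperparameters.
#' @export
default_ddm_prior <- function() {
  list(mu_a_mean = 2, mu_a_sd = 2, mu_v_mean = 0, mu_v_sd = 3,
       mu_t_mean = 0.3, mu_t_sd = 0.5,
       sg_a_scale = 1, sg_v_scale = 1, sg_t_scale = 0.25,
       b_sd = 2, sg_w_scale = 0.5)
}

# design matrix without the intercept column (the intercept is the
# subject-level random effect)
ddm_design <- function(formula, data) {
  X <- model.matrix(formula, data)
  if (colnames(X)[1] != "(Intercept)")
    abort("parameter designs must include an intercept")
  X[, -1, drop = FALSE]
}

#' Fit a hierarchical Bayesian drift-diffusion model
#'
#' Hierarchical estimation of threshold `a`, drift `v` and non-decision
#' time `t0` (unit diffusion coefficient, accuracy coding: correct
#' responses terminate at the upper boundary). Each parameter has a
#' subject-level intercept drawn from a group normal distribution plus
#' optional trial-level fixed effects with identity link, specified as
#' one-sided formulas evaluated on the trial table; trial-level covariates
#' should be standardized per subject ([zscore_by_subject()]). The
#' likelihood is the Wiener first-passage-time density; omissions must be
#' excluded beforehand ([filter_trials()]).
#'
#' Sampling uses adaptive blocked Metropolis-within-Gibbs on the natural
#' scale (subject blocks, single-coefficient fixed-effect updates,
#' conjugate group means, log-scale random walks for group SDs), run as
#' multiple independent chains with dispersed starting values. Convergence
#' is reported via split-R-hat and flagged when any exceeds 1.1.
#'
#' @param data filtered trial tibble with `rt`, `accuracy`, `subject`
#'   columns (plus any design covariates).
#' @param a,v,t one-sided formulas for the trial-level designs (default
#'   intercept-only).
#' @param include_bias estimate a subject-level starting point `w` (logit
#'   scale hierarchy) instead of fixing it at 0.5.
#' @param chains number of chains.
#' @param iter,burn iterations per chain and burn-in (defaults 10000/2000).
#' @param prior named list of prior settings, see source for fields.
#' @param seed RNG seed.
#' @param eps density truncation tolerance.
#' @return an `stn_ddm_fit` with posterior draws, summary, R-hats.
#' @export
fit_hddm <- function(data, a = ~1, v = ~1, t = ~1, include_bias = FALSE,
                     chains = 3, iter = 10000, burn = 2000,
                     prior = default_ddm_prior(), seed = 1, eps = 1e-7) {
  need <- c("rt", "accuracy", "subject")
  if (!all(need %in% names(data))) abort("data needs rt, accuracy, subject columns")
  data <- data[is.finite(data$rt) & !is.na(data$accuracy), , drop = FALSE]
  if (!nrow(data)) abort("no usable trials")
  if (any(data$rt <= 0)) abort("reaction times must be positive")
  if (!all(data$accuracy %in% c(0, 1))) abort("accuracy must be 0/1")
  subj_f <- factor(data$subject)
  subj <- as.integer(subj_f) - 1L
  J <- nlevels(subj_f)
  Xa <- ddm_design(a, data); Xv <- ddm_design(v, data); Xt <- ddm_design(t, data)
  prior <- modifyList(default_ddm_prior(), prior)

  # per-subject EZ starting values
  ez <- t(vapply(split(seq_len(nrow(data)), subj), function(ix) {
    ez_init(data$rt[ix], data$accuracy[ix])
  }, numeric(3)))

  run_chain <- function(c) {
    set.seed(seed + 7919L * c)
    jit <- function(s) rnorm(J, 0, s)
    res <- hddm_mcmc_cpp(
      data$rt, as.integer(data$accuracy), subj, J, Xa, Xv, Xt,
      include_bias, iter, burn,
      ez[, "a"] + jit(0.1), ez[, "v"] + jit(0.1),
      pmax(0.05, ez[, "t0"] + jit(0.01)), jit(0.2),
      prior, eps)
    nm <- c("mu_a", "sg_a", "mu_v", "sg_v", "mu_t", "sg_t")
    if (ncol(Xa)) nm <- c(nm, paste0("a_", colnames(Xa)))
    if (ncol(Xv)) nm <- c(nm, paste0("v_", colnames(Xv)))
    if (ncol(Xt)) nm <- c(nm, paste0("t_", colnames(Xt)))
    if (include_bias) nm <- c(nm, "mu_w_logit", "sg_w_logit")
    nm <- c(nm, paste0("a[", levels(subj_f), "]"),
            paste0("v[", levels(subj_f), "]"),
            paste0("t[", levels(subj_f), "]"))
    colnames(res$draws) <- nm
    res$draws
  }
  draws_by_chain <- lapply(seq_len(chains), run_chain)
  all_draws <- do.call(rbind, draws_by_chain)
  if (include_bias)
    all_draws <- cbind(all_draws, mu_w = plogis(all_draws[, "mu_w_logit"]))
  rhat <- vapply(colnames(draws_by_chain[[1]]), function(cn) {
    split_rhat(do.call(cbind, lapply(draws_by_chain, function(m) m[, cn])))
  }, numeric(1))
  core <- c("mu_a", "mu_v", "mu_t",
            grep("^(a|v|t)_", colnames(all_draws), value = TRUE))
  fit <- structure(list(
    draws = all_draws, draws_by_chain = draws_by_chain, rhat = rhat,
    terms = core, include_bias = include_bias,
    n_obs = nrow(data), n_subjects = J, subjects = levels(subj_f),
    chains = chains, iter = iter, burn = burn,
    designs = list(a = a, v = v, t = t), data = data,
    converged = all(rhat[core] < 1.1, na.rm = TRUE)
  ), class = "stn_ddm_fit")
  if (!fit$converged)
    warn(sprintf("convergence not reached: max R-hat = %.3f",
                 max(rhat[core], na.rm = TRUE)))
  fit
}

#' Hierarchical drift-diffusion regression with a trial-level covariate
#'
#' Convenience wrapper implementing the regression structure used for
#' single-trial covariates (movement times or LFP band-power features):
#' the threshold gets Instruction, the covariate and their interaction;
#' drift and non-decision time get the covariate only. The covariate is
#' z-scored per subject before fitting.
#'
#' @inheritParams fit_hddm
#' @param covariate name of the trial-level covariate column.
#' @param instruction name of the sum-coded instruction column (`instr_c`
#'   from [prepare_behavior()]); set `NULL` to drop instruction terms.
#' @return an `stn_ddm_fit`.
#' @export
fit_hddm_regression <- function(data, covariate, instruction = "instr_c",
                                chains = 3, iter = 10000, burn = 2000,
                                prior = default_ddm_prior(), seed = 1, ...) {
  data <- zscore_by_subject(data, covariate)
  cz <- paste0(covariate, "_z")
  fa <- if (is.null(instruction)) as.formula(paste("~", cz)) else
    as.formula(paste("~", instruction, "*", cz))
  fcv <- as.formula(paste("~", cz))
  fit_hddm(data, a = fa, v = fcv, t = fcv, chains = chains, iter = iter,
           burn = burn, prior = prior, seed = seed, ...)
}

#' Posterior-predictive quantile-probability check
#'
#' For each condition and response type (correct/error), compares the
#' observed 10/30/50/70/90% reaction-time percentiles and cumulative
#' response probabilities against posterior-predictive simulations from the
#' fitted model (group-level parameter means per draw subset, simulated
#' with the package's diffusion simulator).
#'
#' @param fit an `stn_ddm_fit`.
#' @param data trial tibble used for the fit (defaults to the fit's data).
#' @param condition name of the condition column (`instruction` by
#'   default); `NULL` treats all trials as one condition.
#' @param n_draws posterior draws used for prediction.
#' @param seed RNG seed for the predictive simulations.
#' @return tibble with observed and predicted quantiles per condition x
#'   response type.
#' @export
quantile_probability_check <- function(fit, data = NULL, condition = "instruction",
                                       n_draws = 50, seed = 1) {
  data <- data %||% fit$data
  probs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  cond <- if (is.null(condition)) rep("all", nrow(data)) else data[[condition]]
  obs <- purrr::map_dfr(split(seq_len(nrow(data)), cond), function(ix) {
    d <- data[ix, ]
    purrr::map_dfr(c(1, 0), function(cc) {
      sel <- d$accuracy == cc
      if (sum(sel) < 5) return(NULL)
      tibble(response = ifelse(cc == 1, "correct", "error"),
             prob = mean(sel), quantile = probs,
             rt_obs = quantile(d$rt[sel], probs, names = FALSE))
    }) %>% mutate(condition = cond[ix[1]])
  })

  set.seed(seed)
  draws <- fit$draws[sample.int(nrow(fit$draws), n_draws), , drop = FALSE]
  design_shift <- function(draws, prefix, data_cond) {
    cols <- grep(paste0("^", prefix, "_"), colnames(draws), value = TRUE)
    if (!length(cols)) return(rep(0, n_draws))
    # mean design row for the condition
    X <- ddm_design(fit$designs[[prefix]], data_cond)
    xbar <- colMeans(X)
    as.numeric(draws[, cols, drop = FALSE] %*% xbar)
  }
  pred <- purrr::map_dfr(unique(obs$condition), function(cn) {
    ix <- which(cond == cn)
    dc <- data[ix, ]
    sims <- purrr::map_dfr(seq_len(n_draws), function(k) {
      a_k <- draws[k, "mu_a"] + design_shift(draws, "a", dc)[k]
      v_k <- draws[k, "mu_v"] + design_shift(draws, "v", dc)[k]
      t_k <- draws[k, "mu_t"] + design_shift(draws, "t", dc)[k]
      sample_ddm(n = 200, a = max(0.3, a_k), v = v_k, t0 = max(0.01, t_k))
    })
    sims <- sims[is.finite(sims$rt), ]
    purrr::map_dfr(c(1, 0), function(cc) {
      sel <- sims$correct == cc
      if (sum(sel) < 5) return(NULL)
      tibble(condition = cn, response = ifelse(cc == 1, "correct", "error"),
             prob_pred = mean(sel), quantile = probs,
             rt_pred = quantile(sims$rt[sel], probs, names = FALSE))
    })
  })
  left_join(obs, pred, by = c("condition", "response", "quantile"))
}
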