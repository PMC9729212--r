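#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a hierarchical regression posterior
#'
#' One row per fixed effect (and group-level standard deviation), with the
#' posterior mean, SD, the 95% highest-density interval and split-R-hat.
#'
#' @param x an `stn_posterior` from [fit_hlm()] / [fit_hlogit()].
#' @param level credible level.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.stn_posterior <- function(x, level = 0.95, ...) {
  cols <- c(x$terms, x$re_terms, intersect("sigma", colnames(x$draws)))
  purrr::map_dfr(cols, function(tm) {
    d <- x$draws[, tm]
    ci <- cri(d, level = level)
    tibble(term = tm, estimate = mean(d), std.error = sd(d),
           conf.low = ci[["lower"]], conf.high = ci[["upper"]],
           rhat = unname(x$rhat[tm]))
  })
}

#' @rdname tidy.stn_posterior
#' @export
glance.stn_posterior <- function(x, ...) {
  tibble(n_obs = x$n_obs, n_subjects = x$n_subjects, chains = x$chains,
         iter = x$iter, burn = x$burn, family = x$family,
         rhat_max = max(x$rhat, na.rm = TRUE), converged = x$converged)
}

#' Tidy a hierarchical drift-diffusion posterior
#'
#' Rows for the group-level means, group SDs and all trial-level
#' coefficients (`a_*`, `v_*`, `t_*`).
#'
#' @param x an `stn_ddm_fit` from [fit_hddm()].
#' @param level credible level.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.stn_ddm_fit <- function(x, level = 0.95, ...) {
  cols <- c("mu_a", "sg_a", "mu_v", "sg_v", "mu_t", "sg_t",
            grep("^(a|v|t)_", colnames(x$draws), value = TRUE))
  purrr::map_dfr(cols, function(tm) {
    d <- x$draws[, tm]
    ci <- cri(d, level = level)
    tibble(term = tm, estimate = mean(d), std.error = sd(d),
           conf.low = ci[["lower"]], conf.high = ci[["upper"]],
           rhat = unname(x$rhat[tm]))
  })
}

#' @rdname tidy.stn_ddm_fit
#' @export
glance.stn_ddm_fit <- function(x, ...) {
  tibble(n_obs = x$n_obs, n_subjects = x$n_subjects, chains = x$chains,
         iter = x$iter, burn = x$burn,
         rhat_max = max(x$rhat[x$terms], na.rm = TRUE),
         converged = x$converged)
}

#' Tidy a sliding-window cluster test
#'
#' One row per detected cluster with its window span, time span (when the
#' window grid is known), cluster statistic and permutation p-value.
#'
#' @param x an `stn_cluster_test`.
#' @param ... unused.
#' @return a tibble (zero rows when no window exceeded the threshold).
#' @export
tidy.stn_cluster_test <- function(x, ...) {
  as_tibble(x$clusters)
}

#' @rdname tidy.stn_cluster_test
#' @export
glance.stn_cluster_test <- function(x, ...) {
  tibble(n_windows = length(x$t), n_perm = x$n_perm, exact = x$exact,
         alpha = x$alpha, statistic = x$statistic,
         n_clusters = nrow(x$clusters),
         n_significant = sum(x$clusters$significant))
}

#' @export
print.stn_posterior <- function(x, ...) {
  cat(sprintf("<stn_posterior> %s, %d obs / %d subjects, %d chains x %d iter\n",
              x$family, x$n_obs, x$n_subjects, x$chains, x$iter))
  print(tidy(x))
  invisible(x)
}

#' @export
print.stn_ddm_fit <- function(x, ...) {
  cat(sprintf("<stn_ddm_fit> %d obs / %d subjects, %d chains x %d iter (max R-hat %.3f)\n",
              x$n_obs, x$n_subjects, x$chains, x$iter,
              max(x$rhat[x$terms], na.rm = TRUE)))
  print(tidy(x))
  invisible(x)
}

#' @export
print.stn_cluster_test <- function(x, ...) {
  cat(sprintf("<stn_cluster_test> %d windows, %s permutations (%s)\n",
              length(x$t), x$n_perm, if (x$exact) "exact" else "random"))
  if (nrow(x$clusters)) print(tidy(x)) else cat("no supra-threshold clusters\n")
  invisible(x)
}

#' @export
print.stn_dataset <- function(x, ...) {
  cat(sprintf("<stn_dataset> %s scenario: %d trials, %d subjects%s%s\n",
              x$scenario, nrow(x$trials), length(x$schedules),
              if (!is.null(x$force)) ", force" else "",
              if (!is.null(x$lfp)) ", lfp" else ""))
  invisible(x)
}
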