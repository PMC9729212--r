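#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_rect
#'   geom_hline geom_vline geom_point geom_errorbar scale_fill_gradient2
#'   labs theme_minimal facet_wrap geom_histogram
NULL

#' @export
ggplot2::autoplot

#' Plot a time-frequency map
#'
#' Raster of (percent-change or raw) power over time and frequency.
#'
#' @param object an `stn_tfr`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.stn_tfr <- function(object, ...) {
  df2 <- tibble(time = rep(object$times, times = length(object$freqs)),
                freq = rep(object$freqs, each = length(object$times)),
                power = as.vector(object$power))
  ggplot(df2, aes(x = .data$time, y = .data$freq, fill = .data$power)) +
    geom_raster() +
    scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    labs(x = "time (s)", y = "frequency (Hz)",
         fill = if (object$normalized) "% change" else "power") +
    theme_minimal()
}

#' Plot a sliding-window cluster test
#'
#' Per-window t-values with the cluster-forming threshold and shaded
#' significant clusters.
#'
#' @param object an `stn_cluster_test`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.stn_cluster_test <- function(object, ...) {
  xs <- object$starts %||% seq_along(object$t)
  df <- tibble(x = xs, t = object$t, crit = object$crit)
  p <- ggplot(df, aes(x = .data$x, y = .data$t)) +
    geom_hline(yintercept = 0, color = "grey60") +
    geom_line(aes(y = .data$crit), linetype = "dashed", color = "grey40") +
    geom_line(aes(y = -.data$crit), linetype = "dashed", color = "grey40") +
    geom_line() +
    labs(x = if (is.null(object$starts)) "window" else "window onset (s)",
         y = "t") +
    theme_minimal()
  sig <- object$clusters[object$clusters$significant, , drop = FALSE]
  if (nrow(sig)) {
    shade <- tibble(xmin = xs[sig$from], xmax = xs[sig$to],
                    ymin = -Inf, ymax = Inf)
    p <- p + geom_rect(data = shade,
                       aes(xmin = .data$xmin, xmax = .data$xmax,
                           ymin = .data$ymin, ymax = .data$ymax),
                       inherit.aes = FALSE, alpha = 0.15, fill = "firebrick")
  }
  p
}

#' Plot posterior densities of regression coefficients
#'
#' Histograms of the fixed-effect posterior draws with zero marked.
#'
#' @param object an `stn_posterior` or `stn_ddm_fit`.
#' @param terms coefficients to show (default: all fixed effects).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.stn_posterior <- function(object, terms = NULL, ...) {
  terms <- terms %||% object$terms
  df <- purrr::map_dfr(terms, function(tm)
    tibble(term = tm, draw = object$draws[, tm]))
  ggplot(df, aes(x = .data$draw)) +
    geom_histogram(bins = 60, fill = "steelblue", color = NA) +
    geom_vline(xintercept = 0, linetype = "dashed") +
    facet_wrap(~term, scales = "free") +
    labs(x = "posterior draw", y = "count") +
    theme_minimal()
}

#' @rdname autoplot.stn_posterior
#' @export
autoplot.stn_ddm_fit <- function(object, terms = NULL, ...) {
  terms <- terms %||% grep("^(a|v|t)_|^mu_", colnames(object$draws), value = TRUE)
  df <- purrr::map_dfr(terms, function(tm)
    tibble(term = tm, draw = object$draws[, tm]))
  ggplot(df, aes(x = .data$draw)) +
    geom_histogram(bins = 60, fill = "steelblue", color = NA) +
    geom_vline(xintercept = 0, linetype = "dashed") +
    facet_wrap(~term, scales = "free") +
    labs(x = "posterior draw", y = "count") +
    theme_minimal()
}

#' Quantile-probability plot of observed vs predicted response times
#'
#' @param qp output of [quantile_probability_check()].
#' @return a ggplot with observed (points) and model-predicted (crosses)
#'   reaction-time percentiles plotted against response probabilities.
#' @export
plot_quantile_probability <- function(qp) {
  ggplot(qp, aes(color = .data$response)) +
    geom_point(aes(x = .data$prob, y = .data$rt_obs)) +
    geom_point(aes(x = .data$prob_pred, y = .data$rt_pred), shape = 4) +
    facet_wrap(~condition) +
    labs(x = "response probability", y = "RT percentile (s)") +
    theme_minimal()
}
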