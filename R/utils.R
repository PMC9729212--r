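#' Credible interval of posterior draws
#'
#' Highest-density interval (default) or central quantile interval of a
#' vector of posterior draws. The 95% two-tailed interval is the package's
#' default inferential summary; one-tailed decisions use the 90% interval.
#'
#' @param x numeric vector of draws.
#' @param level coverage level in (0, 1).
#' @param method `"hdi"` (shortest interval) or `"quantile"` (central).
#' @return named numeric vector `c(lower, upper)`.
#' @export
cri <- function(x, level = 0.95, method = c("hdi", "quantile")) {
  method <- match.arg(method)
  x <- x[is.finite(x)]
  if (length(x) < 4L) abort("need at least 4 finite draws for a credible interval")
  if (method == "quantile") {
    q <- quantile(x, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
    return(c(lower = q[1], upper = q[2]))
  }
  xs <- sort(x)
  n <- length(xs)
  k <- max(1L, floor(level * n))
  if (k >= n) return(c(lower = xs[1], upper = xs[n]))
  widths <- xs[(k + 1):n] - xs[1:(n - k)]
  i <- which.min(widths)
  c(lower = xs[i], upper = xs[i + k])
}

#' Split-R-hat convergence diagnostic
#'
#' Potential-scale-reduction factor computed after splitting each chain in
#' half, so within-chain drift also inflates the statistic.
#'
#' @param draws numeric matrix, iterations x chains (or a vector for a
#'   single chain, which is split into two half-chains).
#' @return scalar R-hat.
#' @export
split_rhat <- function(draws) {
  if (is.vector(draws)) draws <- matrix(draws, ncol = 1)
  n <- nrow(draws)
  half <- floor(n / 2)
  parts <- do.call(cbind, lapply(seq_len(ncol(draws)), function(c) {
    cbind(draws[seq_len(half), c], draws[(n - half + 1):n, c])
  }))
  m <- ncol(parts); nn <- nrow(parts)
  mns <- colMeans(parts)
  vars <- apply(parts, 2, var)
  B <- nn * var(mns)
  W <- mean(vars)
  if (W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# Independent sub-stream seeds derived from one master seed, so that e.g.
# regenerating the LFP noise does not perturb the behavioral draws.
derive_seeds <- function(seed, names) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  s <- sample.int(.Machine$integer.max - 1L, length(names))
  setNames(as.list(s), names)
}

# z-score within groups; constant vectors map to 0
zscore <- function(x) {
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x, na.rm = TRUE)) / s
}

#' Standardize a trial-level covariate within each subject
#'
#' Trial-level covariates entering drift-diffusion or behavioral regressions
#' are z-scored per subject, matching the convention that single-trial
#' predictors are standardized before model fitting.
#'
#' @param data trial tibble.
#' @param col name of the covariate column.
#' @param subject name of the subject id column.
#' @param suffix appended to the new column name (default `"_z"`).
#' @return `data` with an added standardized column.
#' @export
zscore_by_subject <- function(data, col, subject = "subject", suffix = "_z") {
  data %>%
    group_by(across(all_of(subject))) %>%
    mutate("{col}{suffix}" := zscore(.data[[col]])) %>%
    ungroup()
}
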