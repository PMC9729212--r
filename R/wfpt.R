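#' Wiener first-passage-time density
#'
#' Density of the first boundary crossing of a drift-diffusion process with
#' unit diffusion coefficient, evaluated at response time `rt` for the given
#' boundary. The decision time is `rt - t0`; the density is zero for
#' `rt <= t0`. Internally the standardized density is evaluated with either
#' a small-time or a large-time series expansion, choosing whichever needs
#' fewer terms for a truncation error below `eps`.
#'
#' @param rt numeric vector of response times (s).
#' @param boundary `"upper"` or `"lower"`; with accuracy coding the upper
#'   boundary is the correct response.
#' @param a boundary separation (> 0, evidence units).
#' @param v drift rate (evidence/s, positive drives toward the upper boundary).
#' @param t0 non-decision time (s, >= 0).
#' @param w relative starting point in (0, 1); 0.5 is unbiased.
#' @param eps series truncation tolerance.
#' @return numeric vector of density values.
#' @examples
#' wfpt_density(seq(0.3, 2, by = 0.1), "upper", a = 1.5, v = 1, t0 = 0.25)
#' @export
wfpt_density <- function(rt, boundary = c("upper", "lower"), a, v, t0 = 0,
                         w = 0.5, eps = 1e-7) {
  boundary <- match.arg(boundary)
  if (a <= 0) abort("boundary separation `a` must be positive")
  if (t0 < 0) abort("non-decision time `t0` must be non-negative")
  if (w <= 0 || w >= 1) abort("starting point `w` must lie in (0, 1)")
  wfpt_pdf_cpp(as.numeric(rt), as.integer(boundary == "upper"), a, v, t0, w, eps)
}

#' Boundary hitting probabilities of the diffusion process
#'
#' Closed-form probability that the accumulator is absorbed at the upper
#' (respectively lower) boundary, for drift `v`, separation `a` and relative
#' start `w` (unit diffusion coefficient).
#'
#' @inheritParams wfpt_density
#' @return named numeric vector `c(upper, lower)`.
#' @export
wfpt_hit_prob <- function(a, v, w = 0.5) {
  if (a <= 0) abort("`a` must be positive")
  p_up <- if (abs(v) < 1e-10) {
    w
  } else {
    expm1(-2 * v * a * w) / expm1(-2 * v * a)
  }
  c(upper = p_up, lower = 1 - p_up)
}

#' Simulate drift-diffusion trials by Euler-Maruyama integration
#'
#' Forward-simulates the accumulation process at step `dt` (unit diffusion
#' coefficient). Serves both as the generative engine of the synthetic
#' experiment and as an independent oracle for the analytic first-passage
#' density. Parameters may be scalars or per-trial vectors.
#'
#' @param n number of trials (ignored if parameters are vectors longer than 1).
#' @param a,v,t0,w diffusion parameters, recycled to `n`.
#' @param max_t censoring time (s); trials not terminated by `max_t` are
#'   returned as omissions (`NA` rt).
#' @param dt Euler step (s).
#' @param seed optional RNG seed.
#' @return tibble with columns `rt` (s, includes `t0`), `boundary`
#'   (`"upper"`/`"lower"`/`NA`), `correct` (1 for upper-boundary hits).
#' @export
sample_ddm <- function(n = NULL, a, v, t0 = 0.25, w = 0.5, max_t = 10,
                       dt = 0.001, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  len <- max(length(a), length(v), length(t0), length(w), length(max_t),
             n %||% 0L)
  if (len < 1) abort("need at least one trial")
  a <- rep_len(a, len); v <- rep_len(v, len); t0 <- rep_len(t0, len)
  w <- rep_len(w, len); max_t <- rep_len(max_t, len)
  if (any(a <= 0) || any(t0 < 0) || any(w <= 0 | w >= 1))
    abort("invalid diffusion parameters (need a > 0, t0 >= 0, 0 < w < 1)")
  sim <- sample_ddm_cpp(a, v, t0, w, max_t, dt)
  tibble(
    rt = sim$rt,
    boundary = c("lower", "upper")[sim$boundary + 1L],
    correct = as.integer(sim$boundary)
  )
}
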