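# ---------------------------------------------------------------------------
# Timing-resolved analysis of burst stimulation: binarization, sliding-window
# assignment, cluster-based permutation tests, post-hoc effects, artifact
# removal, and stimulation-conditioned beta power.
#
# Window grids (100 ms length, 10 ms step): cue-aligned -500..+1000 ms,
# movement-aligned -1000..+500 ms; (1500 - 100)/10 + 1 = 141 windows each.
# ---------------------------------------------------------------------------

window_grid <- function(alignment = c("cue", "movement"),
                        width = 0.1, step = 0.01) {
  alignment <- match.arg(alignment)
  lim <- if (alignment == "cue") c(-0.5, 1.0) else c(-1.0, 0.5)
  seq(lim[1], lim[2] - width, by = step)
}

#' Binarize a burst-stimulation schedule
#'
#' Maps the per-sample ramp state to effective stimulation: plateau samples
#' are 1 and ramps 0 by default (ramp intensities are below the clinically
#' effective level). `ramp_inclusion` folds the terminal part of each
#' ramp-up and the initial part of each ramp-down (that many seconds) into
#' the effective-stimulation class, for sensitivity analyses.
#'
#' @param schedule an `stn_burst_schedule`.
#' @param ramp_inclusion seconds of ramp adjacent to the plateau counted as
#'   stimulation (e.g. `0.05`).
#' @return `stn_stim_binary`: logical vectors `left`/`right` plus `rate`.
#' @export
binarize_stimulation <- function(schedule, ramp_inclusion = 0) {
  stopifnot(inherits(schedule, "stn_burst_schedule"))
  k <- round(ramp_inclusion * schedule$rate)
  bin1 <- function(st) {
    b <- st == 2L
    if (k > 0) {
      r <- rle(st)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (seg in which(r$values == 1L))   # last k samples of ramp-up
        b[max(starts[seg], ends[seg] - k + 1L):ends[seg]] <- TRUE
      for (seg in which(r$values == 3L))   # first k samples of ramp-down
        b[starts[seg]:min(ends[seg], starts[seg] + k - 1L)] <- TRUE
    }
    b
  }
  structure(list(left = bin1(schedule$left$state),
                 right = bin1(schedule$right$state),
                 rate = schedule$rate, ramp_inclusion = ramp_inclusion),
            class = "stn_stim_binary")
}

#' Assign stimulation flags to sliding trial windows
#'
#' For each trial and each 100 ms window (10 ms steps; cue-aligned -500 to
#' +1000 ms or movement-aligned -1000 to +500 ms), flags whether effective
#' stimulation occurred at any sample of the window. Windows are half-open
#' `[t, t + width)`; sample `i` carries time `(i - 1) / rate` on the session
#' clock. The relevant hemisphere can be fixed or chosen per trial relative
#' to the responding hand.
#'
#' @param binary `stn_stim_binary` from [binarize_stimulation()].
#' @param events trial tibble with `trial`, `subject`, `t_cue`, `t_onset`,
#'   `response_side`.
#' @param alignment `"cue"` or `"movement"`.
#' @param hemisphere `"either"`, `"left"`, `"right"`, `"contralateral"` or
#'   `"ipsilateral"` (relative to `response_side`).
#' @param width,step window length and shift (s).
#' @return `stn_stim_windows`: logical `flags` (trials x windows), window
#'   `starts`, the events, and settings.
#' @export
assign_windows <- function(binary, events,
                           alignment = c("cue", "movement"),
                           hemisphere = c("either", "left", "right",
                                          "contralateral", "ipsilateral"),
                           width = 0.1, step = 0.01) {
  alignment <- match.arg(alignment)
  hemisphere <- match.arg(hemisphere)
  starts <- window_grid(alignment, width, step)
  anchors <- if (alignment == "cue") events$t_cue else events$t_onset
  rate <- binary$rate
  cs <- list(left = c(0, cumsum(binary$left)), right = c(0, cumsum(binary$right)))
  nmax <- length(binary$left)
  # counts of stim samples per window, vectorized over the window grid:
  # samples i with (i-1)/rate in [a, b)
  count_vec <- function(hemi, a0) {
    a <- a0 + starts
    i1 <- pmax(1L, as.integer(ceiling(a * rate + 1 - 1e-9)))
    i2 <- pmin(nmax, as.integer(ceiling((a + width) * rate + 1 - 1e-9)) - 1L)
    bad <- i1 > i2
    i2[bad] <- i1[bad] <- 1L
    out <- cs[[hemi]][i2 + 1L] - cs[[hemi]][i1]
    out[bad] <- 0
    out
  }
  n_tr <- nrow(events)
  flags <- matrix(FALSE, n_tr, length(starts))
  for (i in seq_len(n_tr)) {
    a0 <- anchors[i]
    if (is.na(a0)) { flags[i, ] <- NA; next }
    hemi <- switch(hemisphere,
      either = c("left", "right"),
      left = "left", right = "right",
      contralateral = if_else(events$response_side[i] == "left", "right", "left"),
      ipsilateral = events$response_side[i])
    cnt <- count_vec(hemi[1], a0)
    if (length(hemi) > 1) cnt <- cnt + count_vec(hemi[2], a0)
    flags[i, ] <- cnt > 0
  }
  structure(list(flags = flags, starts = starts, width = width, step = step,
                 alignment = alignment, hemisphere = hemisphere,
                 events = events),
            class = "stn_stim_windows")
}

#' Per-window fraction of stimulated trials
#'
#' @param windows `stn_stim_windows`.
#' @return tibble with `window`, `start` (s, window onset relative to the
#'   alignment event), and `fraction` of trials with stimulation.
#' @export
stim_coverage <- function(windows) {
  stopifnot(inherits(windows, "stn_stim_windows"))
  tibble(window = seq_along(windows$starts), start = windows$starts,
         fraction = colMeans(windows$flags, na.rm = TRUE))
}

#' Per-subject, per-window stimulation effects
#'
#' For each subject and window, computes either the change of the
#' speed-accuracy trade-off effect under stimulation —
#' `(outcome_acc - outcome_speed)` among stimulated trials minus the same
#' among unstimulated trials (`mode = "sat"`) — or the plain stimulated
#' minus unstimulated outcome difference (`mode = "stim"`). Windows where
#' any required cell is empty yield `NA` for that subject (dropped pairwise
#' by the cluster test).
#'
#' @param windows `stn_stim_windows` whose events carry the needed columns.
#' @param outcome outcome column (`"rt"` or `"mt"`).
#' @param mode `"sat"` or `"stim"`.
#' @return `stn_window_effects`: `effects` matrix (subjects x windows),
#'   `starts`, settings.
#' @export
effect_per_window <- function(windows, outcome = "rt",
                              mode = c("sat", "stim")) {
  mode <- match.arg(mode)
  ev <- windows$events
  y <- ev[[outcome]]
  keep <- is.finite(y)
  subj <- factor(ev$subject)
  eff <- t(vapply(levels(subj), function(s) {
    rows <- which(keep & subj == s)
    vapply(seq_along(windows$starts), function(k) {
      f <- windows$flags[rows, k]
      cell <- function(sel) if (any(sel, na.rm = TRUE))
        mean(y[rows[which(sel)]]) else NA_real_
      if (mode == "stim") {
        cell(f) - cell(!f)
      } else {
        acc <- ev$instruction[rows] == "accuracy"
        (cell(f & acc) - cell(f & !acc)) - (cell(!f & acc) - cell(!f & !acc))
      }
    }, numeric(1))
  }, numeric(length(windows$starts))))
  structure(list(effects = eff, starts = windows$starts,
                 subjects = levels(subj), outcome = outcome, mode = mode,
                 alignment = windows$alignment),
            class = "stn_window_effects")
}

#' @rdname effect_per_window
#' @export
sat_effect_per_window <- function(windows, outcome = "rt") {
  effect_per_window(windows, outcome, mode = "sat")
}

# per-window one-sample t-values of a subjects x windows matrix, optionally
# under a matrix of sign flips (rows = permutations); sums of squares are
# flip-invariant so only means are recomputed per permutation
window_t <- function(X, S = NULL) {
  W <- ncol(X)
  if (is.null(S)) S <- matrix(1, 1, nrow(X))
  out <- matrix(NA_real_, nrow(S), W)
  for (w in seq_len(W)) {
    ok <- which(is.finite(X[, w]))
    n <- length(ok)
    if (n < 2) next
    x <- X[ok, w]
    sxx <- sum(x^2)
    m <- (S[, ok, drop = FALSE] %*% x) / n
    v <- pmax(0, (sxx - n * m^2) / (n - 1))
    out[, w] <- m / sqrt(v / n)
  }
  out
}

# split a t-value trace into signed supra-threshold clusters
find_clusters <- function(tv, crit) {
  supra <- is.finite(tv) & abs(tv) > crit
  sgn <- sign(tv)
  out <- NULL
  k <- 1
  while (k <= length(tv)) {
    if (!supra[k]) { k <- k + 1; next }
    j <- k
    while (j < length(tv) && supra[j + 1] && sgn[j + 1] == sgn[k]) j <- j + 1
    out <- rbind(out, c(from = k, to = j, mass = sum(tv[k:j]),
                        size = j - k + 1))
    k <- j + 1
  }
  if (is.null(out)) out <- matrix(numeric(0), 0, 4,
                                  dimnames = list(NULL, c("from", "to", "mass", "size")))
  as_tibble(as.data.frame(out))
}

#' Cluster-based permutation test over sliding windows
#'
#' Tests per-subject effect time-courses (subjects x windows) against zero:
#' a per-window one-sample t-test forms clusters of adjacent same-sign
#' windows exceeding the two-sided `alpha` critical value; each cluster's
#' statistic (summed t, `"mass"`, or window count, `"size"`) is compared to
#' the permutation distribution of the maximal absolute cluster statistic
#' obtained by flipping the sign of whole subject time-courses (which
#' preserves temporal autocorrelation). When `2^J <= n_perm` all sign
#' assignments are enumerated exactly. Requires at least 5 subjects.
#' Subjects with a missing window are dropped pairwise for that window.
#'
#' @param effects `stn_window_effects` or a numeric subjects x windows
#'   matrix.
#' @param n_perm number of random permutations (ignored when enumerating).
#' @param alpha cluster-forming and cluster-level significance threshold.
#' @param statistic `"mass"` or `"size"`.
#' @param seed RNG seed for random sign flips.
#' @return `stn_cluster_test`: per-window `t`, `clusters` tibble (span
#'   windows and times, statistic, `p`, `significant`), the null
#'   distribution, and settings.
#' @export
cluster_permutation <- function(effects, n_perm = 1000, alpha = 0.05,
                                statistic = c("mass", "size"), seed = 1) {
  statistic <- match.arg(statistic)
  starts <- NULL
  if (inherits(effects, "stn_window_effects")) {
    starts <- effects$starts
    effects <- effects$effects
  }
  X <- as.matrix(effects)
  J <- nrow(X)
  if (J < 5) abort("cluster permutation needs at least 5 subjects")
  n_eff <- apply(X, 2, function(c) sum(is.finite(c)))
  crit <- qt(1 - alpha / 2, df = pmax(1, n_eff - 1))
  tv <- drop(window_t(X))
  obs <- find_clusters(tv, crit)

  exact <- 2^J <= n_perm
  S <- if (exact) {
    as.matrix(expand.grid(rep(list(c(-1, 1)), J)))
  } else {
    set.seed(seed)
    matrix(sample(c(-1, 1), n_perm * J, replace = TRUE), n_perm, J)
  }
  Tperm <- window_t(X, S)
  null_max <- vapply(seq_len(nrow(S)), function(p) {
    cl <- find_clusters(Tperm[p, ], crit)
    if (nrow(cl) == 0) 0 else max(abs(cl[[statistic]]))
  }, numeric(1))

  if (nrow(obs)) {
    stat <- abs(obs[[statistic]])
    obs$p <- if (exact) {
      vapply(stat, function(s) mean(null_max >= s), numeric(1))
    } else {
      vapply(stat, function(s) (1 + sum(null_max >= s)) / (1 + nrow(S)),
             numeric(1))
    }
    obs$significant <- obs$p <= alpha
    if (!is.null(starts)) {
      obs$time_from <- starts[obs$from]
      obs$time_to <- starts[obs$to] + 0.1
    }
  } else {
    obs$p <- numeric(0); obs$significant <- logical(0)
  }
  structure(list(t = tv, df = n_eff - 1, crit = crit, clusters = obs,
                 null = null_max, n_perm = nrow(S), exact = exact,
                 alpha = alpha, statistic = statistic, starts = starts),
            class = "stn_cluster_test")
}

# per-trial effective-stimulation flag over a time span (any flagged window
# whose onset falls inside the span)
span_flag <- function(windows, span) {
  sel <- windows$starts >= span[1] & windows$starts <= span[2]
  if (!any(sel)) abort("span covers no window onsets")
  apply(windows$flags[, sel, drop = FALSE], 1, function(r) any(r, na.rm = TRUE))
}

#' Post-hoc stimulation effects within a significant window span
#'
#' Flags each trial by effective stimulation inside `span` (window onsets
#' within the span), then tests the stimulated-minus-unstimulated outcome
#' difference per instruction condition with one-sample t-tests across
#' subjects, Bonferroni-corrected over the number of tests. Also reports
#' the same contrast on accuracy rates as a speed-accuracy trade-off check.
#'
#' @param windows `stn_stim_windows`.
#' @param span `c(from, to)` seconds relative to the alignment event.
#' @param outcome outcome column.
#' @param n_tests Bonferroni correction factor (default: number of
#'   conditions tested).
#' @return tibble with one row per condition and outcome.
#' @export
posthoc_window <- function(windows, span, outcome = "rt", n_tests = NULL) {
  ev <- windows$events
  stimmed <- span_flag(windows, span)
  one <- function(outc, cond) {
    rows <- which(ev$instruction == cond & is.finite(ev[[outc]]))
    d <- vapply(split(rows, factor(ev$subject[rows])), function(ix) {
      s <- stimmed[ix]
      if (!any(s) || all(s)) return(NA_real_)
      mean(ev[[outc]][ix[s]]) - mean(ev[[outc]][ix[!s]])
    }, numeric(1))
    d <- d[is.finite(d)]
    tt <- t.test(d)
    tibble(outcome = outc, condition = cond, mean_difference = mean(d),
           t = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value, n_subjects = length(d))
  }
  conds <- sort(unique(ev$instruction))
  res <- bind_rows(
    purrr::map_dfr(conds, function(cc) one(outcome, cc)),
    purrr::map_dfr(conds, function(cc) one("accuracy", cc))
  )
  k <- n_tests %||% length(conds)
  res$p_corrected <- pmin(1, res$p * k)
  res
}

#' Stimulation as a predictor of decision thresholds
#'
#' Refits the hierarchical drift-diffusion model on one instruction
#' condition with a centered stimulation flag (stimulation inside `span`)
#' as a trial-level threshold predictor, and evaluates the one-tailed 90%
#' credible interval for a threshold reduction (or the stated direction).
#'
#' @param windows `stn_stim_windows` (events must carry `rt`, `accuracy`).
#' @param span effect window, seconds relative to the alignment event.
#' @param instruction condition to analyse (`NULL` = all trials).
#' @param direction expected direction of the threshold effect.
#' @param ... passed to [fit_hddm()] (chains, iter, burn, seed, ...).
#' @return list with the fit and a one-row decision tibble for the
#'   stimulation coefficient.
#' @export
dbs_threshold_test <- function(windows, span, instruction = NULL,
                               direction = c("negative", "positive"), ...) {
  direction <- match.arg(direction)
  ev <- windows$events
  ev$dbs_c <- as.numeric(span_flag(windows, span)) - 0.5
  if (!is.null(instruction)) ev <- ev[ev$instruction == instruction, , drop = FALSE]
  ev <- ev[is.finite(ev$rt), , drop = FALSE]
  fit <- fit_hddm(ev, a = ~dbs_c, ...)
  dr <- fit$draws[, "a_dbs_c"]
  ci <- cri(dr, level = 0.90)
  sig <- if (direction == "negative") ci["upper"] < 0 else ci["lower"] > 0
  list(fit = fit,
       decision = tibble(term = "a_dbs_c", mean = mean(dr),
                         lower = ci[["lower"]], upper = ci[["upper"]],
                         level = 0.90, tail = "one", direction = direction,
                         significant = unname(sig)))
}

#' Laterality analysis of unilateral stimulation
#'
#' Splits trials by whether the stimulated hemisphere is contralateral or
#' ipsilateral to the responding hand, computes per-subject stimulation
#' effects (stimulated minus unstimulated outcome inside `span`) for each
#' side, and compares them with a paired one-tailed t-test (contralateral
#' effect expected more negative). When per-subject bilateral effects are
#' supplied, also regresses them on the contralateral and ipsilateral
#' effects (simple regressions with r-squared and p, plus a two-predictor
#' multiple regression).
#'
#' @param windows `stn_stim_windows` from a unilateral session.
#' @param span effect window (s relative to the alignment event).
#' @param stim_hemi stimulated hemisphere, `"left"` or `"right"`.
#' @param outcome outcome column.
#' @param bilateral optional named per-subject bilateral effect vector.
#' @return list with `per_subject` tibble, `paired` test tibble, and
#'   `regressions` (when `bilateral` given).
#' @export
unilateral_analysis <- function(windows, span, stim_hemi, outcome = "rt",
                                bilateral = NULL) {
  ev <- windows$events
  stimmed <- span_flag(windows, span)
  contra_hand <- if (stim_hemi == "left") "right" else "left"
  eff <- function(rows) {
    vapply(split(rows, factor(ev$subject[rows]),
                 drop = FALSE), function(ix) {
      s <- stimmed[ix]
      if (!any(s) || all(s)) return(NA_real_)
      mean(ev[[outcome]][ix[s]]) - mean(ev[[outcome]][ix[!s]])
    }, numeric(1))
  }
  ok <- is.finite(ev[[outcome]])
  contra <- eff(which(ok & ev$response_side == contra_hand))
  ipsi <- eff(which(ok & ev$response_side != contra_hand))
  per <- tibble(subject = names(contra), contra = unname(contra),
                ipsi = unname(ipsi))
  cc <- per[complete.cases(per), ]
  tt <- t.test(cc$contra, cc$ipsi, paired = TRUE, alternative = "less")
  out <- list(per_subject = per,
              paired = tibble(mean_contra = mean(cc$contra),
                              mean_ipsi = mean(cc$ipsi),
                              t = unname(tt$statistic), df = unname(tt$parameter),
                              p = tt$p.value, alternative = "contra < ipsi"))
  if (!is.null(bilateral)) {
    b <- bilateral[cc$subject]
    reg <- function(f) {
      m <- summary(lm(f, data = cbind(cc, bilateral = b)))
      tibble(formula = deparse(f), r_squared = m$r.squared,
             p = pf(m$fstatistic[1], m$fstatistic[2], m$fstatistic[3],
                    lower.tail = FALSE))
    }
    out$regressions <- bind_rows(reg(bilateral ~ contra),
                                 reg(bilateral ~ ipsi),
                                 reg(bilateral ~ contra + ipsi))
  }
  out
}

#' Remove stimulation artifacts from an LFP recording
#'
#' Zero-phase 4th-order Butterworth filtering (4 Hz high-pass, 100 Hz
#' low-pass), demeaning and linear detrending, then replacement of samples
#' exceeding `threshold` microvolts (plus `pad` neighboring samples on each
#' side) by linear interpolation between the nearest clean samples, and
#' downsampling to `target_rate`. Aborts when more than half of the samples
#' exceed the threshold. The fraction of interpolated samples per channel
#' is returned in the `interpolated` field.
#'
#' @param lfp an `stn_lfp`.
#' @param threshold artifact amplitude threshold (uV) after filtering.
#' @param pad samples flanking each artifact sample that are also replaced.
#' @param target_rate output rate (Hz).
#' @return the cleaned `stn_lfp` with an `interpolated` named vector.
#' @export
remove_stim_artifact <- function(lfp, threshold = 10, pad = 1,
                                 target_rate = 200) {
  stopifnot(inherits(lfp, "stn_lfp"))
  x <- lfp$data
  nyq <- lfp$rate / 2
  x <- butter_filtfilt(x, 4, 4 / nyq, "high")
  x <- butter_filtfilt(x, 4, min(0.999, 100 / nyq), "low")
  n <- nrow(x)
  tgrid <- seq_len(n)
  frac <- numeric(ncol(x))
  for (cc in seq_len(ncol(x))) {
    col <- x[, cc]
    col <- col - mean(col)
    col <- col - (coef(lm(col ~ tgrid))[2] * (tgrid - mean(tgrid)))
    bad <- abs(col) > threshold
    if (pad > 0 && any(bad)) {
      idx <- which(bad)
      for (d in seq_len(pad)) bad[pmax(1, idx - d)] <- bad[pmin(n, idx + d)] <- TRUE
    }
    frac[cc] <- mean(bad)
    if (frac[cc] > 0.5)
      abort(sprintf("channel %d: %.0f%% of samples exceed the artifact threshold",
                    cc, 100 * frac[cc]))
    if (any(bad)) {
      good <- which(!bad)
      col[bad] <- approx(good, col[good], xout = which(bad), rule = 2)$y
    }
    x[, cc] <- col
  }
  lfp$data <- x
  if (lfp$rate > target_rate) {
    ratio <- lfp$rate / target_rate
    if (abs(ratio - round(ratio)) < 1e-9) {
      lfp$data <- lfp$data[seq(1, n, by = round(ratio)), , drop = FALSE]
    } else {
      t_old <- (tgrid - 1) / lfp$rate
      t_new <- seq(0, t_old[n], by = 1 / target_rate)
      lfp$data <- apply(lfp$data, 2, function(col)
        approx(t_old, col, xout = t_new)$y)
    }
    lfp$rate <- target_rate
  }
  lfp$interpolated <- setNames(frac, lfp$channels)
  lfp
}

# per-trial beta-power traces on a fixed relative time grid, optionally
# capped (NA) from movement onset onward
beta_trace_matrix <- function(tfr, events, span, align = "cue",
                              cap_at_onset = TRUE) {
  cols <- as.character(intersect(band_bins$beta, tfr$freqs))
  beta <- rowMeans(tfr$power[, cols, drop = FALSE])
  rel <- seq(span[1], span[2], by = tfr$step)
  anchors <- if (align == "cue") events$t_cue else events$t_onset
  tr <- t(vapply(seq_len(nrow(events)), function(i) {
    a <- anchors[i]
    if (is.na(a)) return(rep(NA_real_, length(rel)))
    v <- approx(tfr$times, beta, xout = a + rel)$y
    if (cap_at_onset && !is.na(events$t_onset[i]))
      v[a + rel >= events$t_onset[i]] <- NA_real_
    v
  }, numeric(length(rel))))
  list(traces = tr, rel = rel)
}

#' Beta power conditioned on stimulation in a window span
#'
#' For each subject: beta power (13--30 Hz, percent change, movement-onset
#' capped) in a 500 ms window around the tested stimulation span, averaged
#' separately over trials with and without effective stimulation in the
#' span; the per-subject difference traces then enter the cluster
#' permutation test over time.
#'
#' @param tfrs named list (by subject) of normalized `stn_tfr` of the
#'   selected contralateral channel, on the session clock.
#' @param windows_by_subject named list of `stn_stim_windows` per subject
#'   (cue-aligned), whose events carry `t_cue`, `t_onset`.
#' @param span tested stimulation span (s relative to cue), e.g.
#'   `c(-0.180, -0.010)`.
#' @param trace_span beta trace window (default 500 ms centered on `span`).
#' @param cap_at_onset cap each trial's trace at movement onset.
#' @param n_perm,alpha,seed see [cluster_permutation()].
#' @return list with `difference` (subjects x times), `times`, `mean_stim`,
#'   `mean_nostim`, and the `stn_cluster_test`.
#' @export
stim_conditioned_beta <- function(tfrs, windows_by_subject, span,
                                  trace_span = NULL, cap_at_onset = TRUE,
                                  n_perm = 1000, alpha = 0.05, seed = 1) {
  mid <- mean(span)
  trace_span <- trace_span %||% c(mid - 0.25, mid + 0.25)
  subs <- intersect(names(tfrs), names(windows_by_subject))
  rows <- lapply(subs, function(s) {
    w <- windows_by_subject[[s]]
    bt <- beta_trace_matrix(tfrs[[s]], w$events, trace_span, "cue",
                            cap_at_onset)
    flag <- span_flag(w, span)
    ms <- colMeans(bt$traces[flag, , drop = FALSE], na.rm = TRUE)
    mn <- colMeans(bt$traces[!flag, , drop = FALSE], na.rm = TRUE)
    list(diff = ms - mn, stim = ms, nostim = mn, rel = bt$rel)
  })
  D <- do.call(rbind, lapply(rows, `[[`, "diff"))
  rownames(D) <- subs
  test <- cluster_permutation(D, n_perm = n_perm, alpha = alpha, seed = seed)
  test$starts <- rows[[1]]$rel
  list(difference = D, times = rows[[1]]$rel,
       mean_stim = colMeans(do.call(rbind, lapply(rows, `[[`, "stim")), na.rm = TRUE),
       mean_nostim = colMeans(do.call(rbind, lapply(rows, `[[`, "nostim")), na.rm = TRUE),
       test = test)
}

#' Beta power aligned to stimulation-plateau onsets
#'
#' Extracts beta power around every plateau onset of the schedule and
#' normalizes it to the mean beta power over stimulation-free samples
#' (inter-burst intervals only), returning the average time-course.
#'
#' @param tfr normalized or raw `stn_tfr` of one channel on the session
#'   clock.
#' @param schedule the session's `stn_burst_schedule`.
#' @param hemisphere schedule side to take plateau onsets from.
#' @param window time range around plateau onset (s).
#' @return tibble with `time` and `beta_rel` (1 = stimulation-free mean).
#' @export
stim_aligned_beta <- function(tfr, schedule, hemisphere = "left",
                              window = c(-0.2, 0.5)) {
  cols <- as.character(intersect(band_bins$beta, tfr$freqs))
  beta <- rowMeans(tfr$power[, cols, drop = FALSE])
  st <- schedule[[hemisphere]]$state
  onsets <- which(diff(c(0L, as.integer(st == 2L))) == 1L) / schedule$rate
  # stimulation-free reference: samples where the schedule is fully off
  ref_sel <- vapply(tfr$times, function(t) {
    i <- floor(t * schedule$rate) + 1
    i >= 1 && i <= length(st) && st[i] == 0L
  }, logical(1))
  ref <- mean(beta[ref_sel], na.rm = TRUE)
  rel <- seq(window[1], window[2], by = tfr$step)
  mat <- vapply(onsets, function(o)
    approx(tfr$times, beta, xout = o + rel)$y, numeric(length(rel)))
  tibble(time = rel,
         beta_rel = rowMeans(mat, na.rm = TRUE) / ref,
         n_bursts = rowSums(is.finite(mat)))
}
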