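# ---------------------------------------------------------------------------
# LFP preprocessing, Morlet time-frequency maps, contact selection and
# single-trial band-power features.
#
# Channel order convention: channels are listed dorsal-most first; ties in
# contact selection resolve to the first (dorsal-most) channel.
# Band definitions (inclusive integer bins): beta 13-30 Hz, gamma 55-80 Hz,
# theta 4-8 Hz.
# ---------------------------------------------------------------------------

band_bins <- list(beta = 13:30, gamma = 55:80, theta = 4:8)

# zero-phase Butterworth filtering of a matrix, column-wise
butter_filtfilt <- function(x, order, w, type) {
  bf <- signal::butter(order, w, type = type)
  apply(x, 2, function(col) signal::filtfilt(bf, col))
}

#' Preprocess a continuous LFP recording
#'
#' Zero-phase 4th-order Butterworth filtering: 1 Hz high-pass, 49--51 Hz
#' line-noise band-stop, and a 100 Hz anti-alias low-pass, followed by
#' downsampling to `target_rate` (integer decimation when the rates divide
#' cleanly, otherwise linear interpolation onto the new grid). Event times
#' are unchanged (they are stored in seconds).
#'
#' @param lfp an `stn_lfp` (fields `data` samples x channels, `rate`,
#'   `channels`, `hemisphere`, `events`).
#' @param target_rate output sampling rate (Hz).
#' @param line bandstop edges (Hz).
#' @return the preprocessed `stn_lfp` at `target_rate`.
#' @export
preprocess_lfp <- function(lfp, target_rate = 200, line = c(49, 51)) {
  stopifnot(inherits(lfp, "stn_lfp"))
  x <- lfp$data
  nyq <- lfp$rate / 2
  x <- butter_filtfilt(x, 4, 1 / nyq, "high")
  x <- butter_filtfilt(x, 4, line / nyq, "stop")
  if (lfp$rate > 2 * target_rate) {
    x <- butter_filtfilt(x, 4, min(0.999, 100 / nyq), "low")
    ratio <- lfp$rate / target_rate
    if (abs(ratio - round(ratio)) < 1e-9) {
      x <- x[seq(1, nrow(x), by = round(ratio)), , drop = FALSE]
    } else {
      t_old <- (seq_len(nrow(x)) - 1) / lfp$rate
      t_new <- seq(0, t_old[length(t_old)], by = 1 / target_rate)
      x <- apply(x, 2, function(col) approx(t_old, col, xout = t_new)$y)
    }
    lfp$rate <- target_rate
  }
  lfp$data <- x
  lfp
}

# parse contact labels like "c1", "2a", "3" into level number + segment letter
parse_contacts <- function(labels) {
  m <- regmatches(labels, regexec("^[A-Za-z]*([0-9]+)([a-z]?)$", labels))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) abort(paste0("cannot parse contact labels: ",
                             paste(labels[bad], collapse = ", ")))
  tibble(label = labels,
         level = as.integer(vapply(m, `[`, "", 2)),
         segment = vapply(m, `[`, "", 3),
         index = seq_along(labels))
}

#' Re-reference monopolar contacts to a bipolar montage
#'
#' `"neighbor"` subtracts adjacent contact levels: ring-to-ring levels give
#' one channel, segmented levels pair matching segments, and a ring level
#' pairs with every segment of its segmented neighbor. A linear quadripolar
#' lead therefore yields 3 bipolar channels and a 1-3-3-1 directional lead
#' yields 9. `"wide"` builds 2 channels that skip the middle of the lead
#' (most dorsal minus second-most-ventral level, and second-most-dorsal
#' minus most ventral level, averaging segments within a level), leaving the
#' middle contact free for stimulation; it requires at least 4 levels.
#'
#' @param lfp an `stn_lfp` whose `channels` encode contact level (and
#'   optionally a segment letter), dorsal-most first.
#' @param scheme `"neighbor"` or `"wide"`.
#' @return an `stn_lfp` of bipolar channels named `"<anode>-<cathode>"`.
#' @export
bipolar_montage <- function(lfp, scheme = c("neighbor", "wide")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(lfp, "stn_lfp"))
  ct <- parse_contacts(lfp$channels)
  levels_sorted <- sort(unique(ct$level))
  if (length(levels_sorted) < 2) abort("need at least two contact levels")
  x <- lfp$data

  if (scheme == "neighbor") {
    pairs <- purrr::map_dfr(seq_len(length(levels_sorted) - 1), function(k) {
      a <- ct[ct$level == levels_sorted[k], ]
      b <- ct[ct$level == levels_sorted[k + 1], ]
      if (nrow(a) > 1 && nrow(b) > 1) {
        shared <- intersect(a$segment, b$segment)
        tibble(i = a$index[match(shared, a$segment)],
               j = b$index[match(shared, b$segment)])
      } else if (nrow(a) == 1) {
        tibble(i = a$index, j = b$index)
      } else {
        tibble(i = a$index, j = rep(b$index, nrow(a)))
      }
    })
    dat <- x[, pairs$i, drop = FALSE] - x[, pairs$j, drop = FALSE]
    nm <- paste0(lfp$channels[pairs$i], "-", lfp$channels[pairs$j])
  } else {
    if (length(levels_sorted) < 4)
      abort("wide montage needs at least 4 contact levels")
    lvl_mean <- function(l) rowMeans(x[, ct$index[ct$level == l], drop = FALSE])
    L <- length(levels_sorted)
    dorsal <- levels_sorted[1]; ventral <- levels_sorted[L]
    second_dorsal <- levels_sorted[2]; second_ventral <- levels_sorted[L - 1]
    dat <- cbind(lvl_mean(dorsal) - lvl_mean(second_ventral),
                 lvl_mean(second_dorsal) - lvl_mean(ventral))
    nm <- c(paste0("L", dorsal, "-L", second_ventral),
            paste0("L", second_dorsal, "-L", ventral))
  }
  lfp$data <- dat
  lfp$channels <- nm
  lfp
}

# complex Morlet wavelet (unit energy) sampled at `rate` for frequency f
morlet_wavelet <- function(f, rate, cycles) {
  sigma_t <- cycles / (2 * pi * f)
  half <- ceiling(4 * sigma_t * rate)
  t <- (-half:half) / rate
  w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma_t^2))
  w / sqrt(sum(Mod(w)^2))
}

#' Morlet wavelet time-frequency decomposition
#'
#' Convolves one channel with unit-energy complex Morlet wavelets (default
#' 7 cycles, 2--100 Hz in 1 Hz steps) via FFT and returns squared magnitude
#' (power) sampled on a regular coarse time grid (default 20 ms). Samples
#' within 3 temporal SDs of the wavelet envelope from either edge are set
#' to `NA` (edge effects).
#'
#' @param x numeric vector (one preprocessed channel).
#' @param rate sampling rate of `x` (Hz).
#' @param freqs analysis frequencies (Hz); must stay below `rate / 2`.
#' @param step output time step (s).
#' @param cycles wavelet width in cycles.
#' @return an `stn_tfr`: `power` (times x freqs, possibly NA at edges),
#'   `times`, `freqs`, plus settings; `normalized = FALSE`.
#' @export
morlet_tfr <- function(x, rate, freqs = 2:100, step = 0.02, cycles = 7) {
  if (max(freqs) >= rate / 2)
    abort("analysis frequencies must lie below the Nyquist frequency")
  n <- length(x)
  # coarse grid kept on exact sample indices when step*rate is integer
  idx_step <- step * rate
  out_idx <- if (abs(idx_step - round(idx_step)) < 1e-9) {
    seq(1L, n, by = as.integer(round(idx_step)))
  } else {
    unique(pmin(n, 1L + round(seq(0, (n - 1) / rate, by = step) * rate)))
  }
  times <- (out_idx - 1) / rate

  nfft <- nextn(n + ceiling(8 * cycles / (2 * pi * min(freqs)) * rate), 2)
  X <- fft(c(x, numeric(nfft - n)))
  pow <- matrix(NA_real_, length(out_idx), length(freqs),
                dimnames = list(NULL, freqs))
  for (k in seq_along(freqs)) {
    w <- morlet_wavelet(freqs[k], rate, cycles)
    half <- (length(w) - 1L) / 2L
    W <- fft(c(w, complex(real = numeric(nfft - length(w)))))
    conv <- fft(X * W, inverse = TRUE) / nfft
    centered <- conv[(1L + half):(n + half)]
    p <- Mod(centered)^2
    edge <- ceiling(3 * cycles / (2 * pi * freqs[k]) * rate)
    if (edge >= 1) {
      p[seq_len(min(n, edge))] <- NA_real_
      p[seq.int(max(1L, n - edge + 1L), n)] <- NA_real_
    }
    pow[, k] <- p[out_idx]
  }
  structure(list(power = pow, times = times, freqs = freqs, rate = rate,
                 step = step, cycles = cycles, normalized = FALSE),
            class = "stn_tfr")
}

#' Normalize a time-frequency map to percent power change
#'
#' Expresses power as percent change relative to the mean power of each
#' frequency over the whole recording (NA edge samples excluded from the
#' reference mean). The time-mean of each normalized frequency row is
#' exactly zero.
#'
#' @param tfr an `stn_tfr` from [morlet_tfr()].
#' @return the `stn_tfr` with percent-change values, `normalized = TRUE`.
#' @export
normalize_power <- function(tfr) {
  stopifnot(inherits(tfr, "stn_tfr"))
  if (tfr$normalized) return(tfr)
  mu <- colMeans(tfr$power, na.rm = TRUE)
  if (any(!is.finite(mu) | mu <= 0)) abort("degenerate power spectrum")
  tfr$power <- 100 * sweep(sweep(tfr$power, 2, mu, "/"), 2, 1, "-")
  tfr$normalized <- TRUE
  tfr
}

# mean normalized power in a frequency band over [from, to] seconds relative
# to per-trial anchors; returns one value per anchor (NA when the window is
# incomplete)
band_window_mean <- function(tfr, band, anchors, from, to) {
  cols <- as.character(intersect(band_bins[[band]], tfr$freqs))
  if (!length(cols)) abort(sprintf("band %s outside analysis frequencies", band))
  sub <- tfr$power[, cols, drop = FALSE]
  vapply(anchors, function(a) {
    if (is.na(a)) return(NA_real_)
    sel <- tfr$times >= a + from & tfr$times <= a + to
    if (!any(sel)) return(NA_real_)
    m <- sub[sel, , drop = FALSE]
    if (anyNA(m)) return(NA_real_)
    mean(m)
  }, numeric(1))
}

#' Epoch a time-frequency map around trial events and tag laterality
#'
#' Cuts per-trial windows from a continuous map, aligned to the cue or to
#' movement onset, and tags each trial as contralateral or ipsilateral to
#' the recorded hemisphere given the responding hand (left-hand responses
#' are contralateral to the right STN). Trials whose window extends outside
#' the recording (or into NA edges) are dropped.
#'
#' @param tfr normalized `stn_tfr`.
#' @param events trial tibble with `trial`, `response_side`, `t_cue`,
#'   `t_onset` (s, on the recording clock).
#' @param hemisphere `"left"` or `"right"` (the recording side).
#' @param alignment `"cue"` or `"movement"`.
#' @param window epoch limits (s) relative to the alignment event.
#' @return tibble with `trial`, `laterality` and a `map` list-column of
#'   times x freqs matrices (times relative to the event).
#' @export
epoch_and_lateralize <- function(tfr, events, hemisphere,
                                 alignment = c("cue", "movement"),
                                 window = c(-0.5, 1)) {
  alignment <- match.arg(alignment)
  anchors <- if (alignment == "cue") events$t_cue else events$t_onset
  purrr::map_dfr(seq_len(nrow(events)), function(i) {
    a <- anchors[i]
    if (is.na(a)) return(NULL)
    sel <- tfr$times >= a + window[1] & tfr$times <= a + window[2]
    if (!any(sel)) return(NULL)
    m <- tfr$power[sel, , drop = FALSE]
    if (anyNA(m)) return(NULL)
    tibble(trial = events$trial[i],
           laterality = if_else(events$response_side[i] == hemisphere,
                                "ipsilateral", "contralateral"),
           map = list(structure(m, times = tfr$times[sel] - a,
                                freqs = tfr$freqs)))
  })
}

#' Select the analysis contact of one STN
#'
#' Picks, among bipolar channels, the one with the strongest movement-related
#' gamma (55--80 Hz) increase 0--300 ms after movement onset (mean normalized
#' percent change across trials). If no channel shows a gamma increase above
#' `gamma_threshold`, falls back to the channel with the strongest beta
#' (13--30 Hz) decrease in the same window. Ties resolve to the first
#' (dorsal-most) channel.
#'
#' @param tfrs list of normalized `stn_tfr`, one per bipolar channel.
#' @param events trial tibble with `t_onset` (s, recording clock).
#' @param gamma_threshold minimal mean gamma increase (percent) for the
#'   gamma criterion to count as successful.
#' @param window scoring window (s) relative to movement onset.
#' @return list with `index`, `channel` (if `tfrs` is named), `criterion`
#'   (`"gamma"` or `"beta"`), and the per-channel scores.
#' @export
select_contact <- function(tfrs, events, gamma_threshold = 0,
                           window = c(0, 0.3)) {
  score <- function(tfr, band) {
    v <- band_window_mean(tfr, band, events$t_onset, window[1], window[2])
    mean(v, na.rm = TRUE)
  }
  g <- vapply(tfrs, score, numeric(1), band = "gamma")
  b <- vapply(tfrs, score, numeric(1), band = "beta")
  if (any(is.finite(g) & g > gamma_threshold)) {
    idx <- which.max(replace(g, !is.finite(g), -Inf))
    crit <- "gamma"
  } else {
    idx <- which.min(replace(b, !is.finite(b), Inf))
    crit <- "beta"
  }
  list(index = idx, channel = names(tfrs)[idx] %||% idx, criterion = crit,
       gamma_score = g, beta_score = b)
}

#' Extract single-trial band-power features
#'
#' Computes, from a normalized time-frequency map of the selected channel:
#' * `beta_cue`: pre-cue beta (-300 to -100 ms) **minus** post-cue beta
#'   (320--400 ms, around the suppression trough), so positive values mean
#'   stronger cue-related suppression;
#' * `beta_move`, `gamma_move`: mean beta / gamma percent change from
#'   movement onset to 300 ms after it (negative `beta_move` = suppression);
#' * `theta_cue`: mean theta percent change 0--750 ms post cue.
#'
#' Features are z-scored within the table (intended use: one subject and
#' hemisphere at a time; z-scoring across subjects happens at join time via
#' [zscore_by_subject()]). Flags: `ok_<feature>` marks |z| <= 3;
#' `rt_ok_beta_cue` (RT >= 400 ms) and `rt_ok_theta_cue` (RT >= 750 ms)
#' implement the RT-conditional exclusions for RT models.
#'
#' @param tfr normalized `stn_tfr` of the selected channel.
#' @param events trial tibble with `trial`, `t_cue`, `t_onset`, `rt`.
#' @param zscore z-score the features and add exclusion flags.
#' @return tibble keyed by `trial`.
#' @export
extract_features <- function(tfr, events, zscore = TRUE) {
  stopifnot(inherits(tfr, "stn_tfr"), tfr$normalized)
  out <- tibble(
    trial = events$trial,
    beta_cue = band_window_mean(tfr, "beta", events$t_cue, -0.30, -0.10) -
      band_window_mean(tfr, "beta", events$t_cue, 0.32, 0.40),
    beta_move = band_window_mean(tfr, "beta", events$t_onset, 0, 0.30),
    gamma_move = band_window_mean(tfr, "gamma", events$t_onset, 0, 0.30),
    theta_cue = band_window_mean(tfr, "theta", events$t_cue, 0, 0.75)
  )
  if (zscore) {
    for (f in c("beta_cue", "beta_move", "gamma_move", "theta_cue")) {
      z <- zscore(out[[f]][is.finite(out[[f]])])
      zz <- rep(NA_real_, nrow(out))
      zz[is.finite(out[[f]])] <- z
      out[[paste0("ok_", f)]] <- !is.na(zz) & abs(zz) <= 3
    }
    out$rt_ok_beta_cue <- !is.na(events$rt) & events$rt >= 0.4
    out$rt_ok_theta_cue <- !is.na(events$rt) & events$rt >= 0.75
  }
  out
}

#' Full LFP feature pipeline for a simulated dataset
#'
#' Runs, per subject and hemisphere: preprocessing, bipolar montage, Morlet
#' decomposition of each bipolar channel, whole-recording normalization,
#' contact selection, and feature extraction — then keeps each trial's
#' contralateral-hemisphere features (the hemisphere opposite the
#' responding hand). The result joins onto the trial table by
#' `subject` + `trial`.
#'
#' @param dataset an `stn_dataset` with an `lfp` component.
#' @param freqs analysis frequencies; the default restricts to the union of
#'   the theta, beta and gamma bands (a 2--100 Hz map is only needed for
#'   display).
#' @param scheme bipolar montage scheme.
#' @param step,cycles see [morlet_tfr()].
#' @return tibble of per-trial features with `subject`, `trial`,
#'   `hemisphere`, `channel` and the columns of [extract_features()].
#' @export
extract_lfp_features <- function(dataset, freqs = sort(unique(unlist(band_bins))),
                                 scheme = "neighbor", step = 0.02, cycles = 7) {
  stopifnot(inherits(dataset, "stn_dataset"))
  if (is.null(dataset$lfp)) abort("dataset has no LFP component")
  purrr::map_dfr(names(dataset$lfp), function(subj) {
    sess <- dataset$lfp[[subj]]
    purrr::map_dfr(c("left", "right"), function(hemi) {
      lfp <- preprocess_lfp(bipolar_montage(sess[[hemi]], scheme = scheme))
      ev <- lfp$events
      tfrs <- lapply(seq_along(lfp$channels), function(cc)
        normalize_power(morlet_tfr(lfp$data[, cc], lfp$rate, freqs = freqs,
                                   step = step, cycles = cycles)))
      names(tfrs) <- lfp$channels
      pick <- select_contact(tfrs, ev)
      contra <- ev$response_side != hemi
      feats <- extract_features(tfrs[[pick$index]], ev[contra, , drop = FALSE])
      feats$subject <- subj
      feats$hemisphere <- hemi
      feats$channel <- pick$channel
      feats
    })
  })
}

#' Paired condition contrast of a single-trial feature
#'
#' Averages a feature per subject and condition, then compares conditions
#' across subjects with a paired t-test. With `variant = "trough"` the
#' contrast is run on the post-event window value alone rather than the
#' pre-minus-post difference (only meaningful for `beta_cue`-style
#' features built as differences elsewhere).
#'
#' @param features tibble with `subject`, the feature column, and the
#'   condition column.
#' @param feature feature column name.
#' @param by condition column (two levels).
#' @return tibble with per-condition means, mean difference, t, df, p.
#' @export
condition_contrast <- function(features, feature, by = "instruction") {
  lv <- sort(unique(features[[by]]))
  if (length(lv) != 2) abort("condition column must have exactly two levels")
  per <- features %>%
    filter(is.finite(.data[[feature]])) %>%
    group_by(.data$subject, cond = .data[[by]]) %>%
    summarise(m = mean(.data[[feature]]), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "cond", values_from = "m") %>%
    filter(complete.cases(.))
  if (nrow(per) < 2) abort("need at least two subjects with both conditions")
  tt <- t.test(per[[lv[1]]], per[[lv[2]]], paired = TRUE)
  tibble(feature = feature,
         mean_1 = mean(per[[lv[1]]]), mean_2 = mean(per[[lv[2]]]),
         level_1 = lv[1], level_2 = lv[2],
         difference = unname(tt$estimate), t = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value, n_subjects = nrow(per))
}
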