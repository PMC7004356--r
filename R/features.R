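#' Estimate the FHR baseline of a window
#'
#' Iterative trimmed mean: starting from the window median (the lower
#' in-sample median, so the start point is always an observed plateau
#' value), the mean of all samples within `baseline_trim_bpm` of the
#' current estimate is recomputed until the estimate moves by less than
#' `baseline_tol_bpm` (or `baseline_max_iter` iterations). The trim excludes acceleration and
#' deceleration excursions from the plateau estimate without needing them
#' identified first. The converged value is rounded to the nearest 5 bpm,
#' the resolution at which baselines are read clinically.
#'
#' For a bimodal window (e.g. equal time on two plateaus) the median start
#' point selects one plateau; the estimate converges to a single plateau
#' value, not their average.
#'
#' @param fhr Cleaned FHR samples (bpm, `NA` = missing).
#' @param rate Sampling rate (Hz).
#' @param cfg A [feature_config()].
#' @return Baseline in bpm, rounded to the nearest 5.
#' @export
estimate_baseline <- function(fhr, rate, cfg = feature_config()) {
  x <- fhr[!is.na(fhr)]
  if (length(x) < cfg$baseline_min_s * rate)
    stop("insufficient data for baseline estimate: ",
         sprintf("%.0f", length(x) / rate), " s usable, need ",
         cfg$baseline_min_s, " s")
  est <- sort(x)[ceiling(length(x) / 2)]
  for (i in seq_len(cfg$baseline_max_iter)) {
    sel <- x[abs(x - est) <= cfg$baseline_trim_bpm]
    if (!length(sel)) break
    new <- mean(sel)
    if (abs(new - est) < cfg$baseline_tol_bpm) { est <- new; break }
    est <- new
  }
  5 * round(est / 5)
}

#' Classify a baseline rate
#'
#' Bins: `lt80` (< 80), `b80_110` (80 to < 110), `b110_160` (110 to 160,
#' both inclusive — the normal range), `gt160` (> 160). The printed ranges
#' 80–110 and 110–160 overlap at 110; 110 is assigned to the normal side.
#'
#' @param baseline_bpm Baseline in bpm (> 0).
#' @return One of `"lt80"`, `"b80_110"`, `"b110_160"`, `"gt160"`.
#' @export
classify_baseline <- function(baseline_bpm) {
  stopifnot(baseline_bpm > 0)
  if (baseline_bpm < 80) "lt80"
  else if (baseline_bpm < 110) "b80_110"
  else if (baseline_bpm <= 160) "b110_160"
  else "gt160"
}

#' Classify a variability amplitude
#'
#' Printed bins: undetectable (amplitude <= 2 bpm), minimal (3–5), moderate
#' (6–25), marked (>= 26). Real-valued amplitudes between printed bins take
#' the neighbouring class whose printed edge they exceed: (2, 5\] minimal,
#' (5, 26) moderate.
#'
#' @param amp_bpm Variability amplitude (bpm).
#' @return One of `"undetectable"`, `"minimal"`, `"moderate"`, `"marked"`.
#' @export
classify_variability <- function(amp_bpm) {
  if (amp_bpm <= 2) "undetectable"
  else if (amp_bpm <= 5) "minimal"
  else if (amp_bpm < 26) "moderate"
  else "marked"
}

# Moving average with partial windows at the edges (width k samples).
mov_avg <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- k %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Detect excursion episodes of one sign.
# dev: fhr - baseline; sign +1 (accelerations) or -1 (decelerations).
# Core: deviation beyond min_amp sustained >= min_dur_s; each core is
# extended outward to the baseline-return crossing (|dev| < return_tol),
# overlapping extensions merged. Returns a data.frame of sample indices.
episode_spans <- function(dev, rate, sign, min_amp, min_dur_s, max_dur_s,
                          return_tol) {
  core <- !is.na(dev) & sign * dev >= min_amp
  r <- rle(core)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_dur_s * rate
  if (!any(keep)) return(data.frame(start = integer(0), end = integer(0)))
  away <- !is.na(dev) & sign * dev >= return_tol
  s_idx <- starts[keep]; e_idx <- ends[keep]
  for (j in seq_along(s_idx)) {
    s <- s_idx[j]
    while (s > 1L && away[s - 1L]) s <- s - 1L
    e <- e_idx[j]
    while (e < length(dev) && away[e + 1L]) e <- e + 1L
    s_idx[j] <- s; e_idx[j] <- e
  }
  # merge overlapping/adjacent spans
  o <- order(s_idx)
  s_idx <- s_idx[o]; e_idx <- e_idx[o]
  ms <- s_idx[1]; me <- e_idx[1]; out_s <- integer(0); out_e <- integer(0)
  for (j in seq_along(s_idx)[-1]) {
    if (s_idx[j] <= me + 1L) me <- max(me, e_idx[j])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- s_idx[j]; me <- e_idx[j] }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  dur <- (out_e - out_s + 1L) / rate
  keep2 <- dur < max_dur_s
  data.frame(start = out_s[keep2], end = out_e[keep2])
}

#' Detect accelerations
#'
#' An acceleration is an excursion at least `accel_min_bpm` above baseline
#' sustained for at least `accel_min_s` and shorter than `episode_max_s`.
#' Returned spans are disjoint.
#'
#' @param fhr Cleaned FHR samples (bpm).
#' @param baseline Baseline (bpm).
#' @param rate Sampling rate (Hz).
#' @param cfg A [feature_config()].
#' @return Data.frame with columns `onset_s`, `end_s` (segment-relative
#'   seconds), `peak_bpm`.
#' @export
detect_accelerations <- function(fhr, baseline, rate, cfg = feature_config()) {
  sp <- episode_spans(fhr - baseline, rate, +1, cfg$accel_min_bpm,
                      cfg$accel_min_s, cfg$episode_max_s, cfg$return_tol_bpm)
  if (!nrow(sp))
    return(data.frame(onset_s = numeric(0), end_s = numeric(0),
                      peak_bpm = numeric(0)))
  peak <- vapply(seq_len(nrow(sp)), function(j)
    max(fhr[sp$start[j]:sp$end[j]], na.rm = TRUE), 0)
  data.frame(onset_s = (sp$start - 1L) / rate, end_s = (sp$end - 1L) / rate,
             peak_bpm = peak)
}

#' Detect contraction peaks in the UC channel
#'
#' The channel is smoothed with a `uc_smooth_s` moving average; peaks are
#' local maxima rising at least `uc_prominence` units above the resting tone
#' (10th percentile of the smoothed channel), at least `uc_min_sep_s`
#' apart (higher peaks win).
#'
#' @param uc UC samples (arbitrary units).
#' @param rate Sampling rate (Hz).
#' @param cfg A [feature_config()].
#' @return Numeric vector of peak times (segment-relative seconds).
#' @export
find_contractions <- function(uc, rate, cfg = feature_config()) {
  x <- uc
  x[is.na(x)] <- stats::median(x, na.rm = TRUE)
  if (all(is.na(x))) return(numeric(0))
  m <- mov_avg(x, max(1L, round(cfg$uc_smooth_s * rate)))
  tone <- stats::quantile(m, 0.1, names = FALSE)
  thr <- tone + cfg$uc_prominence
  n <- length(m)
  w <- max(1L, round(cfg$uc_min_sep_s * rate / 2))
  cand <- which(m >= thr)
  if (!length(cand)) return(numeric(0))
  is_max <- vapply(cand, function(i)
    m[i] >= max(m[max(1L, i - w):min(n, i + w)]), TRUE)
  cand <- cand[is_max]
  if (!length(cand)) return(numeric(0))
  # collapse plateau ties, then enforce min separation greedily by height
  cand <- cand[c(TRUE, diff(cand) > 1L)]
  o <- cand[order(m[cand], decreasing = TRUE)]
  acc <- integer(0)
  min_sep <- cfg$uc_min_sep_s * rate
  for (i in o) if (!length(acc) || all(abs(acc - i) >= min_sep)) acc <- c(acc, i)
  sort((acc - 1L) / rate)
}

#' Detect and type decelerations
#'
#' A candidate deceleration is an excursion at least `decel_min_bpm` below
#' baseline sustained for at least `decel_min_s`, extended to its
#' baseline-return points. Typing:
#' \itemize{
#'   \item duration >= `prolonged_min_s` (and < `episode_max_s`): prolonged;
#'   \item else onset-to-nadir < `abrupt_onset_s`: variable (abrupt);
#'   \item else (gradual): nadir more than `early_late_window_s` after the
#'     nearest contraction peak — late; otherwise early; with no contraction
#'     peak within `late_assoc_window_s` of the nadir, the gradual
#'     deceleration falls back to variable.
#' }
#' Severity: variable is severe iff nadir < `var_severe_nadir_bpm` and
#' duration >= `var_severe_dur_s`; late is severe iff depth >=
#' `late_severe_depth_bpm`; prolonged is severe iff nadir <
#' `prolonged_severe_nadir_bpm`; early is always mild.
#'
#' @param fhr Cleaned FHR samples (bpm).
#' @param baseline Baseline (bpm).
#' @param contraction_peaks Contraction peak times (segment-relative s),
#'   from [find_contractions()].
#' @param rate Sampling rate (Hz).
#' @param cfg A [feature_config()].
#' @return Data.frame with columns `onset_s`, `nadir_s`, `end_s`,
#'   `nadir_bpm`, `depth_bpm`, `duration_s`, `kind`, `severity`.
#' @export
detect_decelerations <- function(fhr, baseline, contraction_peaks, rate,
                                 cfg = feature_config()) {
  empty <- data.frame(onset_s = numeric(0), nadir_s = numeric(0),
                      end_s = numeric(0), nadir_bpm = numeric(0),
                      depth_bpm = numeric(0), duration_s = numeric(0),
                      kind = character(0), severity = character(0))
  sp <- episode_spans(fhr - baseline, rate, -1, cfg$decel_min_bpm,
                      cfg$decel_min_s, cfg$episode_max_s, cfg$return_tol_bpm)
  if (!nrow(sp)) return(empty)
  out <- lapply(seq_len(nrow(sp)), function(j) {
    idx <- sp$start[j]:sp$end[j]
    seg <- fhr[idx]
    k <- which.min(seg)
    nadir_i <- idx[k]
    onset_s <- (sp$start[j] - 1L) / rate
    end_s <- (sp$end[j] - 1L) / rate
    nadir_s <- (nadir_i - 1L) / rate
    nadir_bpm <- seg[k]
    depth <- baseline - nadir_bpm
    dur <- end_s - onset_s + 1 / rate
    if (dur >= cfg$prolonged_min_s) {
      kind <- "prolonged"
      sev <- if (nadir_bpm < cfg$prolonged_severe_nadir_bpm) "severe" else "mild"
    } else if (nadir_s - onset_s < cfg$abrupt_onset_s) {
      kind <- "variable"
      sev <- if (nadir_bpm < cfg$var_severe_nadir_bpm &&
                 dur >= cfg$var_severe_dur_s) "severe" else "mild"
    } else {
      near <- if (length(contraction_peaks))
        contraction_peaks[which.min(abs(contraction_peaks - nadir_s))]
      else NA_real_
      if (is.na(near) || abs(near - nadir_s) > cfg$late_assoc_window_s) {
        kind <- "variable"
        sev <- if (nadir_bpm < cfg$var_severe_nadir_bpm &&
                   dur >= cfg$var_severe_dur_s) "severe" else "mild"
      } else if (nadir_s - near > cfg$early_late_window_s) {
        kind <- "late"
        sev <- if (depth >= cfg$late_severe_depth_bpm) "severe" else "mild"
      } else {
        kind <- "early"
        sev <- "mild"
      }
    }
    data.frame(onset_s = onset_s, nadir_s = nadir_s, end_s = end_s,
               nadir_bpm = nadir_bpm, depth_bpm = depth, duration_s = dur,
               kind = kind, severity = sev)
  })
  do.call(rbind, out)
}

#' Variability amplitude of a window
#'
#' Samples inside acceleration/deceleration spans are excluded; the
#' remaining samples are split into `var_bin_s` bins; bins with at least
#' `var_bin_min_s` of usable signal contribute their peak-to-peak range
#' (max - min); the window amplitude is the median of the bin ranges.
#'
#' @param fhr Cleaned FHR samples (bpm).
#' @param rate Sampling rate (Hz).
#' @param episode_spans_s Data.frame with columns `onset_s`, `end_s` of
#'   spans to exclude (accelerations and decelerations), or `NULL`.
#' @param cfg A [feature_config()].
#' @return Amplitude in bpm, or `NA` if no bin has enough usable signal.
#' @export
variability_amplitude <- function(fhr, rate, episode_spans_s = NULL,
                                  cfg = feature_config()) {
  x <- fhr
  if (!is.null(episode_spans_s) && nrow(episode_spans_s)) {
    t <- (seq_along(x) - 1) / rate
    for (j in seq_len(nrow(episode_spans_s)))
      x[t >= episode_spans_s$onset_s[j] & t <= episode_spans_s$end_s[j]] <- NA
  }
  bin_len <- max(1L, round(cfg$var_bin_s * rate))
  bins <- split(x, ceiling(seq_along(x) / bin_len))
  amps <- vapply(bins, function(b) {
    b <- b[!is.na(b)]
    if (length(b) < cfg$var_bin_min_s * rate) return(NA_real_)
    max(b) - min(b)
  }, 0)
  amps <- amps[!is.na(amps)]
  if (!length(amps)) return(NA_real_)
  stats::median(amps)
}

#' Detect a sinusoidal FHR pattern
#'
#' A window passes when its dominant spectral component within the
#' `sin_total_band_hz` reference band lies in `sin_band_hz` (3–5 cycles per
#' minute), the sinusoidal band holds at least `sin_power_frac` of the
#' reference-band power, and the oscillation amplitude (half peak-to-peak)
#' is within `sin_amp_bpm`. Windows of `sin_window_s` stepped by
#' `sin_step_s` that overlap a detected deceleration are excluded from the
#' vote; the segment is sinusoidal when at least `sin_frac` of the eligible
#' windows pass and no acceleration was detected.
#'
#' @param fhr Cleaned FHR samples (bpm).
#' @param rate Sampling rate (Hz).
#' @param decel_spans_s Data.frame of deceleration spans (`onset_s`,
#'   `end_s`), or `NULL`.
#' @param accel_count Number of detected accelerations in the segment.
#' @param cfg A [feature_config()].
#' @return Logical flag.
#' @export
detect_sinusoidal <- function(fhr, rate, decel_spans_s = NULL, accel_count = 0,
                              cfg = feature_config()) {
  if (accel_count > 0) return(FALSE)
  n <- length(fhr)
  win <- round(cfg$sin_window_s * rate)
  step <- round(cfg$sin_step_s * rate)
  if (n < win) return(FALSE)
  starts <- seq(1L, n - win + 1L, by = step)
  t0 <- (starts - 1) / rate
  t1 <- t0 + cfg$sin_window_s
  eligible <- rep(TRUE, length(starts))
  if (!is.null(decel_spans_s) && nrow(decel_spans_s)) {
    for (j in seq_len(nrow(decel_spans_s)))
      eligible <- eligible & (t1 < decel_spans_s$onset_s[j] |
                                t0 > decel_spans_s$end_s[j])
  }
  if (!any(eligible)) return(FALSE)
  pass <- vapply(starts[eligible], function(s) {
    y <- fhr[s:(s + win - 1L)]
    y <- y[!is.na(y)]
    if (length(y) < 0.9 * win) return(FALSE)
    amp <- (max(y) - min(y)) / 2
    if (amp < cfg$sin_amp_bpm[1] || amp > cfg$sin_amp_bpm[2]) return(FALSE)
    y <- y - mean(y)
    m <- length(y)
    pw <- Mod(stats::fft(y))^2
    f <- (seq_len(m) - 1) * rate / m
    half <- f > 0 & f <= rate / 2
    f <- f[half]; pw <- pw[half]
    tot_sel <- f >= cfg$sin_total_band_hz[1] & f <= cfg$sin_total_band_hz[2]
    sin_sel <- f >= cfg$sin_band_hz[1] & f <= cfg$sin_band_hz[2]
    tot <- sum(pw[tot_sel])
    if (tot <= 0) return(FALSE)
    dom <- f[tot_sel][which.max(pw[tot_sel])]
    sum(pw[sin_sel]) / tot >= cfg$sin_power_frac &&
      dom >= cfg$sin_band_hz[1] && dom <= cfg$sin_band_hz[2]
  }, TRUE)
  mean(pass) >= cfg$sin_frac
}

#' Extract the classification feature tuple of one 10-minute segment
#'
#' Composes baseline estimation, acceleration/deceleration detection,
#' contraction finding, variability measurement and sinusoidal-pattern
#' detection into the feature tuple both rule-table classifiers consume.
#' Decelerations of a kind are recurrent when their count is at least
#' `recurrence_frac` of the number of contractions and there are at least
#' two contractions in the segment.
#'
#' @param fhr,uc Cleaned FHR and raw UC samples of the segment.
#' @param rate Sampling rate (Hz).
#' @param cfg A [feature_config()].
#' @return An object of class `segment_features`: a list with elements
#'   `baseline_bpm`, `baseline_class`, `variability_amp_bpm`,
#'   `variability_class`, `sinusoidal`, `accel_count`, `decels` (data.frame
#'   from [detect_decelerations()]), `recurrent_late`, `recurrent_variable`,
#'   `n_contractions`, `indeterminate` (logical) and `reason`. When the
#'   baseline or variability cannot be estimated the tuple is marked
#'   indeterminate and classification is reported missing downstream.
#' @export
extract_segment_features <- function(fhr, uc, rate, cfg = feature_config()) {
  indeterminate <- function(reason)
    structure(list(baseline_bpm = NA_real_, baseline_class = NA_character_,
                   variability_amp_bpm = NA_real_,
                   variability_class = NA_character_, sinusoidal = NA,
                   accel_count = NA_integer_, decels = NULL,
                   recurrent_late = NA, recurrent_variable = NA,
                   n_contractions = NA_integer_, indeterminate = TRUE,
                   reason = reason),
              class = "segment_features")
  baseline <- tryCatch(estimate_baseline(fhr, rate, cfg),
                       error = function(e) NA_real_)
  if (is.na(baseline)) return(indeterminate("baseline"))
  peaks <- find_contractions(uc, rate, cfg)
  accels <- detect_accelerations(fhr, baseline, rate, cfg)
  decels <- detect_decelerations(fhr, baseline, peaks, rate, cfg)
  spans <- rbind(accels[, c("onset_s", "end_s")],
                 decels[, c("onset_s", "end_s")])
  if (nrow(spans)) {
    spans$onset_s <- spans$onset_s - cfg$var_exclude_pad_s
    spans$end_s <- spans$end_s + cfg$var_exclude_pad_s
  }
  amp <- variability_amplitude(fhr, rate, spans, cfg)
  if (is.na(amp)) return(indeterminate("variability"))
  sinus <- detect_sinusoidal(fhr, rate, decels[, c("onset_s", "end_s")],
                             nrow(accels), cfg)
  n_con <- length(peaks)
  recur <- function(kind) {
    n_con >= 2 && sum(decels$kind == kind) >= cfg$recurrence_frac * n_con
  }
  structure(list(baseline_bpm = baseline,
                 baseline_class = classify_baseline(baseline),
                 variability_amp_bpm = amp,
                 variability_class = classify_variability(amp),
                 sinusoidal = sinus,
                 accel_count = nrow(accels),
                 decels = decels,
                 recurrent_late = recur("late"),
                 recurrent_variable = recur("variable"),
                 n_contractions = n_con,
                 indeterminate = FALSE, reason = NA_character_),
            class = "segment_features")
}

#' Build a feature tuple directly
#'
#' Convenience constructor for classifying hypothetical feature tuples
#' (e.g. auditing a rule-table cell) without a trace.
#'
#' @param variability_class One of `"undetectable"`, `"minimal"`,
#'   `"moderate"`, `"marked"`.
#' @param baseline_class One of `"lt80"`, `"b80_110"`, `"b110_160"`,
#'   `"gt160"`.
#' @param decels Data.frame with columns `kind` and `severity` (other
#'   deceleration fields optional), or `NULL` for none.
#' @param sinusoidal Logical.
#' @param recurrent_late,recurrent_variable Logical recurrence flags.
#' @param accel_count Number of accelerations.
#' @param n_contractions Number of contractions.
#' @return A `segment_features` object.
#' @export
segment_features <- function(variability_class, baseline_class = "b110_160",
                             decels = NULL, sinusoidal = FALSE,
                             recurrent_late = FALSE, recurrent_variable = FALSE,
                             accel_count = 0L, n_contractions = 3L) {
  stopifnot(variability_class %in% c("undetectable", "minimal", "moderate",
                                     "marked"),
            baseline_class %in% c("lt80", "b80_110", "b110_160", "gt160"))
  if (is.null(decels))
    decels <- data.frame(kind = character(0), severity = character(0))
  structure(list(baseline_bpm = NA_real_, baseline_class = baseline_class,
                 variability_amp_bpm = NA_real_,
                 variability_class = variability_class,
                 sinusoidal = sinusoidal, accel_count = accel_count,
                 decels = decels, recurrent_late = recurrent_late,
                 recurrent_variable = recurrent_variable,
                 n_contractions = n_contractions,
                 indeterminate = FALSE, reason = NA_character_),
            class = "segment_features")
}
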