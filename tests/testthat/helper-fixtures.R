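# Trace-construction helpers used across test files. All fixtures are
# generated in code; none are stored on disk.

# constant-baseline record of given duration with delivery at its end
flat_record <- function(bpm = 140, duration_s = 3600, rate = 4,
                        uc = 10, id = "fx") {
  n <- round(duration_s * rate)
  ctg_record(id, rep(bpm, n), rep(uc, n), delivery_offset_s = duration_s,
             sample_rate_hz = rate)
}

# band-spread multi-sine oscillation with a given peak-to-peak amplitude
osc_wave <- function(t, ptp, freqs = c(0.03, 0.10, 0.17), phases = c(0.3, 1.1, 2.4)) {
  x <- rowSums(vapply(seq_along(freqs),
                      function(i) sin(2 * pi * freqs[i] * t + phases[i]),
                      numeric(length(t))))
  x * ptp / (max(x) - min(x))
}

# 600 s segment: baseline + optional oscillation, with UC bumps at
# peak_times and raised-cosine dips (depth, width, center)
make_segment <- function(baseline = 140, rate = 4, ptp = 0,
                         peak_times = c(150, 330, 510),
                         dips = NULL, uc_tone = 10, uc_amp = 40) {
  n <- round(600 * rate)
  t <- (seq_len(n) - 1) / rate
  fhr <- rep(baseline, n)
  if (ptp > 0) fhr <- fhr + osc_wave(t, ptp)
  if (!is.null(dips)) for (j in seq_len(nrow(dips))) {
    u <- (t - dips$center[j]) / dips$width[j] + 0.5
    s <- ifelse(u >= 0 & u <= 1, 0.5 * (1 - cos(2 * pi * u)), 0)
    fhr <- fhr - dips$depth[j] * s
  }
  uc <- rep(uc_tone, n)
  for (pk in peak_times) uc <- uc + uc_amp * exp(-0.5 * ((t - pk) / 20)^2)
  list(fhr = fhr, uc = uc, t = t, rate = rate)
}

random_record <- function(rate = 4, n = 60, id = "r") {
  fhr <- runif(n, 110, 170)
  fhr[sample(n, round(0.1 * n))] <- NA
  ctg_record(id, fhr, runif(n, 0, 60), delivery_offset_s = n / rate,
             sample_rate_hz = rate)
}

# the expected 5-tier grid as printed, frozen independently of the shipped
# CSV (rows: moderate x 4 baselines, minimal x 4, undetectable, marked,
# sinusoidal; columns: none, early, variable m/s, late m/s, prolonged m/s)
printed_grid_expected <- function() {
  rbind(
    moderate.b110_160 = c(1, 2, 2, 3, 3, 3, 3, 4),
    moderate.gt160    = c(2, 2, 3, 3, 3, 4, 3, 4),
    moderate.b80_110  = c(3, 3, 3, 4, 4, 4, 4, 4),
    moderate.lt80     = c(4, 4, NA, 4, 4, 4, NA, NA),
    minimal.b110_160  = c(3, 3, 3, 4, 3, 4, 4, NA),
    minimal.gt160     = c(3, 3, 4, 4, 4, 5, 4, NA),
    minimal.b80_110   = c(4, 4, 4, 5, 5, 5, 5, 5),
    minimal.lt80      = c(5, 5, NA, 5, 5, 5, NA, NA),
    undetectable      = c(4, 5, 5, 5, 5, 5, 5, 5),
    marked            = c(NA, NA, 3, 3, 3, 4, 3, 4),
    sinusoidal        = c(4, 4, 4, 4, 5, 5, 5, 5))
}

decel_for_column <- function(column) {
  if (column == "none") return(NULL)
  if (column == "early") return(data.frame(kind = "early", severity = "mild"))
  kind <- sub("_(mild|severe)$", "", column)
  severity <- sub("^.*_", "", column)
  data.frame(kind = kind, severity = severity)
}

grid_columns <- c("none", "early", "variable_mild", "variable_severe",
                  "late_mild", "late_severe", "prolonged_mild",
                  "prolonged_severe")

# feature tuple hitting one grid row x column
tuple_for <- function(row_name, column) {
  parts <- strsplit(row_name, ".", fixed = TRUE)[[1]]
  var <- parts[1]
  base <- if (length(parts) > 1) parts[2] else "b110_160"
  segment_features(
    variability_class = if (var == "sinusoidal") "moderate" else var,
    baseline_class = base,
    decels = decel_for_column(column),
    sinusoidal = var == "sinusoidal")
}

seg_levels <- c(60L, 50L, 40L, 30L, 20L, 10L)
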