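#' Preprocessing configuration
#'
#' Artifact-rejection thresholds applied by [clean_fhr()]. Defaults follow
#' conventional CTG signal-processing practice: samples outside a
#' physiological band are rejected, implausibly fast beat-to-beat jumps are
#' treated as transducer artifact, and only short gaps are bridged by
#' interpolation.
#'
#' @param low_bpm Lower physiological limit (beats per minute); samples below
#'   are marked missing. Default 30.
#' @param high_bpm Upper physiological limit (bpm). Default 240.
#' @param max_jump_bpm Maximum allowed sample-to-sample change (bpm); the
#'   later sample of a larger jump is marked missing. Default 25.
#' @param max_interp_s Missing runs strictly shorter than this many seconds
#'   are linearly interpolated; longer runs stay missing. Default 15.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(low_bpm = 30, high_bpm = 240,
                              max_jump_bpm = 25, max_interp_s = 15) {
  stopifnot(low_bpm < high_bpm, max_jump_bpm > 0, max_interp_s >= 0)
  structure(list(low_bpm = low_bpm, high_bpm = high_bpm,
                 max_jump_bpm = max_jump_bpm, max_interp_s = max_interp_s),
            class = "preprocess_config")
}

#' Feature-extraction configuration
#'
#' Thresholds used by the segment feature extractor. All defaults are the
#' standard intrapartum guideline definitions; the deceleration severity
#' cut-offs are stated assumptions (the severity grading of the 5-tier grid
#' is not fully pinned down by published tables) and are therefore
#' configurable.
#'
#' @param baseline_trim_bpm Half-width of the iterative trimmed-mean window
#'   used by [estimate_baseline()] (bpm). Default 15.
#' @param baseline_tol_bpm Convergence tolerance of the baseline iteration
#'   (bpm). Default 0.5.
#' @param baseline_max_iter Maximum baseline iterations. Default 50.
#' @param baseline_min_s Minimum usable (non-missing) signal per window for a
#'   baseline estimate (seconds). Default 120.
#' @param var_bin_s Variability bin width (seconds). Default 60.
#' @param var_bin_min_s Minimum usable signal for a variability bin
#'   (seconds). Default 30.
#' @param var_exclude_pad_s Padding (s) added to each side of an
#'   acceleration/deceleration span when excluding it from variability
#'   bins, so the shallow episode tails between the baseline-return point
#'   and true baseline do not inflate the amplitude of quiet traces.
#'   Default 10.
#' @param accel_min_bpm,accel_min_s Acceleration amplitude (bpm above
#'   baseline) and duration (s) thresholds. Defaults 15 and 15.
#' @param decel_min_bpm,decel_min_s Deceleration excursion depth (bpm below
#'   baseline) and sustained-excursion duration (s) thresholds. Defaults 15
#'   and 15.
#' @param episode_max_s Maximum episode duration (s); longer excursions are
#'   baseline shifts, not episodes. Default 600.
#' @param return_tol_bpm Deviation from baseline (bpm) at which an episode is
#'   considered to have returned to baseline when locating onset/end.
#'   Default 2.
#' @param prolonged_min_s Deceleration duration (s) at or above which the
#'   type is prolonged. Default 120.
#' @param abrupt_onset_s Onset-to-nadir time (s) below which a deceleration
#'   is abrupt (variable); at or above, gradual (early/late). Default 30.
#' @param early_late_window_s Gradual decelerations with nadir within this
#'   many seconds of the contraction peak are early; nadir later than this
#'   after the peak, late. Default 18.
#' @param late_assoc_window_s Gradual decelerations with no contraction peak
#'   within this many seconds fall back to variable. Default 120.
#' @param var_severe_nadir_bpm,var_severe_dur_s A variable deceleration is
#'   severe iff nadir below this rate AND duration at least this long.
#'   Defaults 70 bpm, 60 s.
#' @param late_severe_depth_bpm A late deceleration is severe iff its depth
#'   (baseline minus nadir) is at least this. Default 45.
#' @param prolonged_severe_nadir_bpm A prolonged deceleration is severe iff
#'   its nadir is below this. Default 80.
#' @param uc_smooth_s Moving-average width for the uterine-contraction
#'   channel (s). Default 30.
#' @param uc_prominence Contraction peaks must rise at least this far above
#'   the resting tone (channel units). Default 15.
#' @param uc_min_sep_s Minimum separation between contraction peaks (s).
#'   Default 120.
#' @param recurrence_frac Decelerations of a kind are recurrent when they
#'   accompany at least this fraction of contractions (and there are at
#'   least 2 contractions). Default 0.5.
#' @param sin_band_hz Frequency band of the sinusoidal oscillation (Hz);
#'   default `c(0.05, 0.083)`, i.e. 3-5 cycles per minute.
#' @param sin_total_band_hz Reference band for the spectral concentration
#'   ratio. Default `c(0.02, 0.2)`.
#' @param sin_power_frac Minimum fraction of reference-band power inside the
#'   sinusoidal band. Default 0.6.
#' @param sin_amp_bpm Admissible sinusoidal amplitude range (half
#'   peak-to-peak, bpm). Default `c(5, 15)`.
#' @param sin_window_s,sin_step_s Spectral test window length and step (s).
#'   Defaults 60 and 30 (short enough that windows between recurrent
#'   decelerations remain eligible).
#' @param sin_frac Fraction of eligible windows that must pass for the
#'   segment to be sinusoidal. Default 0.8.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(baseline_trim_bpm = 15, baseline_tol_bpm = 0.5,
                           baseline_max_iter = 50, baseline_min_s = 120,
                           var_bin_s = 60, var_bin_min_s = 30,
                           var_exclude_pad_s = 10,
                           accel_min_bpm = 15, accel_min_s = 15,
                           decel_min_bpm = 15, decel_min_s = 15,
                           episode_max_s = 600, return_tol_bpm = 2,
                           prolonged_min_s = 120, abrupt_onset_s = 30,
                           early_late_window_s = 18, late_assoc_window_s = 120,
                           var_severe_nadir_bpm = 70, var_severe_dur_s = 60,
                           late_severe_depth_bpm = 45,
                           prolonged_severe_nadir_bpm = 80,
                           uc_smooth_s = 30, uc_prominence = 15,
                           uc_min_sep_s = 120, recurrence_frac = 0.5,
                           sin_band_hz = c(0.05, 0.083),
                           sin_total_band_hz = c(0.02, 0.2),
                           sin_power_frac = 0.6, sin_amp_bpm = c(5, 15),
                           sin_window_s = 60, sin_step_s = 30,
                           sin_frac = 0.8) {
  cfg <- as.list(environment())
  structure(cfg, class = "feature_config")
}

#' Statistics configuration
#'
#' @param exact_max_n Exact permutation p-values are used when the total
#'   sample size of a test is at most this; larger samples use tie-corrected
#'   asymptotic approximations. Default 8.
#' @param alpha Significance level reported alongside tests. Default 0.05.
#' @param be_test Which Wilcoxon variant compares the two base-excess
#'   groups: `"rank_sum"` (independent groups, the statistically coherent
#'   choice) or `"signed_rank"`. Default `"rank_sum"`.
#' @return A list of class `stats_config`.
#' @export
stats_config <- function(exact_max_n = 8, alpha = 0.05,
                         be_test = c("rank_sum", "signed_rank")) {
  be_test <- match.arg(be_test)
  structure(list(exact_max_n = exact_max_n, alpha = alpha, be_test = be_test),
            class = "stats_config")
}

#' Full pipeline configuration
#'
#' Bundles the per-stage configurations. Every threshold any stage uses lives
#' here, so an analysis is fully described by one object (serialisable to
#' YAML via [read_config()]/[write_config()]).
#'
#' @param preprocess A [preprocess_config()].
#' @param features A [feature_config()].
#' @param synth A [synth_config()].
#' @param stats A [stats_config()].
#' @param sample_rate_hz Default sampling rate for synthesis (Hz). Default 4.
#' @return A list of class `ctg_config`.
#' @export
ctg_config <- function(preprocess = preprocess_config(),
                       features = feature_config(),
                       synth = synth_config(),
                       stats = stats_config(),
                       sample_rate_hz = 4) {
  structure(list(preprocess = preprocess, features = features,
                 synth = synth, stats = stats,
                 sample_rate_hz = sample_rate_hz),
            class = "ctg_config")
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults; everything else keeps
#' its default, so partial configuration files are fine.
#'
#' @param path Path to a YAML file whose top-level keys are any of
#'   `preprocess`, `features`, `synth`, `stats`, `sample_rate_hz`.
#' @return A `ctg_config` object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- ctg_config()
  for (block in intersect(names(raw), c("preprocess", "features", "synth", "stats"))) {
    known <- names(cfg[[block]])
    extra <- setdiff(names(raw[[block]]), known)
    if (length(extra))
      stop("unknown ", block, " config keys: ", paste(extra, collapse = ", "))
    for (k in names(raw[[block]])) cfg[[block]][[k]] <- raw[[block]][[k]]
  }
  if (!is.null(raw$sample_rate_hz)) cfg$sample_rate_hz <- raw$sample_rate_hz
  cfg
}

#' Write a pipeline configuration to YAML
#'
#' @param cfg A `ctg_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "ctg_config"))
  yaml::write_yaml(lapply(cfg, function(x) if (is.list(x)) unclass(x) else x),
                   path)
  invisible(path)
}
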