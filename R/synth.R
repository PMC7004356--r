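#' Synthetic cohort configuration
#'
#' Parameters of the synthetic CTG cohort generator. The generator emulates
#' a cohort of low-risk vaginal deliveries: per-segment 5-tier level
#' frequencies drift toward worse classes as delivery approaches, subjects'
#' levels are correlated across segments through a latent-severity Gaussian
#' copula, and umbilical artery pH and base excess decrease linearly in the
#' level trajectory with segment weights growing toward delivery — the
#' smallest model reproducing the directional findings the pipeline is
#' meant to detect (worse classes imply lower pH/BE, association
#' strengthening near delivery).
#'
#' @param n_subjects Cohort size. Default 1909.
#' @param rho Latent-severity copula correlation in \[0, 1). Default 0.6.
#' @param segment_marginals 5 x 6 matrix of per-segment level probabilities
#'   (rows = Levels 1-5, columns = 60...10 min before delivery). The default
#'   is the reported per-segment frequency table of the reference cohort,
#'   with zero cells given mass 5e-4 to keep the support complete, columns
#'   renormalised.
#' @param cat1_targets Per-segment target proportions of 3-tier Category I.
#'   Within Level 2 the probability of the only non-Level-1 Category-I grid
#'   cell (moderate variability, baseline 110-160, early decelerations) is
#'   calibrated per segment to `(cat1_targets - P(Level 1)) / P(Level 2)`
#'   so the derived 3-tier marginals match these targets; remaining Level-2
#'   mass is uniform over the other Level-2 cells. All other levels select
#'   their grid cell uniformly.
#' @param ph0,ph_weights,sigma_ph pH model: `ph = ph0 - sum(w_t * (level_t
#'   - 1)) + N(0, sigma_ph^2)`, weights ordered 60 to 10 min. Defaults
#'   7.38, (0.004, 0.004, 0.005, 0.006, 0.008, 0.012), 0.055.
#' @param be0,be_weights,sigma_be Base-excess model, same form. Defaults
#'   -3.0, (0.2, 0.2, 0.25, 0.3, 0.4, 0.6), 2.6 (mmol/L).
#' @param variability_ptp Target peak-to-peak oscillation (bpm) rendered for
#'   each variability class.
#' @param osc_freqs_hz,osc_freqs_marked_hz Oscillation component
#'   frequencies (Hz) for normal and marked variability rendering; chosen
#'   outside the 3-5 cycles/min sinusoidal band, faster for marked so large
#'   excursions never mimic a sustained deceleration.
#' @param sin_amp_bpm,sin_freq_hz Sinusoidal-pattern rendering amplitude
#'   (half peak-to-peak) and frequency. Defaults 8 bpm, 4 cycles/min.
#' @param contraction_interval_s Range of contraction peak spacing (s).
#'   Default c(150, 210).
#' @param uc_tone,uc_amp,uc_sd_s UC channel resting tone, bump amplitude
#'   and Gaussian bump width (s).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 1909,
                         rho = 0.6,
                         segment_marginals = default_marginals(),
                         cat1_targets = c(0.555, 0.506, 0.472, 0.367,
                                          0.235, 0.019),
                         ph0 = 7.38,
                         ph_weights = c(0.004, 0.004, 0.005, 0.006, 0.008,
                                        0.012),
                         sigma_ph = 0.055,
                         be0 = -3.0,
                         be_weights = c(0.2, 0.2, 0.25, 0.3, 0.4, 0.6),
                         sigma_be = 2.6,
                         variability_ptp = c(undetectable = 1, minimal = 4,
                                             moderate = 15, marked = 34),
                         osc_freqs_hz = c(0.03, 0.10, 0.17),
                         osc_freqs_marked_hz = c(0.07, 0.11, 0.18),
                         sin_amp_bpm = 8, sin_freq_hz = 4 / 60,
                         contraction_interval_s = c(150, 210),
                         uc_tone = 10, uc_amp = 40, uc_sd_s = 20) {
  segment_marginals <- as.matrix(segment_marginals)
  stopifnot(nrow(segment_marginals) == 5, ncol(segment_marginals) == 6,
            all(segment_marginals >= 0),
            abs(colSums(segment_marginals) - 1) < 1e-9,
            rho >= 0, rho < 1,
            all(ph_weights >= 0), all(be_weights >= 0),
            length(cat1_targets) == 6)
  structure(as.list(environment()), class = "synth_config")
}

#' Default per-segment 5-tier level marginals
#'
#' The reported per-segment Level 1-5 frequencies of the reference cohort
#' (columns 60...10 min before delivery), zero cells replaced by 5e-4,
#' columns renormalised to sum to one.
#'
#' @return A 5 x 6 probability matrix.
#' @export
default_marginals <- function() {
  m <- matrix(c(
    0.540, 0.493, 0.462, 0.359, 0.229, 0.019,
    0.345, 0.380, 0.390, 0.460, 0.512, 0.357,
    0.107, 0.116, 0.138, 0.163, 0.225, 0.445,
    0.007, 0.010, 0.010, 0.017, 0.032, 0.175,
    0.001, 0.000, 0.000, 0.001, 0.002, 0.004),
    nrow = 5, byrow = TRUE,
    dimnames = list(paste0("level", 1:5), paste0("seg", SEGMENT_LEVELS)))
  m[m == 0] <- 5e-4
  sweep(m, 2, colSums(m), "/")
}

#' Enumerate the cells of the 5-tier grid
#'
#' One row per (grid row x deceleration column) cell of the resolved grid,
#' with the level and the rendering attributes of the cell. Rows whose grid
#' row ignores the baseline (undetectable, marked, sinusoidal) render with
#' a normal-range baseline.
#'
#' @return Data.frame with columns `variability`, `baseline`, `column`,
#'   `sinusoidal`, `level`.
#' @export
grid_cells <- function() {
  g <- five_tier_grid()
  out <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    data.frame(variability = g$variability[i], baseline = g$baseline[i],
               column = DECEL_COLUMNS,
               sinusoidal = g$variability[i] == "sinusoidal",
               level = as.integer(g[i, DECEL_COLUMNS]))
  }))
  out$baseline[out$baseline == "any"] <- "b110_160"
  out$variability[out$variability == "sinusoidal"] <- "moderate"
  out
}

# index of the one non-Level-1 Category-I cell (moderate, 110-160, early)
cat1_early_cell <- function(cells) {
  which(cells$variability == "moderate" & cells$baseline == "b110_160" &
          cells$column == "early" & !cells$sinusoidal)
}

# 3-tier category each cell produces under the rendering policy
# (late/variable decelerations rendered on every contraction -> recurrent)
cell_category <- function(cells) {
  kind <- sub("_(mild|severe)$", "", cells$column)
  cat <- rep("II", nrow(cells))
  cat[cells$sinusoidal] <- "III"
  cat[!cells$sinusoidal & cells$variability == "undetectable" &
        kind %in% c("late", "variable")] <- "III"
  cat[!cells$sinusoidal & cells$variability == "moderate" &
        cells$baseline == "b110_160" & kind %in% c("none", "early")] <- "I"
  cat
}

# per-segment cell selection probabilities given the level
cell_probs <- function(cells, level, seg_index, cfg) {
  sel <- which(cells$level == level)
  p <- numeric(nrow(cells))
  if (level == 2) {
    p1 <- cfg$segment_marginals[1, seg_index]
    p2 <- cfg$segment_marginals[2, seg_index]
    w <- min(1, max(0, (cfg$cat1_targets[seg_index] - p1) / p2))
    ec <- cat1_early_cell(cells)
    others <- setdiff(sel, ec)
    p[ec] <- w
    p[others] <- (1 - w) / length(others)
  } else {
    p[sel] <- 1 / length(sel)
  }
  p
}

#' Derived 3-tier per-segment marginals
#'
#' The 3-tier Category I/II/III probabilities implied by the 5-tier
#' marginals, the cell-selection weights and the rendering policy.
#'
#' @param cfg A [synth_config()].
#' @return A 3 x 6 probability matrix (rows I, II, III).
#' @export
derive_3tier_marginals <- function(cfg = synth_config()) {
  cells <- grid_cells()
  cat <- cell_category(cells)
  out <- matrix(0, 3, 6, dimnames = list(c("I", "II", "III"),
                                         colnames(cfg$segment_marginals)))
  for (s in 1:6) {
    for (l in 1:5) {
      p <- cell_probs(cells, l, s, cfg) * cfg$segment_marginals[l, s]
      for (k in 1:3)
        out[k, s] <- out[k, s] + sum(p[cat == c("I", "II", "III")[k]])
    }
  }
  out
}

#' Sample per-subject level trajectories
#'
#' Gaussian-copula sampler: each subject has a latent severity `z ~ N(0,1)`;
#' the segment score is `sqrt(rho) z + sqrt(1 - rho) e_t` with independent
#' `e_t ~ N(0,1)`; the score is pushed through the segment's marginal
#' cut-points, so per-segment marginals are preserved exactly in
#' expectation while `rho` controls within-subject concordance.
#'
#' Uses the current RNG stream; call `set.seed()` first for reproducibility.
#'
#' @param cfg A [synth_config()].
#' @param n Number of subjects (default `cfg$n_subjects`).
#' @return Integer matrix `n x 6` of levels (columns 60...10 min).
#' @export
sample_trajectories <- function(cfg = synth_config(), n = cfg$n_subjects) {
  z <- stats::rnorm(n)
  e <- matrix(stats::rnorm(n * 6), n, 6)
  score <- sqrt(cfg$rho) * z + sqrt(1 - cfg$rho) * e
  traj <- matrix(0L, n, 6,
                 dimnames = list(NULL, colnames(cfg$segment_marginals)))
  for (s in 1:6) {
    cuts <- stats::qnorm(cumsum(cfg$segment_marginals[, s]))
    cuts[5] <- Inf
    traj[, s] <- 1L + as.integer(rowSums(outer(score[, s], cuts[-5], ">")))
  }
  traj
}

#' Sample grid cells for a trajectory matrix
#'
#' For each subject x segment, draws the grid cell realising the target
#' level with the per-segment cell weights of [cell_probs()].
#'
#' @param traj Level matrix from [sample_trajectories()].
#' @param cfg A [synth_config()].
#' @return Integer matrix of row indices into [grid_cells()].
#' @export
sample_cells <- function(traj, cfg = synth_config()) {
  cells <- grid_cells()
  n <- nrow(traj)
  out <- matrix(0L, n, 6)
  for (s in 1:6) {
    for (l in sort(unique(traj[, s]))) {
      idx <- which(traj[, s] == l)
      p <- cell_probs(cells, l, s, cfg)
      out[idx, s] <- sample.int(nrow(cells), length(idx), replace = TRUE,
                                prob = p)
    }
  }
  out
}

raised_cosine <- function(t, center, width) {
  u <- (t - center) / width + 0.5
  s <- numeric(length(t))
  in_bump <- u >= 0 & u <= 1
  s[in_bump] <- 0.5 * (1 - cos(2 * pi * u[in_bump]))
  s
}

# piecewise-linear trapezoid profile in [0,1]: drop, hold (with a slight
# upward tilt so the nadir sits at the hold start), rise
trapezoid <- function(t, onset, drop, hold, rise, tilt_frac = 0) {
  s <- numeric(length(t))
  t1 <- onset + drop; t2 <- t1 + hold; t3 <- t2 + rise
  i <- t >= onset & t < t1
  s[i] <- (t[i] - onset) / drop
  i <- t >= t1 & t < t2
  s[i] <- 1 - tilt_frac * (t[i] - t1) / hold
  i <- t >= t2 & t <= t3
  s[i] <- (1 - tilt_frac) * (t3 - t[i]) / rise
  s
}

render_uc <- function(t, cfg) {
  n_end <- max(t)
  peaks <- numeric(0)
  p <- stats::runif(1, 60, 120)
  while (p < n_end - 60) {
    peaks <- c(peaks, p)
    p <- p + stats::runif(1, cfg$contraction_interval_s[1],
                          cfg$contraction_interval_s[2])
  }
  uc <- rep(cfg$uc_tone, length(t))
  for (pk in peaks)
    uc <- uc + cfg$uc_amp * exp(-0.5 * ((t - pk) / cfg$uc_sd_s)^2)
  list(uc = uc, peaks = peaks)
}

baseline_for <- function(baseline_class, column) {
  switch(baseline_class,
         b110_160 = sample(seq(125, 150, by = 5), 1),
         gt160 = sample(c(170, 175, 180), 1),
         b80_110 = if (column == "prolonged_mild") 100
                   else sample(c(90, 95, 100), 1),
         lt80 = sample(c(65, 70), 1))
}

render_oscillation <- function(t, variability, ptp, cfg) {
  freqs <- if (variability == "marked") cfg$osc_freqs_marked_hz
           else cfg$osc_freqs_hz
  ph <- stats::runif(length(freqs), 0, 2 * pi)
  x <- rowSums(vapply(seq_along(freqs),
                      function(i) sin(2 * pi * freqs[i] * t + ph[i]),
                      numeric(length(t))))
  rng <- max(x) - min(x)
  if (rng > 0) x * ptp / rng else x
}

# deceleration profile (0..1 shape scaled to depth) for one grid column
render_decels <- function(t, column, baseline, peaks, cfg) {
  shape <- numeric(length(t))
  kind <- sub("_(mild|severe)$", "", column)
  if (kind == "none") return(shape)
  if (kind == "prolonged") {
    depth <- if (column == "prolonged_severe") baseline - min(70, baseline - 25)
             else baseline - max(82, baseline - 40)
    if (depth < 15) depth <- 20  # low baselines: severity collapses anyway
    center <- 300
    shape <- depth * raised_cosine(t, center, 200)
    return(shape)
  }
  usable <- peaks[peaks > 70 & peaks < max(t) - 90]
  for (pk in usable) {
    prof <- switch(
      kind,
      early = 30 * raised_cosine(t, pk, 100),
      late = {
        depth <- if (column == "late_severe") min(55, baseline - 35) else 35
        depth * raised_cosine(t, pk + 30, 100)
      },
      variable = {
        if (column == "variable_severe") {
          depth <- baseline - min(65, baseline - 25)
          depth * trapezoid(t, pk - 35, 10, 50, 10)
        } else {
          depth <- min(35, baseline - 35)
          depth * trapezoid(t, pk - 18, 8, 20, 8)
        }
      })
    shape <- pmax(shape, prof)
  }
  shape
}

#' Render one 10-minute segment embodying a grid cell
#'
#' Synthesises paired FHR/UC samples whose extracted features land in the
#' given cell: baseline plateau drawn within the cell's baseline class,
#' multi-sine oscillation scaled to the class's target peak-to-peak
#' amplitude (a pure 4 cycles/min sinusoid for sinusoidal cells),
#' deceleration episodes of the cell's column placed on the rendered
#' contractions (one mid-segment episode for prolonged columns), and
#' Gaussian contraction bumps on the UC channel. The oscillation is tapered
#' to zero inside deceleration episodes.
#'
#' @param cell One row of [grid_cells()].
#' @param rate Sampling rate (Hz).
#' @param cfg A [synth_config()].
#' @return List with numeric vectors `fhr` and `uc` (600 s worth of
#'   samples).
#' @export
render_segment <- function(cell, rate, cfg = synth_config()) {
  n <- round(600 * rate)
  t <- (seq_len(n) - 1) / rate
  baseline <- baseline_for(cell$baseline, cell$column)
  ucp <- render_uc(t, cfg)
  if (cell$sinusoidal) {
    osc <- cfg$sin_amp_bpm * sin(2 * pi * cfg$sin_freq_hz * t +
                                   stats::runif(1, 0, 2 * pi))
  } else {
    osc <- render_oscillation(t, cell$variability,
                              cfg$variability_ptp[[cell$variability]], cfg)
  }
  dec <- render_decels(t, cell$column, baseline, ucp$peaks, cfg)
  # oscillation fades quickly inside deceleration episodes so large
  # excursions never blur an episode's onset/nadir geometry
  taper <- if (max(dec) > 0) pmax(0, 1 - dec / max(1e-9, max(dec)))^3 else 1
  fhr <- baseline + osc * taper - dec
  list(fhr = fhr, uc = ucp$uc)
}

#' Render a full last-hour CTG trace for one subject
#'
#' Concatenates six rendered segments (60 to 10 minutes before delivery)
#' into one trace with delivery at 3600 s.
#'
#' @param cells_row Integer vector of 6 cell indices into [grid_cells()].
#' @param subject_id Subject identifier.
#' @param rate Sampling rate (Hz).
#' @param cfg A [synth_config()].
#' @return A [ctg_record()].
#' @export
render_trace <- function(cells_row, subject_id, rate = 4,
                         cfg = synth_config()) {
  cells <- grid_cells()
  parts <- lapply(cells_row, function(ci)
    render_segment(cells[ci, ], rate, cfg))
  ctg_record(subject_id = subject_id,
             fhr_bpm = unlist(lapply(parts, `[[`, "fhr")),
             uc = unlist(lapply(parts, `[[`, "uc")),
             delivery_offset_s = 3600, sample_rate_hz = rate)
}

#' Sample outcomes for a trajectory matrix
#'
#' Linear-additive outcome model: `ph = ph0 - sum_t w_t (level_t - 1) +
#' N(0, sigma_ph^2)` and likewise for base excess; values clipped to the
#' outcome sanity bounds. The model is synthetic — a directional stand-in,
#' not an estimate of any real cohort.
#'
#' @param traj Level matrix from [sample_trajectories()].
#' @param cfg A [synth_config()].
#' @param subject_ids Optional subject identifiers.
#' @return Data.frame with columns `subject_id`, `ph`, `be_mmol_l`.
#' @export
sample_outcomes <- function(traj, cfg = synth_config(),
                            subject_ids = sprintf("s%04d", seq_len(nrow(traj)))) {
  n <- nrow(traj)
  burden_ph <- as.vector((traj - 1) %*% cfg$ph_weights)
  burden_be <- as.vector((traj - 1) %*% cfg$be_weights)
  ph <- cfg$ph0 - burden_ph + stats::rnorm(n, 0, cfg$sigma_ph)
  be <- cfg$be0 - burden_be + stats::rnorm(n, 0, cfg$sigma_be)
  data.frame(subject_id = subject_ids,
             ph = pmin(pmax(ph, 6.5), 7.8),
             be_mmol_l = pmin(pmax(be, -35), 15))
}

#' Simulate and classify a synthetic cohort in memory
#'
#' End-to-end driver: samples level trajectories and outcomes, renders each
#' subject's trace, and runs the full clean/segment/extract/classify
#' pipeline on it, without writing traces to disk. The returned
#' classifications carry the generator's target level and category per
#' segment (`target_level`, `target_category`) so recovery can be measured.
#'
#' @param cfg A [ctg_config()].
#' @param seed Integer seed for the single RNG stream.
#' @param n Number of subjects (default `cfg$synth$n_subjects`).
#' @param render If `FALSE`, skip trace rendering and classify the target
#'   cells directly (fast path for outcome-only analyses).
#' @param progress Print progress every 200 subjects.
#' @return List with `classifications` (data.frame), `outcomes`,
#'   `trajectories`.
#' @export
simulate_cohort <- function(cfg = ctg_config(), seed = 1,
                            n = cfg$synth$n_subjects, render = TRUE,
                            progress = FALSE) {
  set.seed(seed)
  scfg <- cfg$synth
  traj <- sample_trajectories(scfg, n)
  cellm <- sample_cells(traj, scfg)
  outcomes <- sample_outcomes(traj, scfg)
  cells <- grid_cells()
  cat_map <- cell_category(cells)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sid <- outcomes$subject_id[i]
    tgt <- data.frame(subject_id = sid, segment = SEGMENT_LEVELS,
                      target_level = traj[i, ],
                      target_category = cat_map[cellm[i, ]])
    if (render) {
      rec <- render_trace(cellm[i, ], sid, cfg$sample_rate_hz, scfg)
      cl <- classify_record(rec, cfg)
      rows[[i]] <- merge(cl, tgt, by = c("subject_id", "segment"))
    } else {
      tgt$covered <- TRUE
      tgt$category <- tgt$target_category
      tgt$level <- tgt$target_level
      rows[[i]] <- tgt
    }
    if (progress && i %% 200 == 0) message("subject ", i, "/", n)
  }
  cl <- do.call(rbind, rows)
  cl$category_value <- category_value(cl$category)
  cl$level_value <- cl$level
  list(classifications = cl, outcomes = outcomes, trajectories = traj)
}

#' Generate a synthetic cohort on disk
#'
#' Writes one trace CSV per subject (`trace_<id>.csv`), the outcome table
#' (`outcomes.csv`) and a provenance JSON (`provenance.json`: configuration
#' echo, seed, package version). Deterministic under (config, seed).
#'
#' @param cfg A [ctg_config()].
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param n Number of subjects (default `cfg$synth$n_subjects`).
#' @return Invisible list with `trace_files`, `outcome_file`.
#' @export
generate_cohort <- function(cfg = ctg_config(), dir, seed = 1,
                            n = cfg$synth$n_subjects) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  scfg <- cfg$synth
  traj <- sample_trajectories(scfg, n)
  cellm <- sample_cells(traj, scfg)
  outcomes <- sample_outcomes(traj, scfg)
  files <- character(n)
  for (i in seq_len(n)) {
    rec <- render_trace(cellm[i, ], outcomes$subject_id[i],
                        cfg$sample_rate_hz, scfg)
    files[i] <- file.path(dir, sprintf("trace_%s.csv", rec$subject_id))
    write_ctg(rec, files[i])
  }
  out_file <- file.path(dir, "outcomes.csv")
  write_outcomes(outcomes, out_file)
  prov <- list(seed = seed, n_subjects = n,
               package_version = as.character(utils::packageVersion("ctgtier")),
               sample_rate_hz = cfg$sample_rate_hz,
               synth = lapply(unclass(scfg), function(x)
                 if (is.matrix(x)) as.data.frame(x) else x))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(trace_files = files, outcome_file = out_file))
}
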