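fcfg <- feature_config()

test_that("baseline estimation rounds to 5 bpm and trims excursions", {
  expect_equal(estimate_baseline(rep(142, 4 * 600), 4), 140)
  # 60 s deceleration to 100 bpm does not drag the baseline down
  seg <- make_segment(140, dips = data.frame(center = 300, width = 60,
                                             depth = 40))
  expect_equal(estimate_baseline(seg$fhr, 4), 140)
  # bimodal square wave converges to one plateau, not their average
  sq <- rep(c(120, 160), each = 4 * 300)
  expect_true(estimate_baseline(sq, 4) %in% c(120, 160))
  expect_error(estimate_baseline(rep(140, 100), 4), "insufficient data")
})

test_that("baseline classes use the documented boundary inclusivity", {
  expect_equal(classify_baseline(140), "b110_160")
  expect_equal(classify_baseline(110), "b110_160")
  expect_equal(classify_baseline(160), "b110_160")
  expect_equal(classify_baseline(161), "gt160")
  expect_equal(classify_baseline(80), "b80_110")
  expect_equal(classify_baseline(109), "b80_110")
  expect_equal(classify_baseline(79), "lt80")
})

test_that("variability classes partition the amplitude axis at printed bins", {
  expect_equal(classify_variability(0), "undetectable")
  expect_equal(classify_variability(2), "undetectable")
  expect_equal(classify_variability(3), "minimal")
  expect_equal(classify_variability(5), "minimal")
  expect_equal(classify_variability(6), "moderate")
  expect_equal(classify_variability(25), "moderate")
  expect_equal(classify_variability(26), "marked")
  # every amplitude gets exactly one class
  for (a in seq(0, 40, by = 0.5))
    expect_length(classify_variability(a), 1)
})

test_that("variability amplitude matches the closed form for a pure sine", {
  t <- (seq_len(4 * 600) - 1) / 4
  fhr <- 140 + 10 * sin(2 * pi * 0.05 * t)
  amp <- variability_amplitude(fhr, 4)
  expect_equal(amp, 20, tolerance = 1e-3)
  expect_equal(classify_variability(amp), "moderate")
  expect_equal(variability_amplitude(rep(140, 2400), 4), 0)
  # invariant to adding a constant
  expect_equal(variability_amplitude(fhr + 37, 4), amp, tolerance = 1e-9)
})

test_that("excluding a deceleration spans reproduces the dip-free amplitude", {
  seg <- make_segment(140, ptp = 12,
                      dips = data.frame(center = 300, width = 80, depth = 40))
  ref <- make_segment(140, ptp = 12)
  base <- estimate_baseline(seg$fhr, 4)
  peaks <- find_contractions(seg$uc, 4)
  dec <- detect_decelerations(seg$fhr, base, peaks, 4)
  expect_equal(nrow(dec), 1)
  spans <- data.frame(onset_s = dec$onset_s - 10, end_s = dec$end_s + 10)
  expect_equal(variability_amplitude(seg$fhr, 4, spans),
               variability_amplitude(ref$fhr, 4, spans), tolerance = 1e-9)
})

test_that("accelerations require 15 bpm for 15 s", {
  flat <- rep(140, 2400)
  expect_equal(nrow(detect_accelerations(flat, 140, 4)), 0)
  t <- (seq_len(2400) - 1) / 4
  bump20 <- flat + 20 * ifelse(t >= 200 & t <= 220, 1, 0)
  acc <- detect_accelerations(bump20, 140, 4)
  expect_equal(nrow(acc), 1)
  expect_true(acc$onset_s <= 200 && acc$end_s >= 219)
  bump10 <- flat + 10 * ifelse(t >= 200 & t <= 260, 1, 0)
  expect_equal(nrow(detect_accelerations(bump10, 140, 4)), 0)
})

test_that("contraction peaks are found with the min-separation rule", {
  expect_length(find_contractions(rep(10, 2400), 4), 0)
  seg <- make_segment(peak_times = c(120, 300, 480))
  pk <- find_contractions(seg$uc, 4)
  expect_length(pk, 3)
  expect_true(all(abs(pk - c(120, 300, 480)) <= 5))
  seg2 <- make_segment(peak_times = c(270, 330))
  expect_length(find_contractions(seg2$uc, 4), 1)
})

test_that("deceleration typing follows timing and severity rules", {
  expect_equal(nrow(detect_decelerations(rep(140, 2400), 140, c(150, 330), 4)),
               0)
  # gradual 30 bpm dip, nadir 20 s after the contraction peak -> late/mild
  seg <- make_segment(140, peak_times = c(150, 330, 510),
                      dips = data.frame(center = 330 + 20, width = 100,
                                        depth = 30))
  peaks <- find_contractions(seg$uc, 4)
  dec <- detect_decelerations(seg$fhr, 140, peaks, 4)
  expect_equal(nrow(dec), 1)
  expect_equal(dec$kind, "late")
  expect_equal(dec$severity, "mild")
  expect_gt(dec$nadir_s - peaks[2], 18)

  # abrupt dip to 65 bpm lasting ~70 s -> variable/severe
  n <- 2400; t <- (seq_len(n) - 1) / 4
  fhr <- rep(140, n)
  drop <- 75
  fhr[t >= 300 & t < 310] <- 140 - drop * (t[t >= 300 & t < 310] - 300) / 10
  fhr[t >= 310 & t < 360] <- 65
  fhr[t >= 360 & t < 370] <- 65 + drop * (t[t >= 360 & t < 370] - 360) / 10
  dec2 <- detect_decelerations(fhr, 140, peaks, 4)
  expect_equal(nrow(dec2), 1)
  expect_equal(dec2$kind, "variable")
  expect_equal(dec2$severity, "severe")

  # gradual dip centred on the peak -> early (always mild)
  seg3 <- make_segment(140, dips = data.frame(center = 330, width = 100,
                                              depth = 30))
  dec3 <- detect_decelerations(seg3$fhr, 140, peaks, 4)
  expect_equal(dec3$kind, "early")
  expect_equal(dec3$severity, "mild")
})

test_that("reported decelerations satisfy their defining predicates", {
  withr::local_seed(91)
  cells <- grid_cells()
  cfg <- feature_config()
  some <- cells[cells$column != "none", ][sample(1:77, 25), ]
  for (i in seq_len(nrow(some))) {
    seg <- render_segment(some[i, ], 4)
    base <- estimate_baseline(seg$fhr, 4)
    peaks <- find_contractions(seg$uc, 4)
    dec <- detect_decelerations(seg$fhr, base, peaks, 4)
    if (!nrow(dec)) next
    expect_true(all(dec$depth_bpm >= cfg$decel_min_bpm))
    expect_true(all(dec$duration_s >= cfg$decel_min_s &
                      dec$duration_s < cfg$episode_max_s))
    expect_true(all(dec$onset_s < dec$nadir_s & dec$nadir_s <= dec$end_s))
    expect_true(all(dec$kind[dec$duration_s >= cfg$prolonged_min_s] ==
                      "prolonged"))
    # spans disjoint
    if (nrow(dec) > 1) {
      o <- order(dec$onset_s)
      expect_true(all(dec$onset_s[o][-1] > dec$end_s[o][-nrow(dec)]))
    }
  }
})

test_that("sinusoidal detection requires the 3-5 cpm band and no accelerations", {
  t <- (seq_len(2400) - 1) / 4
  sin_fhr <- 140 + 8 * sin(2 * pi * (4 / 60) * t)
  expect_true(detect_sinusoidal(sin_fhr, 4))
  withr::local_seed(8)
  noise_fhr <- 140 + osc_wave(t, 16)  # band-spread oscillation
  expect_false(detect_sinusoidal(noise_fhr, 4))
  expect_false(detect_sinusoidal(sin_fhr, 4, accel_count = 1))
})

test_that("recurrence needs half the contractions and at least two", {
  # late dips after 2 of 3 contractions -> recurrent
  seg <- make_segment(140, ptp = 12, peak_times = c(150, 330, 510),
                      dips = data.frame(center = c(180, 360),
                                        width = 100, depth = 35))
  f <- extract_segment_features(seg$fhr, seg$uc, 4)
  expect_equal(f$n_contractions, 3)
  expect_equal(sum(f$decels$kind == "late"), 2)
  expect_true(f$recurrent_late)

  # 1 late dip over 4 contractions -> not recurrent
  seg2 <- make_segment(140, ptp = 12, peak_times = c(75, 225, 375, 525),
                       dips = data.frame(center = 255, width = 100,
                                         depth = 35))
  f2 <- extract_segment_features(seg2$fhr, seg2$uc, 4)
  expect_equal(f2$n_contractions, 4)
  expect_false(f2$recurrent_late)
})

test_that("a clean normal trace yields the normal feature tuple", {
  withr::local_seed(13)
  seg <- make_segment(140, ptp = 15)
  f <- extract_segment_features(seg$fhr, seg$uc, 4)
  expect_false(f$indeterminate)
  expect_equal(f$baseline_class, "b110_160")
  expect_equal(f$variability_class, "moderate")
  expect_equal(nrow(f$decels), 0)
  expect_false(f$sinusoidal)
})

test_that("segments without enough usable signal come back indeterminate", {
  fhr <- rep(NA_real_, 2400)
  fhr[1:400] <- 140
  f <- extract_segment_features(fhr, rep(10, 2400), 4)
  expect_true(f$indeterminate)
  expect_equal(f$reason, "baseline")
  expect_true(is.na(classify_5tier(f)))
  expect_true(is.na(classify_3tier(f)))
})

test_that("rendered tuples round-trip through feature extraction", {
  withr::local_seed(71)
  cells <- grid_cells()
  # severity cells whose defining predicate conflicts with the bradycardic
  # nadir floor cannot be embodied by any trace; they are excluded here
  # (their levels coincide with the extracted column's, see the docs)
  realizable <- !(cells$baseline == "lt80" &
                    cells$column %in% c("late_severe", "prolonged_mild"))
  pool <- which(realizable)
  draws <- sample(pool, 200, replace = TRUE)
  ok <- 0L
  for (i in draws) {
    seg <- render_segment(cells[i, ], 4)
    f <- extract_segment_features(seg$fhr, seg$uc, 4)
    got_col <- if (is.null(f$decels) || !nrow(f$decels)) "none" else {
      kinds <- unique(ifelse(f$decels$kind == "early", "early",
                             paste(f$decels$kind, f$decels$severity,
                                   sep = "_")))
      if (length(kinds) == 1) kinds else "mixed"
    }
    hit <- !f$indeterminate &&
      f$baseline_class == cells$baseline[i] &&
      f$sinusoidal == cells$sinusoidal[i] &&
      (cells$sinusoidal[i] ||
         f$variability_class == cells$variability[i]) &&
      got_col == cells$column[i]
    ok <- ok + hit
  }
  expect_gte(ok / length(draws), 0.95)
})
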