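PH_BIN_LEVELS <- c("lt7.0", "7.0_7.1", "7.1_7.2", "7.2_7.3", "7.3_7.4",
                   "ge7.4")
BE_BIN_LEVELS <- c("lt_m12", "ge_m12")
SEGMENT_LEVELS <- c(60L, 50L, 40L, 30L, 20L, 10L)

#' Bin umbilical artery pH
#'
#' Six half-open bins, lower-closed: pH < 7.0, \[7.0, 7.1), \[7.1, 7.2),
#' \[7.2, 7.3), \[7.3, 7.4), pH >= 7.4.
#'
#' @param ph Numeric pH values (vectorised).
#' @return Factor with levels `lt7.0`, `7.0_7.1`, ..., `ge7.4`.
#' @export
bin_ph <- function(ph) {
  cut(ph, breaks = c(-Inf, 7.0, 7.1, 7.2, 7.3, 7.4, Inf),
      labels = PH_BIN_LEVELS, right = FALSE)
}

#' Bin base excess
#'
#' Two bins: BE < -12 mmol/L and BE >= -12 mmol/L (acidotic cut-off; -12
#' itself belongs to the upper bin).
#'
#' @param be Numeric base-excess values (mmol/L, vectorised).
#' @return Factor with levels `lt_m12`, `ge_m12`.
#' @export
bin_be <- function(be) {
  cut(be, breaks = c(-Inf, -12, Inf), labels = BE_BIN_LEVELS, right = FALSE)
}

class_column <- function(classifications, tier) {
  stopifnot(tier %in% c(3, 5))
  if (tier == 3) {
    factor(classifications$category, levels = c("I", "II", "III"))
  } else {
    factor(classifications$level, levels = 1:5)
  }
}

value_column <- function(classifications, tier) {
  if (tier == 3) classifications$category_value else classifications$level_value
}

#' Per-segment classification frequency table
#'
#' Percentage of classified segments in each class, per 10-minute segment
#' column; the denominator of a column is the number of subjects whose
#' segment is covered and classifiable. Percentages are rounded to one
#' decimal, so each column sums to 100 +/- 0.1.
#'
#' @param classifications Output of [classify_cohort()].
#' @param tier 3 or 5.
#' @return Data.frame: first column `class`, then one column per segment
#'   (`seg60` ... `seg10`), plus attribute `n` (per-segment denominators).
#' @export
frequency_table <- function(classifications, tier) {
  cls <- class_column(classifications, tier)
  seg <- factor(classifications$segment, levels = SEGMENT_LEVELS)
  keep <- !is.na(cls)
  tab <- table(cls[keep], seg[keep])
  n <- colSums(tab)
  pct <- sweep(tab, 2, pmax(n, 1), "/") * 100
  out <- data.frame(class = rownames(pct), round(as.data.frame.matrix(pct), 1),
                    row.names = NULL, check.names = FALSE)
  names(out)[-1] <- paste0("seg", colnames(pct))
  attr(out, "n") <- n
  out
}

#' Outcome summaries by classification group
#'
#' Mean and standard deviation of umbilical artery pH and base excess per
#' segment x class group (the data behind "outcome vs class" panels).
#'
#' @param classifications Output of [classify_cohort()].
#' @param outcomes Data.frame from [read_outcomes()] (or
#'   [sample_outcomes()]).
#' @param tier 3 or 5.
#' @return Data.frame with columns `segment`, `class`, `n`, `mean_ph`,
#'   `sd_ph`, `mean_be`, `sd_be`.
#' @export
outcome_by_class <- function(classifications, outcomes, tier) {
  df <- merge(classifications, outcomes, by = "subject_id")
  df$class <- class_column(df, tier)
  df <- df[!is.na(df$class), ]
  agg <- function(v, f) as.vector(tapply(v, list(df$segment, df$class), f))
  grid <- expand.grid(segment = sort(unique(df$segment)),
                      class = levels(df$class))
  out <- data.frame(segment = grid$segment, class = grid$class,
                    n = agg(df$ph, length),
                    mean_ph = agg(df$ph, mean),
                    sd_ph = agg(df$ph, stats::sd),
                    mean_be = agg(df$be_mmol_l, mean),
                    sd_be = agg(df$be_mmol_l, stats::sd))
  out$n[is.na(out$n)] <- 0L
  out[order(-out$segment, out$class), , drop = FALSE]
}

#' Mean classification value by outcome group
#'
#' Mean and standard deviation of the numeric classification value
#' (Category I/II/III as 1/2/3, or the level itself) per segment x outcome
#' bin, with outcomes grouped by pH bin or BE bin.
#'
#' @param classifications Output of [classify_cohort()].
#' @param outcomes Outcome data.frame.
#' @param tier 3 or 5.
#' @param grouping `"by_ph_bin"` or `"by_be_bin"`.
#' @return Data.frame with columns `segment`, `group`, `n`, `mean_value`,
#'   `sd_value`.
#' @export
class_value_by_outcome_group <- function(classifications, outcomes, tier,
                                         grouping = c("by_ph_bin", "by_be_bin")) {
  grouping <- match.arg(grouping)
  df <- merge(classifications, outcomes, by = "subject_id")
  df$value <- value_column(df, tier)
  df <- df[!is.na(df$value), ]
  df$group <- if (grouping == "by_ph_bin") bin_ph(df$ph) else bin_be(df$be_mmol_l)
  grid <- expand.grid(segment = sort(unique(df$segment)),
                      group = levels(df$group))
  agg <- function(f) as.vector(tapply(df$value, list(df$segment, df$group), f))
  out <- data.frame(segment = grid$segment, group = grid$group,
                    n = agg(length), mean_value = agg(mean),
                    sd_value = agg(stats::sd))
  out$n[is.na(out$n)] <- 0L
  out[order(-out$segment, out$group), , drop = FALSE]
}

#' Run the nonparametric test battery
#'
#' Reproduces the cohort analyses:
#' \itemize{
#'   \item Friedman test of the classification value across the six
#'     repeated segments (subjects with all six classified);
#'   \item Kruskal-Wallis test of classification values across pH bins
#'     within each segment, followed by Tukey HSD pairwise contrasts;
#'   \item Wilcoxon comparison of classification values between the two BE
#'     bins within each segment (rank-sum by default; the groups are
#'     independent, so a signed-rank test is not well defined there — see
#'     [stats_config()]);
#'   \item Wilcoxon signed-rank tests of paired adjacent-segment contrasts
#'     (60 vs 50 min, ..., 20 vs 10 min).
#' }
#' All tests are run for both tiers at `cfg$alpha`.
#'
#' @param classifications Output of [classify_cohort()].
#' @param outcomes Outcome data.frame.
#' @param cfg A [stats_config()].
#' @return Data.frame with columns `test`, `tier`, `segment`, `groups`,
#'   `statistic`, `p_value`, `method`, `alpha`. Tukey rows carry the
#'   pairwise contrast in `groups` and the adjusted p-value.
#' @export
run_tests <- function(classifications, outcomes, cfg = stats_config()) {
  rows <- list()
  add <- function(test, tier, segment, groups, res) {
    rows[[length(rows) + 1L]] <<- data.frame(
      test = test, tier = tier, segment = segment, groups = groups,
      statistic = res$statistic, p_value = res$p_value,
      method = res$method, alpha = cfg$alpha)
  }
  df <- merge(classifications, outcomes, by = "subject_id")
  df$ph_bin <- bin_ph(df$ph)
  df$be_bin <- bin_be(df$be_mmol_l)
  for (tier in c(3, 5)) {
    df$value <- value_column(df, tier)
    # Friedman across segments
    wide <- stats::reshape(
      df[, c("subject_id", "segment", "value")], direction = "wide",
      idvar = "subject_id", timevar = "segment")
    y <- as.matrix(wide[, paste0("value.", SEGMENT_LEVELS)])
    add("friedman", tier, NA_integer_, "segments", friedman_test_seg(y, cfg))
    for (s in SEGMENT_LEVELS) {
      d <- df[df$segment == s & !is.na(df$value), ]
      if (!nrow(d)) next
      # Kruskal-Wallis across pH bins + Tukey HSD pairwise
      res <- withCallingHandlers(
        kw_test(d$value, d$ph_bin, cfg),
        warning = function(w) invokeRestart("muffleWarning"))
      add("kruskal_wallis", tier, s, "ph_bins", res)
      tk <- tukey_hsd(d$value, d$ph_bin)
      if (!is.null(tk)) for (j in seq_len(nrow(tk)))
        add("tukey_hsd", tier, s, tk$contrast[j],
            list(statistic = tk$diff[j], p_value = tk$p_value[j],
                 method = "studentized_range"))
      # BE-bin comparison
      x <- d$value[d$be_bin == "lt_m12"]
      yv <- d$value[d$be_bin == "ge_m12"]
      if (cfg$be_test == "signed_rank" && length(x) == length(yv)) {
        add("wilcoxon_signed_rank", tier, s, "be_bins",
            signed_rank_test(x, yv, cfg = cfg))
      } else {
        add("wilcoxon_rank_sum", tier, s, "be_bins",
            rank_sum_test(x, yv, cfg = cfg))
      }
    }
    # paired adjacent-segment contrasts
    for (j in seq_len(length(SEGMENT_LEVELS) - 1L)) {
      s1 <- SEGMENT_LEVELS[j]; s2 <- SEGMENT_LEVELS[j + 1L]
      a <- y[, paste0("value.", s1)]; b <- y[, paste0("value.", s2)]
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < 2) next
      add("wilcoxon_signed_rank", tier, s2,
          sprintf("seg%d_vs_seg%d", s1, s2),
          signed_rank_test(a[ok], b[ok], cfg = cfg))
    }
  }
  do.call(rbind, rows)
}

#' Write the cohort analysis output set
#'
#' Writes the tidy CSVs of a full analysis: `frequency_3.csv`,
#' `frequency_5.csv`, `outcome_by_class_3.csv`, `outcome_by_class_5.csv`,
#' `class_value_by_group_3.csv`, `class_value_by_group_5.csv`, `tests.csv`.
#'
#' @param classifications Output of [classify_cohort()].
#' @param outcomes Outcome data.frame.
#' @param dir Output directory (created if needed).
#' @param cfg A [stats_config()].
#' @return Invisible character vector of the files written.
#' @export
write_analysis <- function(classifications, outcomes, dir,
                           cfg = stats_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(x, name) {
    p <- file.path(dir, name)
    utils::write.csv(x, p, row.names = FALSE)
    files <<- c(files, p)
  }
  for (tier in c(3, 5)) {
    emit(frequency_table(classifications, tier),
         sprintf("frequency_%d.csv", tier))
    emit(outcome_by_class(classifications, outcomes, tier),
         sprintf("outcome_by_class_%d.csv", tier))
    g <- rbind(
      cbind(grouping = "by_ph_bin",
            class_value_by_outcome_group(classifications, outcomes, tier,
                                         "by_ph_bin")),
      cbind(grouping = "by_be_bin",
            class_value_by_outcome_group(classifications, outcomes, tier,
                                         "by_be_bin")))
    emit(g, sprintf("class_value_by_group_%d.csv", tier))
  }
  emit(run_tests(classifications, outcomes, cfg), "tests.csv")
  invisible(files)
}

#' Plot mean outcome by classification group
#'
#' Base-graphics companion to [outcome_by_class()]: mean with standard
#' deviation bars per class, one panel per segment.
#'
#' @param summaries Output of [outcome_by_class()].
#' @param outcome `"ph"` or `"be"`.
#' @export
plot_outcome_by_class <- function(summaries, outcome = c("ph", "be")) {
  outcome <- match.arg(outcome)
  m <- if (outcome == "ph") summaries$mean_ph else summaries$mean_be
  s <- if (outcome == "ph") summaries$sd_ph else summaries$sd_be
  segs <- sort(unique(summaries$segment), decreasing = TRUE)
  old <- graphics::par(mfrow = c(2, 3), mar = c(3, 3, 2, 1))
  on.exit(graphics::par(old))
  for (sg in segs) {
    sel <- summaries$segment == sg & summaries$n > 0
    x <- seq_len(sum(sel))
    ylim <- range(c(m[sel] - s[sel], m[sel] + s[sel]), na.rm = TRUE)
    graphics::plot(x, m[sel], ylim = ylim, pch = 19, xaxt = "n",
                   xlab = "", ylab = toupper(outcome),
                   main = sprintf("%d min before delivery", sg))
    graphics::axis(1, at = x, labels = summaries$class[sel])
    graphics::arrows(x, m[sel] - s[sel], x, m[sel] + s[sel],
                     angle = 90, code = 3, length = 0.04)
  }
  invisible(NULL)
}
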