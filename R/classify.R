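DECEL_COLUMNS <- c("none", "early", "variable_mild", "variable_severe",
                   "late_mild", "late_severe", "prolonged_mild",
                   "prolonged_severe")

.grid_cache <- new.env(parent = emptyenv())

#' The 5-tier classification grid
#'
#' The 5-tier framework assigns Level 1 (normal) to Level 5 (most severe)
#' from a grid indexed by variability class (moderate and minimal rows
#' sub-indexed by baseline class; undetectable, marked and sinusoidal rows
#' ignore the baseline) crossed with eight deceleration columns (none,
#' early, then variable/late/prolonged each split mild/severe). The printed
#' grid leaves some cells blank; the resolved grid fills each blank with the
#' nearest printed cell to its left in the same row, else the nearest to the
#' right — a local rule that keeps rows monotone where they were printed
#' monotone. Both versions ship as CSV resources so the rule table can be
#' audited without reading code.
#'
#' @param resolved If `TRUE` (default) return the blank-resolved grid; if
#'   `FALSE`, the printed grid with `NA` in blank cells.
#' @return Data.frame with columns `variability`, `baseline` and the eight
#'   deceleration columns.
#' @export
five_tier_grid <- function(resolved = TRUE) {
  key <- if (resolved) "resolved" else "printed"
  if (is.null(.grid_cache[[key]])) {
    f <- system.file("extdata",
                     if (resolved) "five_tier_grid_resolved.csv"
                     else "five_tier_grid.csv",
                     package = "ctgtier", mustWork = TRUE)
    .grid_cache[[key]] <- utils::read.csv(f, stringsAsFactors = FALSE)
  }
  .grid_cache[[key]]
}

#' Resolve blank grid cells
#'
#' Applies the blank-resolution rule (copy the nearest printed cell to the
#' left in the same row, else the nearest printed cell to the right) to a
#' grid in the layout of [five_tier_grid()].
#'
#' @param grid Data.frame in the printed-grid layout (`NA` = blank).
#' @return The same data.frame with every cell filled.
#' @export
resolve_grid <- function(grid) {
  for (i in seq_len(nrow(grid))) {
    vals <- as.numeric(grid[i, DECEL_COLUMNS])
    printed <- which(!is.na(vals))
    if (!length(printed)) stop("row ", i, " has no printed cells")
    for (j in which(is.na(vals))) {
      left <- printed[printed < j]
      vals[j] <- if (length(left)) vals[max(left)]
                 else vals[min(printed[printed > j])]
    }
    grid[i, DECEL_COLUMNS] <- as.list(as.integer(vals))
  }
  grid
}

grid_row <- function(f, grid = five_tier_grid()) {
  if (isTRUE(f$sinusoidal)) {
    sel <- grid$variability == "sinusoidal"
  } else if (f$variability_class %in% c("undetectable", "marked")) {
    sel <- grid$variability == f$variability_class
  } else {
    sel <- grid$variability == f$variability_class &
      grid$baseline == f$baseline_class
  }
  as.numeric(grid[sel, DECEL_COLUMNS])
}

decel_column <- function(kind, severity) {
  ifelse(kind == "early", "early", paste(kind, severity, sep = "_"))
}

# Worst deceleration column for an active grid row: the column whose cell
# value is highest among the decelerations present; ties break toward the
# rightmost column. Rows are not monotone left-to-right, so "worst" is
# defined by cell value, not column position.
worst_decel_column <- function(decels, row_vals) {
  if (is.null(decels) || !nrow(decels)) return(1L)
  cols <- match(decel_column(decels$kind, decels$severity), DECEL_COLUMNS)
  vals <- row_vals[cols]
  cand <- cols[vals == max(vals)]
  max(cand)
}

#' 5-tier (Level 1-5) classification of a segment
#'
#' Looks up the feature tuple in the resolved 5-tier grid: the sinusoidal
#' row if the sinusoidal flag is set, else the variability-class row
#' (sub-indexed by baseline class for moderate/minimal); the column is the
#' worst deceleration present (highest cell value in the active row,
#' rightmost on ties), or "none".
#'
#' @param f A `segment_features` object.
#' @return Integer level 1-5, or `NA` for an indeterminate tuple.
#' @export
classify_5tier <- function(f) {
  stopifnot(inherits(f, "segment_features"))
  if (isTRUE(f$indeterminate)) return(NA_integer_)
  row_vals <- grid_row(f)
  as.integer(row_vals[worst_decel_column(f$decels, row_vals)])
}

#' 3-tier (Category I/II/III) classification of a segment
#'
#' Category I: baseline 110-160 bpm, moderate variability, no late,
#' variable or prolonged decelerations, not sinusoidal (early decelerations
#' and accelerations do not block Category I; a prolonged deceleration does,
#' an explicit extension of the printed rule, which enumerates only late and
#' variable). Category III: sinusoidal pattern, or absent (undetectable)
#' variability with recurrent late decelerations, recurrent variable
#' decelerations or bradycardia (baseline below 80 bpm). Category II: all
#' other tracings.
#'
#' @param f A `segment_features` object.
#' @return `"I"`, `"II"` or `"III"`, or `NA` for an indeterminate tuple.
#' @export
classify_3tier <- function(f) {
  stopifnot(inherits(f, "segment_features"))
  if (isTRUE(f$indeterminate)) return(NA_character_)
  kinds <- if (is.null(f$decels)) character(0) else f$decels$kind
  if (isTRUE(f$sinusoidal)) return("III")
  if (f$variability_class == "undetectable" &&
      (isTRUE(f$recurrent_late) || isTRUE(f$recurrent_variable) ||
       f$baseline_class == "lt80"))
    return("III")
  if (f$baseline_class == "b110_160" && f$variability_class == "moderate" &&
      !any(kinds %in% c("late", "variable", "prolonged")))
    return("I")
  "II"
}

#' Numeric value of a 3-tier category
#' @param category `"I"`, `"II"` or `"III"` (vectorised; `NA` passed through).
#' @return Integer 1, 2 or 3.
#' @export
category_value <- function(category) {
  match(category, c("I", "II", "III"))
}

#' Segment the last hour before delivery
#'
#' Returns the six 10-minute windows `(d - 600 k, d - 600 (k - 1)]`,
#' `k = 6..1`, in trace seconds, where `d` is the delivery offset. Windows
#' whose overlap with the recorded trace covers less than 80% of their
#' samples are marked uncovered and excluded from analysis.
#'
#' @param record A [ctg_record()].
#' @return Data.frame with columns `segment` (minutes before delivery: 60,
#'   50, 40, 30, 20, 10), `start_s`, `end_s`, `covered`.
#' @export
segment_last_hour <- function(record) {
  stopifnot(inherits(record, "ctg_record"))
  d <- record$delivery_offset_s
  n <- length(record$fhr_bpm)
  rate <- record$sample_rate_hz
  trace_end <- (n - 1) / rate
  seg <- data.frame(segment = c(60L, 50L, 40L, 30L, 20L, 10L))
  seg$start_s <- d - seg$segment * 60
  seg$end_s <- seg$start_s + 600
  expected <- 600 * rate
  covered_n <- vapply(seq_len(6), function(k) {
    lo <- max(seg$start_s[k], -1 / rate / 2)  # first sample time is 0
    hi <- min(seg$end_s[k], trace_end)
    if (hi <= lo) 0 else floor(hi * rate + 1e-9) - ceiling((lo + 1e-9) * rate) + 1
  }, 0)
  seg$covered <- covered_n >= 0.8 * expected
  seg
}

segment_indices <- function(record, start_s, end_s) {
  t <- ctg_times(record)
  which(t > start_s + 1e-9 & t <= end_s + 1e-9)
}

#' Classify one subject's last hour
#'
#' Cleans the trace, segments the last hour, extracts features and applies
#' both classifiers to every covered segment.
#'
#' @param record A [ctg_record()].
#' @param cfg A [ctg_config()].
#' @return Data.frame with one row per segment: `subject_id`, `segment`,
#'   `covered`, `baseline_class`, `variability_class`, `category`, `level`,
#'   `category_value`, `level_value` (`NA` where uncovered or
#'   indeterminate).
#' @export
classify_record <- function(record, cfg = ctg_config()) {
  clean <- clean_fhr(record, cfg$preprocess)
  seg <- segment_last_hour(clean)
  rate <- clean$sample_rate_hz
  rows <- lapply(seq_len(nrow(seg)), function(k) {
    out <- data.frame(subject_id = record$subject_id,
                      segment = seg$segment[k], covered = seg$covered[k],
                      baseline_class = NA_character_,
                      variability_class = NA_character_,
                      category = NA_character_, level = NA_integer_)
    if (!seg$covered[k]) return(out)
    idx <- segment_indices(clean, seg$start_s[k], seg$end_s[k])
    f <- extract_segment_features(clean$fhr_bpm[idx], clean$uc[idx], rate,
                                  cfg$features)
    if (!f$indeterminate) {
      out$baseline_class <- f$baseline_class
      out$variability_class <- f$variability_class
    }
    out$category <- classify_3tier(f)
    out$level <- classify_5tier(f)
    out
  })
  res <- do.call(rbind, rows)
  res$category_value <- category_value(res$category)
  res$level_value <- res$level
  res
}

#' Classify a cohort of CTG records
#'
#' @param records A list of [ctg_record()]s.
#' @param cfg A [ctg_config()].
#' @param progress Print a progress note every 200 subjects.
#' @return Row-bound result of [classify_record()] over the cohort: six rows
#'   per subject.
#' @export
classify_cohort <- function(records, cfg = ctg_config(), progress = FALSE) {
  out <- vector("list", length(records))
  for (i in seq_along(records)) {
    out[[i]] <- classify_record(records[[i]], cfg)
    if (progress && i %% 200 == 0)
      message("classified ", i, "/", length(records), " subjects")
  }
  do.call(rbind, out)
}
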