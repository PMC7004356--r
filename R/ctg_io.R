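#' Construct a CTG record
#'
#' A CTG record holds one subject's paired fetal-heart-rate (FHR) and
#' uterine-contraction (UC) channels on a uniform time grid, together with
#' the time of delivery relative to trace start. Sample `i` is at time
#' `(i - 1) / sample_rate_hz` seconds.
#'
#' @param subject_id Subject identifier (single string).
#' @param fhr_bpm Numeric vector of FHR samples in beats per minute; `NA` for
#'   missing (signal loss).
#' @param uc Numeric vector of uterine-contraction samples (arbitrary
#'   units, >= 0); same length as `fhr_bpm`.
#' @param delivery_offset_s Time of delivery in seconds from trace start;
#'   must not exceed the trace duration.
#' @param sample_rate_hz Sampling rate in Hz (>= 1). Default 4, the usual
#'   CTG monitor output rate.
#' @return An object of class `ctg_record`. The logical attribute
#'   `full_coverage` records whether the trace covers the full 3600 s before
#'   delivery; shorter records are analysed for the segments they cover.
#' @export
ctg_record <- function(subject_id, fhr_bpm, uc, delivery_offset_s,
                       sample_rate_hz = 4) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  fhr_bpm <- as.numeric(fhr_bpm)
  uc <- as.numeric(uc)
  if (length(fhr_bpm) != length(uc))
    stop("fhr_bpm and uc must have equal length")
  if (!is.numeric(sample_rate_hz) || sample_rate_hz < 1)
    stop("sample_rate_hz must be >= 1")
  bad <- which(!is.na(fhr_bpm) & (fhr_bpm < 0 | fhr_bpm > 300))
  if (length(bad))
    stop("FHR values outside [0, 300] bpm at sample(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (any(!is.na(uc) & uc < 0)) stop("UC values must be >= 0")
  duration <- length(fhr_bpm) / sample_rate_hz
  if (delivery_offset_s > duration + 1e-9)
    stop("delivery_offset_s (", delivery_offset_s,
         ") exceeds trace duration (", duration, " s)")
  rec <- structure(list(subject_id = subject_id,
                        sample_rate_hz = sample_rate_hz,
                        fhr_bpm = fhr_bpm, uc = uc,
                        delivery_offset_s = delivery_offset_s),
                   class = "ctg_record")
  attr(rec, "full_coverage") <- delivery_offset_s >= 3600
  rec
}

#' @export
print.ctg_record <- function(x, ...) {
  n <- length(x$fhr_bpm)
  cat(sprintf("<ctg_record> subject %s: %d samples @ %g Hz (%.1f min), %.1f%% FHR missing, delivery at %.0f s\n",
              x$subject_id, n, x$sample_rate_hz, n / x$sample_rate_hz / 60,
              100 * mean(is.na(x$fhr_bpm)), x$delivery_offset_s))
  invisible(x)
}

#' Sample times of a CTG record
#' @param record A `ctg_record`.
#' @return Numeric vector of sample times in seconds from trace start.
#' @export
ctg_times <- function(record) {
  (seq_along(record$fhr_bpm) - 1) / record$sample_rate_hz
}

fmt_num <- function(x) {
  out <- sprintf("%.6g", x)
  out[is.na(x)] <- ""
  out
}

#' Read a CTG trace file
#'
#' The trace dialect is a plain CSV with header `time_s,fhr_bpm,uc`, a
#' uniform time grid starting at 0, empty cells for missing FHR samples, and
#' metadata carried in leading comment lines of the form
#' `# key=value` (`delivery_offset_s`, required; `subject_id`, optional —
#' the file name stem is used when absent).
#'
#' @param path Path to the trace file.
#' @return A [ctg_record()]. The sampling rate is inferred from the median
#'   time step.
#' @export
read_ctg <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  meta <- character(0)
  i <- 1L
  while (i <= length(lines) && startsWith(lines[i], "#")) {
    meta <- c(meta, lines[i]); i <- i + 1L
  }
  if (i > length(lines) || trimws(lines[i]) != "time_s,fhr_bpm,uc")
    stop("malformed header at line ", i, " of ", path,
         ": expected 'time_s,fhr_bpm,uc'")
  kv <- list()
  for (m in meta) {
    m2 <- sub("^#\\s*", "", m)
    if (grepl("=", m2, fixed = TRUE)) {
      k <- trimws(sub("=.*$", "", m2)); v <- trimws(sub("^[^=]*=", "", m2))
      kv[[k]] <- v
    }
  }
  if (is.null(kv$delivery_offset_s))
    stop("missing '# delivery_offset_s=<x>' metadata line in ", path)
  body <- lines[seq.int(i + 1L, length.out = length(lines) - i)]
  body <- body[nzchar(body)]
  if (!length(body)) stop("no data rows in ", path)
  parts <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L | nf > 3L))
    stop("malformed row at line ", i + which(nf < 2L | nf > 3L)[1], " of ", path)
  # pad rows whose trailing uc cell is empty ("0,140," splits to 2 fields)
  get_cell <- function(p, j) if (length(p) >= j) p[j] else ""
  as_num <- function(col, what) {
    raw <- trimws(vapply(parts, get_cell, "", j = col))
    out <- suppressWarnings(as.numeric(raw))
    bad <- which(nzchar(raw) & is.na(out))
    if (length(bad))
      stop("non-numeric ", what, " at line ", i + bad[1], " of ", path,
           ": '", raw[bad[1]], "'")
    out
  }
  time_s <- as_num(1, "time_s")
  fhr <- as_num(2, "fhr_bpm")
  uc <- as_num(3, "uc")
  if (anyNA(time_s)) stop("empty time_s cell at line ",
                          i + which(is.na(time_s))[1], " of ", path)
  steps <- diff(time_s)
  if (any(steps <= 0))
    stop("time_s not strictly increasing at line ",
         i + which(steps <= 0)[1] + 1L, " of ", path)
  if (length(steps)) {
    med <- stats::median(steps)
    if (any(abs(steps - med) > 0.01 * med))
      stop("non-uniform time grid in ", path, " (step jitter > 1% at line ",
           i + which(abs(steps - med) > 0.01 * med)[1] + 1L, ")")
    rate <- 1 / med
  } else {
    rate <- as.numeric(kv$sample_rate_hz %||% 4)
  }
  subject <- kv$subject_id %||% sub("\\.[^.]*$", "", basename(path))
  ctg_record(subject_id = subject, fhr_bpm = fhr, uc = uc,
             delivery_offset_s = as.numeric(kv$delivery_offset_s),
             sample_rate_hz = rate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a CTG trace file
#'
#' Inverse of [read_ctg()]: UTF-8, LF line endings, `%.6g` floats, missing
#' FHR as empty cells.
#'
#' @param record A `ctg_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ctg <- function(record, path) {
  stopifnot(inherits(record, "ctg_record"))
  t <- ctg_times(record)
  lines <- c(sprintf("# subject_id=%s", record$subject_id),
             sprintf("# delivery_offset_s=%s", fmt_num(record$delivery_offset_s)),
             "time_s,fhr_bpm,uc",
             paste(fmt_num(t), fmt_num(record$fhr_bpm), fmt_num(record$uc),
                   sep = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a cohort outcome table
#'
#' Expects a CSV with header `subject_id,ph,be_mmol_l`: one row per subject
#' with umbilical artery pH (unitless) and base excess (mmol/L) at delivery.
#' Values outside sanity bounds (pH in \[6.5, 7.8\], BE in \[-35, 15\]) and
#' duplicated subjects are rejected.
#'
#' @param path Path to the outcome CSV.
#' @return A data.frame with columns `subject_id`, `ph`, `be_mmol_l`.
#' @export
read_outcomes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = c("character", "numeric", "numeric"))
  if (!identical(names(df), c("subject_id", "ph", "be_mmol_l")))
    stop("malformed header in ", path,
         ": expected 'subject_id,ph,be_mmol_l'")
  dup <- unique(df$subject_id[duplicated(df$subject_id)])
  if (length(dup))
    stop("duplicated subject_id in ", path, ": ",
         paste(utils::head(dup, 5), collapse = ", "))
  bad <- df$subject_id[is.na(df$ph) | df$ph < 6.5 | df$ph > 7.8 |
                         is.na(df$be_mmol_l) | df$be_mmol_l < -35 |
                         df$be_mmol_l > 15]
  if (length(bad))
    stop("out-of-bounds pH/BE for subject(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  df
}

#' Write a cohort outcome table
#'
#' @param outcomes Data.frame with columns `subject_id`, `ph`, `be_mmol_l`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_outcomes <- function(outcomes, path) {
  stopifnot(all(c("subject_id", "ph", "be_mmol_l") %in% names(outcomes)))
  lines <- c("subject_id,ph,be_mmol_l",
             paste(outcomes$subject_id, fmt_num(outcomes$ph),
                   fmt_num(outcomes$be_mmol_l), sep = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
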