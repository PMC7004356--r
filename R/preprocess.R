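#' Clean an FHR trace
#'
#' Artifact rejection and gap handling applied before feature extraction:
#' \enumerate{
#'   \item samples outside `[low_bpm, high_bpm]` are marked missing;
#'   \item where two consecutive samples are both present, a jump larger
#'     than `max_jump_bpm` marks the later sample missing (transducer
#'     slippage / maternal-signal pickup produces such steps, the fetal
#'     heart does not);
#'   \item missing runs strictly shorter than `max_interp_s` with valid
#'     samples on both sides are linearly interpolated; longer runs (and
#'     runs touching the trace ends) remain missing.
#' }
#' The operation is idempotent and never alters in-range samples that pass
#' the jump rule. The UC channel is passed through untouched.
#'
#' @param record A [ctg_record()].
#' @param cfg A [preprocess_config()].
#' @return A new `ctg_record` with attribute `fraction_missing` (fraction of
#'   FHR samples still missing after cleaning). The input is not modified.
#' @export
clean_fhr <- function(record, cfg = preprocess_config()) {
  stopifnot(inherits(record, "ctg_record"))
  x <- record$fhr_bpm
  rate <- record$sample_rate_hz
  # range rule
  x[!is.na(x) & (x < cfg$low_bpm | x > cfg$high_bpm)] <- NA_real_
  # jump rule: adjacent pairs both present
  if (length(x) > 1L) {
    d <- abs(diff(x))
    jump <- which(!is.na(d) & d > cfg$max_jump_bpm) + 1L
    x[jump] <- NA_real_
  }
  # interpolate short interior gaps
  x <- interp_short_gaps(x, rate, cfg$max_interp_s)
  out <- record
  out$fhr_bpm <- x
  attr(out, "full_coverage") <- attr(record, "full_coverage")
  attr(out, "fraction_missing") <- mean(is.na(x))
  out
}

# Linear interpolation of NA runs shorter than max_s seconds, interior only.
interp_short_gaps <- function(x, rate, max_s) {
  if (!anyNA(x) || max_s <= 0) return(x)
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  max_len <- max_s * rate
  for (j in which(r$values)) {
    len <- r$lengths[j]
    s <- starts[j]; e <- ends[j]
    if (len < max_len && s > 1L && e < length(x)) {
      x[s:e] <- x[s - 1L] + (x[e + 1L] - x[s - 1L]) * seq_len(len) / (len + 1L)
    }
  }
  x
}
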