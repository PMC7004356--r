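#' ctgtier: rule-based intrapartum FHR classification and cohort analysis
#'
#' Automated cardiotocography analysis of the last hour of labor: feature
#' extraction (baseline, variability, accelerations, decelerations,
#' sinusoidal pattern), 3-tier and 5-tier rule-table classification of each
#' 10-minute segment, association analysis against umbilical artery pH and
#' base excess, and a synthetic cohort generator.
#'
#' @keywords internal
"_PACKAGE"

#' Run the full pipeline on a synthetic cohort
#'
#' Simulates a cohort, classifies every rendered trace, runs the cohort
#' analyses and writes the output set (per-segment classifications,
#' frequency tables, outcome summaries, test battery, provenance) to
#' `out_dir`.
#'
#' @param cfg A [ctg_config()].
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param n Number of subjects (default `cfg$synth$n_subjects`).
#' @param progress Print progress.
#' @return Invisible list with `classifications`, `outcomes` and the files
#'   written.
#' @export
run_pipeline <- function(cfg = ctg_config(), out_dir, seed = 1,
                         n = cfg$synth$n_subjects, progress = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(cfg, seed = seed, n = n, progress = progress)
  cls_file <- file.path(out_dir, "classifications.csv")
  utils::write.csv(sim$classifications, cls_file, row.names = FALSE)
  write_outcomes(sim$outcomes, file.path(out_dir, "outcomes.csv"))
  files <- write_analysis(sim$classifications, sim$outcomes, out_dir,
                          cfg$stats)
  jsonlite::write_json(
    list(seed = seed, n_subjects = n,
         package_version = as.character(utils::packageVersion("ctgtier"))),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(classifications = sim$classifications,
                 outcomes = sim$outcomes,
                 files = c(cls_file, files)))
}

#' Classify a directory of trace files
#'
#' Reads every `trace_*.csv` in `dir`, classifies each subject's last hour
#' and returns the combined per-segment classification table. Subjects
#' whose trace does not cover the full hour get per-segment coverage
#' warnings.
#'
#' @param dir Directory of trace CSVs written by [write_ctg()] /
#'   [generate_cohort()].
#' @param cfg A [ctg_config()].
#' @return Data.frame as from [classify_cohort()].
#' @export
classify_directory <- function(dir, cfg = ctg_config()) {
  files <- list.files(dir, pattern = "^trace_.*\\.csv$", full.names = TRUE)
  if (!length(files)) stop("no trace_*.csv files in ", dir)
  out <- vector("list", length(files))
  for (i in seq_along(files)) {
    rec <- read_ctg(files[i])
    cl <- classify_record(rec, cfg)
    if (any(!cl$covered))
      warning("subject ", rec$subject_id, ": segment(s) ",
              paste(cl$segment[!cl$covered], collapse = ", "),
              " min not covered by the trace", call. = FALSE)
    out[[i]] <- cl
  }
  do.call(rbind, out)
}
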