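# Shared full-scale synthetic cohort for the acceptance checks: the
# default n = 1909 generator configuration, rendered at 1 Hz (the smoke
# sampling-rate variant; the acceptance script runs the 4 Hz default) and
# pushed through the complete clean/segment/extract/classify pipeline.
# Computed once per test run and reused.

.cohort_cache <- new.env(parent = emptyenv())

acceptance_cohort <- function() {
  if (is.null(.cohort_cache$sim)) {
    cfg <- ctg_config(sample_rate_hz = 1)
    .cohort_cache$cfg <- cfg
    .cohort_cache$sim <- simulate_cohort(cfg, seed = 42)
  }
  .cohort_cache$sim
}
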