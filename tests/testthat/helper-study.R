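# Replicate recovery study shared by several acceptance checks.  Computed
# lazily once per test run and cached; 50 replicates per arm of a 10-year
# synthetic city analysed at 5 df/year.

study_cache <- new.env(parent = emptyenv())

get_study <- function(arm) {
  key <- paste0("arm_", arm)
  if (is.null(study_cache[[key]])) {
    study_cache[[key]] <- recovery_study(n_reps = 50, seed = 101, arm = arm,
                                         df_per_year = 5)
  }
  study_cache[[key]]
}
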