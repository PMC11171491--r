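# Shared expensive fixture: one default-condition synthetic study (the
# enriched 500/1000-per-pathology standalone design plus the nine-reader
# two-session comparison), simulated once per test run and reused.

.study_cache <- new.env(parent = emptyenv())

get_default_study <- function() {
  if (is.null(.study_cache$bundle)) {
    .study_cache$bundle <- simulate_study(sim_config(), seed = 101L)
    .study_cache$eval <- evaluate_standalone(.study_cache$bundle)
  }
  .study_cache
}

# small study configuration for fast structural tests
small_config <- function(...) {
  sim_config(n_positive_per_label = 8L, n_negative_per_label = 16L,
             reader_n_images = 60L,
             reader_positive_counts = c(consolidation = 5L,
                                        pleural_effusion = 4L,
                                        pneumothorax = 3L,
                                        cardiomegaly = 2L,
                                        acute_pulmonary_edema = 3L,
                                        pulmonary_nodule = 3L),
             ...)
}
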