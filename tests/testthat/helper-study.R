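# Heavy shared fixtures for the acceptance tests, computed once per test run.
# The phantom validation study (train + explain + occlusion) dominates the
# suite's runtime; every acceptance criterion that needs trained models reads
# from this cache.

.study_cache <- new.env(parent = emptyenv())

acceptance_study <- function() {
  if (is.null(.study_cache$study))
    .study_cache$study <- phantom_validation_study(seed = 20240901)
  .study_cache$study
}

acceptance_progression <- function() {
  if (is.null(.study_cache$prog))
    .study_cache$prog <- progression_study(seed = 20240902)
  .study_cache$prog
}
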