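# Shared fixtures, built lazily once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

.memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small reference set + 4-library study: fast, used by module tests
small_refs <- function() .memo("small_refs", function() {
  build_reference_set(
    genome_length = 60000L, n_genes = 8L,
    n_planted = list(known_mirna = 10L, novel_mirna = 6L,
                     mirtron_typical = 1L, mirtron_atypical = 1L,
                     rrna = 2L, mrna_decoy = 2L),
    seed = 7L)
})

small_study <- function() .memo("small_study", function() {
  refs <- small_refs()
  cfgs <- default_study_configs(refs, n_profiles = 2L,
                                reps_per_profile = 2L, n_reads = 5000L,
                                seed = 11L)
  run_study(refs, cfgs, seed = 11L)
})

# full default-scale study: the end-to-end acceptance conditions
acceptance_refs <- function() .memo("acceptance_refs", function() {
  build_reference_set(seed = 1L)
})

acceptance_study <- function() .memo("acceptance_study", function() {
  refs <- acceptance_refs()
  cfgs <- default_study_configs(refs, seed = 1L)
  run_study(refs, cfgs, seed = 1L)
})

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
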