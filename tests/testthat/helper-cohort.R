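# Shared fixtures, built once per test session and memoized: the
# effect-carrying synthetic cohort (the pipeline's standard study
# conditions: 20 + 20 subjects, 90 regions, 200 voxels/region, ten
# injected pairs at delta = 3) is expensive, and several test files probe
# different aspects of the same run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small cohort for fast structural tests
small_cohort <- function() {
  memo("small_cohort", simulate_cohort(simulation_config(
    n_per_group = 3, n_regions = 12, n_vox = 40,
    effect_pairs = cbind(c(1, 3), c(2, 4)), effect_size = 3, seed = 11
  )))
}

# one standard-condition subject network (90 regions, 200 voxels)
standard_subject_network <- function() {
  memo("standard_subject_network", {
    cohort <- simulate_cohort(simulation_config(n_per_group = 2, seed = 5))
    build_connectome(cohort$samples[[1]])
  })
}

# full standard-condition cohort with features (null-ensemble size 10 per
# threshold keeps the sweep tractable on one CPU; see the methods vignette)
standard_cohort_features <- function() {
  memo("standard_cohort_features", {
    cohort <- simulate_cohort(simulation_config(seed = 20260101))
    cohort <- add_connectomes(cohort)
    add_features(cohort, n_nulls = 10, seed = 1)
  })
}

standard_cohort_cv <- function() {
  memo("standard_cohort_cv", {
    nested_loocv(standard_cohort_features(), beta_step = 0.25)
  })
}

injected_pair_names <- function() {
  nm <- aal90_region_names()
  pairs <- default_effect_pairs()
  paste(nm[pairs[, 1]], nm[pairs[, 2]], sep = "--")
}
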