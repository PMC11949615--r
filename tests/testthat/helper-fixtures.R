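# Shared fixtures. The default study-scale cohort (n = 54, p = 50, seed 42)
# is expensive enough to build once and reuse across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_cohort <- function() {
  cached("default_cohort", generate_cohort(synth_config(seed = 42)))
}

default_run <- function() {
  cached("default_run", run_pipeline(default_cohort()))
}

# small cohort for structural/shape tests
small_cohort <- function(n = 10, p = 12, seed = 11, ...) {
  generate_cohort(synth_config(n_subjects = n, n_regions = p, seed = seed, ...))
}

rand_spd <- function(p, n = 1, seed = 1, cap = 50) {
  generate_spd(p, n, condition_number_cap = cap, seed = seed)
}

frob <- function(M) sqrt(sum(M^2))

symmetrize_for_test <- function(M) (M + t(M)) / 2
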