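# One default 15-bird cohort, simulated and processed once per test run and
# shared across test files. Seed 42 is the suite's fixed convention.
.cohort_cache <- new.env(parent = emptyenv())

get_default_cohort <- function(seed = 42L, n_birds = 15L) {
  key <- paste0("s", seed, "n", n_birds)
  if (is.null(.cohort_cache[[key]])) {
    cohort <- simulate_cohort(n_birds, seed = seed)
    migrations <- process_cohort(cohort)
    .cohort_cache[[key]] <- list(cohort = cohort, migrations = migrations)
  }
  .cohort_cache[[key]]
}

# truth vs detected label per flight night, one row per flight
label_comparison <- function(cohort, migrations) {
  do.call(rbind, lapply(names(cohort), function(b) {
    tr <- cohort[[b]]$truth$flights
    de <- migrations[[b]]$flights
    merge(data.frame(night = tr$night, truth = tr$label),
          data.frame(night = de$night, detected = de$label))
  }))
}
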