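# Shared small fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# 3-class cohort with clear planted signal; small enough for RF unit tests
small_sim <- function() {
  fixture("small_sim", function() {
    simulate_methylation(sim_config(
      n_classes = 3, samples_per_class = 15, n_probes = 300,
      informative_per_class = 5, effect_delta = 0.35, precision = 30,
      seed = 42
    ))
  })
}

tiny_beta <- function() {
  tibble::tibble(sample_id = c("s1", "s2"),
                 p1 = c(0.1, NA), p2 = c(0.9, 0.5))
}
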