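# Shared fixtures built once per test run. Templates are deterministic, so
# caching them is purely a speed measure.

.fixture_env <- new.env()

fix_templates <- function(n = 4) {
  key <- paste0("tmpl", n)
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- crc_templates(n_families = n)
  .fixture_env[[key]]
}

# A small planted genome shared by detection/annotation/census tests.
fix_small_sim <- function() {
  if (is.null(.fixture_env$small_sim)) {
    .fixture_env$small_sim <- simulate_genome(
      bg_length = 2e5, templates = fix_templates(4), n_complete = 6,
      n_fragments = 3, ages = 2e6, min_spacing = 18000, seed = 11)
  }
  .fixture_env$small_sim
}
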