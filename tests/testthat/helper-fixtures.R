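# Shared small simulation fixtures (built once per test run).

small_config <- function(..., seed = 101) {
  sim_config(n_genes = 600, n_tfs = 50, noise_sd = 0.02, seed = seed, ...)
}

# a cached default small simulation used by several test files
.fixture_env <- new.env()
small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_dataset(small_config())
    ex <- .fixture_env$sim
    .fixture_env$fit <- partition_expression(
      ex$expression$raw, ex$expression$meta,
      n_invariant = sum(ex$truth$sector == "invariant"))
  }
  .fixture_env$sim
}
small_fit <- function() { small_sim(); .fixture_env$fit }
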