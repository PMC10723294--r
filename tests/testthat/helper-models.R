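## Shared helpers: tiny constant-size models and record builders used
## across the test files.

toy_constant_model <- function(N, c = 2e-5, name = paste0("toy", N)) {
  demographic_model(name, list(
    list(duration = NA, size_start = N, growth_rate = 0)), c = c)
}

## classify a batch of engine replicates into a records data.frame
run_records <- function(model, params, seeds, ...) {
  do.call(rbind, lapply(seeds, function(sd)
    classify_replicate(run_replicate(model, params, seed = sd, ...))))
}

## random valid genotype count vector (for property-style loops)
random_genotype_state <- function(N = 50L) {
  counts <- genotype_counts()
  counts[] <- as.numeric(rmultinom(1L, N, prob = runif(10L, 0.01, 1)))
  counts
}
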