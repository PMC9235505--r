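# Seed derivation for the replication harness. A master seed spawns
# per-replication (and per-stage) seeds through a Lehmer-style recurrence so
# that adding replications never perturbs earlier ones. All derived seeds
# stay below 2^31 - 1.
derive_seed <- function(seed, ...) {
  k <- as.double(seed) %% 2147483647
  for (i in c(...)) {
    k <- (k * 48271 + as.double(i) * 104729 + 1) %% 2147483647
  }
  as.integer(k)
}
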