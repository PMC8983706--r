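# Small default plate for fast structural tests.
tiny_sim <- function(seed = 1, ...) {
  args <- list(
    n_coding = 120, n_ncrna = 15, n_spikein = 20,
    n_top_canonical = 20, n_top_candidate = 25,
    conditions = c("DMSO", "drugA"), n_wells_per_condition = 4,
    depth_mean = 4e4, seed = seed
  )
  args[names(list(...))] <- list(...)
  simulate_experiment(do.call(sim_config, args))
}

# Hand step-up BH, the independent oracle for bh_adjust.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Naive classic running-sum ES, the independent oracle for gsea ES.
# On an exact |max| = |min| tie the positive deviation is reported, matching
# the documented convention.
es_oracle <- function(ranked, set) {
  N <- length(ranked)
  k <- sum(ranked %in% set)
  # integer numerators over the common denominator k(N-k) keep exact ties exact
  run <- cumsum(ifelse(ranked %in% set, N - k, -k))
  mx <- max(run, 0)
  mn <- min(run, 0)
  (if (mx >= -mn) mx else mn) / (k * (N - k))
}
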