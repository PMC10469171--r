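# Shared helpers for building tiny in-code fixtures.

write_spike_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("channel,time_s", rows), path)
  path
}

# Exact self-similar mean profiles s(t, D) = D^gamma * 4 x (1 - x) sampled
# at x = (0:(D-1))/(D-1), replicated so every duration clears min_count.
make_collapse_profiles <- function(gamma = 1, durations = 4:20,
                                   copies = 4) {
  lapply(rep(durations, each = copies), function(D) {
    x <- (0:(D - 1)) / (D - 1)
    D^gamma * 4 * x * (1 - x)
  })
}

# Small near-critical session used by several tests.
quick_critical_session <- function(seed, T = 2e4, m = 0.99, rate = 5) {
  simulate_branching(m = m, h = rate * (1 - m), T = T, seed = seed)
}
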