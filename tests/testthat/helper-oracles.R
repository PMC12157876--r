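# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: stance episodes are counted by threshold
# crossings on the raw force trace, and window counts by brute-force
# enumeration of start positions.

# Number of stance episodes: contiguous runs where the force exceeds a
# fraction of its peak.
count_stance_episodes <- function(x, frac = 0.3) {
  above <- x > frac * max(x)
  sum(diff(above) == 1L) + as.integer(above[1])
}

# Brute-force window count: slide starts by `stride` samples and count how
# many full windows fit.
brute_window_count <- function(n, w, stride) {
  count <- 0L
  s <- 1L
  while (s + w - 1L <= n) {
    count <- count + 1L
    s <- s + stride
  }
  count
}

# Median peak-to-peak interval (seconds) between stance episode onsets,
# estimated from threshold upcrossings.
stance_onset_times <- function(x, fs, frac = 0.3) {
  above <- x > frac * max(x)
  which(diff(above) == 1L) / fs
}

# A small shared cohort, built once per test run.
.cohort_cache <- new.env(parent = emptyenv())
tiny_cohort <- function() {
  if (is.null(.cohort_cache$tiny))
    .cohort_cache$tiny <- generate_cohort(4, 4, duration_s = 12, seed = 7)
  .cohort_cache$tiny
}
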