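# Shared fixtures: all inputs are generated in code at test time.

# A small fully-specified valid recording.
tiny_recording <- function(names = NULL) {
  mea_recording(
    epos = cbind(c(0, 100, 100), c(0, 0, 100)),
    spikes = c(0.1, 0.9, 0.2, 0.4, 0.8, 0.5),
    sCount = c(2, 3, 1),
    array = "MCS_8x8_100um",
    meta = mea_metadata("Wong1993", "ferret", age = 0),
    names = names)
}

# Randomised valid recording for round-trip / property tests.
random_recording <- function(seed, max_units = 8L, max_spikes = 40L) {
  set.seed(seed)
  n <- sample(2:max_units, 1L)
  counts <- sample(0:max_spikes, n, replace = TRUE)
  if (sum(counts) == 0L) counts[1L] <- 1L
  trains <- lapply(counts, function(k) sort(runif(k, 0, 60)))
  mea_recording(
    epos = cbind(runif(n, 0, 700), runif(n, 0, 700)),
    spikes = unlist(trains),
    sCount = counts,
    array = sample(c("MCS_8x8_100um", "hex_60um_61"), 1L),
    meta = mea_metadata(sample(c("Wong1993", "Demas2003"), 1L),
                        sample(c("mouse", "ferret"), 1L),
                        age = sample(c(0:13, 500), 1L),
                        genotype = sample(c("wt", "b2ko"), 1L),
                        cond = sample(c("ctl", "dr"), 1L)),
    names = if (runif(1) < 0.5) sprintf("u%02d", seq_len(n)))
}

# O(n^2) brute-force coincidence oracle, independent of the sweep.
brute_coincidences <- function(a, b, dt) {
  if (!length(a) || !length(b)) return(0)
  as.numeric(sum(abs(outer(a, b, "-")) <= dt))
}

# Spike train with bursts planted at given onsets: `n_spikes` spikes at
# fixed `isi`, so each burst spans (n_spikes - 1) * isi exactly.
planted_burst_train <- function(onsets, n_spikes = 5L, isi = 0.02) {
  sort(unlist(lapply(onsets, function(t0)
    t0 + (seq_len(n_spikes) - 1L) * isi)))
}

expect_no_errors <- function(v) {
  expect_equal(sum(v$severity == "error"), 0L, info = paste(v$code, collapse = ","))
}
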