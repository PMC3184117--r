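# Shared fixtures, built in code. The expensive study scaffolds (the
# homology screens dominate) are memoized across test files.

.fixture_cache <- new.env(parent = emptyenv())

# full study-scale scaffold: 88 + 86 panel, default off-panel universe
full_scaffold <- function() {
  if (is.null(.fixture_cache$full)) {
    panel <- make_panel(seed = 7)
    .fixture_cache$full <- study_scaffold(
      panel, make_offpanel(panel, seed = 11), seed = 17)
  }
  .fixture_cache$full
}

# reduced scaffold for fast functional tests
small_scaffold <- function() {
  if (is.null(.fixture_cache$small)) {
    panel <- make_panel(n_pool_a = 30, n_pool_b = 30, seed = 3)
    off <- make_offpanel(panel, n_random = 60,
                         homolog_counts = c(2L, 6L, 8L, 10L, 12L),
                         seed = 4)
    .fixture_cache$small <- study_scaffold(panel, off,
                                           n_endogenous = 20L, seed = 5)
  }
  .fixture_cache$small
}

small_study <- function(seed = 9L) {
  simulate_study(small_scaffold(), seed = seed)
}

# a tiny hand-written Ct table: one sample, two replicates
toy_ct <- function(assays, rep1, rep2, sample = "S1", max_cycles = 40) {
  ct_table(rep(sample, 2L * length(assays)),
           rep(c("r1", "r2"), each = length(assays)),
           c(assays, assays), c(rep1, rep2), max_cycles = max_cycles)
}
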