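# Shared fixtures and independent oracles used across the test files.

# Independent brute-force aligner built on Biostrings::neditStartingAt: every
# start position on both strands, minimum Hamming distance, tie count.
oracle_align <- function(read, ref, max_mismatch = 5) {
  subject <- Biostrings::DNAString(ref)
  len <- nchar(read)
  starts <- seq_len(nchar(ref) - len + 1)
  best <- max_mismatch + 1L
  best_pos <- NA_integer_; best_strand <- NA_character_; ties <- 0L
  for (strand in c("+", "-")) {
    pat <- Biostrings::DNAString(read)
    if (strand == "-") pat <- Biostrings::reverseComplement(pat)
    d <- Biostrings::neditStartingAt(pat, subject, starting.at = starts,
                                     with.indels = FALSE)
    for (i in seq_along(d)) {
      if (d[i] < best) {
        best <- d[i]; best_pos <- starts[i]; best_strand <- strand; ties <- 1L
      } else if (d[i] == best && best <= max_mismatch) {
        ties <- ties + 1L
      }
    }
  }
  if (best > max_mismatch) {
    list(aligned = FALSE)
  } else {
    list(aligned = ties == 1L, pos = best_pos, strand = best_strand,
         mismatch = as.integer(best), ties = ties)
  }
}

# Random evolution series with exact final cell counts.
random_series <- function(m, n0_range = c(1e4, 1e6), fold_range = c(10, 1e5)) {
  n0 <- round(runif(m, n0_range[1], n0_range[2]))
  n_final <- round(n0 * runif(m, fold_range[1], fold_range[2]))
  evolution_series(n0 = n0, final_cells = n_final)
}

# Lineage table matching the simulator's internal layout.
new_lineages_for_test <- function(id, growth_rate, cell_count) {
  data.frame(id = as.integer(id), growth_rate = growth_rate,
             cell_count = cell_count)
}

# Agent-based synchronous doubling: every cell divides once per generation.
# Exact oracle for generations/divisions when N/n0 is a power of two and the
# population stays enumerable.
agent_doubling <- function(n0, generations) {
  cells <- rep(1L, n0)   # each entry one cell
  divisions <- 0
  for (g in seq_len(generations)) {
    divisions <- divisions + length(cells)
    cells <- rep(cells, 2L)
  }
  list(n_final = length(cells), divisions = divisions,
       generations = generations)
}
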