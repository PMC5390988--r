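# Shared small simulation products, built once per test run.

small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_transcripts = 15, length_range = c(500, 1000),
                        fixed_diff_rate = 0.004, seed = 101)
      cache <<- simulate_two_species(cfg)
    }
    cache
  }
})

# Build a per-species count-table row set directly (for joint-site toys):
# counts is a named list transcript/pos -> c(A=, C=, G=, T=).
toy_counts <- function(tid, pos, ref, A = 0, C = 0, G = 0, T = 0) {
  data.frame(transcript_id = tid, pos = pos, ref = ref,
             depth = A + C + G + T, A = A, C = C, G = G, T = T,
             stringsAsFactors = FALSE)
}

# One pileup column as parse_pileup would emit it.
toy_column <- function(tid = "t1", pos = 1L, ref = "A", base, qual,
                       mapq = NA_integer_) {
  list(transcript_id = tid, pos = pos, ref = ref, depth = length(base),
       base = base, qual = qual, strand = rep("+", length(base)),
       mapq = rep(mapq, length(base)))
}
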