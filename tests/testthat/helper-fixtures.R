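# Shared fixtures, built in code at test time.

# Small, fast simulation configuration for unit tests.
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_residues = 5L, depth_init = 2e4, depth_cf = 2e4,
         n_cells_transduced = 2e4, seed = 1L),
    list(...))
  do.call(sim_config, args)
}

# Deterministic toy count table: 1 library, 1 replicate, 4 variants
# (3 missense + synonymous anchor at residue 1, ref A).
toy_counts <- function() {
  tibble::tibble(
    library_id = "lib001", replicate_id = 1L, residue_index = 1L,
    ref_aa = "A", alt_aa = c("A", "C", "D", "E"),
    count_day9 = c(1000L, 1000L, 500L, 2000L),
    count_confluent = c(1000L, 4000L, 500L, 2000L),
    day_confluent = 20L
  )
}

# Toy amplicon: 30 codons; residues near the middle are covered by both
# 60-nt mates.
toy_reference <- function() protein_to_cds(reference_protein(30L))

# Independent reverse-complement helper for building read fixtures.
reverse_complement_chr <- function(x) {
  vapply(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Brute-force BH step-up oracle: largest k with p_(k) <= k/m * level,
# reject everything with p <= p_(k).
bh_oracle <- function(p, level) {
  m <- length(p)
  ps <- sort(p)
  ok <- which(ps <= seq_len(m) / m * level)
  if (length(ok) == 0L) return(rep(FALSE, m))
  p <= ps[max(ok)]
}
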