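# Amplicon read simulation, paired-end merging and codon-level counting.
#
# Coordinates: residues and CDS positions are 1-based; codon i spans CDS
# positions 3i-2 .. 3i.  The supplied reference sequence is the amplicon:
# mate 1 reads its 5' end, mate 2 (stored as sequenced, i.e. reverse strand)
# its 3' end.

#' Emit paired reads realizing a variant count table
#'
#' For every counted variant, emits that many read pairs whose merged
#' sequence matches the reference CDS except at the target codon, which is
#' replaced by a codon encoding the variant amino acid (the reference codon
#' itself for the synonymous variant).  Qualities are constant.
#'
#' @param count_table Tibble with columns `residue_index`, `alt_aa`, `count`.
#' @param reference_cds Amplicon/CDS string; length divisible by 3.
#' @param read_length Length of each mate (default 150).
#' @param base_quality Constant Phred quality of every base (default 40).
#' @param seed Seed used to shuffle the emitted pairs.
#' @return Tibble of read pairs: `read_id`, `seq1`, `qual1`, `seq2`, `qual2`
#'   (mate 2 reverse-complemented, as sequenced).
#' @export
emit_reads <- function(count_table, reference_cds, read_length = 150L,
                       base_quality = 40L, seed = 1L) {
  check_columns(count_table, c("residue_index", "alt_aa", "count"))
  L <- nchar(reference_cds)
  if (L %% 3L != 0L) abort("`reference_cds` length must be divisible by 3.")
  if (read_length > L) read_length <- L
  for (i in unique(count_table$residue_index)) {
    s <- 3L * i - 2L
    # both mates must span the target codon
    if (s < (L - read_length + 1L) || (3L * i) > read_length) {
      abort(sprintf("residue %d codon not covered by both mates (amplicon %d nt, reads %d nt).",
                    i, L, read_length))
    }
  }
  qual <- strrep(rawToChar(as.raw(base_quality + 33L)), read_length)
  pairs <- purrr::pmap(count_table[, c("residue_index", "alt_aa", "count")],
    function(residue_index, alt_aa, count) {
      if (count <= 0L) return(NULL)
      s <- 3L * residue_index - 2L
      cds <- reference_cds
      substr(cds, s, s + 2L) <-
        if (alt_aa == translate_codon(substr(reference_cds, s, s + 2L))) {
          substr(reference_cds, s, s + 2L)
        } else {
          codon_for(alt_aa)
        }
      tibble(
        seq1 = rep(substr(cds, 1L, read_length), count),
        seq2 = rep(reverse_complement(substr(cds, L - read_length + 1L, L)),
                   count)
      )
    }) |> list_rbind()
  if (is.null(pairs) || nrow(pairs) == 0L) {
    return(tibble(read_id = character(), seq1 = character(),
                  qual1 = character(), seq2 = character(),
                  qual2 = character()))
  }
  withr::local_seed(seed)
  pairs <- pairs[sample.int(nrow(pairs)), ]
  tibble(
    read_id = sprintf("read%06d", seq_len(nrow(pairs))),
    seq1 = pairs$seq1, qual1 = qual,
    seq2 = pairs$seq2, qual2 = qual
  )
}

# Merge a single pair; returns list(merged, qual, overlap) or NULL when no
# admissible overlap exists.
merge_one_pair <- function(seq1, qual1, seq2, qual2, min_overlap,
                           max_mismatch_frac) {
  m1 <- strsplit(seq1, "", fixed = TRUE)[[1]]
  q1 <- utf8ToInt(qual1) - 33L
  m2 <- strsplit(reverse_complement(seq2), "", fixed = TRUE)[[1]]
  q2 <- rev(utf8ToInt(qual2) - 33L)
  L1 <- length(m1); L2 <- length(m2)
  if (min(L1, L2) < min_overlap) return(NULL)
  best <- 0L
  for (o in seq(min(L1, L2), min_overlap)) {
    t1 <- m1[(L1 - o + 1L):L1]
    h2 <- m2[1:o]
    mm <- sum(t1 != h2 | t1 == "N" | h2 == "N")
    if (mm / o <= max_mismatch_frac) { best <- o; break }
  }
  if (best == 0L) return(NULL)
  o <- best
  i1 <- (L1 - o + 1L):L1
  i2 <- 1:o
  take1 <- q1[i1] >= q2[i2]  # quality tie resolves to mate 1
  cons <- ifelse(take1, m1[i1], m2[i2])
  consq <- ifelse(take1, q1[i1], q2[i2])
  agree <- m1[i1] == m2[i2]
  consq[agree] <- pmax(q1[i1], q2[i2])[agree]
  merged <- c(m1[seq_len(L1 - o)], cons, m2[seq(o + 1L, length.out = L2 - o)])
  mq <- c(q1[seq_len(L1 - o)], consq, q2[seq(o + 1L, length.out = L2 - o)])
  list(merged = paste(merged, collapse = ""),
       qual = intToUtf8(mq + 33L),
       overlap = o)
}

#' Merge paired-end reads into contiguous amplicon sequences
#'
#' Finds the longest ungapped overlap of mate 1's 3' end with the
#' reverse-complemented mate 2's 5' end whose mismatch fraction does not
#' exceed `max_mismatch_frac` and whose length is at least `min_overlap`.
#' Overlap disagreements resolve to the higher-quality base (ties to mate 1).
#' Pairs with no admissible overlap are returned with `status = "rejected"`,
#' not dropped, so discards can be tallied.
#'
#' @param pairs Tibble with `seq1`, `qual1`, `seq2`, `qual2` (and optionally
#'   `read_id`), mate 2 as sequenced.
#' @param min_overlap Minimum admissible overlap (default 10).
#' @param max_mismatch_frac Maximum mismatch fraction within the overlap
#'   (default 0.1).
#' @return Tibble: `read_id`, `status` (`"merged"`/`"rejected"`), `merged`,
#'   `qual`, `overlap`.
#' @export
merge_read_pairs <- function(pairs, min_overlap = 10L,
                             max_mismatch_frac = 0.1) {
  check_columns(pairs, c("seq1", "qual1", "seq2", "qual2"))
  if (!"read_id" %in% names(pairs)) {
    pairs$read_id <- sprintf("read%06d", seq_len(nrow(pairs)))
  }
  bad <- which(nchar(pairs$seq1) != nchar(pairs$qual1) |
                 nchar(pairs$seq2) != nchar(pairs$qual2))
  if (length(bad) > 0L) {
    abort(sprintf("sequence/quality length mismatch in row(s): %s",
                  paste(head(bad, 5L), collapse = ", ")))
  }
  if (any(nchar(pairs$seq1) == 0L | nchar(pairs$seq2) == 0L)) {
    abort("reads must be non-empty.")
  }
  res <- purrr::pmap(pairs[, c("seq1", "qual1", "seq2", "qual2")],
                     merge_one_pair,
                     min_overlap = min_overlap,
                     max_mismatch_frac = max_mismatch_frac)
  tibble(
    read_id = pairs$read_id,
    status = ifelse(vapply(res, is.null, logical(1)), "rejected", "merged"),
    merged = vapply(res, function(r) if (is.null(r)) NA_character_ else r$merged,
                    character(1)),
    qual = vapply(res, function(r) if (is.null(r)) NA_character_ else r$qual,
                  character(1)),
    overlap = vapply(res, function(r) if (is.null(r)) NA_integer_ else r$overlap,
                     integer(1))
  )
}

#' Count amino-acid variants at a residue from merged reads
#'
#' Each merged read is anchored ungapped to the reference amplicon; reads
#' whose length differs from the amplicon span (e.g. indels), that carry `N`
#' in the target codon, or that mismatch the reference outside the target
#' codon in more than `max_other_mismatch` positions are discarded.  The
#' target codon of every retained read is translated with the standard
#' genetic code and the corresponding amino-acid count incremented; stop
#' codons are tallied under `"*"`, separately from the 20 amino acids.
#'
#' @param merged Output of [merge_read_pairs()] (rejected rows are ignored)
#'   or a character vector of merged sequences.
#' @param reference_cds Reference amplicon/CDS string, in frame.
#' @param residue_index 1-based residue whose codon is genotyped.
#' @param max_other_mismatch Tolerated mismatches outside the target codon
#'   (default 0, strict).
#' @return Tibble `amino_acid`, `count` (sorted, `"*"` last), with attributes
#'   `n_reads` (merged reads considered) and `n_discarded`;
#'   `sum(count) + n_discarded == n_reads`.
#' @export
count_variants <- function(merged, reference_cds, residue_index,
                           max_other_mismatch = 0L) {
  if (is.data.frame(merged)) {
    check_columns(merged, c("status", "merged"))
    seqs <- merged$merged[merged$status == "merged"]
  } else {
    seqs <- merged
  }
  L <- nchar(reference_cds)
  if (L %% 3L != 0L) abort("`reference_cds` must be in frame.")
  s <- 3L * residue_index - 2L
  if (residue_index < 1L || s + 2L > L) {
    abort(sprintf("residue %d codon not covered by the amplicon.",
                  residue_index))
  }
  refv <- strsplit(reference_cds, "", fixed = TRUE)[[1]]
  codon_idx <- s:(s + 2L)
  tally <- integer(0)
  discarded <- 0L
  for (sq in seqs) {
    if (nchar(sq) != L) { discarded <- discarded + 1L; next }
    v <- strsplit(sq, "", fixed = TRUE)[[1]]
    codon <- paste(v[codon_idx], collapse = "")
    if (grepl("N", codon, fixed = TRUE)) { discarded <- discarded + 1L; next }
    mm <- sum(v[-codon_idx] != refv[-codon_idx])
    if (mm > max_other_mismatch) { discarded <- discarded + 1L; next }
    aa <- translate_codon(codon)
    if (is.na(aa)) { discarded <- discarded + 1L; next }
    tally[aa] <- (if (aa %in% names(tally)) tally[[aa]] else 0L) + 1L
  }
  aa <- names(tally)
  ord <- order(aa == "*", aa)  # amino acids alphabetical, "*" last
  out <- tibble(amino_acid = aa[ord], count = as.integer(unname(tally)[ord]))
  attr(out, "n_reads") <- length(seqs)
  attr(out, "n_discarded") <- discarded
  out
}

#' Write and read paired FASTQ files
#'
#' Standard 4-line FASTQ records with Phred+33 qualities, via Biostrings.
#'
#' @param pairs Read-pair tibble (`read_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`).
#' @param path1,path2 Output (input) files for mates 1 and 2.
#' @return `write_fastq_pairs()` returns the paths invisibly;
#'   `read_fastq_pairs()` returns a read-pair tibble.
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  check_columns(pairs, c("read_id", "seq1", "qual1", "seq2", "qual2"))
  for (m in 1:2) {
    seqs <- Biostrings::DNAStringSet(pairs[[paste0("seq", m)]])
    names(seqs) <- pairs$read_id
    qs <- Biostrings::QualityScaledDNAStringSet(
      seqs, Biostrings::PhredQuality(pairs[[paste0("qual", m)]]))
    Biostrings::writeQualityScaledXStringSet(qs, c(path1, path2)[m])
  }
  invisible(c(path1, path2))
}

#' @rdname write_fastq_pairs
#' @export
read_fastq_pairs <- function(path1, path2) {
  # Biostrings warns that quality metadata columns are dropped while
  # constructing the QualityScaledDNAStringSet; qualities are re-attached
  # explicitly below, so the warning is noise here
  r1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path1))
  r2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path2))
  if (length(r1) != length(r2)) abort("mate files differ in read count.")
  suppressWarnings(tibble(
    read_id = names(r1),
    seq1 = as.character(r1),
    qual1 = as.character(Biostrings::quality(r1)),
    seq2 = as.character(r2),
    qual2 = as.character(Biostrings::quality(r2))
  ))
}
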