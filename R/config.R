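#' Simulation configuration for a pooled variant competition assay
#'
#' Bundles the design, growth and sequencing parameters of the synthetic-data
#' generator.  Defaults emulate a saturation assay of a 156-residue protein in
#' which each residue is covered by its own 20-variant lentiviral library
#' (19 missense + 1 synonymous), cells compete by exponential growth between
#' a Day-9 sample and harvest at confluency (a day drawn uniformly from
#' `confluency_day_range`), and both timepoints are sequenced to a fixed depth.
#'
#' @param n_residues Number of residues in the protein (one library each).
#' @param variants_per_residue Variants per library; 20 = 19 missense + 1
#'   synonymous anchor.
#' @param library_concentration Symmetric Dirichlet concentration used to draw
#'   each library's variant proportions. Larger values give more even
#'   libraries; the default 10 yields realistic skew in which occasional
#'   variants fall below `underrep_threshold` and trigger the spike-in rule.
#' @param underrep_threshold Proportion at or below which a drawn variant is
#'   considered under-represented (default 0.01).
#' @param spike_to Proportion to which under-represented variants are raised
#'   at library construction (default 0.05), mirroring wet-lab re-spiking.
#' @param n_cells_transduced Cells transduced per library (multinomial
#'   bottleneck; default 1e5).
#' @param neutral_growth_rate Per-day exponential growth rate shared by all
#'   functionally neutral variants (default 0.1/day: cells expressing the
#'   functional tumor suppressor are growth-arrested; an all-neutral pool
#'   seeded at 5e5 cells then reaches a ~2e7-cell confluent flask in the
#'   ~5 weeks observed for the neutral-barcode control).
#' @param deleterious_advantage Additive per-day growth-rate advantage of a
#'   fitness-advantaged (functionally deleterious) variant.  The default 0.1
#'   doubles the neutral rate, i.e. a 2-fold growth advantage.
#' @param depth_init,depth_cf Sequencing read depth per library at Day 9 and
#'   at confluency (default 1e5 each).
#' @param n_replicates Independent assay replicates per library.
#' @param confluency_day_range Inclusive integer range of days from which each
#'   library's harvest day is drawn uniformly (default 16--40).
#' @param seed Master seed; all per-library substreams are derived from it and
#'   it is recorded in every output.
#'
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_residues = 5, depth_init = 1e4, depth_cf = 1e4)
#' cfg$n_residues
sim_config <- function(n_residues = 156L,
                       variants_per_residue = 20L,
                       library_concentration = 10,
                       underrep_threshold = 0.01,
                       spike_to = 0.05,
                       n_cells_transduced = 1e5,
                       neutral_growth_rate = 0.1,
                       deleterious_advantage = 0.1,
                       depth_init = 1e5,
                       depth_cf = 1e5,
                       n_replicates = 1L,
                       confluency_day_range = c(16L, 40L),
                       seed = 1L) {
  check_scalar_number(n_residues, "n_residues", lower = 1, integerish = TRUE)
  check_scalar_number(variants_per_residue, "variants_per_residue",
                      lower = 2, upper = 20, integerish = TRUE)
  check_scalar_number(library_concentration, "library_concentration")
  if (library_concentration <= 0) {
    abort("`library_concentration` must be positive.")
  }
  check_proportion(underrep_threshold, "underrep_threshold")
  check_proportion(spike_to, "spike_to")
  if (spike_to <= underrep_threshold) {
    abort("`spike_to` must exceed `underrep_threshold`.")
  }
  check_scalar_number(n_cells_transduced, "n_cells_transduced",
                      lower = 1, integerish = TRUE)
  check_scalar_number(neutral_growth_rate, "neutral_growth_rate")
  check_scalar_number(deleterious_advantage, "deleterious_advantage")
  check_scalar_number(depth_init, "depth_init", lower = 1, integerish = TRUE)
  check_scalar_number(depth_cf, "depth_cf", lower = 1, integerish = TRUE)
  check_scalar_number(n_replicates, "n_replicates", lower = 1,
                      integerish = TRUE)
  if (length(confluency_day_range) != 2L ||
      any(confluency_day_range != round(confluency_day_range)) ||
      confluency_day_range[1] > confluency_day_range[2] ||
      confluency_day_range[1] < 10) {
    abort("`confluency_day_range` must be an increasing integer pair past Day 9.")
  }
  check_scalar_number(seed, "seed", integerish = TRUE)

  structure(
    list(
      n_residues = as.integer(n_residues),
      variants_per_residue = as.integer(variants_per_residue),
      library_concentration = library_concentration,
      underrep_threshold = underrep_threshold,
      spike_to = spike_to,
      n_cells_transduced = as.integer(n_cells_transduced),
      neutral_growth_rate = neutral_growth_rate,
      deleterious_advantage = deleterious_advantage,
      depth_init = as.integer(depth_init),
      depth_cf = as.integer(depth_cf),
      n_replicates = as.integer(n_replicates),
      confluency_day_range = as.integer(confluency_day_range),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d residues x %d variants; Dirichlet conc. %.3g, spike %0.3g -> %0.3g\n",
              x$n_residues, x$variants_per_residue, x$library_concentration,
              x$underrep_threshold, x$spike_to))
  cat(sprintf("  growth %.3g/day (+%.3g/day if advantaged); confluency Day %d-%d\n",
              x$neutral_growth_rate, x$deleterious_advantage,
              x$confluency_day_range[1], x$confluency_day_range[2]))
  cat(sprintf("  depths %d / %d; %d replicate(s); seed %d\n",
              x$depth_init, x$depth_cf, x$n_replicates, x$seed))
  invisible(x)
}

#' Classification thresholds
#'
#' Cutoffs for the three-way functional classification.  Defaults are the
#' published operating points of the assay this package models: on the gamma
#' GLM scale, combined log2 p-values at or below -53.2 are functionally
#' deleterious and at or above -5.8 functionally neutral; on the fold-change
#' scale, mean log2 normalized fold change at or above 1.09 is deleterious and
#' at or below 0.24 neutral (the fold-change cutoffs are the extrema of the
#' benchmark pathogenic / benign sets, see [derive_nfc_thresholds()]).
#'
#' @param fdr_level Benjamini-Hochberg false discovery rate (default 0.05)
#'   used by the adaptive classification mode.
#' @param log2p_deleterious Log2 combined p-value at or below which a variant
#'   is deleterious in paper mode.
#' @param log2p_neutral Log2 combined p-value at or above which a variant is
#'   neutral.
#' @param nfc_neutral_max Log2 normalized fold change at or below which a
#'   variant is neutral.
#' @param nfc_deleterious_min Log2 normalized fold change at or above which a
#'   variant is deleterious.
#'
#' @return A `classification_thresholds` list.
#' @export
classification_thresholds <- function(fdr_level = 0.05,
                                      log2p_deleterious = -53.2,
                                      log2p_neutral = -5.8,
                                      nfc_neutral_max = 0.24,
                                      nfc_deleterious_min = 1.09) {
  check_proportion(fdr_level, "fdr_level")
  check_scalar_number(log2p_deleterious, "log2p_deleterious")
  check_scalar_number(log2p_neutral, "log2p_neutral")
  if (!(log2p_deleterious < log2p_neutral) || log2p_neutral > 0) {
    abort("need log2p_deleterious < log2p_neutral <= 0.")
  }
  check_scalar_number(nfc_neutral_max, "nfc_neutral_max")
  check_scalar_number(nfc_deleterious_min, "nfc_deleterious_min")
  if (!(nfc_neutral_max < nfc_deleterious_min)) {
    abort("need nfc_neutral_max < nfc_deleterious_min.")
  }
  structure(
    list(fdr_level = fdr_level,
         log2p_deleterious = log2p_deleterious,
         log2p_neutral = log2p_neutral,
         nfc_neutral_max = nfc_neutral_max,
         nfc_deleterious_min = nfc_deleterious_min),
    class = "classification_thresholds"
  )
}

#' Synthetic reference protein
#'
#' A deterministic stand-in protein sequence (the 20 amino acids repeated in
#' alphabetical order) used by the simulator to name variants.  It is
#' synthetic: none of the statistics downstream depend on residue identity,
#' only on counts, so any fixed sequence serves.
#'
#' @param n_residues Protein length (default 156).
#' @return Character vector of one-letter amino-acid codes, length
#'   `n_residues`.
#' @export
#' @examples
#' reference_protein(5)
reference_protein <- function(n_residues = 156L) {
  check_scalar_number(n_residues, "n_residues", lower = 1, integerish = TRUE)
  rep_len(AA20, n_residues)
}

#' Enumerate the variant space of a saturation design
#'
#' All single amino-acid variants of a protein: at every residue, the 19
#' missense changes plus the synonymous (reference = alternate) variant.
#' For a 156-residue protein this is 2,964 missense and 3,120 total variants.
#'
#' @param n_residues Protein length.
#' @param reference Reference protein sequence (character vector of
#'   one-letter codes); defaults to [reference_protein()].
#' @return A tibble with columns `residue_index`, `ref_aa`, `alt_aa`,
#'   `variant`, `type` (`"missense"` or `"synonymous"`).
#' @export
#' @examples
#' nrow(enumerate_variants(156))              # 3120
#' sum(enumerate_variants(156)$type == "missense")  # 2964
enumerate_variants <- function(n_residues = 156L,
                               reference = reference_protein(n_residues)) {
  if (length(reference) != n_residues) {
    abort("`reference` length must equal `n_residues`.")
  }
  out <- expand_grid(residue_index = seq_len(n_residues), alt_aa = AA20)
  out$ref_aa <- reference[out$residue_index]
  out$variant <- variant_label(out$ref_aa, out$residue_index, out$alt_aa)
  out$type <- ifelse(out$alt_aa == out$ref_aa, "synonymous", "missense")
  out[, c("residue_index", "ref_aa", "alt_aa", "variant", "type")]
}

#' Reverse-translate a protein to a coding sequence
#'
#' Builds an in-frame CDS encoding `protein`, picking for each amino acid the
#' alphabetically first codon of the standard genetic code.  Used to make
#' reference sequences for read simulation and counting fixtures.
#'
#' @param protein Character vector of one-letter amino-acid codes.
#' @return A single DNA string of length `3 * length(protein)`.
#' @export
protein_to_cds <- function(protein) {
  bad <- setdiff(protein, AA20)
  if (length(bad) > 0L) {
    abort(sprintf("unknown amino acid(s): %s", paste(bad, collapse = ", ")))
  }
  paste(codon_for(protein), collapse = "")
}

# First codon (alphabetically) encoding each amino acid, standard code.
codon_for <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  first <- vapply(split(names(gc), unname(gc)), min, character(1))
  unname(first[aa])
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}
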