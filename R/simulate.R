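# Synthetic pooled-competition assay generator.
#
# Generative model: library proportions ~ symmetric Dirichlet with a wet-lab
# spike-in correction; transduction is a multinomial bottleneck over cells;
# between sampling events variant proportions evolve deterministically as
# p_v(t) proportional to p_v(0) * exp(g_v * t); sequencing at Day 9 and at
# confluency is multinomial at the configured depths.

rdirichlet1 <- function(k, concentration) {
  g <- rgamma(k, shape = concentration, rate = 1)
  g / sum(g)
}

#' Spike-in correction of library proportions
#'
#' Variants drawn at or below the under-representation threshold are raised to
#' the spike proportion (mirroring the wet-lab practice of re-spiking
#' under-represented clones to a calculated 5%) and the vector renormalized.
#' The raise-and-renormalize step repeats until no proportion sits at or below
#' the threshold.
#'
#' @param proportions Numeric vector of library proportions (sums to 1).
#' @param threshold Under-representation threshold (default 0.01).
#' @param spike_to Target proportion before renormalization (default 0.05).
#' @return Corrected proportions summing to 1.
#' @export
#' @examples
#' p <- c(0.005, rep(0.995 / 19, 19))
#' min(apply_spike_in(p))  # ~0.05 / 1.045
apply_spike_in <- function(proportions, threshold = 0.01, spike_to = 0.05) {
  if (spike_to <= threshold) abort("`spike_to` must exceed `threshold`.")
  p <- proportions
  repeat {
    low <- p <= threshold
    if (!any(low)) break
    p[low] <- spike_to
    p <- p / sum(p)
  }
  p
}

#' Draw the variant composition of one residue library
#'
#' Proportions of the 20 variants (19 missense + 1 synonymous) at one residue
#' are drawn from a symmetric Dirichlet and spike-in corrected.
#'
#' @param residue_index 1-based residue position.
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to a substream of `config$seed`.
#' @param reference Reference protein (character vector).
#' @return Tibble: `residue_index`, `ref_aa`, `alt_aa`, `variant`,
#'   `proportion`.
#' @export
make_library_design <- function(residue_index, config = sim_config(),
                                seed = derive_seed(config$seed, residue_index, 1L),
                                reference = reference_protein(config$n_residues)) {
  check_scalar_number(residue_index, "residue_index", lower = 1,
                      upper = config$n_residues, integerish = TRUE)
  withr::local_seed(seed)
  k <- config$variants_per_residue
  alt <- AA20[seq_len(k)]
  ref <- reference[residue_index]
  if (!ref %in% alt) alt[k] <- ref  # synonymous anchor always present
  p <- rdirichlet1(k, config$library_concentration)
  p <- apply_spike_in(p, config$underrep_threshold, config$spike_to)
  tibble(
    residue_index = as.integer(residue_index),
    ref_aa = ref,
    alt_aa = alt,
    variant = variant_label(ref, residue_index, alt),
    proportion = p
  )
}

#' Assign ground-truth growth rates to a library design
#'
#' Each missense variant is independently fitness-advantaged (functionally
#' deleterious: its cells outgrow the pool) with probability
#' `prop_deleterious`; advantaged variants grow at
#' `neutral_growth_rate + deleterious_advantage` per day.  The synonymous
#' variant is always neutral.
#'
#' @param design One or more stacked library designs
#'   (see [make_library_design()]).
#' @param config A [sim_config()].
#' @param prop_deleterious Probability a missense variant is advantaged.
#' @param seed Integer seed.
#' @return Tibble: `residue_index`, `alt_aa`, `variant`, `growth_rate`,
#'   `is_deleterious`.
#' @export
make_fitness_map <- function(design, config = sim_config(),
                             prop_deleterious = 0,
                             seed = derive_seed(config$seed, 0L, 2L)) {
  check_columns(design, c("residue_index", "ref_aa", "alt_aa", "variant"))
  check_scalar_number(prop_deleterious, "prop_deleterious", lower = 0,
                      upper = 1)
  withr::local_seed(seed)
  missense <- design$alt_aa != design$ref_aa
  hit <- missense & (rbinom(nrow(design), 1L, prop_deleterious) == 1L)
  tibble(
    residue_index = design$residue_index,
    alt_aa = design$alt_aa,
    variant = design$variant,
    growth_rate = config$neutral_growth_rate +
      ifelse(hit, config$deleterious_advantage, 0),
    is_deleterious = hit
  )
}

#' Deterministic exponential competition
#'
#' Propagates variant proportions forward `t` days under exponential growth at
#' per-day rates `rates`, renormalizing to the pool.
#'
#' @param p0 Initial proportions.
#' @param rates Per-day growth rates, same length as `p0`.
#' @param t Elapsed days.
#' @return Proportions at day `t`.
#' @export
#' @examples
#' propagate_proportions(c(0.5, 0.5), c(0.2, 0), 10)[1]  # e^2/(e^2+1)
propagate_proportions <- function(p0, rates, t) {
  if (length(p0) != length(rates)) abort("`p0` and `rates` lengths differ.")
  w <- p0 * exp(rates * t)
  w / sum(w)
}

# Core sampling engine shared by assay and CellTag simulations.  The
# confluency day is a library property (it reflects the library's growth
# composition), so replicates of one library pass the same `day_cf`.
sim_counts_engine <- function(p0, rates, config, seed, day_cf = NULL) {
  withr::local_seed(seed)
  if (length(p0) == 0L) abort("empty design.")
  if (config$depth_init <= 0 || config$depth_cf <= 0) abort("zero depth.")
  n0 <- rmultinom(1L, config$n_cells_transduced, p0)[, 1L]
  pc <- n0 / sum(n0)
  if (is.null(day_cf)) {
    day_cf <- sample(seq(config$confluency_day_range[1],
                         config$confluency_day_range[2]), 1L)
  }
  p9 <- propagate_proportions(pc, rates, 9)
  pcf <- propagate_proportions(pc, rates, day_cf)
  list(
    count_day9 = rmultinom(1L, config$depth_init, p9)[, 1L],
    count_confluent = rmultinom(1L, config$depth_cf, pcf)[, 1L],
    day_confluent = day_cf
  )
}

#' Simulate one library's competition assay
#'
#' Cells are assigned to variants by a multinomial draw of
#' `n_cells_transduced`; proportions then evolve deterministically under
#' exponential growth until a confluency day drawn uniformly from
#' `confluency_day_range`; sequencing reads at Day 9 and at confluency are
#' multinomial draws at the configured depths.
#'
#' @param design Library design tibble from [make_library_design()].
#' @param fitness Fitness map from [make_fitness_map()] covering the same
#'   variants.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param library_id,replicate_id Identifiers recorded in the output.
#' @param day_confluent Harvest day; `NULL` draws it from
#'   `confluency_day_range`.  Replicates of the same library should share it
#'   (confluency timing is a property of the library's composition), as
#'   [simulate_screen()] arranges.
#' @return Count-table tibble with columns `library_id`, `replicate_id`,
#'   `residue_index`, `ref_aa`, `alt_aa`, `count_day9`, `count_confluent`,
#'   `day_confluent`.
#' @export
simulate_assay <- function(design, fitness, config = sim_config(),
                           seed = derive_seed(config$seed,
                                              design$residue_index[1], 3L),
                           library_id = sprintf("lib%03d",
                                                design$residue_index[1]),
                           replicate_id = 1L,
                           day_confluent = NULL) {
  check_columns(design, c("residue_index", "ref_aa", "alt_aa", "variant",
                          "proportion"))
  if (nrow(design) == 0L) abort("empty design.")
  key <- design[, c("residue_index", "alt_aa")]
  fit <- inner_join(key, fitness, by = c("residue_index", "alt_aa"))
  if (nrow(fit) != nrow(design)) {
    abort("`fitness` must cover exactly the variants in `design`.")
  }
  cts <- sim_counts_engine(design$proportion, fit$growth_rate, config, seed,
                           day_cf = day_confluent)
  tibble(
    library_id = library_id,
    replicate_id = as.integer(replicate_id),
    residue_index = design$residue_index,
    ref_aa = design$ref_aa,
    alt_aa = design$alt_aa,
    count_day9 = cts$count_day9,
    count_confluent = cts$count_confluent,
    day_confluent = cts$day_confluent
  )
}

#' Simulate the neutral-barcode (CellTag) control experiments
#'
#' The control pool carries 20 non-functional barcodes at equal initial
#' representation in cells already expressing the functional protein, so every
#' barcode is neutral and shares one growth rate.  The experiment is run
#' `n_experiments` times (default 3, the triplicate design used to calibrate
#' the null model).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (default `config$seed`).
#' @param n_experiments Number of independent control experiments.
#' @param n_barcodes Barcodes per pool (default 20).
#' @return Count-table tibble: one block per experiment, `replicate_id` is the
#'   experiment index and `alt_aa` holds the barcode label.
#' @export
simulate_celltag_control <- function(config = sim_config(),
                                     seed = config$seed,
                                     n_experiments = 3L,
                                     n_barcodes = 20L) {
  check_scalar_number(n_experiments, "n_experiments", lower = 1,
                      integerish = TRUE)
  check_scalar_number(n_barcodes, "n_barcodes", lower = 2, integerish = TRUE)
  bc <- sprintf("BC%02d", seq_len(n_barcodes))
  purrr::map(seq_len(n_experiments), function(e) {
    cts <- sim_counts_engine(rep(1 / n_barcodes, n_barcodes),
                             rep(config$neutral_growth_rate, n_barcodes),
                             config, derive_seed(seed, 9000L, e))
    tibble(
      library_id = "celltag",
      replicate_id = as.integer(e),
      residue_index = NA_integer_,
      ref_aa = NA_character_,
      alt_aa = bc,
      count_day9 = cts$count_day9,
      count_confluent = cts$count_confluent,
      day_confluent = cts$day_confluent
    )
  }) |> list_rbind()
}

#' Simulate a full saturation screen
#'
#' Draws a library design and ground-truth fitness for every residue, then
#' simulates `config$n_replicates` assay replicates per library.
#'
#' @param config A [sim_config()].
#' @param prop_deleterious Probability each missense variant is
#'   fitness-advantaged.
#' @param seed Master seed (default `config$seed`).
#' @return List with `counts` (stacked count table) and `truth` (fitness map
#'   with `is_deleterious`).
#' @export
simulate_screen <- function(config = sim_config(), prop_deleterious = 0,
                            seed = config$seed) {
  reference <- reference_protein(config$n_residues)
  designs <- purrr::map(seq_len(config$n_residues), function(i) {
    make_library_design(i, config, seed = derive_seed(seed, i, 1L),
                        reference = reference)
  })
  truth <- make_fitness_map(list_rbind(designs), config, prop_deleterious,
                            seed = derive_seed(seed, 0L, 2L))
  days <- local({
    withr::local_seed(derive_seed(seed, 0L, 4L))
    sample(seq(config$confluency_day_range[1],
               config$confluency_day_range[2]),
           config$n_residues, replace = TRUE)
  })
  counts <- purrr::map(seq_len(config$n_residues), function(i) {
    purrr::map(seq_len(config$n_replicates), function(r) {
      simulate_assay(designs[[i]], truth, config,
                     seed = derive_seed(seed, i, 3L, r),
                     replicate_id = r, day_confluent = days[i])
    }) |> list_rbind()
  }) |> list_rbind()
  list(counts = counts, truth = truth)
}
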