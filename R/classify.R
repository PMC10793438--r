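# Replicate combination, FDR control and three-way functional classification.

#' Combine p-values with Fisher's method
#'
#' Upper tail of a chi-square with 2k degrees of freedom at
#' `-2 * sum(log p)`.  A single p-value passes through unchanged.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param clamp_zero If `TRUE`, p-values of exactly 0 are clamped to the
#'   smallest representable double instead of erroring.
#' @return The combined p-value.
#' @export
#' @examples
#' combine_pvalues_fisher(c(0.1, 0.1))  # 0.05605
combine_pvalues_fisher <- function(p_values, clamp_zero = FALSE) {
  if (length(p_values) == 0L) abort("`p_values` must be non-empty.")
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  if (any(p_values == 0)) {
    if (!clamp_zero) abort("p-value of 0 supplied; see `clamp_zero`.")
    p_values <- pmax(p_values, .Machine$double.xmin)
  }
  exp(fisher_combine_logp(log(p_values)))
}

# Log-space Fisher combination (keeps astronomically small p representable).
fisher_combine_logp <- function(log_p) {
  pchisq(-2 * sum(log_p), df = 2 * length(log_p), lower.tail = FALSE,
         log.p = TRUE)
}

#' Benjamini-Hochberg step-up procedure
#'
#' Standard BH: order the m p-values increasingly, find the largest rank i
#' with `p_(i) <= i/m * level`, and reject all hypotheses at or below it
#' (ties broken stably).  Also reports the largest raw p-value among
#' rejections -- the data-dependent significance cutoff that the adaptive
#' classification mode uses.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param fdr_level Target false discovery rate (default 0.05).
#' @return Tibble `p_value`, `p_adjusted`, `rejected` (input order), with
#'   attribute `p_cutoff` (largest rejected raw p; `NA` when nothing is
#'   rejected).
#' @export
bh_fdr <- function(p_values, fdr_level = 0.05) {
  if (length(p_values) == 0L) abort("`p_values` must be non-empty.")
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  check_proportion(fdr_level, "fdr_level")
  m <- length(p_values)
  ord <- order(p_values)  # stable in R
  ps <- p_values[ord]
  padj_sorted <- rev(cummin(rev(ps * m / seq_len(m))))
  padj_sorted <- pmin(padj_sorted, 1)
  crossing <- which(ps <= seq_len(m) / m * fdr_level)
  k <- if (length(crossing) > 0L) max(crossing) else 0L
  cutoff <- if (k > 0L) ps[k] else NA_real_
  rejected_sorted <- if (k > 0L) ps <= cutoff else rep(FALSE, m)
  out <- tibble(
    p_value = p_values,
    p_adjusted = padj_sorted[order(ord)],
    rejected = rejected_sorted[order(ord)]
  )
  attr(out, "p_cutoff") <- cutoff
  out
}

#' Three-way classification from log2 combined p-values
#'
#' In `"paper"` mode the published fixed cutoffs apply: log2 p at or below
#' `log2p_deleterious` is functionally deleterious, at or above
#' `log2p_neutral` functionally neutral, in between indeterminate.  In
#' `"adaptive"` mode the deleterious cutoff is the data-dependent
#' Benjamini-Hochberg raw-p cutoff (`bh_cutoff`), while the neutral bound
#' stays at `log2p_neutral`.
#'
#' @param log2_p Numeric vector of log2 combined p-values.
#' @param thresholds A [classification_thresholds()].
#' @param mode `"paper"` or `"adaptive"`.
#' @param bh_cutoff Raw-p BH cutoff (required for adaptive mode; `NA` means
#'   no rejections, hence nothing deleterious).
#' @return Factor with levels deleterious, indeterminate, neutral.
#' @export
classify_glm <- function(log2_p, thresholds = classification_thresholds(),
                         mode = c("paper", "adaptive"), bh_cutoff = NULL) {
  mode <- arg_match(mode)
  del_cut <- switch(mode,
    paper = thresholds$log2p_deleterious,
    adaptive = {
      if (is.null(bh_cutoff)) {
        abort("adaptive mode needs `bh_cutoff` (see bh_fdr()).")
      }
      if (is.na(bh_cutoff)) -Inf else log2(bh_cutoff)
    })
  cls <- ifelse(log2_p <= del_cut, "deleterious",
                ifelse(log2_p >= thresholds$log2p_neutral, "neutral",
                       "indeterminate"))
  factor(cls, levels = c("deleterious", "indeterminate", "neutral"))
}

#' Classify assay variants with the gamma GLM null model
#'
#' The full testing pipeline: build synonymous-anchored triplets from the
#' assay count table, compute one-sided upper-tail p-values under the
#' calibrated null, combine replicate p-values per variant with Fisher's
#' method, run Benjamini-Hochberg across all tested variants, and assign the
#' three-way class.
#'
#' @param counts Assay count table (one synonymous anchor per library).
#' @param model Fitted [fit_null()] model.
#' @param thresholds A [classification_thresholds()].
#' @param mode `"paper"` (fixed log2 p cutoffs) or `"adaptive"`
#'   (BH-derived deleterious cutoff).
#' @param pseudocount Passed to [build_triplets()].
#' @return Tibble, one row per tested variant: identifiers, `n_replicates`,
#'   `p_replicates` (list column), `p_combined`, `log2_p`, `p_adjusted`,
#'   `rejected`, `class`; attribute `bh_cutoff`.
#' @export
classify_variants <- function(counts, model,
                              thresholds = classification_thresholds(),
                              mode = c("paper", "adaptive"),
                              pseudocount = 0.5) {
  mode <- arg_match(mode)
  trip <- build_triplets(counts, reference = "synonymous",
                         pseudocount = pseudocount)
  pv <- variant_pvalue(trip, model)
  res <- pv |>
    group_by(.data$variant, .data$residue_index, .data$ref_aa,
             .data$alt_aa) |>
    summarise(
      n_replicates = dplyr::n(),
      p_replicates = list(.data$p_value),
      log2_p = fisher_combine_logp(.data$log_p) / log(2),
      .groups = "drop"
    ) |>
    mutate(p_combined = pmin(2^.data$log2_p, 1))
  # extreme significance underflows to p = 0; clamp for BH only (the step-up
  # decision is unaffected, log2_p retains the information)
  bh <- bh_fdr(pmax(res$p_combined, .Machine$double.xmin),
               thresholds$fdr_level)
  res$p_adjusted <- bh$p_adjusted
  res$rejected <- bh$rejected
  res$class <- classify_glm(res$log2_p, thresholds, mode,
                            bh_cutoff = attr(bh, "p_cutoff"))
  res <- arrange(res, .data$residue_index, .data$alt_aa)
  attr(res, "bh_cutoff") <- attr(bh, "p_cutoff")
  attr(res, "mode") <- mode
  res
}

#' Derive fold-change thresholds from benchmark variants
#'
#' The deleterious cutoff is the minimum log2 normalized fold change over
#' benchmark pathogenic variants; the neutral cutoff is the maximum over
#' benchmark benign variants.
#'
#' @param pathogenic,benign Numeric vectors of benchmark log2 NFC values.
#' @param thresholds Base thresholds whose fold-change cutoffs are replaced.
#' @return A [classification_thresholds()] with updated
#'   `nfc_deleterious_min` / `nfc_neutral_max`.
#' @export
#' @examples
#' th <- derive_nfc_thresholds(c(1.2, 1.09, 1.5), c(0.1, 0.24))
#' c(th$nfc_neutral_max, th$nfc_deleterious_min)  # 0.24, 1.09
derive_nfc_thresholds <- function(pathogenic, benign,
                                  thresholds = classification_thresholds()) {
  if (length(pathogenic) == 0L || length(benign) == 0L) {
    abort("both benchmark sets must be non-empty.")
  }
  thresholds$nfc_deleterious_min <- min(pathogenic)
  thresholds$nfc_neutral_max <- max(benign)
  if (!(thresholds$nfc_neutral_max < thresholds$nfc_deleterious_min)) {
    abort("benchmark sets overlap: max(benign) must be < min(pathogenic).")
  }
  thresholds
}

#' Classify variants by normalized fold change
#'
#' Per library and replicate, each variant's fold change is its share of
#' reads at confluency divided by its share at Day 9; normalized fold change
#' (NFC) divides by the synonymous anchor's fold change at the same residue,
#' so the anchor's own log2 NFC is exactly 0.  Log2 NFC is averaged across
#' replicates.  Classes: deleterious at or above `nfc_deleterious_min`,
#' neutral at or below `nfc_neutral_max`, indeterminate between.
#'
#' @param counts Assay count table.
#' @param thresholds A [classification_thresholds()]; alternatively derive
#'   one from benchmark sets with [derive_nfc_thresholds()].
#' @param pseudocount Added to counts before proportions (default 0.5).
#' @param keep_synonymous Keep anchor rows (log2 NFC 0) in the output?
#' @return Tibble per variant: identifiers, `n_replicates`, `log2_nfc`,
#'   `class`.
#' @export
foldchange_classify <- function(counts,
                                thresholds = classification_thresholds(),
                                pseudocount = 0.5,
                                keep_synonymous = FALSE) {
  check_columns(counts, c("library_id", "replicate_id", "residue_index",
                          "ref_aa", "alt_aa", "count_day9",
                          "count_confluent"))
  per_rep <- counts |>
    group_by(.data$library_id, .data$replicate_id) |>
    dplyr::group_modify(function(g, key) {
      c9 <- g$count_day9 + pseudocount
      ccf <- g$count_confluent + pseudocount
      fc <- (ccf / sum(ccf)) / (c9 / sum(c9))
      syn <- which(g$alt_aa == g$ref_aa)
      if (length(syn) != 1L) {
        abort("missing (or duplicated) synonymous anchor in a library.")
      }
      g$log2_nfc <- log2(fc / fc[syn])
      g
    }) |>
    ungroup()
  res <- per_rep |>
    group_by(.data$residue_index, .data$ref_aa, .data$alt_aa) |>
    summarise(
      variant = variant_label(.data$ref_aa[1], .data$residue_index[1],
                              .data$alt_aa[1]),
      n_replicates = dplyr::n(),
      log2_nfc = mean(.data$log2_nfc),
      .groups = "drop"
    )
  if (!keep_synonymous) res <- filter(res, .data$alt_aa != .data$ref_aa)
  res$class <- factor(
    ifelse(res$log2_nfc >= thresholds$nfc_deleterious_min, "deleterious",
           ifelse(res$log2_nfc <= thresholds$nfc_neutral_max, "neutral",
                  "indeterminate")),
    levels = c("deleterious", "indeterminate", "neutral"))
  res[, c("variant", "residue_index", "ref_aa", "alt_aa", "n_replicates",
          "log2_nfc", "class")]
}

#' Cross-replicate classification concordance
#'
#' Compares the three-way classes assigned to the same variants in two
#' replicates: the full 3x3 cross-tabulation, the percent concordant, and
#' the count of deleterious-vs-neutral flips (the safety-critical
#' discordance; deleterious-vs-indeterminate disagreements are discordant
#' but not flips).
#'
#' @param results_rep1,results_rep2 Classification tibbles (columns
#'   `variant`, `class`) over the same variant set.
#' @return List: `crosstab` (tibble `class_rep1`, `class_rep2`, `n`),
#'   `n` (variants compared), `percent_concordant`, `n_flips`.
#' @export
replicate_concordance <- function(results_rep1, results_rep2) {
  check_columns(results_rep1, c("variant", "class"), "results_rep1")
  check_columns(results_rep2, c("variant", "class"), "results_rep2")
  if (!setequal(results_rep1$variant, results_rep2$variant) ||
      nrow(results_rep1) != nrow(results_rep2)) {
    abort("replicates cover different variant sets.")
  }
  lv <- c("deleterious", "indeterminate", "neutral")
  j <- inner_join(
    tibble(variant = results_rep1$variant,
           class_rep1 = factor(results_rep1$class, levels = lv)),
    tibble(variant = results_rep2$variant,
           class_rep2 = factor(results_rep2$class, levels = lv)),
    by = "variant")
  crosstab <- j |>
    count(.data$class_rep1, .data$class_rep2, name = "n") |>
    complete(class_rep1 = factor(lv, levels = lv),
             class_rep2 = factor(lv, levels = lv),
             fill = list(n = 0L))
  flips <- sum(
    (j$class_rep1 == "deleterious" & j$class_rep2 == "neutral") |
    (j$class_rep1 == "neutral" & j$class_rep2 == "deleterious"))
  list(
    crosstab = crosstab,
    n = nrow(j),
    percent_concordant = 100 * mean(j$class_rep1 == j$class_rep2),
    n_flips = as.integer(flips)
  )
}
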