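# Protein-domain assignment and enrichment of deleterious variants.

#' Ankyrin-repeat domain map of the 156-residue protein
#'
#' The tumor suppressor p16INK4a consists of four ankyrin repeats (ANK1
#' codons 11-40, ANK2 44-72, ANK3 77-106, ANK4 110-139); every other residue
#' belongs to the non-ANK complement.  Optional 10-residue subregions
#' (16-25, 46-55, 80-89) refine repeats 1-3.
#'
#' @param n_residues Protein length (default 156).
#' @param subregions Append the three subregion intervals?
#' @return Tibble: `region`, `start`, `end` (inclusive residue intervals).
#' @export
ankyrin_domains <- function(n_residues = 156L, subregions = FALSE) {
  d <- tibble(
    region = c("ANK1", "ANK2", "ANK3", "ANK4"),
    start = c(11L, 44L, 77L, 110L),
    end = c(40L, 72L, 106L, 139L)
  )
  if (any(d$end > n_residues)) abort("domain intervals exceed protein length.")
  if (subregions) {
    d <- bind_rows(d, tibble(
      region = c("ANK1_16_25", "ANK2_46_55", "ANK3_80_89"),
      start = c(16L, 46L, 80L), end = c(25L, 55L, 89L)))
  }
  d
}

#' Assign residues to protein regions
#'
#' Inclusive-interval lookup against a domain map; residues between the
#' mapped intervals fall in `"non-ANK"`.
#'
#' @param residue_index Integer vector of 1-based residues.
#' @param domains Domain map tibble (`region`, `start`, `end`); subregion
#'   rows are ignored here (primary regions must be disjoint).
#' @param n_residues Protein length for bounds checking.
#' @return Character vector of region names.
#' @export
#' @examples
#' assign_domain(c(50, 107, 1))  # ANK2, non-ANK, non-ANK
assign_domain <- function(residue_index, domains = ankyrin_domains(),
                          n_residues = 156L) {
  if (any(residue_index < 1L | residue_index > n_residues)) {
    abort("residue index out of protein bounds.")
  }
  out <- rep("non-ANK", length(residue_index))
  for (i in seq_len(nrow(domains))) {
    hit <- residue_index >= domains$start[i] & residue_index <= domains$end[i]
    out[hit] <- domains$region[i]
  }
  out
}

#' Domain enrichment of functionally deleterious variants
#'
#' For each region (the four ankyrin repeats plus the non-ANK complement,
#' by default), the fraction of classified variants that are functionally
#' deleterious is compared to the fraction in all other regions with a
#' two-proportion z-test (pooled standard error, two-sided p), Bonferroni
#' corrected by the number of regions tested.
#'
#' @param classes Classification tibble with `residue_index` and `class`.
#' @param domains Domain map (see [ankyrin_domains()]).
#' @param n_residues Protein length.
#' @param regions Regions to test (default: every mapped region plus
#'   `"non-ANK"`); the Bonferroni factor is the number tested.
#' @return Tibble per region: `region`, `n`, `n_deleterious`, `proportion`,
#'   `z`, `p_value`, `p_adjusted`.
#' @export
domain_enrichment <- function(classes, domains = ankyrin_domains(),
                              n_residues = 156L, regions = NULL) {
  check_columns(classes, c("residue_index", "class"))
  x <- tibble(
    region = assign_domain(classes$residue_index, domains, n_residues),
    deleterious = as.character(classes$class) == "deleterious"
  )
  if (is.null(regions)) regions <- unique(c(domains$region, "non-ANK"))
  n_tests <- length(regions)
  purrr::map(regions, function(rg) {
    inr <- x$region == rg
    n1 <- sum(inr); n2 <- sum(!inr)
    if (n1 == 0L) abort(sprintf("region %s has no classified variants.", rg))
    if (n2 == 0L) abort("complement has no classified variants.")
    x1 <- sum(x$deleterious[inr]); x2 <- sum(x$deleterious[!inr])
    p1 <- x1 / n1; p2 <- x2 / n2
    pp <- (x1 + x2) / (n1 + n2)
    se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    z <- if (se == 0) 0 else (p1 - p2) / se
    p <- 2 * pnorm(-abs(z))
    tibble(region = rg, n = n1, n_deleterious = x1, proportion = p1,
           z = z, p_value = p, p_adjusted = min(1, p * n_tests))
  }) |> list_rbind()
}

#' Per-residue deleterious fractions with a bootstrap confidence interval
#'
#' For each residue, the fraction of its missense variants classified
#' functionally deleterious; across residues, the mean fraction with a
#' seeded percentile-bootstrap confidence interval (residues resampled).
#'
#' @param classes Classification tibble with `residue_index`, `ref_aa`,
#'   `alt_aa`, `class` (synonymous rows, if present, are ignored).
#' @param n_bootstrap Bootstrap resamples (default 10,000).
#' @param seed Integer seed for the bootstrap.
#' @param conf_level Confidence level (default 0.95).
#' @return List: `residues` (tibble `residue_index`, `n_missense`,
#'   `n_deleterious`, `fraction`) and `overall` (one-row tibble `mean`,
#'   `ci_lower`, `ci_upper`, `conf_level`, `n_bootstrap`, `seed`).
#' @export
residue_summary <- function(classes, n_bootstrap = 10000L, seed = 1L,
                            conf_level = 0.95) {
  check_columns(classes, c("residue_index", "class"))
  if (all(c("ref_aa", "alt_aa") %in% names(classes))) {
    classes <- filter(classes, .data$alt_aa != .data$ref_aa)
  }
  if (nrow(classes) == 0L) abort("no missense variants to summarize.")
  per <- classes |>
    group_by(.data$residue_index) |>
    summarise(n_missense = dplyr::n(),
              n_deleterious = sum(as.character(.data$class) == "deleterious"),
              .groups = "drop") |>
    mutate(fraction = .data$n_deleterious / .data$n_missense) |>
    arrange(.data$residue_index)
  withr::local_seed(seed)
  nres <- nrow(per)
  boots <- vapply(seq_len(n_bootstrap), function(i) {
    mean(per$fraction[sample.int(nres, nres, replace = TRUE)])
  }, numeric(1))
  alpha <- (1 - conf_level) / 2
  ci <- unname(quantile(boots, c(alpha, 1 - alpha), type = 7))
  list(
    residues = per,
    overall = tibble(mean = mean(per$fraction),
                     ci_lower = ci[1], ci_upper = ci[2],
                     conf_level = conf_level,
                     n_bootstrap = as.integer(n_bootstrap),
                     seed = as.integer(seed))
  )
}
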