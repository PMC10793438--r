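# Benchmarking external variant-effect predictors against functional classes,
# and the assay's contingency statistics.

#' Default binarization cutoffs for common variant-effect predictors
#'
#' Direction-aware cutoffs used by [binarize_scores()].  The source study
#' states none, so these are widely used published defaults and explicitly
#' assumptions: CADD phred >= 20, SIFT < 0.05, VEST >= 0.5, ESM1b < -7.5,
#' PrimateAI-3D >= 0.5 call damaging; PolyPhen-2 is categorical (probably /
#' possibly damaging = damaging) as is AlphaMissense (pathogenic only =
#' damaging; ambiguous groups with tolerated).
#'
#' @return Tibble: `predictor`, `kind` (`"numeric"`/`"categorical"`),
#'   `cutoff`, `direction` (`"ge"`: damaging when score >= cutoff; `"lt"`:
#'   damaging when score < cutoff), `damaging_classes` (list column).
#' @export
default_predictor_cutoffs <- function() {
  tibble(
    predictor = c("CADD", "SIFT", "VEST", "ESM1b", "PrimateAI-3D",
                  "PolyPhen-2", "AlphaMissense"),
    kind = c(rep("numeric", 5), rep("categorical", 2)),
    cutoff = c(20, 0.05, 0.5, -7.5, 0.5, NA, NA),
    direction = c("ge", "lt", "ge", "lt", "ge", NA, NA),
    damaging_classes = list(NULL, NULL, NULL, NULL, NULL,
                            c("probably_damaging", "possibly_damaging"),
                            "pathogenic")
  )
}

#' Binarize predictor scores into damaging / tolerated calls
#'
#' Numeric predictors are thresholded with their direction-aware cutoff
#' (boundary values on the damaging side for `"ge"`, tolerated side for
#' `"lt"`); when several scores exist for one variant-predictor pair they are
#' reduced by their mean before the cutoff.  Categorical predictors map their
#' damaging classes directly; any other category (including "ambiguous" and
#' "benign") maps to tolerated.  Variants with no score for a predictor are
#' excluded from that predictor's calls and tallied in the `n_missing`
#' attribute.
#'
#' @param scores Tibble: `variant`, `predictor`, and `score` (numeric) and/or
#'   `category` (character).
#' @param cutoffs Cutoff table as [default_predictor_cutoffs()].
#' @return Tibble: `variant`, `predictor`, `call`
#'   (`"damaging"`/`"tolerated"`), with attribute `n_missing` (named count of
#'   score-less records per predictor).
#' @export
binarize_scores <- function(scores, cutoffs = default_predictor_cutoffs()) {
  check_columns(scores, c("variant", "predictor"))
  if (!"score" %in% names(scores)) scores$score <- NA_real_
  if (!"category" %in% names(scores)) scores$category <- NA_character_
  unknown <- setdiff(unique(scores$predictor), cutoffs$predictor)
  if (length(unknown) > 0L) {
    abort(sprintf("no cutoff defined for predictor(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  # mean-reduce multiple numeric scores per variant x predictor
  reduced <- scores |>
    group_by(.data$variant, .data$predictor) |>
    summarise(score = if (all(is.na(.data$score))) NA_real_
              else mean(.data$score, na.rm = TRUE),
              category = if (all(is.na(.data$category))) NA_character_
              else .data$category[!is.na(.data$category)][1],
              .groups = "drop")
  miss <- integer(0)
  calls <- purrr::pmap(reduced, function(variant, predictor, score, category) {
    cfg <- cutoffs[cutoffs$predictor == predictor, ]
    if (cfg$kind == "numeric") {
      if (is.na(score)) return(NULL)
      damaging <- if (cfg$direction == "ge") score >= cfg$cutoff
                  else score < cfg$cutoff
    } else {
      if (is.na(category)) return(NULL)
      damaging <- category %in% cfg$damaging_classes[[1]]
    }
    tibble(variant = variant, predictor = predictor,
           call = if (damaging) "damaging" else "tolerated")
  }) |> list_rbind()
  missing_tbl <- reduced |>
    filter(is.na(.data$score) & is.na(.data$category)) |>
    count(.data$predictor, name = "n_missing")
  if (is.null(calls)) calls <- tibble(variant = character(),
                                      predictor = character(),
                                      call = character())
  attr(calls, "n_missing") <- setNames(missing_tbl$n_missing,
                                       missing_tbl$predictor)
  calls
}

#' Confusion metrics of predictor calls against functional truth
#'
#' Functionally deleterious truth is the positive class and a damaging call
#' the positive prediction.  Indeterminate truth variants are excluded by
#' default; alternatively they may be folded into either truth side.
#' Variants without a call for a predictor are excluded from that
#' predictor's table and counted in `n_missing`.
#'
#' @param truth Tibble: `variant`, `class` (deleterious / indeterminate /
#'   neutral).
#' @param calls Tibble from [binarize_scores()] or [ensemble_majority()].
#' @param indeterminate_policy `"exclude"` (default), `"as_damaging_truth"`,
#'   or `"as_tolerated_truth"`.
#' @return Tibble, one row per predictor: `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`, `n_evaluated`,
#'   `n_missing`.
#' @export
confusion_metrics <- function(truth, calls,
                              indeterminate_policy = c("exclude",
                                                       "as_damaging_truth",
                                                       "as_tolerated_truth")) {
  indeterminate_policy <- arg_match(indeterminate_policy)
  check_columns(truth, c("variant", "class"), "truth")
  check_columns(calls, c("variant", "predictor", "call"), "calls")
  truth <- mutate(truth, class = as.character(.data$class))
  truth <- switch(indeterminate_policy,
    exclude = filter(truth, .data$class != "indeterminate"),
    as_damaging_truth = mutate(truth, class = ifelse(
      .data$class == "indeterminate", "deleterious", .data$class)),
    as_tolerated_truth = mutate(truth, class = ifelse(
      .data$class == "indeterminate", "neutral", .data$class)))
  ev <- inner_join(calls, truth, by = "variant")
  if (nrow(ev) == 0L) abort("no evaluable variants (empty truth/call overlap).")
  n_total <- length(unique(truth$variant))
  ev |>
    group_by(.data$predictor) |>
    summarise(
      tp = sum(.data$class == "deleterious" & .data$call == "damaging"),
      fp = sum(.data$class != "deleterious" & .data$call == "damaging"),
      tn = sum(.data$class != "deleterious" & .data$call == "tolerated"),
      fn = sum(.data$class == "deleterious" & .data$call == "tolerated"),
      .groups = "drop"
    ) |>
    mutate(
      sensitivity = .data$tp / (.data$tp + .data$fn),
      specificity = .data$tn / (.data$tn + .data$fp),
      ppv = .data$tp / (.data$tp + .data$fp),
      npv = .data$tn / (.data$tn + .data$fn),
      accuracy = (.data$tp + .data$tn) /
        (.data$tp + .data$fp + .data$tn + .data$fn),
      n_evaluated = .data$tp + .data$fp + .data$tn + .data$fn,
      n_missing = n_total - .data$n_evaluated
    )
}

#' Majority-vote ensemble of predictor calls
#'
#' A variant is called damaging when at least `quorum` of the predictors with
#' an available call for it vote damaging.  By default the quorum is the
#' strict majority of available predictors, `ceiling((k + 1) / 2)`: 4 of 7,
#' 3 of 5.  Quorum 1 is a logical OR, quorum k a logical AND.
#'
#' @param calls Tibble from [binarize_scores()].
#' @param quorum Fixed vote quorum, or `NULL` for the per-variant majority.
#' @return Tibble `variant`, `predictor = "ensemble"`, `call`, `n_available`,
#'   `n_damaging`.
#' @export
ensemble_majority <- function(calls, quorum = NULL) {
  check_columns(calls, c("variant", "predictor", "call"))
  if (!is.null(quorum)) {
    check_scalar_number(quorum, "quorum", lower = 1, integerish = TRUE)
  }
  calls |>
    group_by(.data$variant) |>
    summarise(n_available = dplyr::n(),
              n_damaging = sum(.data$call == "damaging"),
              .groups = "drop") |>
    mutate(
      predictor = "ensemble",
      call = ifelse(
        .data$n_damaging >=
          (if (is.null(quorum)) ceiling((.data$n_available + 1) / 2)
           else quorum),
        "damaging", "tolerated")
    ) |>
    select("variant", "predictor", "call", "n_available", "n_damaging")
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected (no continuity correction) Pearson chi-square with 1 degree of
#' freedom, as used to compare the deleterious fraction between
#' under-represented (< 2% of the pool) and well-represented variants.
#'
#' @param table_2x2 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' contingency_chisq(matrix(c(12, 41, 496, 2415), 2, byrow = TRUE))
contingency_chisq <- function(table_2x2) {
  check_2x2(table_2x2)
  if (any(rowSums(table_2x2) == 0) || any(colSums(table_2x2) == 0)) {
    abort("all margins of the 2x2 table must be positive.")
  }
  ht <- suppressWarnings(chisq.test(table_2x2, correct = FALSE))
  tibble(statistic = unname(ht$statistic), df = 1L,
         p_value = unname(ht$p.value))
}

#' One-sided Fisher exact test on a 2x2 table
#'
#' Hypergeometric lower-tail probability of the top-left cell given fixed
#' margins: the direction tested is depletion in the first row (first row's
#' first-column proportion smaller than the second row's).  Degenerate
#' tables (an all-zero row or column) return p = 1.
#'
#' @param table_2x2 2x2 matrix of non-negative integer counts.
#' @return One-row tibble: `p_value`.
#' @export
#' @examples
#' fisher_exact_one_sided(matrix(c(0, 12, 6, 17), 2, byrow = TRUE))
fisher_exact_one_sided <- function(table_2x2) {
  check_2x2(table_2x2)
  r1 <- sum(table_2x2[1, ]); r2 <- sum(table_2x2[2, ])
  c1 <- sum(table_2x2[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(table_2x2[, 2]) == 0) {
    return(tibble(p_value = 1))
  }
  # log-space lower tail for numerical stability at large counts
  lp <- phyper(table_2x2[1, 1], m = r1, n = r2, k = c1, log.p = TRUE)
  tibble(p_value = min(exp(lp), 1))
}

check_2x2 <- function(x) {
  if (!is.matrix(x) || !all(dim(x) == c(2L, 2L))) {
    abort("`table_2x2` must be a 2x2 matrix.")
  }
  if (any(x < 0) || any(x != round(x))) {
    abort("`table_2x2` must contain non-negative integers.")
  }
  invisible(x)
}
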