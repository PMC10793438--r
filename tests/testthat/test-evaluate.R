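# Predictor benchmarking and contingency statistics.

test_that("score binarization respects direction, boundaries and categories", {
  scores <- tibble::tibble(
    variant = c("A1C", "A1D", "A1E", "A1F", "A1G", "A1H"),
    predictor = c("CADD", "CADD", "SIFT", "PolyPhen-2", "AlphaMissense",
                  "VEST"),
    score = c(20, 10, 0.05, NA, NA, NA),
    category = c(NA, NA, NA, "ambiguous", "pathogenic", NA))
  calls <- binarize_scores(scores)
  get <- function(v) calls$call[calls$variant == v]
  expect_equal(get("A1C"), "damaging")    # boundary: >= cutoff is damaging
  expect_equal(get("A1D"), "tolerated")
  expect_equal(get("A1E"), "tolerated")   # SIFT boundary: < 0.05 is damaging
  expect_equal(get("A1F"), "tolerated")   # ambiguous groups with tolerated
  expect_equal(get("A1G"), "damaging")
  expect_false("A1H" %in% calls$variant)  # missing score -> excluded
  expect_equal(unname(attr(calls, "n_missing")["VEST"]), 1L)
  # multiple scores reduce by mean before the cutoff
  multi <- tibble::tibble(variant = "A1C", predictor = "CADD",
                          score = c(30, 14), category = NA)
  expect_equal(binarize_scores(multi)$call, "damaging")  # mean 22 >= 20
  expect_error(binarize_scores(tibble::tibble(variant = "x",
                                              predictor = "mystery",
                                              score = 1)), "no cutoff")
})

test_that("confusion metrics reproduce hand-computed values and stay consistent", {
  # truth 10 deleterious / 90 neutral; calls: 9 TP, 1 FN, 30 FP, 60 TN
  truth <- tibble::tibble(
    variant = sprintf("V%03d", 1:100),
    class = rep(c("deleterious", "neutral"), c(10, 90)))
  calls <- tibble::tibble(
    variant = truth$variant, predictor = "toy",
    call = c(rep("damaging", 9), "tolerated",
             rep("damaging", 30), rep("tolerated", 60)))
  m <- confusion_metrics(truth, calls)
  expect_equal(m$tp, 9); expect_equal(m$fn, 1)
  expect_equal(m$fp, 30); expect_equal(m$tn, 60)
  expect_equal(m$sensitivity, 0.90)
  expect_equal(m$specificity, 2 / 3, tolerance = 1e-3)
  expect_equal(m$ppv, 9 / 39, tolerance = 1e-3)
  expect_equal(m$npv, 60 / 61, tolerance = 1e-3)
  expect_equal(m$accuracy, 0.69)
  # metrics recompute exactly from the returned counts
  expect_equal(m$accuracy, (m$tp + m$tn) / (m$tp + m$fp + m$tn + m$fn),
               tolerance = 1e-12)
  expect_equal(m$sensitivity, m$tp / (m$tp + m$fn), tolerance = 1e-12)
  # perfect predictor: all five metrics 1
  perfect <- dplyr::mutate(calls, call = ifelse(
    truth$class == "deleterious", "damaging", "tolerated"))
  mp <- confusion_metrics(truth, perfect)
  expect_equal(unlist(mp[, c("sensitivity", "specificity", "ppv", "npv",
                             "accuracy")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1,
                 accuracy = 1))
})

test_that("indeterminate truth variants follow the chosen policy", {
  truth <- tibble::tibble(variant = c("a", "b", "c"),
                          class = c("deleterious", "indeterminate", "neutral"))
  calls <- tibble::tibble(variant = c("a", "b", "c"), predictor = "toy",
                          call = c("damaging", "damaging", "tolerated"))
  expect_equal(confusion_metrics(truth, calls)$n_evaluated, 2)
  expect_equal(confusion_metrics(truth, calls, "as_damaging_truth")$tp, 2)
  expect_equal(confusion_metrics(truth, calls, "as_tolerated_truth")$fp, 1)
})

test_that("majority-vote ensemble honors quorums including OR and AND", {
  calls <- tibble::tibble(
    variant = rep(c("v1", "v2", "v3"), c(7, 7, 5)),
    predictor = c(paste0("P", 1:7), paste0("P", 1:7), paste0("P", 1:5)),
    call = c(rep("damaging", 4), rep("tolerated", 3),    # 4/7
             rep("tolerated", 7),                        # 0/7
             rep("damaging", 3), rep("tolerated", 2)))   # 3/5
  # the cutoff table only needs names here; calls are already binary
  ens <- ensemble_majority(calls)
  expect_equal(ens$call[ens$variant == "v1"], "damaging")   # 4 of 7
  expect_equal(ens$call[ens$variant == "v2"], "tolerated")  # 0 of 7
  expect_equal(ens$call[ens$variant == "v3"], "damaging")   # 3 of 5
  # quorum 1 behaves as OR; quorum = k as AND
  or1 <- ensemble_majority(calls, quorum = 1)
  any_dmg <- tapply(calls$call == "damaging", calls$variant, any)
  expect_equal(or1$call,
               unname(ifelse(as.vector(any_dmg[or1$variant]),
                             "damaging", "tolerated")))
  and7 <- ensemble_majority(calls, quorum = 7)
  expect_equal(and7$call[and7$variant == "v1"], "tolerated")
})

test_that("chi-square matches the O/E oracle and the published table", {
  # published comparison: under- vs well-represented variants
  tab <- matrix(c(12, 41, 496, 2415), 2, byrow = TRUE)
  got <- contingency_chisq(tab)
  expect_equal(round(got$p_value, 2), 0.28)  # printed precision
  # direct sum((O - E)^2 / E) oracle
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(got$statistic, sum((tab - E)^2 / E), tolerance = 1e-10)
  # identical row proportions: statistic 0, p = 1
  flat <- contingency_chisq(matrix(c(10, 30, 20, 60), 2, byrow = TRUE))
  expect_equal(flat$statistic, 0, tolerance = 1e-12)
  expect_equal(flat$p_value, 1)
  expect_error(contingency_chisq(matrix(c(0, 0, 5, 5), 2)), "margins")
})

test_that("one-sided Fisher exact matches full hypergeometric enumeration", {
  # published table: colorectal cases with/without mismatch-repair mutations
  expect_equal(round(fisher_exact_one_sided(
    matrix(c(0, 12, 6, 17), 2, byrow = TRUE))$p_value, 3),
    0.062)  # printed precision
  # enumeration oracle over all tables with N <= 40 (margins scanned)
  enum_oracle <- function(tab) {
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
    xs <- max(0, c1 - r2):min(r1, c1)
    probs <- choose(r1, xs) * choose(r2, c1 - xs) / choose(r1 + r2, c1)
    sum(probs[xs <= tab[1, 1]])
  }
  withr::with_seed(13, {
    for (i in 1:200) {
      tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
      if (sum(tab) == 0 || sum(tab) > 40) next
      got <- fisher_exact_one_sided(tab)$p_value
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        expect_equal(got, 1)
      } else {
        expect_equal(got, enum_oracle(tab), tolerance = 1e-10)
      }
    }
  })
  # all-zero row is degenerate: p = 1
  expect_equal(fisher_exact_one_sided(
    matrix(c(0, 0, 5, 7), 2, byrow = TRUE))$p_value, 1)
})
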