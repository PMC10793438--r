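# Fisher combination, BH, three-way classes, fold change, concordance.

test_that("Fisher's method matches the chi-square tail", {
  expect_equal(combine_pvalues_fisher(0.3), 0.3)               # k = 1 identity
  # (0.1, 0.1): chi2_4 upper tail at -2 * 2 * log(0.1) = e^{-x/2}(1 + x/2)
  x <- -2 * sum(log(c(0.1, 0.1)))
  expect_equal(combine_pvalues_fisher(c(0.1, 0.1)),
               exp(-x / 2) * (1 + x / 2), tolerance = 1e-10)
  expect_equal(combine_pvalues_fisher(c(0.1, 0.1)), 0.05605, tolerance = 1e-4)
  expect_equal(combine_pvalues_fisher(c(1, 1, 1)), 1)
  expect_error(combine_pvalues_fisher(c(0.5, 0)), "0")
  expect_gt(combine_pvalues_fisher(c(0.5, 0), clamp_zero = TRUE), 0)
})

test_that("BH agrees with the exhaustive step-up oracle on all short inputs", {
  expect_equal(sum(bh_fdr(c(0.001, 0.02, 0.03, 0.9), 0.05)$rejected), 3L)
  expect_equal(sum(bh_fdr(rep(1, 6), 0.05)$rejected), 0L)
  withr::with_seed(99, {
    for (i in 1:200) {
      n <- sample(1:8, 1)
      p <- round(runif(n), 3)
      p[p == 0] <- 0.001
      if (sample(c(TRUE, FALSE), 1)) p[sample(n, 1)] <- p[1]  # force ties
      level <- sample(c(0.01, 0.05, 0.1, 0.25), 1)
      got <- bh_fdr(p, level)
      expect_identical(got$rejected, bh_oracle(p, level))
      expect_equal(got$p_adjusted, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    }
  })
})

test_that("BH rejections are monotone in the level and report the raw cutoff", {
  withr::with_seed(7, {
    for (i in 1:50) {
      p <- runif(sample(2:30, 1))
      r1 <- bh_fdr(p, 0.01); r5 <- bh_fdr(p, 0.05)
      expect_true(all(!r1$rejected | r5$rejected))  # level-0.01 set nested
    }
  })
  r <- bh_fdr(c(0.001, 0.02, 0.03, 0.9), 0.05)
  expect_equal(attr(r, "p_cutoff"), 0.03)
  expect_true(is.na(attr(bh_fdr(rep(0.9, 3), 0.05), "p_cutoff")))
})

test_that("paper-mode log2 p cutoffs classify with the published inequalities", {
  th <- classification_thresholds()
  cls <- classify_glm(c(-60, -19.3, -3), th, mode = "paper")
  expect_equal(as.character(cls),
               c("deleterious", "indeterminate", "neutral"))
  # boundaries are inclusive on the deleterious/neutral sides
  expect_equal(as.character(classify_glm(c(-53.2, -5.8), th, "paper")),
               c("deleterious", "neutral"))
  # adaptive mode replaces the deleterious cutoff with the BH raw-p cutoff
  ad <- classify_glm(log2(c(0.001, 0.01, 0.5)), th, "adaptive",
                     bh_cutoff = 0.005)
  expect_equal(as.character(ad), c("deleterious", "indeterminate", "neutral"))
  expect_equal(as.character(classify_glm(-300, th, "adaptive",
                                         bh_cutoff = NA_real_)),
               "indeterminate")  # no rejections: nothing is deleterious
  expect_error(classify_glm(-3, th, "adaptive"), "bh_cutoff")
})

test_that("fold-change classifier normalizes to the synonymous anchor", {
  counts <- toy_counts()
  fc <- foldchange_classify(counts, pseudocount = 0)
  # C: proportion doubles while others static; anchor A is flat
  # hand computation: shares 9 = (1000,1000,500,2000)/4500;
  # shares cf = (1000,4000,500,2000)/7500; FC_C/FC_A = 4
  expect_equal(fc$log2_nfc[fc$alt_aa == "C"], 2, tolerance = 1e-12)
  expect_equal(fc$class[fc$alt_aa == "C"], factor("deleterious",
    levels = c("deleterious", "indeterminate", "neutral")))
  # variants with the anchor's dynamics sit at exactly 0 -> neutral
  expect_equal(fc$log2_nfc[fc$alt_aa == "D"], 0, tolerance = 1e-12)
  expect_equal(as.character(fc$class[fc$alt_aa == "D"]), "neutral")
  # the anchor itself is exactly 0 in every library
  fc_syn <- foldchange_classify(counts, pseudocount = 0,
                                keep_synonymous = TRUE)
  expect_equal(fc_syn$log2_nfc[fc_syn$alt_aa == "A"], 0)
  # missing anchor is an error
  expect_error(foldchange_classify(counts[counts$alt_aa != "A", ]),
               "synonymous anchor")
})

test_that("benchmark extrema set the fold-change thresholds", {
  th <- derive_nfc_thresholds(pathogenic = c(1.2, 1.09, 1.5),
                              benign = c(0.1, 0.24))
  expect_equal(th$nfc_deleterious_min, 1.09)
  expect_equal(th$nfc_neutral_max, 0.24)
  expect_error(derive_nfc_thresholds(c(0.2), c(0.5)), "overlap")
})

test_that("replicate concordance counts flips and preserves margins", {
  lv <- c("deleterious", "indeterminate", "neutral")
  r1 <- tibble::tibble(variant = sprintf("V%d", 1:6),
                       class = factor(lv[c(1, 1, 2, 3, 3, 3)], levels = lv))
  expect_equal(replicate_concordance(r1, r1)$percent_concordant, 100)
  expect_equal(replicate_concordance(r1, r1)$n_flips, 0L)
  r2 <- r1
  r2$class <- factor(lv[c(2, 1, 2, 3, 1, 3)], levels = lv)
  cc <- replicate_concordance(r1, r2)
  # V1 deleterious->indeterminate: discordant but NOT a flip;
  # V5 neutral->deleterious: a flip
  expect_equal(cc$n_flips, 1L)
  expect_equal(cc$percent_concordant, 100 * 4 / 6, tolerance = 1e-10)
  # crosstab margins equal each replicate's class totals
  ct <- cc$crosstab
  m1 <- tapply(ct$n, ct$class_rep1, sum)
  expect_equal(as.integer(m1[lv]), as.integer(table(r1$class)[lv]))
  m2 <- tapply(ct$n, ct$class_rep2, sum)
  expect_equal(as.integer(m2[lv]), as.integer(table(r2$class)[lv]))
  expect_error(replicate_concordance(r1, r2[1:5, ]), "different variant")
})

test_that("BH controls FDR when p-values are calibrated", {
  # nulls drawn uniform, signals at p ~ 0: realized FDP among rejections
  # averaged over seeds stays within 2 MC standard errors of the level
  fdps <- withr::with_seed(11, vapply(1:40, function(i) {
    p <- c(runif(850), rep(1e-12, 150))
    truth_null <- c(rep(TRUE, 850), rep(FALSE, 150))
    r <- bh_fdr(p, 0.05)$rejected
    if (any(r)) sum(r & truth_null) / sum(r) else 0
  }, numeric(1)))
  mc_se <- sd(fdps) / sqrt(length(fdps))
  expect_lte(mean(fdps), 0.05 + 2 * mc_se)
})

test_that("the glm pipeline classifies a calibrated simulated screen sensibly", {
  cfg <- tiny_config(depth_init = 1e5, depth_cf = 1e5,
                     library_concentration = 1e9)
  ctrl <- simulate_celltag_control(cfg, seed = 5)
  m <- fit_null(build_triplets(ctrl, "all"))
  sc <- simulate_screen(cfg, prop_deleterious = 0.25, seed = 5)
  res <- classify_variants(sc$counts, m, mode = "adaptive")
  expect_equal(nrow(res), 5 * 19)
  j <- dplyr::inner_join(res, sc$truth, by = c("residue_index", "alt_aa"))
  # every truly advantaged variant is detected at these effect sizes
  expect_true(all(j$class[j$is_deleterious] == "deleterious"))
  expect_true(all(j$p_combined >= 0 & j$p_combined <= 1))
  expect_s3_class(res$class, "factor")
})
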