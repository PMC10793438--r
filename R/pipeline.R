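# End-to-end orchestration: simulate -> calibrate -> classify -> summarize.

#' Pipeline configuration
#'
#' Validated bag of pipeline parameters.  Unknown keys are rejected so typos
#' fail before any computation.  `control_counts` may be a count table, a
#' TSV path, or `NULL` (controls are then simulated); likewise
#' `assay_counts` (`NULL` simulates a screen with `prop_deleterious`
#' advantaged variants).
#'
#' @param sim A [sim_config()].
#' @param thresholds A [classification_thresholds()].
#' @param mode Classification mode, `"paper"` or `"adaptive"`.
#' @param prop_deleterious Fraction of missense variants simulated as
#'   fitness-advantaged when `assay_counts` is NULL.
#' @param control_counts,assay_counts Optional inputs (tibble or TSV path).
#' @param n_control_experiments Control experiments to simulate (default 3).
#' @param pseudocount Pseudocount for ratios.
#' @param seed Master seed; defaults to `sim$seed`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            thresholds = classification_thresholds(),
                            mode = c("adaptive", "paper"),
                            prop_deleterious = 0.15,
                            control_counts = NULL,
                            assay_counts = NULL,
                            n_control_experiments = 3L,
                            pseudocount = 0.5,
                            seed = sim$seed) {
  mode <- arg_match(mode)
  if (!inherits(sim, "sim_config")) abort("`sim` must be a sim_config.")
  if (!inherits(thresholds, "classification_thresholds")) {
    abort("`thresholds` must be a classification_thresholds.")
  }
  check_scalar_number(prop_deleterious, "prop_deleterious", lower = 0,
                      upper = 1)
  for (nm in c("control_counts", "assay_counts")) {
    v <- get(nm)
    if (!is.null(v) && !is.data.frame(v)) {
      if (!(is.character(v) && length(v) == 1L)) {
        abort(sprintf("`%s` must be a tibble, a TSV path, or NULL.", nm))
      }
      if (!file.exists(v)) {
        abort(sprintf("`%s` path does not exist: %s", nm, v))
      }
    }
  }
  structure(
    list(sim = sim, thresholds = thresholds, mode = mode,
         prop_deleterious = prop_deleterious,
         control_counts = control_counts, assay_counts = assay_counts,
         n_control_experiments = as.integer(n_control_experiments),
         pseudocount = pseudocount, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Stages, in order: obtain control count tables (simulate or load), build
#' all-reference triplets and calibrate the gamma GLM null; obtain assay
#' count tables (simulate or load); compute per-variant p-values, Fisher
#' combination, Benjamini-Hochberg and classes; run the fold-change
#' classifier; summarize classes per residue and per domain.  When
#' `out_dir` is given, every table is written as TSV, the model and a
#' provenance record (config echo, seed, package version) as JSON; identical
#' config and seed give byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param quiet Suppress the one-line-per-stage progress log?
#' @return Invisible list: `control_counts`, `model`, `assay_counts`,
#'   `truth` (when simulated), `glm_results`, `fc_results`, `enrichment`,
#'   `residues`, `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a pipeline_config (see pipeline_config()).")
  }
  log_stage <- function(...) if (!quiet) rlang::inform(sprintf(...))
  load_or <- function(x, simulate) {
    if (is.null(x)) return(simulate())
    if (is.character(x)) read_count_table(x) else as_tibble(x)
  }
  controls <- load_or(config$control_counts, function() {
    simulate_celltag_control(config$sim, seed = derive_seed(config$seed, 1L),
                             n_experiments = config$n_control_experiments)
  })
  log_stage("[controls] %d rows, %d experiment(s), seed %d",
            nrow(controls), length(unique(controls$replicate_id)),
            config$seed)
  model <- fit_null(build_triplets(controls, reference = "all",
                                   pseudocount = config$pseudocount))
  log_stage("[calibrate] gamma null: shape %.3g, a %.3g, b %.3g (n = %d)",
            model$shape, model$exp_rinit, model$exp_pinit, model$n)
  truth <- NULL
  assay <- load_or(config$assay_counts, function() {
    sc <- simulate_screen(config$sim, config$prop_deleterious,
                          seed = derive_seed(config$seed, 2L))
    truth <<- sc$truth
    sc$counts
  })
  log_stage("[assay] %d rows across %d libraries", nrow(assay),
            length(unique(assay$library_id)))
  glm_results <- classify_variants(assay, model, config$thresholds,
                                   mode = config$mode,
                                   pseudocount = config$pseudocount)
  log_stage("[classify] %d variants tested (%s mode): %s",
            nrow(glm_results), config$mode,
            paste(sprintf("%s %d", levels(glm_results$class),
                          table(glm_results$class)), collapse = ", "))
  fc_results <- foldchange_classify(assay, config$thresholds,
                                    pseudocount = config$pseudocount)
  n_res <- max(assay$residue_index, na.rm = TRUE)
  domains <- ankyrin_domains(max(n_res, 156L))
  # enrichment needs classified variants both inside and outside a region;
  # small screens confined to one region skip it
  present <- unique(assign_domain(glm_results$residue_index, domains,
                                  n_residues = max(n_res, 156L)))
  enrichment <- if (length(present) >= 2L) {
    domain_enrichment(glm_results, domains, n_residues = max(n_res, 156L),
                      regions = present)
  } else {
    NULL
  }
  residues <- residue_summary(glm_results, n_bootstrap = 2000L,
                              seed = derive_seed(config$seed, 3L))
  provenance <- list(
    package = "mavenull",
    version = as.character(packageVersion("mavenull")),
    seed = config$seed,
    mode = config$mode,
    thresholds = unclass(config$thresholds),
    sim = unclass(config$sim),
    prop_deleterious = config$prop_deleterious,
    pseudocount = config$pseudocount,
    n_variants_tested = nrow(glm_results),
    bh_cutoff = attr(glm_results, "bh_cutoff")
  )
  bundle <- list(control_counts = controls, model = model,
                 assay_counts = assay, truth = truth,
                 glm_results = glm_results, fc_results = fc_results,
                 enrichment = enrichment, residues = residues,
                 provenance = provenance)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_count_table(controls, file.path(out_dir, "control_counts.tsv"))
    write_count_table(assay, file.path(out_dir, "assay_counts.tsv"))
    write_null_model(model, file.path(out_dir, "null_model.json"))
    write_results_tsv(glm_results, file.path(out_dir, "glm_results.tsv"))
    readr::write_tsv(fc_results, file.path(out_dir, "foldchange_results.tsv"),
                     na = ".")
    if (!is.null(enrichment)) {
      readr::write_tsv(enrichment,
                       file.path(out_dir, "domain_enrichment.tsv"), na = ".")
    }
    readr::write_tsv(residues$residues,
                     file.path(out_dir, "residue_summary.tsv"), na = ".")
    if (!is.null(truth)) {
      readr::write_tsv(truth, file.path(out_dir, "ground_truth.tsv"), na = ".")
    }
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(bundle)
}
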