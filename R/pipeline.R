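#' Run the full screening pipeline on a synthetic study
#'
#' Orchestrates every stage end-to-end on generated data with known
#' ground truth: simulate a correlated exposure panel and outcome,
#' univariable screen (with Q, Egger, Steiger), PRESSO on the
#' top-ranked exposure, colocalization of a simulated locus,
#' model-averaging ranking (nominally significant exposures) and
#' identification (all exposures), a two-step mediation triad, the
#' specificity screen against simulated null outcomes, and the consensus
#' table.  All randomness derives from `config$seed`, so identical
#' configurations give byte-identical stage outputs; when `out_dir` is
#' given, every stage table is written as TSV along with a
#' machine-readable JSON run report and a plain-text summary.
#'
#' @param config An [mr_config()].
#' @param out_dir Optional output directory (created if needed).
#' @param n_exposures,n_variants Synthetic panel dimensions.
#' @param causal_effect True causal effect of the first exposure.
#' @param netmoss Optional tibble `exposure_id, score` of external
#'   network scores.
#' @return A list of stage results (`screen`, `presso`, `coloc`,
#'   `bma_ranking`, `bma_identification`, `mediation`, `specificity`,
#'   `consensus`, `report`), invisibly when writing to disk.
#' @export
run_pipeline <- function(config = mr_config(), out_dir = NULL,
                         n_exposures = 5, n_variants = 60,
                         causal_effect = -0.25, netmoss = NULL) {
  report <- list(settings = unclass(config),
                 sizes = list(n_exposures = n_exposures,
                              n_variants = n_variants,
                              causal_effect = causal_effect),
                 stages = list())
  results <- list()
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      report$stages[[name]] <<- list(status = "failed",
                                     error = conditionMessage(e))
      NULL
    })
    if (!is.null(res)) report$stages[[name]] <<- list(status = "ok")
    res
  }

  sim <- run_stage("simulate", simulate_multivariable(
    n_variants = n_variants, n_exposures = n_exposures,
    causal_subset = 1, causal_effects = causal_effect,
    seed = derive_seed(config$seed, "panel")))

  results$screen <- run_stage("univariable", {
    run_univariable_screen(sim$exposures, sim$outcome, config)
  })

  results$presso <- run_stage("presso", {
    top_id <- results$screen$exposure_id[which.min(results$screen$pvalue)]
    sel <- select_instruments(sim$exposures[[top_id]], config$iv_p_microbe)
    h <- harmonize(sel, sim$outcome, config$palindrome_maf, config$f_min)
    mr_presso(h, n_simulations = config$presso_n_sim,
              seed = derive_seed(config$seed, "presso"),
              outlier_alpha = config$presso_outlier_alpha)
  })

  results$coloc <- run_stage("coloc", {
    region <- simulate_coloc_region(
      scenario = "distinct_causal",
      seed = derive_seed(config$seed, "coloc"))
    colocalize(region$trait1, region$trait2,
               p1 = config$coloc_p1, p2 = config$coloc_p2,
               p12 = config$coloc_p12,
               prior_sd1 = config$coloc_prior_sd,
               prior_sd2 = config$coloc_prior_sd,
               pp_h4_threshold = config$pp_h4)
  })

  bma_in <- run_stage("bma_input", prepare_bma_input(
    sim$exposures, sim$outcome, p_threshold = config$iv_p_microbe,
    correlation_bound = config$corr_prune,
    palindrome_maf = config$palindrome_maf, f_min = config$f_min))

  results$bma_identification <- run_stage("bma_identification", {
    bma_rank(bma_in, prior_prob = config$bma_prior_prob,
             prior_sd = config$bma_prior_sd,
             search_budget = config$bma_budget,
             seed = derive_seed(config$seed, "bma_id"),
             mip_threshold = config$mip_threshold, top_k = config$top_k)
  })

  results$bma_ranking <- run_stage("bma_ranking", {
    nominal <- results$screen$exposure_id[
      !is.na(results$screen$pvalue) &
        results$screen$pvalue < config$potential_alpha]
    if (length(nominal) >= 2) {
      bma_rank(prepare_bma_input(
        sim$exposures[nominal], sim$outcome,
        p_threshold = config$iv_p_microbe,
        correlation_bound = config$corr_prune,
        palindrome_maf = config$palindrome_maf, f_min = config$f_min),
        prior_prob = config$bma_prior_prob, prior_sd = config$bma_prior_sd,
        search_budget = config$bma_budget,
        seed = derive_seed(config$seed, "bma_rank"),
        mip_threshold = config$mip_threshold, top_k = config$top_k)
    } else {
      results$bma_identification
    }
  })

  results$mediation <- run_stage("mediation", {
    triad <- simulate_mediation(seed = derive_seed(config$seed, "mediation"))
    direction_consistency(run_two_step(
      triad$exposure, triad$mediator, triad$outcome, config))
  })

  results$specificity <- run_stage("specificity", {
    null_outcomes <- lapply(seq_len(2), function(i) {
      simulate_multivariable(
        n_variants = n_variants, n_exposures = n_exposures,
        causal_subset = integer(0),
        seed = derive_seed(config$seed, paste0("null_outcome", i)))$outcome
    })
    specificity_screen(sim$exposures, null_outcomes,
                       alpha = config$potential_alpha, config = config)
  })

  results$consensus <- run_stage("consensus", build_evidence_table(
    results$screen, results$bma_ranking, results$bma_identification,
    netmoss = netmoss, specificity = results$specificity, config = config))

  report$counts <- list(
    exposures_screened = nrow(results$screen),
    significant_fdr = sum(results$screen$tier == "significant_fdr"),
    potential = sum(results$screen$tier %in%
                      c("significant_fdr", "potential")),
    presso_outliers = length(results$presso$outlier_ids),
    robust_exposures = sum(results$consensus$robust)
  )
  results$report <- report

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_stage <- function(df, name) {
      readr::write_tsv(as_tibble(df), file.path(out_dir, name),
                       progress = FALSE)
    }
    write_stage(results$screen, "screen.tsv")
    write_stage(glance(results$presso), "presso.tsv")
    write_stage(tidy(results$coloc), "coloc.tsv")
    write_stage(results$bma_ranking$ranking, "bma_ranking.tsv")
    write_stage(results$bma_identification$ranking, "bma_identification.tsv")
    write_stage(results$mediation, "mediation.tsv")
    write_stage(results$specificity, "specificity.tsv")
    write_stage(results$consensus %>%
                  select(-dplyr::any_of("estimates")), "consensus.tsv")
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    summary_lines <- c(
      "Synthetic screening pipeline summary",
      sprintf("seed: %d", config$seed),
      sprintf("exposures screened: %d", report$counts$exposures_screened),
      sprintf("FDR-significant exposures: %d", report$counts$significant_fdr),
      sprintf("PRESSO outliers flagged: %d", report$counts$presso_outliers),
      sprintf("robust exposures (>= %d methods): %d", config$min_methods,
              report$counts$robust_exposures),
      sprintf("mediation pathway consistent: %s",
              results$mediation$direction_consistent)
    )
    writeLines(summary_lines, file.path(out_dir, "summary.txt"))
    return(invisible(results))
  }
  results
}
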