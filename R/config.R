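#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with the study's
#' standard settings as defaults: instrument p-value 1e-5 for microbial
#' exposures and 5e-8 for well-powered (dietary/disease) traits, F >= 10,
#' LD clumping at r-squared 0.01 within 10,000 kb, palindrome
#' minor-allele-frequency limit 0.3, FDR significance at 0.2 and
#' potential significance at 0.05, colocalization PP.H4 threshold 0.8,
#' MIP threshold 0.1 with top-10 identification, exposure-correlation
#' pruning at 0.985, model-averaging prior probability 0.1 and prior SD
#' 0.5 with a 10,000-model search budget, and a 3-of-4 consensus rule.
#'
#' @param ... Named overrides of the defaults listed above.
#' @return A named list of class `mr_config`.
#' @export
mr_config <- function(...) {
  defaults <- list(
    iv_p_microbe = 1e-5, iv_p_other = 5e-8, f_min = 10,
    clump_r2 = 0.01, clump_window_kb = 10000, palindrome_maf = 0.3,
    fdr_alpha = 0.2, potential_alpha = 0.05,
    pp_h4 = 0.8, coloc_p1 = 1e-4, coloc_p2 = 1e-4, coloc_p12 = 1e-5,
    coloc_prior_sd = 0.15,
    mip_threshold = 0.1, top_k = 10, corr_prune = 0.985,
    bma_prior_prob = 0.1, bma_prior_sd = 0.5, bma_budget = 10000,
    presso_n_sim = 1000, presso_outlier_alpha = 0.05,
    min_methods = 3, netmoss_score_threshold = 1,
    seed = 1
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort_mrscreen(sprintf("unknown config field(s): %s",
                           paste(unknown, collapse = ", ")),
                   class = "mrscreen_config_error")
  }
  cfg <- modifyList(defaults, overrides)
  with(cfg, stopifnot(
    iv_p_microbe > 0, iv_p_microbe < 1, iv_p_other > 0, iv_p_other < 1,
    f_min >= 0, clump_r2 > 0, clump_r2 < 1, clump_window_kb > 0,
    palindrome_maf > 0, palindrome_maf <= 0.5,
    fdr_alpha > 0, fdr_alpha <= 1, potential_alpha > 0, potential_alpha <= 1,
    pp_h4 > 0, pp_h4 < 1, mip_threshold > 0, mip_threshold < 1,
    top_k >= 1, corr_prune > 0, corr_prune <= 1,
    bma_prior_prob > 0, bma_prior_prob < 1, bma_prior_sd > 0,
    bma_budget >= 1, presso_n_sim >= 1,
    presso_outlier_alpha > 0, presso_outlier_alpha < 1, min_methods >= 1
  ))
  structure(cfg, class = "mr_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Reads a flat YAML mapping of configuration fields and validates it
#' through [mr_config()]; unknown fields and out-of-domain values raise
#' configuration errors.
#'
#' @param path Path to a YAML file.
#' @return An `mr_config`.
#' @export
mr_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort_mrscreen("the 'yaml' package is required to read YAML configs",
                   class = "mrscreen_config_error")
  }
  fields <- yaml::read_yaml(path)
  if (!is.list(fields)) {
    abort_mrscreen("YAML config must be a mapping of field: value pairs",
                   class = "mrscreen_config_error")
  }
  do.call(mr_config, fields)
}
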