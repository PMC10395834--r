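#' Specificity screen against non-target outcomes
#'
#' Runs the univariable screen of each exposure against a panel of
#' non-target disease outcomes; an exposure is a *specific* biomarker of
#' the target disease iff no non-target outcome reaches `p < alpha`.
#'
#' @param exposures List of exposure `summary_dataset`s.
#' @param non_target_outcomes List of outcome `summary_dataset`s (may be
#'   empty, in which case every exposure is vacuously specific).
#' @param alpha Significance level (default 0.05).
#' @param config An [mr_config()].
#' @param ld Optional [ld_matrix()].
#' @return A tibble `exposure_id, specific, n_outcomes_tested, min_p`.
#' @export
specificity_screen <- function(exposures, non_target_outcomes, alpha = 0.05,
                               config = mr_config(), ld = NULL) {
  if (inherits(exposures, "summary_dataset")) exposures <- list(exposures)
  exposure_ids <- vapply(exposures, function(e) attr(e, "trait_id"),
                         character(1))
  if (length(non_target_outcomes) == 0) {
    return(tibble(exposure_id = exposure_ids, specific = TRUE,
                  n_outcomes_tested = 0L, min_p = NA_real_))
  }
  all_rows <- purrr::map(non_target_outcomes, function(out) {
    run_univariable_screen(exposures, out, config, ld)
  }) %>% list_rbind()
  all_rows %>%
    group_by(.data$exposure_id) %>%
    summarise(specific = !any(.data$pvalue < alpha, na.rm = TRUE),
              n_outcomes_tested = dplyr::n_distinct(.data$outcome_id),
              min_p = suppressWarnings(min(.data$pvalue, na.rm = TRUE)),
              .groups = "drop") %>%
    mutate(min_p = ifelse(is.finite(.data$min_p), .data$min_p, NA_real_))
}

#' Cross-method consensus evidence table
#'
#' Merges the four evidence streams for one outcome — univariable MR
#' significance, model-averaging MIP ranking, top-k identification, and
#' an externally supplied network (module-shift) score — plus the
#' specificity screen, into one row per exposure.  `evidence_count`
#' counts the streams supporting the exposure among those with available
#' data; `robust` flags exposures supported by at least
#' `config$min_methods` (default 3) streams.
#'
#' Network scores are always an input (this package does not compute
#' correlation-network module shifts); a missing score table simply
#' restricts the count to the three MR-derived streams.
#'
#' @param screen_rows An `mr_screen` tibble for the target outcome.
#' @param ranking A `bma_result` (or its `ranking` tibble) from the
#'   MIP-ranking analysis.
#' @param identification A `bma_result` (or tibble) from the
#'   identification analysis (top-k flags).
#' @param netmoss Optional tibble `exposure_id, score`.
#' @param specificity Optional tibble `exposure_id, specific` from
#'   [specificity_screen()].
#' @param config An [mr_config()].
#' @return A tibble of class `evidence_table`, sorted by outcome then
#'   decreasing `evidence_count`.
#' @export
build_evidence_table <- function(screen_rows, ranking, identification,
                                 netmoss = NULL, specificity = NULL,
                                 config = mr_config()) {
  pull_ranking <- function(x) if (inherits(x, "bma_result")) x$ranking else as_tibble(x)
  rk <- pull_ranking(ranking)
  idf <- pull_ranking(identification)

  if (anyDuplicated(paste(screen_rows$exposure_id, screen_rows$outcome_id))) {
    abort_mrscreen("duplicate (exposure, outcome) keys in screen rows",
                   class = "mrscreen_aggregation_error")
  }
  tbl <- screen_rows %>%
    select("exposure_id", "outcome_id", "or_point", "or_low", "or_high",
           "pvalue", "fdr_adjusted_p", "tier") %>%
    left_join(rk %>% select("exposure_id", ranking_mip = "mip"),
              by = "exposure_id") %>%
    left_join(idf %>% select("exposure_id", identification_mip = "mip",
                             identification_top_k = "top_k"),
              by = "exposure_id")
  if (!is.null(netmoss)) {
    tbl <- left_join(tbl, as_tibble(netmoss) %>%
                       select("exposure_id", netmoss_score = "score"),
                     by = "exposure_id")
  } else {
    tbl$netmoss_score <- NA_real_
  }
  if (!is.null(specificity)) {
    tbl <- left_join(tbl, specificity %>% select("exposure_id", "specific"),
                     by = "exposure_id")
  } else {
    tbl$specific <- NA
  }

  votes <- cbind(
    univariable = !is.na(tbl$pvalue) & tbl$pvalue < config$potential_alpha,
    ranking = ifelse(is.na(tbl$ranking_mip), NA,
                     tbl$ranking_mip > config$mip_threshold),
    identification = ifelse(is.na(tbl$identification_top_k), NA,
                            tbl$identification_top_k),
    netmoss = ifelse(is.na(tbl$netmoss_score), NA,
                     tbl$netmoss_score >= config$netmoss_score_threshold)
  )
  tbl$evidence_count <- as.integer(rowSums(votes, na.rm = TRUE))
  tbl$n_streams_available <- as.integer(rowSums(!is.na(votes)))
  tbl$robust <- tbl$evidence_count >= config$min_methods
  tbl <- tbl %>% arrange(.data$outcome_id, dplyr::desc(.data$evidence_count))
  class(tbl) <- c("evidence_table", class(tibble()))
  tbl
}

#' Roll up an evidence table to unique taxa
#'
#' An exposure can be robust for several outcome subsites/stages; this
#' view reports each exposure once with the outcomes supporting it.
#'
#' @param evidence An `evidence_table` (rows from one or more outcomes).
#' @export
summarise_robust_taxa <- function(evidence) {
  evidence %>%
    group_by(.data$exposure_id) %>%
    summarise(n_outcomes_robust = sum(.data$robust),
              outcomes_robust = paste(.data$outcome_id[.data$robust],
                                      collapse = ";"),
              max_evidence_count = max(.data$evidence_count),
              .groups = "drop") %>%
    arrange(dplyr::desc(.data$n_outcomes_robust))
}
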