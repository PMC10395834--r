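#' Univariable MR screen of an exposure panel against one outcome
#'
#' For each exposure: select instruments, optionally LD-clump, harmonize
#' against the outcome, estimate the causal effect (Wald ratio when a
#' single instrument survives, otherwise multiplicative-random-effects
#' IVW), and attach Cochran's Q, the MR-Egger slope/intercept (when >= 3
#' instruments) and the Steiger directionality test.  P-values are
#' BH-adjusted across exposures and each row is assigned a significance
#' tier: `significant_fdr` (adjusted p below `fdr_alpha`), `potential`
#' (raw p below `potential_alpha`), or `null`.
#'
#' Per-exposure failures (no surviving instruments, estimator errors) are
#' recorded in the row's `error` field and never abort the screen.
#'
#' @param exposures A list of exposure `summary_dataset`s (or a single
#'   one).
#' @param outcome An outcome `summary_dataset`.
#' @param config An [mr_config()].
#' @param ld Optional [ld_matrix()] for clumping.
#' @param iv_p Instrument p-value threshold; defaults to
#'   `config$iv_p_microbe`.
#' @return A tibble of class `mr_screen`, one row per exposure.
#' @export
run_univariable_screen <- function(exposures, outcome, config = mr_config(),
                                   ld = NULL, iv_p = NULL) {
  if (inherits(exposures, "summary_dataset")) exposures <- list(exposures)
  iv_p <- iv_p %||% config$iv_p_microbe
  outcome_id <- attr(outcome, "trait_id")

  rows <- purrr::map(exposures, function(exposure) {
    base <- tibble(
      exposure_id = attr(exposure, "trait_id"), outcome_id = outcome_id,
      method = NA_character_, n_snps = NA_integer_,
      theta_hat = NA_real_, se = NA_real_, ci_low = NA_real_,
      ci_high = NA_real_, or_point = NA_real_, or_low = NA_real_,
      or_high = NA_real_, pvalue = NA_real_,
      q = NA_real_, q_pvalue = NA_real_,
      egger_theta = NA_real_, egger_p = NA_real_,
      egger_intercept = NA_real_, egger_intercept_p = NA_real_,
      steiger_forward = NA, steiger_p = NA_real_,
      error = NA_character_
    )
    tryCatch({
      sel <- select_instruments(exposure, iv_p)
      if (!is.null(ld) && nrow(sel) > 1) {
        sel <- ld_clump(sel, ld, config$clump_r2, config$clump_window_kb)
      }
      h <- harmonize(sel, outcome, config$palindrome_maf, config$f_min)
      if (nrow(h) == 0) {
        base$error <- "no_instruments_after_harmonization"
        return(base)
      }
      est <- if (nrow(h) == 1) {
        wald_ratio(h$beta_x, h$se_x, h$beta_y, h$se_y)
      } else {
        ivw(h, "multiplicative_random")
      }
      base$method <- est$method
      base$n_snps <- est$n_snps
      base[c("theta_hat", "se", "ci_low", "ci_high", "or_point", "or_low",
             "or_high", "pvalue")] <-
        est[c("theta_hat", "se", "ci_low", "ci_high", "or_point", "or_low",
              "or_high", "pvalue")]
      if (nrow(h) >= 2) {
        qres <- cochran_q(h, est$theta_hat)
        base$q <- qres$q
        base$q_pvalue <- qres$q_pvalue
      }
      if (nrow(h) >= 3) {
        eg <- tryCatch(mr_egger(h), mrscreen_error = function(e) NULL)
        if (!is.null(eg)) {
          base$egger_theta <- eg$theta_hat
          base$egger_p <- eg$pvalue
          base$egger_intercept <- eg$intercept
          base$egger_intercept_p <- eg$intercept_p
        }
      }
      st <- steiger_test(h)
      base$steiger_forward <- st$direction_forward
      base$steiger_p <- st$pvalue
      base
    }, mrscreen_error = function(e) {
      base$error <- conditionMessage(e)
      base
    })
  }) %>% list_rbind()

  rows$fdr_adjusted_p <- NA_real_
  ok <- !is.na(rows$pvalue)
  rows$fdr_adjusted_p[ok] <- bh_fdr(rows$pvalue[ok])
  rows$tier <- case_when(
    !is.na(rows$fdr_adjusted_p) & rows$fdr_adjusted_p < config$fdr_alpha ~
      "significant_fdr",
    !is.na(rows$pvalue) & rows$pvalue < config$potential_alpha ~ "potential",
    TRUE ~ "null"
  )
  class(rows) <- c("mr_screen", class(tibble()))
  rows
}

#' Forest plot of a univariable MR screen
#'
#' Odds-ratio forest plot of screen rows, mirroring the forest-plot
#' exports used to report microbial screens: exposures on the y axis,
#' OR with 95% CI on a log x axis, coloured by significance tier.
#'
#' @param object An `mr_screen` tibble.
#' @param ... Unused.
#' @method autoplot mr_screen
#' @export
autoplot.mr_screen <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$or_point))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or_point,
                                   y = stats::reorder(.data$exposure_id,
                                                      .data$or_point),
                                   colour = .data$tier)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$or_low,
                                          xmax = .data$or_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI)", y = NULL, colour = "Tier") +
    ggplot2::theme_minimal()
}
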