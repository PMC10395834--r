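#' Indirect effect by the coefficient-product method
#'
#' The indirect (mediated) effect of an exposure on an outcome through a
#' mediator is the product `b = b2 * b3` of the exposure -> mediator and
#' mediator -> outcome effects, with delta-method standard error
#' `se_b = sqrt(b2^2 se3^2 + b3^2 se2^2)`.  The reported mediation
#' probability is by default the one-sided upper-tail normal probability
#' `P(indirect <= 0)` — small when the indirect effect is reliably
#' positive; a two-sided option is available.
#'
#' @param b2,se2 Exposure -> mediator effect and SE.
#' @param b3,se3 Mediator -> outcome effect and SE.
#' @param alternative `"greater"` (one-sided, default) or `"two.sided"`.
#' @return A tibble `b, se_b, p` (vectorized over inputs).
#' @export
indirect_effect <- function(b2, se2, b3, se3,
                            alternative = c("greater", "two.sided")) {
  alternative <- rlang::arg_match(alternative)
  stopifnot(all(se2 > 0), all(se3 > 0))
  b <- b2 * b3
  se_b <- sqrt(b2^2 * se3^2 + b3^2 * se2^2)
  z <- b / se_b
  p <- if (alternative == "greater") pnorm(z, lower.tail = FALSE) else {
    2 * pnorm(-abs(z))
  }
  tibble(b = b, se_b = se_b, p = p)
}

#' Mediated proportion
#'
#' `100 * b / b1` — the percentage of the total effect `b1` transmitted
#' through the mediator.  Values outside \[0, 100\]% (inconsistent
#' mediation, amplification) are passed through unclipped.
#'
#' @param b Indirect effect.
#' @param b1 Total effect (must be nonzero).
#' @return Percentage (vectorized).
#' @export
mediated_proportion <- function(b, b1) {
  if (any(b1 == 0)) {
    abort_mrscreen("mediated proportion undefined for b1 = 0",
                   class = "mrscreen_undefined_proportion_error")
  }
  100 * b / b1
}

#' Flag pathways whose mediation direction matches the total effect
#'
#' A pathway is direction-consistent when its indirect effect has the
#' same sign as the total effect — the configurations in which the
#' mediator transmits (rather than opposes) the exposure's effect.
#'
#' @param results A data frame with columns `b` (indirect effect) and
#'   `b1` (total effect).
#' @return The input with a logical `direction_consistent` column; the
#'   consistent-row count is attached as attribute `n_consistent`.
#' @export
direction_consistency <- function(results) {
  results <- as_tibble(results)
  results$direction_consistent <- sign(results$b) == sign(results$b1)
  attr(results, "n_consistent") <- sum(results$direction_consistent,
                                       na.rm = TRUE)
  results
}

#' Two-step MR mediation for one exposure -> mediator -> outcome pathway
#'
#' Estimates the total effect `b1` (exposure -> outcome), the
#' exposure -> mediator effect `b2` and the mediator -> outcome effect
#' `b3`, each by univariable MR (Wald ratio for a single instrument,
#' multiplicative-random-effects IVW otherwise), with
#' exposure-appropriate instrument thresholds: `config$iv_p_other`
#' (5e-8) for the well-powered exposure, `config$iv_p_microbe` (1e-5)
#' for the microbial mediator.  The indirect effect, delta-method SE,
#' mediation probability and mediated proportion follow.
#'
#' @param exposure,mediator,outcome `summary_dataset`s; `mediator` and
#'   `outcome` must report associations for the instruments of the trait
#'   upstream of them.
#' @param config An [mr_config()].
#' @param label Optional pathway label.
#' @return A one-row tibble of class `mediation_result`: `pathway`,
#'   `exposure_id`, `mediator_id`, `outcome_id`, `b1`, `se1`, `b2`,
#'   `se2`, `b3`, `se3`, `b`, `se_b`, `p`, `proportion`,
#'   `direction_consistent`, `n_snps_*`, `error`.
#' @export
run_two_step <- function(exposure, mediator, outcome, config = mr_config(),
                         label = NULL) {
  ids <- c(exposure = attr(exposure, "trait_id"),
           mediator = attr(mediator, "trait_id"),
           outcome = attr(outcome, "trait_id"))
  label <- label %||% paste(ids, collapse = " -> ")
  row <- tibble(
    pathway = label, exposure_id = ids[["exposure"]],
    mediator_id = ids[["mediator"]], outcome_id = ids[["outcome"]],
    b1 = NA_real_, se1 = NA_real_, b2 = NA_real_, se2 = NA_real_,
    b3 = NA_real_, se3 = NA_real_, b = NA_real_, se_b = NA_real_,
    p = NA_real_, proportion = NA_real_, direction_consistent = NA,
    n_snps_b1 = NA_integer_, n_snps_b2 = NA_integer_,
    n_snps_b3 = NA_integer_, error = NA_character_
  )
  step <- function(from, to, iv_p) {
    sel <- select_instruments(from, iv_p)
    h <- harmonize(sel, to, config$palindrome_maf, config$f_min)
    check_instruments(h, 1L, "two-step MR stage")
    if (nrow(h) == 1) wald_ratio(h$beta_x, h$se_x, h$beta_y, h$se_y)
    else ivw(h, "multiplicative_random")
  }
  out <- tryCatch({
    e1 <- step(exposure, outcome, config$iv_p_other)
    e2 <- step(exposure, mediator, config$iv_p_other)
    e3 <- step(mediator, outcome, config$iv_p_microbe)
    ind <- indirect_effect(e2$theta_hat, e2$se, e3$theta_hat, e3$se)
    row$b1 <- e1$theta_hat; row$se1 <- e1$se
    row$b2 <- e2$theta_hat; row$se2 <- e2$se
    row$b3 <- e3$theta_hat; row$se3 <- e3$se
    row$b <- ind$b; row$se_b <- ind$se_b; row$p <- ind$p
    row$proportion <- mediated_proportion(ind$b, e1$theta_hat)
    row$direction_consistent <- sign(ind$b) == sign(e1$theta_hat)
    row$n_snps_b1 <- e1$n_snps; row$n_snps_b2 <- e2$n_snps
    row$n_snps_b3 <- e3$n_snps
    row
  }, mrscreen_error = function(e) {
    row$error <- conditionMessage(e)
    row
  })
  class(out) <- c("mediation_result", class(out))
  out
}

#' Format a mediation table at display precision
#'
#' Rounds the effect columns half-away-from-zero at two decimals for
#' reporting; internal values are never rounded.
#'
#' @param results A tibble of mediation rows.
#' @param digits Display digits (default 2).
#' @export
format_mediation_table <- function(results, digits = 2) {
  cols <- intersect(c("b1", "b2", "b3", "b", "p", "proportion"),
                    names(results))
  for (cl in cols) results[[cl]] <- round_half_away(results[[cl]], digits)
  results
}

#' Bundled worked example: published diet -> gut microbe -> colorectal
#' tumour mediation estimates
#'
#' Loads a small bundled table of 20 published two-step MR mediation
#' rows (total effect `b1`, step effects `b2`, `b3`, indirect effect
#' `b`, mediation probability `p`, mediated proportion) for dietary
#' habits acting on colorectal cancer subsites and stages through gut
#' bacteria.  Used in examples and as a fixed worked example for the
#' coefficient-product arithmetic.
#'
#' @return A tibble with one row per pathway.
#' @export
mediation_example <- function() {
  path <- system.file("extdata", "mediation_pathways_example.tsv",
                      package = "mrscreen", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
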