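#' Wakefield-style approximate Bayes factor
#'
#' For a single variant with estimate `beta` and standard error `se`,
#' under a `N(0, prior_effect_sd^2)` effect prior: with `z = beta/se`,
#' `V = se^2`, `W = prior_effect_sd^2` and shrinkage `r = W/(V+W)`, the
#' log ABF against the null is `0.5 * (log(1 - r) + r * z^2)`.
#'
#' @param beta,se Effect estimate and standard error (vectorized).
#' @param prior_effect_sd Prior SD of true effects.
#' @param log Return the log ABF (default; recommended for accumulation).
#' @return Numeric vector of (log) approximate Bayes factors.
#' @export
approx_bayes_factor <- function(beta, se, prior_effect_sd = 0.15, log = TRUE) {
  stopifnot(all(se > 0), prior_effect_sd >= 0)
  z2 <- (beta / se)^2
  r <- prior_effect_sd^2 / (se^2 + prior_effect_sd^2)
  labf <- 0.5 * (log1p(-r) + r * z2)
  if (log) labf else exp(labf)
}

#' Approximate-Bayes-factor colocalization of two traits at a locus
#'
#' Enumerates the five hypotheses about a shared locus — H0 neither trait
#' associated, H1/H2 only one, H3 both via distinct causal variants, H4
#' both via a shared variant — assuming at most one causal variant per
#' trait.  Per-variant log ABFs are combined with configuration priors
#' (`p1`, `p2` per-variant association priors, `p12` shared-variant
#' prior) by log-sum-exp accumulation; the H3 sum excludes the
#' shared-variant diagonal.  A posterior `PP.H4` above `pp_h4_threshold`
#' flags that the exposure-outcome MR estimate at this locus may be
#' confounded by a shared causal variant rather than a causal pathway,
#' i.e. the MR exclusion-restriction reading is violated.
#'
#' @param trait1,trait2 Data frames with columns `variant_id`, `beta`,
#'   `se` over an identical variant list (>= 2 variants).
#' @param p1,p2,p12 Prior probabilities (defaults 1e-4, 1e-4, 1e-5).
#' @param prior_sd1,prior_sd2 Effect priors for the two traits.
#' @param pp_h4_threshold Decision threshold on PP.H4 (default 0.8).
#' @return A `coloc_result` list: `posteriors` (named, H0..H4), `abf`
#'   (per-variant log ABFs), `priors`, `mr_assumption_violated`.
#' @export
colocalize <- function(trait1, trait2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                       prior_sd1 = 0.15, prior_sd2 = 0.15,
                       pp_h4_threshold = 0.8) {
  if (nrow(trait1) < 2 || !identical(trait1$variant_id, trait2$variant_id)) {
    abort_mrscreen(
      "trait profiles must share an identical variant list of >= 2 variants",
      class = "mrscreen_alignment_error")
  }
  l1 <- approx_bayes_factor(trait1$beta, trait1$se, prior_sd1)
  l2 <- approx_bayes_factor(trait2$beta, trait2$se, prior_sd2)

  ls1 <- logsumexp(l1)
  ls2 <- logsumexp(l2)
  ls4 <- logsumexp(l1 + l2)
  ls3 <- logdiffexp(ls1 + ls2, ls4)

  log_ev <- c(h0 = 0,
              h1 = log(p1) + ls1,
              h2 = log(p2) + ls2,
              h3 = log(p1) + log(p2) + ls3,
              h4 = log(p12) + ls4)
  pp <- exp(log_ev - logsumexp(log_ev))
  pp <- pp / sum(pp)
  names(pp) <- paste0("pp_", names(log_ev))

  structure(list(
    posteriors = pp,
    abf = tibble(variant_id = trait1$variant_id,
                 log_abf_trait1 = l1, log_abf_trait2 = l2),
    priors = c(p1 = p1, p2 = p2, p12 = p12),
    pp_h4_threshold = pp_h4_threshold,
    mr_assumption_violated = unname(pp["pp_h4"]) > pp_h4_threshold
  ), class = "coloc_result")
}

#' @method tidy coloc_result
#' @export
tidy.coloc_result <- function(x, ...) {
  tibble(hypothesis = toupper(sub("pp_", "", names(x$posteriors))),
         posterior = unname(x$posteriors))
}

#' @method glance coloc_result
#' @export
glance.coloc_result <- function(x, ...) {
  as_tibble(as.list(x$posteriors)) %>%
    mutate(mr_assumption_violated = x$mr_assumption_violated)
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("Colocalization posteriors (single causal variant per trait):\n")
  print(round(x$posteriors, 4))
  cat(sprintf("PP.H4 > %.2f (MR assumption violated): %s\n",
              x$pp_h4_threshold, x$mr_assumption_violated))
  invisible(x)
}

#' Bar chart of colocalization posteriors
#'
#' @param object A `coloc_result`.
#' @param ... Unused.
#' @method autoplot coloc_result
#' @export
autoplot.coloc_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hypothesis, y = .data$posterior)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$pp_h4_threshold, linetype = 2) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "Posterior probability") +
    ggplot2::theme_minimal()
}
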