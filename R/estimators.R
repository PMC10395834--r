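#' @noRd
# One-row tibble of class mr_estimate; all estimators funnel through here.
new_mr_estimate <- function(method, theta_hat, se, pvalue, n_snps,
                            intercept = NA_real_, intercept_se = NA_real_,
                            intercept_p = NA_real_, q = NA_real_,
                            q_df = NA_integer_, q_pvalue = NA_real_) {
  z <- qnorm(0.975)
  out <- tibble(
    method = method, theta_hat = theta_hat, se = se,
    ci_low = theta_hat - z * se, ci_high = theta_hat + z * se,
    or_point = exp(theta_hat), or_low = exp(theta_hat - z * se),
    or_high = exp(theta_hat + z * se),
    pvalue = pvalue, n_snps = as.integer(n_snps),
    intercept = intercept, intercept_se = intercept_se,
    intercept_p = intercept_p,
    q = q, q_df = q_df, q_pvalue = q_pvalue
  )
  class(out) <- c("mr_estimate", class(out))
  out
}

check_instruments <- function(hset, min_n, method) {
  if (nrow(hset) < min_n) {
    abort_mrscreen(
      sprintf("%s requires at least %d instrument(s), got %d",
              method, min_n, nrow(hset)),
      class = "mrscreen_insufficient_instruments_error"
    )
  }
  invisible(hset)
}

#' Wald ratio causal estimate from a single instrument
#'
#' `theta = beta_y / beta_x` with first-order delta-method standard error
#' `se_y / |beta_x|` (the uncertainty in `beta_x` is ignored, adequate for
#' strong instruments); p-value from the normal reference.
#'
#' @param beta_x,se_x SNP-exposure effect and SE.
#' @param beta_y,se_y SNP-outcome effect and SE.
#' @param second_order If `TRUE`, use the second-order delta SE
#'   `sqrt(se_y^2/beta_x^2 + beta_y^2 se_x^2 / beta_x^4)`.
#' @return An `mr_estimate` tibble (one row).
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y, second_order = FALSE) {
  if (beta_x == 0) {
    abort_mrscreen("Wald ratio undefined for beta_x = 0",
                   class = "mrscreen_undefined_ratio_error")
  }
  theta <- beta_y / beta_x
  se <- if (second_order) {
    sqrt(se_y^2 / beta_x^2 + beta_y^2 * se_x^2 / beta_x^4)
  } else {
    se_y / abs(beta_x)
  }
  new_mr_estimate("wald_ratio", theta, se,
                  pval_from_z(theta / se), 1L)
}

#' Inverse-variance-weighted causal estimate
#'
#' Zero-intercept weighted regression of outcome on exposure effects with
#' weights `1/se_y^2` — algebraically the precision-weighted mean of the
#' per-variant Wald ratios.  Under the multiplicative-random-effects
#' model (the headline estimator for screens of heterogeneous microbial
#' instruments) the fixed-effects standard error is inflated by
#' `max(1, sqrt(Q/(J-1)))`: over-dispersion widens the interval, while
#' under-dispersion never shrinks it.
#'
#' @param hset A `harmonized_set` (or any data frame with `beta_x`,
#'   `se_x`, `beta_y`, `se_y`).
#' @param effects_model `"multiplicative_random"` (default) or `"fixed"`.
#' @return An `mr_estimate` tibble with Cochran's Q attached.
#' @export
ivw <- function(hset, effects_model = c("multiplicative_random", "fixed")) {
  effects_model <- rlang::arg_match(effects_model)
  check_instruments(hset, 1L, "ivw")
  if (nrow(hset) == 1L) {
    est <- wald_ratio(hset$beta_x, hset$se_x, hset$beta_y, hset$se_y)
    est$method <- if (effects_model == "fixed") "ivw_fe" else "ivw_mre"
    return(est)
  }
  w <- 1 / hset$se_y^2
  sxx <- sum(w * hset$beta_x^2)
  theta <- sum(w * hset$beta_x * hset$beta_y) / sxx
  se_fe <- 1 / sqrt(sxx)
  J <- nrow(hset)
  q <- sum(w * (hset$beta_y - theta * hset$beta_x)^2)
  se <- if (effects_model == "fixed") se_fe else se_fe * max(1, sqrt(q / (J - 1)))
  new_mr_estimate(
    if (effects_model == "fixed") "ivw_fe" else "ivw_mre",
    theta, se, pval_from_z(theta / se), J,
    q = q, q_df = J - 1L, q_pvalue = pchisq(q, J - 1, lower.tail = FALSE)
  )
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects with a free
#' intercept (weights `1/se_y^2`).  The slope estimates the causal
#' effect under the InSIDE assumption; the intercept estimates average
#' directional pleiotropy and its test is the pleiotropy diagnostic.
#' Standard errors are inflated by `max(1, sqrt(Q_egger/(J-2)))`.
#'
#' @param hset A `harmonized_set` with at least 3 instruments.
#' @return An `mr_estimate` tibble with intercept fields and Egger Q.
#' @export
mr_egger <- function(hset) {
  check_instruments(hset, 3L, "mr_egger")
  if (sd(hset$beta_x) < .Machine$double.eps^0.5 * max(1, abs(mean(hset$beta_x)))) {
    abort_mrscreen("MR-Egger is unidentifiable: all beta_x equal",
                   class = "mrscreen_collinearity_error")
  }
  w <- 1 / hset$se_y^2
  X <- cbind(1, hset$beta_x)
  XtWX <- crossprod(X, w * X)
  XtWy <- crossprod(X, w * hset$beta_y)
  V0 <- solve(XtWX)
  coefs <- drop(V0 %*% XtWy)
  J <- nrow(hset)
  resid <- hset$beta_y - drop(X %*% coefs)
  q <- sum(w * resid^2)
  infl <- max(1, sqrt(q / (J - 2)))
  se0 <- sqrt(diag(V0)) * infl
  # Egger p-values use the t reference with J - 2 df (the convention of
  # the reference implementations), unlike IVW's normal reference.
  pt2 <- function(t) pmax(2 * stats::pt(-abs(t), df = J - 2),
                          .Machine$double.xmin)
  new_mr_estimate(
    "egger", coefs[2], se0[2], pt2(coefs[2] / se0[2]), J,
    intercept = coefs[1], intercept_se = se0[1],
    intercept_p = pt2(coefs[1] / se0[1]),
    q = q, q_df = J - 2L, q_pvalue = pchisq(q, J - 2, lower.tail = FALSE)
  )
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum((beta_y - theta * beta_x)^2 / se_y^2)` against a chi-square
#' reference with J - 1 degrees of freedom; large Q signals instruments
#' whose Wald ratios disagree (heterogeneity / pleiotropy).
#'
#' @param hset A `harmonized_set` with >= 2 instruments.
#' @param theta_hat Causal estimate to form residuals around (defaults to
#'   the fixed-effects IVW estimate).
#' @return A one-row tibble `q, df, q_pvalue`.
#' @export
cochran_q <- function(hset, theta_hat = NULL) {
  check_instruments(hset, 2L, "cochran_q")
  if (is.null(theta_hat)) theta_hat <- ivw(hset, "fixed")$theta_hat
  q <- sum((hset$beta_y - theta_hat * hset$beta_x)^2 / hset$se_y^2)
  df <- nrow(hset) - 1L
  tibble(q = q, df = df, q_pvalue = pchisq(q, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (via [stats::p.adjust()]), preserving
#' input order.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(all(pvalues > 0 & pvalues <= 1, na.rm = TRUE))
  p.adjust(pvalues, method = "BH")
}

#' Steiger directionality test
#'
#' Compares the variance the instruments explain in the exposure versus
#' the outcome.  Per-variant r-squared is recovered from the association
#' t-statistic (`r2 = t^2 / (t^2 + n - 2)`) and summed per trait; the
#' aggregate correlations (square roots of the sums) are compared by a
#' z-test on their Fisher transforms.  A forward causal direction has
#' `r2_exposure > r2_outcome`.
#'
#' @param hset A `harmonized_set`.
#' @param n_exposure,n_outcome GWAS sample sizes (default: median `n`
#'   columns of the harmonized set).
#' @return A one-row tibble `r2_exposure, r2_outcome, direction_forward,
#'   pvalue`.
#' @export
steiger_test <- function(hset, n_exposure = NULL, n_outcome = NULL) {
  check_instruments(hset, 1L, "steiger_test")
  n_exposure <- n_exposure %||% stats::median(hset$n_x, na.rm = TRUE)
  n_outcome <- n_outcome %||% stats::median(hset$n_y, na.rm = TRUE)
  stopifnot(n_exposure > 3, n_outcome > 3)
  r2_one <- function(beta, se, n) {
    t2 <- (beta / se)^2
    sum(t2 / (t2 + n - 2))
  }
  r2x <- min(r2_one(hset$beta_x, hset$se_x, n_exposure), 1 - 1e-12)
  r2y <- min(r2_one(hset$beta_y, hset$se_y, n_outcome), 1 - 1e-12)
  zx <- atanh(sqrt(r2x))
  zy <- atanh(sqrt(r2y))
  z <- (zx - zy) / sqrt(1 / (n_exposure - 3) + 1 / (n_outcome - 3))
  tibble(r2_exposure = r2x, r2_outcome = r2y,
         direction_forward = r2x > r2y,
         pvalue = pval_from_z(z))
}

#' Leave-one-out IVW analysis
#'
#' Refits the IVW estimate excluding each instrument in turn; a utility
#' for spotting single-variant leverage.
#'
#' @param hset A `harmonized_set` with >= 3 instruments.
#' @param effects_model Passed to [ivw()].
#' @return A tibble with one row per left-out variant.
#' @export
leave_one_out <- function(hset, effects_model = "multiplicative_random") {
  check_instruments(hset, 3L, "leave_one_out")
  purrr::map(seq_len(nrow(hset)), function(j) {
    est <- ivw(hset[-j, , drop = FALSE], effects_model)
    tibble(left_out = hset$variant_id[j], theta_hat = est$theta_hat,
           se = est$se, pvalue = est$pvalue)
  }) %>% list_rbind()
}
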