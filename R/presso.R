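#' Simulation-based pleiotropy outlier testing (PRESSO-style)
#'
#' Detects and corrects horizontally pleiotropic instruments through
#' three steps.  The *global* test compares the observed residual sum of
#' squares — each instrument's squared standardized residual around its
#' leave-one-out IVW prediction — to a parametric null in which
#' `beta_y* ~ N(theta_loo_j * beta_x_j, se_y_j)` and
#' `beta_x* ~ N(beta_x_j, se_x_j)`, with leave-one-out predictions
#' recomputed inside every simulation.  The *outlier* test compares each
#' variant's observed squared residual to its own simulated distribution
#' (Bonferroni-adjusted across instruments).  The *distortion* test asks
#' whether removing the flagged outliers shifts the causal estimate more
#' than removing an equally sized random set of non-outliers.
#'
#' Empirical p-values carry the +1 correction, so they are never exactly
#' zero and are bounded below by `1/(n_simulations + 1)`.
#'
#' @param hset A `harmonized_set` with >= 4 instruments.
#' @param n_simulations Number of parametric simulations (default 1000).
#' @param seed Integer seed; identical seeds reproduce results exactly.
#' @param outlier_alpha Significance level for the Bonferroni-adjusted
#'   per-variant outlier test.
#' @return An object of class `presso_result`: a list with
#'   `rss_observed`, `global_p`, `per_variant` (tibble of per-variant
#'   residuals and p-values), `outlier_ids`, `theta_raw`,
#'   `theta_corrected` (`mr_estimate`s), `distortion_p`,
#'   `n_simulations`, `seed`.
#' @export
mr_presso <- function(hset, n_simulations = 1000, seed = 1,
                      outlier_alpha = 0.05) {
  check_instruments(hset, 4L, "mr_presso")
  res <- presso_engine(hset, n_simulations, seed)

  adj <- pmin(res$per_variant$pvalue * nrow(hset), 1)
  res$per_variant$adj_pvalue <- adj
  res$per_variant$outlier <- adj < outlier_alpha
  res$outlier_ids <- res$per_variant$variant_id[res$per_variant$outlier]

  res$theta_raw <- ivw(hset, "multiplicative_random")
  res$theta_corrected <- res$theta_raw
  res$distortion_p <- NA_real_
  if (length(res$outlier_ids) > 0) {
    keep <- !(hset$variant_id %in% res$outlier_ids)
    if (sum(keep) >= 2) {
      res$theta_corrected <- ivw(hset[keep, , drop = FALSE],
                                 "multiplicative_random")
      res$distortion_p <- distortion_pvalue(
        hset, res$outlier_ids, n_simulations,
        derive_seed(seed, "distortion"))
    }
  }
  res$outlier_alpha <- outlier_alpha
  class(res) <- "presso_result"
  res
}

#' @rdname mr_presso
#' @export
presso_global <- function(hset, n_simulations = 1000, seed = 1) {
  check_instruments(hset, 4L, "presso_global")
  res <- presso_engine(hset, n_simulations, seed)
  res[c("rss_observed", "global_p", "n_simulations", "seed")]
}

#' @rdname mr_presso
#' @export
presso_outlier <- function(hset, n_simulations = 1000, seed = 1,
                           outlier_alpha = 0.05) {
  mr_presso(hset, n_simulations, seed, outlier_alpha)
}

#' @rdname mr_presso
#' @param outlier_ids Variant ids to treat as the flagged outlier set.
#' @export
presso_distortion <- function(hset, outlier_ids, n_simulations = 1000,
                              seed = 1) {
  raw <- ivw(hset, "multiplicative_random")
  if (length(outlier_ids) == 0) {
    return(list(theta_raw = raw, theta_corrected = raw,
                distortion_p = NA_real_,
                note = "no outliers flagged; distortion test is a no-op"))
  }
  keep <- !(hset$variant_id %in% outlier_ids)
  corrected <- ivw(hset[keep, , drop = FALSE], "multiplicative_random")
  list(theta_raw = raw, theta_corrected = corrected,
       distortion_p = distortion_pvalue(hset, outlier_ids, n_simulations, seed))
}

# Core simulation shared by global and outlier tests.  All simulations are
# run as J x S matrices; leave-one-out IVW predictions are closed-form
# downdates of the full weighted sums.
presso_engine <- function(hset, n_simulations, seed) {
  set.seed(seed)
  J <- nrow(hset)
  S <- n_simulations
  x <- hset$beta_x; y <- hset$beta_y
  sx <- hset$se_x; sy <- hset$se_y
  w <- 1 / sy^2

  loo_theta <- function(xm, ym) {
    # xm, ym: J x S (or J-vector); returns matching leave-one-out thetas.
    sxy <- colSums(w * xm * ym)
    sxx <- colSums(w * xm * xm)
    (rep(sxy, each = J) - w * xm * ym) / (rep(sxx, each = J) - w * xm * xm)
  }
  th_obs <- drop(loo_theta(matrix(x), matrix(y)))
  r_obs <- ((y - th_obs * x) / sy)^2
  rss_obs <- sum(r_obs)

  xs <- matrix(x, J, S) + matrix(rnorm(J * S), J, S) * sx
  ys <- matrix(th_obs * x, J, S) + matrix(rnorm(J * S), J, S) * sy
  th_sim <- loo_theta(xs, ys)
  r_sim <- ((ys - th_sim * xs) / sy)^2
  rss_sim <- colSums(r_sim)

  per_p <- (1 + rowSums(r_sim >= r_obs)) / (1 + S)
  list(
    rss_observed = rss_obs,
    global_p = (1 + sum(rss_sim >= rss_obs)) / (1 + S),
    per_variant = tibble(variant_id = hset$variant_id,
                         r2_obs = r_obs, pvalue = per_p),
    n_simulations = S, seed = seed
  )
}

distortion_pvalue <- function(hset, outlier_ids, n_boot, seed) {
  set.seed(seed)
  is_out <- hset$variant_id %in% outlier_ids
  non_out <- which(!is_out)
  k <- sum(is_out)
  if (length(non_out) - k < 2) return(NA_real_)
  # The IVW point estimate is a ratio of weighted sums, so each
  # leave-k-out refit is a closed-form downdate.
  w <- 1 / hset$se_y^2
  wxy <- w * hset$beta_x * hset$beta_y
  wxx <- w * hset$beta_x^2
  sxy <- sum(wxy); sxx <- sum(wxx)
  theta_raw <- sxy / sxx
  d_obs <- (sxy - sum(wxy[is_out])) / (sxx - sum(wxx[is_out])) - theta_raw
  d_sim <- vapply(seq_len(n_boot), function(b) {
    idx <- sample(non_out, k)
    (sxy - sum(wxy[idx])) / (sxx - sum(wxx[idx])) - theta_raw
  }, numeric(1))
  (1 + sum(abs(d_sim) >= abs(d_obs))) / (1 + n_boot)
}

#' @method tidy presso_result
#' @export
tidy.presso_result <- function(x, ...) x$per_variant

#' @method glance presso_result
#' @export
glance.presso_result <- function(x, ...) {
  tibble(rss_observed = x$rss_observed, global_p = x$global_p,
         n_outliers = length(x$outlier_ids),
         theta_raw = x$theta_raw$theta_hat,
         theta_corrected = x$theta_corrected$theta_hat,
         distortion_p = x$distortion_p,
         n_simulations = x$n_simulations, seed = x$seed)
}

#' @export
print.presso_result <- function(x, ...) {
  cat("PRESSO-style pleiotropy test\n")
  cat(sprintf("  instruments: %d, simulations: %d\n",
              nrow(x$per_variant), x$n_simulations))
  cat(sprintf("  RSS observed: %.3f, global p: %.4g\n",
              x$rss_observed, x$global_p))
  cat(sprintf("  outliers: %s\n",
              if (length(x$outlier_ids) == 0) "none"
              else paste(x$outlier_ids, collapse = ", ")))
  cat(sprintf("  theta raw: %.4f, corrected: %.4f, distortion p: %s\n",
              x$theta_raw$theta_hat, x$theta_corrected$theta_hat,
              format(x$distortion_p)))
  invisible(x)
}
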