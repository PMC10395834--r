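#' Simulate a two-sample GWAS summary-statistics pair with known truth
#'
#' Generates per-variant exposure and outcome association records under a
#' known causal effect `theta`, for calibration and recovery experiments.
#' True SNP-exposure effects are drawn `gamma_j ~ N(0, gamma_sd^2)`;
#' direct (pleiotropic) effects `alpha_j` follow `pleiotropy_mode`; true
#' outcome effects are `theta * gamma_j + alpha_j`.  A random
#' `outlier_fraction` of variants receive an additional direct effect of
#' `outlier_scale` outcome standard errors (planted pleiotropic
#' outliers).  Observed effects add `N(0, se^2)` noise with the standard
#' GWAS calibration `se = 1/sqrt(2 n eaf (1-eaf))`.
#'
#' Allele labels, frequencies, and deliberate allele swaps / strand flips
#' in the emitted outcome table exercise harmonization; the defaults
#' mirror the study conditions this generator stands in for: a
#' microbiome-scale exposure GWAS (n = 7738, instrument F statistics of
#' several hundred at `gamma_sd = 0.4`) against a biobank-scale binary
#' outcome (n = 221814).
#'
#' @param n_variants Number of variants J (>= 2).
#' @param theta True causal effect of exposure on outcome.
#' @param gamma_sd SD of true SNP-exposure effects.
#' @param pleiotropy_mode One of `"none"`, `"balanced"`, `"directional"`,
#'   `"inside_violation"`.
#' @param pleiotropy_sd SD of direct effects (balanced/directional/inside).
#' @param pleiotropy_mean Mean direct effect under `"directional"`.
#' @param outlier_fraction Fraction of variants planted as outliers, in
#'   \[0, 1).
#' @param outlier_scale Outlier magnitude in units of the outcome standard
#'   error.
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param palindrome_fraction Fraction of variants given palindromic
#'   (A/T or C/G) allele pairs.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return A list with elements `exposure` and `outcome`
#'   ([summary_dataset()]s), `ld` (identity [ld_matrix()]), and `truth`
#'   (a list of all latent values).
#' @export
simulate_univariable <- function(n_variants = 50, theta = 0, gamma_sd = 0.4,
                                 pleiotropy_mode = c("none", "balanced",
                                                     "directional",
                                                     "inside_violation"),
                                 pleiotropy_sd = 0.02, pleiotropy_mean = 0.05,
                                 outlier_fraction = 0, outlier_scale = 5,
                                 n_exposure = 7738, n_outcome = 221814,
                                 palindrome_fraction = 0.1, seed = 1) {
  pleiotropy_mode <- rlang::arg_match(pleiotropy_mode)
  stopifnot(n_variants >= 2, gamma_sd >= 0, pleiotropy_sd >= 0,
            outlier_fraction >= 0, outlier_fraction < 1)
  set.seed(seed)
  J <- n_variants

  eaf <- runif(J, 0.05, 0.95)
  se_x <- se_from_n_eaf(n_exposure, eaf)
  se_y <- se_from_n_eaf(n_outcome, eaf)

  gamma <- rnorm(J, 0, gamma_sd)
  alpha <- switch(pleiotropy_mode,
    none = rep(0, J),
    balanced = rnorm(J, 0, pleiotropy_sd),
    directional = rnorm(J, pleiotropy_mean, pleiotropy_sd),
    inside_violation = {
      rho <- 0.6
      z <- if (gamma_sd > 0) gamma / gamma_sd else rnorm(J)
      pleiotropy_sd * (rho * z + sqrt(1 - rho^2) * rnorm(J))
    })
  outlier_idx <- integer(0)
  n_out <- floor(outlier_fraction * J)
  if (n_out > 0) {
    outlier_idx <- sort(sample.int(J, n_out))
    alpha[outlier_idx] <- alpha[outlier_idx] +
      outlier_scale * se_y[outlier_idx] * sample(c(-1, 1), n_out, replace = TRUE)
  }
  Gamma <- theta * gamma + alpha

  beta_x <- gamma + rnorm(J, 0, se_x)
  beta_y <- Gamma + rnorm(J, 0, se_y)

  ids <- sprintf("rs%06d", seq_len(J))
  chrom <- as.character(((seq_len(J) - 1) %% 22) + 1)
  pos <- 1000000L * seq_len(J)

  pal <- runif(J) < palindrome_fraction
  ea <- oa <- character(J)
  pal_pairs <- matrix(c("A", "T", "C", "G"), ncol = 2, byrow = TRUE)
  npal_pairs <- matrix(c("A", "C", "A", "G", "T", "C", "T", "G",
                         "C", "A", "G", "A", "C", "T", "G", "T"),
                       ncol = 2, byrow = TRUE)
  pick_pal <- sample.int(2, J, replace = TRUE)
  pick_np <- sample.int(8, J, replace = TRUE)
  ea[pal] <- pal_pairs[pick_pal[pal], 1]; oa[pal] <- pal_pairs[pick_pal[pal], 2]
  ea[!pal] <- npal_pairs[pick_np[!pal], 1]; oa[!pal] <- npal_pairs[pick_np[!pal], 2]

  exposure <- summary_dataset(
    tibble(variant_id = ids, chrom = chrom, pos = pos,
           effect_allele = ea, other_allele = oa, eaf = eaf,
           beta = beta_x, se = se_x,
           pval = pval_from_z(beta_x / se_x), n = n_exposure),
    trait_id = "sim_exposure", trait_type = "exposure")

  # Outcome table: random allele swaps everywhere, strand flips for
  # non-palindromic variants, so harmonization has real work to do.
  swap <- runif(J) < 0.3
  strand <- !pal & runif(J) < 0.2
  ea_y <- ea; oa_y <- oa
  ea_y[swap] <- oa[swap]; oa_y[swap] <- ea[swap]
  ea_y[strand] <- allele_complement(ea_y[strand])
  oa_y[strand] <- allele_complement(oa_y[strand])
  beta_y_rep <- ifelse(swap, -beta_y, beta_y)
  eaf_y_rep <- ifelse(swap, 1 - eaf, eaf)

  outcome <- summary_dataset(
    tibble(variant_id = ids, chrom = chrom, pos = pos,
           effect_allele = ea_y, other_allele = oa_y, eaf = eaf_y_rep,
           beta = beta_y_rep, se = se_y,
           pval = pval_from_z(beta_y_rep / se_y), n = n_outcome),
    trait_id = "sim_outcome", trait_type = "outcome")

  r <- diag(J)
  dimnames(r) <- list(ids, ids)
  ld <- ld_matrix(r, tibble(variant_id = ids, chrom = chrom, pos = pos))

  list(exposure = exposure, outcome = outcome, ld = ld,
       truth = list(theta = theta, gamma = gamma, alpha = alpha,
                    Gamma = Gamma, outlier_idx = outlier_idx,
                    se_x = se_x, se_y = se_y, eaf = eaf, seed = seed))
}

#' Simulate correlated exposure panels with a known causal subset
#'
#' Per-variant SNP effects on K exposures are drawn jointly normal with a
#' specified cross-exposure correlation (microbial traits are strongly
#' genetically correlated); true outcome effects are the linear
#' combination over the causal subset.  Used to test multivariable-MR
#' model averaging.
#'
#' @param n_variants Number of shared variants.
#' @param n_exposures Number of candidate exposures K.
#' @param causal_subset Integer indices of truly causal exposures (may be
#'   empty).
#' @param causal_effects True effects, recycled over `causal_subset`.
#' @param exposure_correlation K x K correlation matrix (default identity);
#'   must be positive semidefinite with unit diagonal.
#' @param gamma_sd SD of SNP-exposure effects.
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param seed Integer seed.
#' @return A list: `exposures` (list of K [summary_dataset()]s), `outcome`,
#'   and `truth`.
#' @export
simulate_multivariable <- function(n_variants = 60, n_exposures = 3,
                                   causal_subset = 1, causal_effects = 0.2,
                                   exposure_correlation = NULL,
                                   gamma_sd = 0.4,
                                   n_exposure = 7738, n_outcome = 221814,
                                   seed = 1) {
  K <- n_exposures
  stopifnot(all(causal_subset %in% seq_len(K)) || length(causal_subset) == 0)
  if (is.null(exposure_correlation)) exposure_correlation <- diag(K)
  stopifnot(nrow(exposure_correlation) == K, ncol(exposure_correlation) == K)
  ev <- eigen(exposure_correlation, symmetric = TRUE)
  if (any(ev$values < -1e-8) || max(abs(diag(exposure_correlation) - 1)) > 1e-8) {
    abort_mrscreen("exposure_correlation must be PSD with unit diagonal",
                   class = "mrscreen_validation_error")
  }
  set.seed(seed)
  J <- n_variants
  sqrt_corr <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), K) %*% t(ev$vectors)

  eaf <- runif(J, 0.05, 0.95)
  se_x <- se_from_n_eaf(n_exposure, eaf)
  se_y <- se_from_n_eaf(n_outcome, eaf)
  gamma <- matrix(rnorm(J * K), J, K) %*% sqrt_corr * gamma_sd

  theta <- rep(0, K)
  if (length(causal_subset) > 0) {
    theta[causal_subset] <- rep_len(causal_effects, length(causal_subset))
  }
  Gamma <- drop(gamma %*% theta)

  beta_x <- gamma + matrix(rnorm(J * K), J, K) * se_x
  beta_y <- Gamma + rnorm(J, 0, se_y)

  ids <- sprintf("rs%06d", seq_len(J))
  chrom <- as.character(((seq_len(J) - 1) %% 22) + 1)
  pos <- 1000000L * seq_len(J)
  base <- tibble(variant_id = ids, chrom = chrom, pos = pos,
                 effect_allele = "A", other_allele = "G", eaf = eaf)

  exposures <- lapply(seq_len(K), function(k) {
    summary_dataset(
      base %>% mutate(beta = beta_x[, k], se = se_x,
                      pval = pval_from_z(beta_x[, k] / se_x),
                      n = n_exposure),
      trait_id = sprintf("sim_exposure_%02d", k), trait_type = "exposure")
  })
  names(exposures) <- vapply(exposures, trait_id, character(1))
  outcome <- summary_dataset(
    base %>% mutate(beta = beta_y, se = se_y,
                    pval = pval_from_z(beta_y / se_y), n = n_outcome),
    trait_id = "sim_outcome", trait_type = "outcome")

  list(exposures = exposures, outcome = outcome,
       truth = list(theta = theta, causal_subset = causal_subset,
                    gamma = gamma, Gamma = Gamma, seed = seed))
}

#' Simulate an exposure -> mediator -> outcome triad
#'
#' Emits three summary datasets over a union of exposure instruments and
#' mediator instruments whose true effects decompose as
#' `b1 = true_direct + true_b2 * true_b3`: the exposure's instruments
#' carry effects `gamma` on the exposure, `b2 * gamma` on the mediator and
#' `b1 * gamma` on the outcome; the mediator's own instruments carry
#' `delta` on the mediator and `b3 * delta` on the outcome.  Defaults
#' emulate a dietary exposure (biobank n, instruments at 5e-8), a
#' microbial mediator (n = 7738, instruments at 1e-5) and a binary
#' disease outcome.
#'
#' @param true_b2 Exposure -> mediator effect.
#' @param true_b3 Mediator -> outcome effect.
#' @param true_direct Exposure -> outcome effect not through the mediator.
#' @param n_exposure_instruments,n_mediator_instruments Instrument counts.
#' @param gamma_sd_exposure,gamma_sd_mediator SNP-effect SDs for the two
#'   instrument sets.
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes.
#' @param seed Integer seed.
#' @return A list: `exposure`, `mediator`, `outcome`
#'   ([summary_dataset()]s over the union of variants) and `truth`.
#' @export
simulate_mediation <- function(true_b2 = 0.5, true_b3 = 0.4, true_direct = 0,
                               n_exposure_instruments = 60,
                               n_mediator_instruments = 25,
                               gamma_sd_exposure = 0.05,
                               gamma_sd_mediator = 0.4,
                               n_exposure = 360726, n_mediator = 7738,
                               n_outcome = 221814, seed = 1) {
  set.seed(seed)
  Jx <- n_exposure_instruments
  Jm <- n_mediator_instruments
  J <- Jx + Jm
  b1 <- true_direct + true_b2 * true_b3

  eaf <- runif(J, 0.05, 0.95)
  gamma <- rnorm(Jx, 0, gamma_sd_exposure)   # exposure instrument effects
  delta <- rnorm(Jm, 0, gamma_sd_mediator)   # mediator instrument effects

  # True effects of every variant on each trait.
  mu_exposure <- c(gamma, rep(0, Jm))
  mu_mediator <- c(true_b2 * gamma, delta)
  mu_outcome <- c(b1 * gamma, true_b3 * delta)

  make <- function(mu, n, id, type) {
    se <- se_from_n_eaf(n, eaf)
    beta <- mu + rnorm(J, 0, se)
    summary_dataset(
      tibble(variant_id = sprintf("rs%06d", seq_len(J)),
             chrom = as.character(((seq_len(J) - 1) %% 22) + 1),
             pos = 1000000L * seq_len(J),
             effect_allele = "A", other_allele = "G", eaf = eaf,
             beta = beta, se = se, pval = pval_from_z(beta / se), n = n),
      trait_id = id, trait_type = type)
  }
  list(
    exposure = make(mu_exposure, n_exposure, "sim_diet", "exposure"),
    mediator = make(mu_mediator, n_mediator, "sim_microbe", "mediator"),
    outcome = make(mu_outcome, n_outcome, "sim_disease", "outcome"),
    truth = list(b1 = b1, b2 = true_b2, b3 = true_b3,
                 direct = true_direct, indirect = true_b2 * true_b3,
                 gamma = gamma, delta = delta, seed = seed)
  )
}

#' Simulate two association profiles over a shared locus
#'
#' Builds an autoregressive LD structure `r[i, j] = ld_decay^|i-j|`,
#' places causal variants per scenario, and returns per-variant observed
#' effect/SE profiles for both traits with LD-correlated estimation
#' noise.  Scenarios map onto the colocalization hypotheses: shared
#' causal variant (H4), distinct causal variants (H3), one trait only
#' (H1), no signal (H0).
#'
#' @param n_variants Variants in the region.
#' @param scenario One of `"shared_causal"`, `"distinct_causal"`,
#'   `"one_trait_only"`, `"no_signal"`.
#' @param beta1,beta2 Causal effect sizes for trait 1 and 2 (per-SD scale).
#' @param n1,n2 Per-trait GWAS sample sizes.
#' @param ld_decay AR(1) LD parameter in \[0, 1).
#' @param seed Integer seed.
#' @return A list: `trait1`, `trait2` (tibbles `variant_id, beta, se, n`)
#'   and `truth` (causal indices and scenario).
#' @export
simulate_coloc_region <- function(n_variants = 50,
                                  scenario = c("shared_causal",
                                               "distinct_causal",
                                               "one_trait_only", "no_signal"),
                                  beta1 = 0.1, beta2 = 0.02,
                                  n1 = 7738, n2 = 221814,
                                  ld_decay = 0.9, seed = 1) {
  scenario <- rlang::arg_match(scenario)
  stopifnot(n_variants >= 2, ld_decay >= 0, ld_decay < 1)
  set.seed(seed)
  J <- n_variants
  R <- ld_decay^abs(outer(seq_len(J), seq_len(J), "-"))
  L <- chol(R)

  c1 <- c2 <- NA_integer_
  mid <- ceiling(J / 2)
  if (scenario == "shared_causal") { c1 <- mid; c2 <- mid }
  if (scenario == "distinct_causal") { c1 <- ceiling(J / 4); c2 <- ceiling(3 * J / 4) }
  if (scenario == "one_trait_only") { c1 <- mid }

  profile <- function(causal, b, n) {
    se <- rep(1 / sqrt(n), J)
    mu <- if (is.na(causal)) rep(0, J) else R[, causal] * b
    noise <- drop(t(L) %*% rnorm(J)) * se
    tibble(variant_id = sprintf("rs%06d", seq_len(J)),
           beta = mu + noise, se = se, n = n)
  }
  list(trait1 = profile(c1, beta1, n1),
       trait2 = profile(c2, beta2, n2),
       truth = list(scenario = scenario, causal1 = c1, causal2 = c2,
                    ld = R, seed = seed))
}
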