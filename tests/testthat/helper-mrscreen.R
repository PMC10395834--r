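# Small builders shared across test files.

toy_table <- function(n = 3, ...) {
  base <- tibble::tibble(
    variant_id = sprintf("rs%d", seq_len(n)),
    chrom = "1", pos = 1000000L * seq_len(n),
    effect_allele = rep(c("A", "C", "G"), length.out = n),
    other_allele = rep(c("G", "T", "A"), length.out = n),
    eaf = seq(0.2, 0.4, length.out = n),
    beta = seq(0.1, 0.3, length.out = n),
    se = rep(0.05, n),
    pval = rep(1e-6, n),
    n = 10000
  )
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}

toy_dataset <- function(n = 3, trait_id = "toy", trait_type = "exposure", ...) {
  mrscreen::summary_dataset(toy_table(n, ...), trait_id, trait_type)
}

# Harmonized-set-shaped tibble for estimator tests (skips allele plumbing).
toy_hset <- function(beta_x, beta_y, se_x = 0.01, se_y = 0.05,
                     n_x = 10000, n_y = 20000) {
  J <- length(beta_x)
  tibble::tibble(
    variant_id = sprintf("rs%d", seq_len(J)),
    chrom = "1", pos = 1000000L * seq_len(J),
    effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta_x = beta_x, se_x = rep_len(se_x, J),
    pval_x = 2 * stats::pnorm(-abs(beta_x / rep_len(se_x, J))),
    beta_y = beta_y, se_y = rep_len(se_y, J),
    pval_y = 2 * stats::pnorm(-abs(beta_y / rep_len(se_y, J))),
    f_stat = (beta_x / rep_len(se_x, J))^2,
    n_x = n_x, n_y = n_y
  )
}

# Simulate, select and harmonize in one step for recovery experiments.
sim_hset <- function(seed, theta = 0.2, J = 50, ...) {
  sim <- mrscreen::simulate_univariable(n_variants = J, theta = theta,
                                        seed = seed, ...)
  mrscreen::harmonize(mrscreen::select_instruments(sim$exposure, 1e-5),
                      sim$outcome)
}

round_half_away2 <- function(x) sign(x) * floor(abs(x) * 100 + 0.5) / 100

# Indices of the planted outliers for a replay of simulate_univariable.
sim_hset_truth_outliers <- function(seed, J, theta = 0.2,
                                    outlier_fraction = 1 / 30,
                                    outlier_scale = 12, ...) {
  mrscreen::simulate_univariable(
    n_variants = J, theta = theta, seed = seed,
    outlier_fraction = outlier_fraction,
    outlier_scale = outlier_scale, ...)$truth$outlier_idx
}
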