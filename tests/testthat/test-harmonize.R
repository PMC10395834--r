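make_pair <- function(exposure_rows, outcome_rows) {
  list(exposure = summary_dataset(exposure_rows, "ex", "exposure"),
       outcome = summary_dataset(outcome_rows, "out", "outcome"))
}

test_that("swapped outcome alleles flip the outcome beta and frequency", {
  p <- make_pair(
    toy_table(1, effect_allele = "A", other_allele = "G", beta = 0.5, se = 0.01),
    toy_table(1, effect_allele = "G", other_allele = "A", beta = 0.3,
              eaf = 0.8, se = 0.01)
  )
  h <- harmonize(p$exposure, p$outcome)
  expect_equal(h$beta_y, -0.3)
  expect_equal(h$beta_x, 0.5)
})

test_that("strand-complement alleles align without a sign flip", {
  p <- make_pair(
    toy_table(1, effect_allele = "A", other_allele = "G", beta = 0.5, se = 0.01),
    toy_table(1, effect_allele = "T", other_allele = "C", beta = 0.3, se = 0.01)
  )
  h <- harmonize(p$exposure, p$outcome)
  expect_equal(h$beta_y, 0.3)
})

test_that("intermediate-frequency palindromes are excluded as ambiguous", {
  p <- make_pair(
    toy_table(1, effect_allele = "A", other_allele = "T", eaf = 0.45,
              beta = 0.5, se = 0.01),
    toy_table(1, effect_allele = "A", other_allele = "T", eaf = 0.45,
              beta = 0.3, se = 0.01)
  )
  h <- harmonize(p$exposure, p$outcome, palindrome_maf_limit = 0.3)
  expect_equal(nrow(h), 0)
  expect_equal(exclusion_log(h)$reason, "palindrome_ambiguous")

  # A low-frequency palindrome aligns by frequency matching instead.
  p2 <- make_pair(
    toy_table(1, effect_allele = "A", other_allele = "T", eaf = 0.1,
              beta = 0.5, se = 0.01),
    toy_table(1, effect_allele = "A", other_allele = "T", eaf = 0.9,
              beta = 0.3, se = 0.01)
  )
  h2 <- harmonize(p2$exposure, p2$outcome)
  expect_equal(h2$beta_y, -0.3)
})

test_that("irreconcilable allele pairs and unmatched variants are logged", {
  p <- make_pair(
    toy_table(2, effect_allele = c("A", "A"), other_allele = c("G", "G"),
              beta = 0.5, se = 0.01),
    toy_table(2, variant_id = c("rs1", "rs9"),
              effect_allele = c("A", "A"), other_allele = c("C", "G"),
              beta = 0.3, se = 0.01)
  )
  h <- harmonize(p$exposure, p$outcome)
  log <- exclusion_log(h)
  expect_equal(nrow(h), 0)
  expect_setequal(log$reason[log$variant_id == "rs1"], "allele_mismatch")
  expect_true(all(c("rs2", "rs9") %in%
                    log$variant_id[log$reason == "unmatched"]))
})

test_that("weak instruments are excluded with the weak_instrument reason", {
  p <- make_pair(
    toy_table(2, beta = c(0.5, 0.01), se = 0.01),
    toy_table(2, beta = 0.3, se = 0.01)
  )
  h <- harmonize(p$exposure, p$outcome, f_min = 10)
  expect_equal(h$variant_id, "rs1")
  expect_equal(exclusion_log(h)$reason, "weak_instrument")
  expect_true(all(h$f_stat >= 10))
})

test_that("every input variant appears exactly once across set and log", {
  for (seed in 1:5) {
    sim <- simulate_univariable(n_variants = 40, seed = seed,
                                palindrome_fraction = 0.3)
    h <- harmonize(sim$exposure, sim$outcome)
    accounted <- c(h$variant_id, exclusion_log(h)$variant_id)
    expect_setequal(accounted,
                    union(sim$exposure$variant_id, sim$outcome$variant_id))
    expect_equal(anyDuplicated(accounted), 0)
  }
})

test_that("harmonization is idempotent", {
  sim <- simulate_univariable(n_variants = 40, theta = 0.1, seed = 7,
                              palindrome_fraction = 0.3)
  h1 <- harmonize(sim$exposure, sim$outcome)
  h2 <- harmonize(as_summary_dataset(h1, "exposure"),
                  as_summary_dataset(h1, "outcome"))
  expect_equal(h2$variant_id, h1$variant_id)
  expect_equal(h2$beta_x, h1$beta_x)
  expect_equal(h2$beta_y, h1$beta_y)
})

test_that("re-coding exposure alleles leaves the causal signal invariant", {
  sim <- simulate_univariable(n_variants = 30, theta = 0.2, seed = 11)
  ex <- as_tibble(sim$exposure)
  flip <- seq_len(nrow(ex)) %% 2 == 0
  tmp <- ex$effect_allele[flip]
  ex$effect_allele[flip] <- ex$other_allele[flip]
  ex$other_allele[flip] <- tmp
  ex$beta[flip] <- -ex$beta[flip]
  ex$eaf[flip] <- 1 - ex$eaf[flip]
  ex <- summary_dataset(ex, "ex_flipped", "exposure")

  h0 <- harmonize(sim$exposure, sim$outcome)
  h1 <- harmonize(ex, sim$outcome)
  expect_setequal(h1$variant_id, h0$variant_id)
  h1 <- h1[match(h0$variant_id, h1$variant_id), ]
  # Wald ratios (and hence all estimates) are unchanged by re-coding.
  expect_equal(h1$beta_y / h1$beta_x, h0$beta_y / h0$beta_x)
  expect_equal(ivw(h1)$theta_hat, ivw(h0)$theta_hat)
})

test_that("greedy clumping keeps the dominant variant of a correlated pair", {
  ds <- toy_dataset(2, pos = c(1000000L, 1001000L), chrom = "1",
                    pval = c(1e-8, 1e-6))
  r <- matrix(c(1, sqrt(0.5), sqrt(0.5), 1), 2, 2,
              dimnames = list(ds$variant_id, ds$variant_id))
  ld <- ld_matrix(r, tibble::tibble(variant_id = ds$variant_id,
                                    chrom = "1", pos = ds$pos))
  out <- ld_clump(ds, ld, r2_threshold = 0.01, window_kb = 10000)
  expect_equal(out$variant_id, "rs1")

  r0 <- diag(2); dimnames(r0) <- dimnames(r)
  ld0 <- ld_matrix(r0, tibble::tibble(variant_id = ds$variant_id,
                                      chrom = "1", pos = ds$pos))
  expect_equal(nrow(ld_clump(ds, ld0)), 2)
})

test_that("clumping matches a brute-force greedy oracle on block LD", {
  set.seed(21)
  J <- 20
  ids <- sprintf("rs%02d", 1:J)
  block <- rep(1:4, each = 5)
  r <- outer(block, block, function(a, b) ifelse(a == b, 0.6, 0))
  diag(r) <- 1
  dimnames(r) <- list(ids, ids)
  pos <- tibble::tibble(variant_id = ids, chrom = "1",
                        pos = 10000L * (1:J))
  ds <- toy_dataset(J, variant_id = ids, chrom = "1", pos = pos$pos,
                    pval = runif(J, 1e-10, 1e-4),
                    effect_allele = "A", other_allele = "G",
                    eaf = 0.3, beta = 0.2)
  ld <- ld_matrix(r, pos)
  out <- ld_clump(ds, ld, r2_threshold = 0.01, window_kb = 10000)

  # Independent brute-force greedy on the same ordering.
  remaining <- ids[order(ds$pval)]
  kept <- character(0)
  while (length(remaining) > 0) {
    top <- remaining[1]
    kept <- c(kept, top)
    near <- abs(pos$pos[match(remaining, ids)] - pos$pos[match(top, ids)]) <=
      1e7
    remaining <- remaining[!(near & r[top, remaining]^2 >= 0.01)]
  }
  expect_equal(out$variant_id, kept)

  # Output never contains a close correlated pair.
  if (nrow(out) > 1) {
    combs <- utils::combn(out$variant_id, 2)
    for (i in seq_len(ncol(combs))) {
      expect_lt(r[combs[1, i], combs[2, i]]^2, 0.01)
    }
  }
})

test_that("clumping errors when a variant is missing from the LD matrix", {
  ds <- toy_dataset(2)
  r <- diag(1); dimnames(r) <- list("rs1", "rs1")
  ld <- ld_matrix(r, tibble::tibble(variant_id = "rs1", chrom = "1",
                                    pos = 1000000L))
  expect_error(ld_clump(ds, ld), class = "mrscreen_config_error",
               regexp = "rs2")
})
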