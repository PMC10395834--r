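test_that("Wald ratio arithmetic and degenerate cases", {
  est <- wald_ratio(0.5, 0.01, 0.1, 0.05)
  expect_equal(est$theta_hat, 0.2)
  expect_equal(est$se, 0.1)
  expect_equal(est$or_point, exp(0.2))
  expect_equal(wald_ratio(0.5, 0.01, 0, 0.05)$theta_hat, 0)
  expect_error(wald_ratio(0, 0.01, 0.1, 0.05),
               class = "mrscreen_undefined_ratio_error")
})

test_that("first-order Wald SE matches the Monte-Carlo ratio SD", {
  set.seed(31)
  bx <- 0.5; sx <- 0.01; by <- 0.1; sy <- 0.05
  draws <- (by + rnorm(1e5, 0, sy)) / (bx + rnorm(1e5, 0, sx))
  expect_lt(abs(wald_ratio(bx, sx, by, sy)$se - sd(draws)) / sd(draws), 0.05)
})

test_that("IVW with a single instrument equals the Wald ratio exactly", {
  h <- toy_hset(beta_x = 0.4, beta_y = 0.12, se_x = 0.02, se_y = 0.03)
  expect_equal(ivw(h)$theta_hat, wald_ratio(0.4, 0.02, 0.12, 0.03)$theta_hat)
  expect_equal(ivw(h)$se, wald_ratio(0.4, 0.02, 0.12, 0.03)$se)
})

test_that("fixed-effects IVW is the precision-weighted mean of Wald ratios", {
  h <- toy_hset(beta_x = c(0.5, 0.3, 0.8), beta_y = c(0.11, 0.05, 0.2),
                se_y = c(0.03, 0.07, 0.02))
  ratios <- h$beta_y / h$beta_x
  wts <- h$beta_x^2 / h$se_y^2
  expect_equal(ivw(h, "fixed")$theta_hat, sum(wts * ratios) / sum(wts))
  # Two-instrument case against the closed form.
  h2 <- h[1:2, ]
  r2 <- h2$beta_y / h2$beta_x
  w2 <- h2$beta_x^2 / h2$se_y^2
  expect_equal(ivw(h2, "fixed")$theta_hat, sum(w2 * r2) / sum(w2))
  expect_equal(ivw(h2, "fixed")$se, 1 / sqrt(sum(w2)))
})

test_that("multiplicative-random-effects SE never shrinks below fixed", {
  for (seed in 1:20) {
    set.seed(seed)
    h <- toy_hset(beta_x = rnorm(8, 0, 0.3), beta_y = rnorm(8, 0, 0.05),
                  se_y = runif(8, 0.01, 0.1))
    expect_gte(ivw(h, "multiplicative_random")$se, ivw(h, "fixed")$se)
    expect_equal(ivw(h, "multiplicative_random")$theta_hat,
                 ivw(h, "fixed")$theta_hat)
  }
})

test_that("estimates are invariant under joint allele re-coding", {
  set.seed(8)
  h <- toy_hset(beta_x = rnorm(10, 0, 0.3), beta_y = rnorm(10, 0, 0.05))
  flip <- c(1, 4, 7)
  h2 <- h
  h2$beta_x[flip] <- -h2$beta_x[flip]
  h2$beta_y[flip] <- -h2$beta_y[flip]
  expect_equal(ivw(h2)$theta_hat, ivw(h)$theta_hat)
  expect_equal(ivw(h2)$se, ivw(h)$se)
  expect_equal(cochran_q(h2)$q, cochran_q(h)$q)
})

test_that("Egger recovers slope and intercept on exact linear data", {
  bx <- seq(0.1, 0.9, length.out = 6)
  h <- toy_hset(beta_x = bx, beta_y = 0.03 + 0.25 * bx, se_y = 0.02)
  eg <- mr_egger(h)
  expect_equal(eg$theta_hat, 0.25, tolerance = 1e-10)
  expect_equal(eg$intercept, 0.03, tolerance = 1e-10)
  expect_equal(eg$q, 0, tolerance = 1e-10)
})

test_that("Egger is unidentifiable when all exposure effects are equal", {
  h <- toy_hset(beta_x = rep(0.3, 5), beta_y = rnorm(5, 0, 0.05))
  expect_error(mr_egger(h), class = "mrscreen_collinearity_error")
  expect_error(mr_egger(toy_hset(beta_x = c(0.1, 0.2), beta_y = c(0, 0))),
               class = "mrscreen_insufficient_instruments_error")
})

test_that("Cochran's Q is zero for identical Wald ratios", {
  bx <- c(0.2, 0.4, 0.8)
  h <- toy_hset(beta_x = bx, beta_y = 0.3 * bx)
  expect_equal(cochran_q(h)$q, 0, tolerance = 1e-12)
  expect_equal(cochran_q(h)$df, 2)
})

test_that("Q follows its chi-square reference under the null", {
  qs <- vapply(1:400, function(s) {
    set.seed(s)
    bx <- rnorm(10, 0, 0.3)
    h <- toy_hset(beta_x = bx, beta_y = 0.2 * bx + rnorm(10, 0, 0.03),
                  se_y = 0.03)
    cochran_q(h)$q
  }, numeric(1))
  expect_gt(stats::ks.test(qs, stats::pchisq, df = 9)$p.value, 0.01)
})

test_that("a planted outlier inflates Q detectably", {
  hits <- vapply(1:100, function(s) {
    h <- sim_hset(s, theta = 0.2, J = 30, outlier_fraction = 1 / 30,
                  outlier_scale = 5)
    cochran_q(h)$q_pvalue < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(13)
  p <- runif(50)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  expect_equal(order(adj[order(p)]), seq_len(50))  # monotone transform
})

test_that("Steiger symmetry, antisymmetry and direction recovery", {
  # Identical association profiles and sample sizes: no direction, p = 1.
  h <- toy_hset(beta_x = c(0.3, 0.4), beta_y = c(0.3, 0.4),
                se_x = 0.05, se_y = 0.05, n_x = 5000, n_y = 5000)
  st <- steiger_test(h)
  expect_equal(st$pvalue, 1)
  expect_false(st$direction_forward)

  # Swapping exposure and outcome flips the call.
  h2 <- toy_hset(beta_x = c(0.3, 0.4), beta_y = c(0.05, 0.06),
                 se_x = 0.05, se_y = 0.05, n_x = 5000, n_y = 5000)
  fwd <- steiger_test(h2)
  rev <- steiger_test(toy_hset(beta_x = c(0.05, 0.06), beta_y = c(0.3, 0.4),
                               se_x = 0.05, se_y = 0.05,
                               n_x = 5000, n_y = 5000))
  expect_true(fwd$direction_forward)
  expect_false(rev$direction_forward)
  expect_equal(fwd$pvalue, rev$pvalue)

  # Simulated forward-causal data is called forward essentially always.
  calls <- vapply(1:50, function(s) {
    steiger_test(sim_hset(s, theta = 0.2))$direction_forward
  }, logical(1))
  expect_gte(mean(calls), 0.95)
})

test_that("leave-one-out returns one refit per instrument", {
  h <- sim_hset(3, theta = 0.2, J = 10)
  loo <- leave_one_out(h)
  expect_equal(nrow(loo), nrow(h))
  expect_equal(loo$left_out, h$variant_id)
  expect_lt(max(abs(loo$theta_hat - 0.2)), 0.05)
})
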