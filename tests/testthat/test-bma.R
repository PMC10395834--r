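# Build a bma_input straight from a multivariable simulation's observed
# effects (harmonization is exercised separately through prepare_bma_input).
sim_bma_input <- function(seed, K = 3, J = 40, causal = 1, effect = 0.3,
                          corr = NULL) {
  sim <- simulate_multivariable(n_variants = J, n_exposures = K,
                                causal_subset = causal,
                                causal_effects = effect,
                                exposure_correlation = corr, seed = seed)
  X <- vapply(sim$exposures, function(e) e$beta, numeric(J))
  rownames(X) <- sim$outcome$variant_id
  bma_input(X, sim$outcome$beta, sim$outcome$se)
}

test_that("model evidence matches direct multivariate-density evaluation", {
  inp <- sim_bma_input(1, K = 3, J = 6)
  for (subset in list(1, c(1, 2), c(2, 3), c(1, 2, 3))) {
    le <- model_log_evidence(inp, subset, prior_sd = 0.5)
    # Independent brute force: density of whitened y under
    # N(0, I + s^2 X X'), dropping the same 2*pi constant.
    Xt <- inp$X[, subset, drop = FALSE] / inp$se_y
    yt <- inp$beta_y / inp$se_y
    M <- diag(6) + 0.25 * Xt %*% t(Xt)
    oracle <- -0.5 * (determinant(M)$modulus[1] +
                        drop(t(yt) %*% solve(M) %*% yt))
    expect_equal(as.numeric(le), oracle, tolerance = 1e-10)
  }
})

test_that("evidence shrinks to the null model as the prior SD vanishes", {
  inp <- sim_bma_input(2, K = 3, J = 10)
  null_ev <- model_log_evidence(inp, integer(0))
  expect_equal(as.numeric(model_log_evidence(inp, c(1, 2), prior_sd = 1e-8)),
               as.numeric(null_ev), tolerance = 1e-6)
})

test_that("a truly causal exposure out-scores a null one", {
  inp <- sim_bma_input(3, K = 2, J = 40, causal = 1, effect = 0.3)
  expect_gt(as.numeric(model_log_evidence(inp, 1)),
            as.numeric(model_log_evidence(inp, 2)))
})

test_that("collinear subsets and oversized models raise typed errors", {
  inp <- sim_bma_input(4, K = 3, J = 10)
  inp$X[, 2] <- 2 * inp$X[, 1]
  expect_error(model_log_evidence(inp, c(1, 2)),
               class = "mrscreen_collinearity_error")
  small <- sim_bma_input(4, K = 3, J = 3)
  expect_error(model_log_evidence(small, c(1, 2, 3)),
               class = "mrscreen_validation_error")
})

test_that("MIP and MACE equal brute-force sums over the full model list", {
  for (K in c(4, 6)) {
    inp <- sim_bma_input(10 + K, K = K, J = 30, causal = c(1, 2),
                         effect = c(0.3, -0.2))
    res <- bma_rank(inp, prior_prob = 0.1, prior_sd = 0.5)
    expect_equal(sum(res$models$posterior), 1, tolerance = 1e-12)

    # Independent enumeration with its own posterior arithmetic.
    subsets <- unlist(lapply(0:K, function(m) {
      utils::combn(K, m, simplify = FALSE)
    }), recursive = FALSE)
    lp <- vapply(subsets, function(s) {
      as.numeric(model_log_evidence(inp, s, 0.5)) +
        length(s) * log(0.1) + (K - length(s)) * log(0.9)
    }, numeric(1))
    post <- exp(lp - max(lp)); post <- post / sum(post)
    mip <- vapply(1:K, function(k) {
      sum(post[vapply(subsets, function(s) k %in% s, logical(1))])
    }, numeric(1))
    mace <- vapply(1:K, function(k) {
      sum(vapply(seq_along(subsets), function(i) {
        if (!(k %in% subsets[[i]])) return(0)
        est <- attr(model_log_evidence(inp, subsets[[i]], 0.5), "estimates")
        post[i] * est[[inp$exposure_ids[k]]]
      }, numeric(1)))
    }, numeric(1))

    ord <- match(inp$exposure_ids, res$ranking$exposure_id)
    expect_equal(res$ranking$mip[ord], mip, tolerance = 1e-10)
    expect_equal(res$ranking$mace[ord], mace, tolerance = 1e-10)
    max_conditional <- vapply(seq_len(K), function(k) {
      max(abs(vapply(res$models$estimates, function(e) {
        v <- e[inp$exposure_ids[k]]
        if (is.na(v)) 0 else v
      }, numeric(1))))
    }, numeric(1))
    expect_true(all(abs(res$ranking$mace) <= max_conditional[ord] + 1e-12))
  }
})

test_that("with one exposure and flat evidence the MIP recovers the prior", {
  X <- matrix(1e-10, 20, 1, dimnames = list(sprintf("rs%02d", 1:20), "e1"))
  inp <- bma_input(X, rnorm(20, 0, 0.01), rep(0.01, 20))
  res <- bma_rank(inp, prior_prob = 0.1)
  expect_equal(res$ranking$mip, 0.1, tolerance = 1e-4)
})

test_that("an inclusion prior near one recovers the full-model estimate", {
  inp <- sim_bma_input(6, K = 1, J = 30, causal = 1, effect = 0.3)
  res <- bma_rank(inp, prior_prob = 0.999)
  full <- attr(model_log_evidence(inp, 1, 0.5), "estimates")[[1]]
  expect_equal(res$ranking$mace[1], full, tolerance = 1e-2)
})

test_that("permuting exposure columns permutes MIP and MACE identically", {
  inp <- sim_bma_input(7, K = 4, J = 30, causal = c(1, 3),
                       effect = c(0.3, -0.2))
  perm <- c(3, 1, 4, 2)
  inp2 <- bma_input(inp$X[, perm], inp$beta_y, inp$se_y)
  r1 <- bma_rank(inp)$ranking
  r2 <- bma_rank(inp2)$ranking
  expect_equal(r1$mip[match(inp$exposure_ids[perm], r1$exposure_id)],
               r2$mip[match(colnames(inp2$X), r2$exposure_id)],
               tolerance = 1e-12)
  expect_equal(r1$mace[match(inp$exposure_ids[perm], r1$exposure_id)],
               r2$mace[match(colnames(inp2$X), r2$exposure_id)],
               tolerance = 1e-12)
})

test_that("shotgun search reproduces exhaustive MIPs on a covered space", {
  inp <- sim_bma_input(8, K = 10, J = 50, causal = c(1, 2),
                       effect = c(0.3, -0.25))
  ex <- bma_rank(inp, method = "exhaustive")
  sg <- bma_rank(inp, method = "shotgun", search_budget = 2000, seed = 3)
  m <- match(ex$ranking$exposure_id, sg$ranking$exposure_id)
  expect_lt(max(abs(ex$ranking$mip - sg$ranking$mip[m])), 0.02)
})

test_that("exposure pruning removes the duplicated trait", {
  corr <- diag(3); corr[1, 2] <- corr[2, 1] <- 1
  sim <- simulate_multivariable(n_variants = 50, n_exposures = 3,
                                causal_subset = 1, causal_effects = 0.3,
                                exposure_correlation = corr, seed = 9)
  inp <- prepare_bma_input(sim$exposures, sim$outcome)
  expect_equal(length(inp$exposure_ids), 2)
  expect_equal(nrow(inp$pruned), 1)
  expect_true(inp$pruned$exposure_id %in%
                c("sim_exposure_01", "sim_exposure_02"))

  # Orthogonal exposures are never pruned, matching a brute-force scan.
  sim2 <- simulate_multivariable(n_variants = 50, n_exposures = 4,
                                 causal_subset = 1, seed = 10)
  inp2 <- prepare_bma_input(sim2$exposures, sim2$outcome)
  expect_equal(length(inp2$exposure_ids), 4)
  cm <- cor(inp2$X)
  expect_true(all(abs(cm[upper.tri(cm)]) <= 0.985))
})

test_that("degenerate panels direct the user to univariable analysis", {
  corr <- diag(2); corr[1, 2] <- corr[2, 1] <- 1
  sim <- simulate_multivariable(n_variants = 40, n_exposures = 2,
                                causal_subset = 1,
                                exposure_correlation = corr, seed = 11)
  expect_error(prepare_bma_input(sim$exposures, sim$outcome),
               class = "mrscreen_degeneracy_error")
})

test_that("a planted high-leverage variant dominates the diagnostics", {
  inp <- sim_bma_input(12, K = 3, J = 40, causal = 1, effect = 0.3)
  lev <- which.max(abs(inp$X[, 1]))
  inp$X[lev, 1] <- 10 * inp$X[lev, 1]
  res <- bma_rank(inp)
  diag_tbl <- bma_diagnostics(inp, res, top_models = 1)
  top_variant <- diag_tbl$variant_id[which.max(diag_tbl$cooks_d)]
  expect_equal(top_variant, inp$variant_ids[lev])
  expect_true(diag_tbl$influential[which.max(diag_tbl$cooks_d)])

  # The re-run hook excludes it and changes the ranking inputs.
  res2 <- bma_rank(inp, exclude_variants = top_variant)
  expect_equal(nrow(res2$input$X), 39)
})

test_that("clean homogeneous data yields only sporadic low-level flags", {
  flagged <- vapply(1:10, function(s) {
    inp <- sim_bma_input(100 + s, K = 3, J = 40, causal = 1, effect = 0.3)
    res <- bma_rank(inp)
    mean(bma_diagnostics(inp, res, top_models = 1)$influential)
  }, numeric(1))
  expect_lt(mean(flagged), 0.12)
})
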