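#' Assemble the multivariable-MR design from an exposure panel
#'
#' Takes the union of instruments significant for any exposure at
#' `p_threshold`, harmonizes every exposure against the outcome on a
#' common (outcome-allele) orientation, and greedily prunes exposures
#' whose instrument-effect vectors are nearly collinear: while any pair
#' has absolute correlation above `correlation_bound` (default 0.985),
#' the member with the larger univariable IVW p-value is removed.
#' Genetically near-duplicate microbial traits otherwise make the model
#' space unidentifiable.
#'
#' @param exposures List of exposure `summary_dataset`s (>= 2).
#' @param outcome Outcome `summary_dataset`.
#' @param p_threshold Instrument significance threshold (default 1e-5).
#' @param correlation_bound Pruning bound on pairwise |cor| of exposure
#'   effect vectors.
#' @param palindrome_maf,f_min Passed to [harmonize()].
#' @return A `bma_input` list: `X` (J x K matrix of SNP-exposure effects,
#'   variants x exposures), `beta_y`, `se_y`, `exposure_ids`,
#'   `univariable_p`, `pruned` (log of removed exposures), `variant_ids`.
#' @export
prepare_bma_input <- function(exposures, outcome, p_threshold = 1e-5,
                              correlation_bound = 0.985,
                              palindrome_maf = 0.3, f_min = 10) {
  stopifnot(length(exposures) >= 2)
  out_tbl <- as_tibble(outcome)

  harmonized <- purrr::map(exposures, function(ex) {
    sel <- select_instruments(ex, p_threshold)
    if (nrow(sel) == 0) return(NULL)
    h <- harmonize(sel, outcome, palindrome_maf, f_min)
    if (nrow(h) == 0) return(NULL)
    # Re-express on the outcome's reported effect allele so all exposure
    # columns share one orientation.
    orig <- out_tbl$beta[match(h$variant_id, out_tbl$variant_id)]
    flip <- abs(h$beta_y - orig) > abs(h$beta_y + orig)
    h$beta_x[flip] <- -h$beta_x[flip]
    h$beta_y[flip] <- -h$beta_y[flip]
    h
  })
  names(harmonized) <- vapply(exposures, function(e) attr(e, "trait_id"),
                              character(1))
  kept <- !vapply(harmonized, is.null, logical(1))
  harmonized <- harmonized[kept]
  if (length(harmonized) < 2) {
    abort_mrscreen(
      "fewer than 2 exposures have usable instruments; run a univariable analysis instead",
      class = "mrscreen_degeneracy_error")
  }

  union_ids <- sort(unique(unlist(lapply(harmonized, function(h) h$variant_id))))
  # Full effect vectors over the union require each exposure dataset to
  # report all union variants (standard for a panel from one GWAS).
  X <- vapply(names(harmonized), function(id) {
    ex <- exposures[[which(vapply(exposures, function(e)
      identical(attr(e, "trait_id"), id), logical(1)))[1]]]
    h_all <- harmonize(restamp(as_tibble(ex), ex), outcome,
                       palindrome_maf, f_min = 0)
    orig <- out_tbl$beta[match(h_all$variant_id, out_tbl$variant_id)]
    flip <- abs(h_all$beta_y - orig) > abs(h_all$beta_y + orig)
    h_all$beta_x[flip] <- -h_all$beta_x[flip]
    h_all$beta_x[match(union_ids, h_all$variant_id)]
  }, numeric(length(union_ids)))
  rownames(X) <- union_ids
  keep_rows <- complete.cases(X) & union_ids %in% out_tbl$variant_id
  X <- X[keep_rows, , drop = FALSE]
  union_ids <- union_ids[keep_rows]
  beta_y <- out_tbl$beta[match(union_ids, out_tbl$variant_id)]
  se_y <- out_tbl$se[match(union_ids, out_tbl$variant_id)]

  univ_p <- vapply(harmonized, function(h) ivw(h)$pvalue, numeric(1))

  # Greedy correlation pruning.
  pruned <- tibble(exposure_id = character(0), against = character(0),
                   correlation = numeric(0))
  active <- colnames(X)
  repeat {
    if (length(active) < 2) break
    cm <- cor(X[, active, drop = FALSE])
    diag(cm) <- 0
    mx <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
    if (abs(cm[mx[1], mx[2]]) <= correlation_bound) break
    pair <- active[mx]
    worse <- pair[which.max(univ_p[pair])]
    pruned <- bind_rows(pruned, tibble(
      exposure_id = worse, against = setdiff(pair, worse)[1],
      correlation = cm[mx[1], mx[2]]))
    active <- setdiff(active, worse)
  }
  if (length(active) < 2) {
    abort_mrscreen(
      "fewer than 2 exposures survive correlation pruning; run a univariable analysis instead",
      class = "mrscreen_degeneracy_error")
  }
  structure(list(
    X = X[, active, drop = FALSE], beta_y = beta_y, se_y = se_y,
    exposure_ids = active, univariable_p = univ_p[active],
    pruned = pruned, variant_ids = union_ids
  ), class = "bma_input")
}

#' Construct a `bma_input` directly from matrices
#'
#' Low-level constructor used by tests and simulations that already hold
#' harmonized effect matrices.
#'
#' @param X J x K matrix of SNP-exposure effects (column names = exposure
#'   ids, row names = variant ids).
#' @param beta_y,se_y Outcome effects and SEs (length J).
#' @export
bma_input <- function(X, beta_y, se_y) {
  stopifnot(is.matrix(X), nrow(X) == length(beta_y),
            length(beta_y) == length(se_y), all(se_y > 0))
  if (is.null(colnames(X))) colnames(X) <- sprintf("exposure_%02d", seq_len(ncol(X)))
  if (is.null(rownames(X))) rownames(X) <- sprintf("rs%06d", seq_len(nrow(X)))
  structure(list(X = X, beta_y = beta_y, se_y = se_y,
                 exposure_ids = colnames(X),
                 univariable_p = setNames(rep(NA_real_, ncol(X)), colnames(X)),
                 pruned = tibble(), variant_ids = rownames(X)),
            class = "bma_input")
}

#' Log marginal likelihood of one exposure subset
#'
#' Inverse-variance whitened regression of outcome effects on the
#' subset's effect columns with independent `N(0, prior_sd^2)` priors on
#' the causal effects.  With whitened `X`, `y` and
#' `A = I_k + prior_sd^2 * X'X`, the evidence is
#' `-0.5 * (log det A + y'y - prior_sd^2 * b' A^-1 b)` where `b = X'y`;
#' the `-J/2 log(2pi)` constant common to all models is dropped (only
#' evidence differences matter).  The empty subset gives the null-model
#' evidence `-0.5 * y'y`.
#'
#' @param input A `bma_input`.
#' @param subset Integer indices (or exposure ids) of the model's
#'   exposures; may be empty.
#' @param prior_sd Prior SD of causal effects (default 0.5).
#' @return Scalar log evidence, with attribute `estimates` (conditional
#'   posterior-mean causal effects for the subset).
#' @export
model_log_evidence <- function(input, subset, prior_sd = 0.5) {
  if (is.character(subset)) subset <- match(subset, input$exposure_ids)
  stopifnot(!anyNA(subset), all(subset %in% seq_along(input$exposure_ids)))
  yt <- input$beta_y / input$se_y
  if (length(subset) == 0) {
    le <- -0.5 * sum(yt^2)
    attr(le, "estimates") <- setNames(numeric(0), character(0))
    return(le)
  }
  if (length(subset) >= nrow(input$X)) {
    abort_mrscreen("model size must be below the instrument count",
                   class = "mrscreen_validation_error")
  }
  Xt <- input$X[, subset, drop = FALSE] / input$se_y
  if (qr(Xt)$rank < ncol(Xt)) {
    abort_mrscreen("rank-deficient subset design (collinear exposures)",
                   class = "mrscreen_collinearity_error")
  }
  A <- diag(length(subset)) + prior_sd^2 * crossprod(Xt)
  b <- crossprod(Xt, yt)
  cA <- chol(A)
  logdet <- 2 * sum(log(diag(cA)))
  Ainv_b <- backsolve(cA, forwardsolve(t(cA), b))
  le <- -0.5 * (logdet + sum(yt^2) - prior_sd^2 * sum(b * Ainv_b))
  attr(le, "estimates") <- setNames(drop(prior_sd^2 * Ainv_b),
                                    input$exposure_ids[subset])
  le
}

subset_key <- function(s) {
  if (length(s) == 0) "(null)" else paste(sort(s), collapse = ",")
}

#' Bayesian model averaging over multivariable MR models
#'
#' Scores exposure subsets by their marginal likelihood
#' ([model_log_evidence()]) combined with the independent-inclusion model
#' prior `prior_prob^|S| * (1-prior_prob)^(K-|S|)`, then reports each
#' exposure's marginal inclusion probability (MIP — the summed posterior
#' of models containing it) and model-averaged causal effect (MACE — the
#' posterior-weighted conditional estimate, zero in models excluding the
#' exposure, hence a conservative direct-effect estimate).  The model
#' space (including the empty model) is enumerated exhaustively when
#' `K <= 15`; otherwise a seeded shotgun stochastic search with
#' add/delete/swap moves evaluates at most `search_budget` distinct
#' models and posteriors are normalized over the evaluated space.
#'
#' @param input A `bma_input`.
#' @param prior_prob Prior inclusion probability per exposure (default 0.1).
#' @param prior_sd Prior SD of causal effects (default 0.5).
#' @param search_budget Maximum distinct models evaluated under stochastic
#'   search (default 10000).
#' @param seed Seed for the stochastic search.
#' @param mip_threshold Reporting threshold on MIP (default 0.1).
#' @param top_k Top-k selection flag in the ranking (default 10).
#' @param exclude_variants Optional variant ids to drop before fitting
#'   (the influence-diagnostic re-run hook).
#' @param method `"auto"`, `"exhaustive"` or `"shotgun"`.
#' @return A `bma_result` list: `ranking` (tibble exposure/mip/mace/rank/
#'   flags), `models` (tibble of evaluated models with posteriors),
#'   `hyper`, `input`.
#' @export
bma_rank <- function(input, prior_prob = 0.1, prior_sd = 0.5,
                     search_budget = 10000, seed = 1, mip_threshold = 0.1,
                     top_k = 10, exclude_variants = NULL,
                     method = c("auto", "exhaustive", "shotgun")) {
  method <- rlang::arg_match(method)
  stopifnot(prior_prob > 0, prior_prob < 1, prior_sd > 0)
  if (!is.null(exclude_variants)) {
    keep <- !(input$variant_ids %in% exclude_variants)
    input$X <- input$X[keep, , drop = FALSE]
    input$beta_y <- input$beta_y[keep]
    input$se_y <- input$se_y[keep]
    input$variant_ids <- input$variant_ids[keep]
  }
  K <- ncol(input$X)
  if (method == "auto") method <- if (K <= 15) "exhaustive" else "shotgun"

  log_prior <- function(k) k * log(prior_prob) + (K - k) * log(1 - prior_prob)

  cache <- new.env(parent = emptyenv())
  evaluate <- function(s) {
    key <- subset_key(s)
    if (!is.null(cache[[key]])) return(cache[[key]])
    le <- model_log_evidence(input, s, prior_sd)
    rec <- list(subset = sort(s), log_evidence = as.numeric(le),
                estimates = attr(le, "estimates"),
                log_post_unnorm = as.numeric(le) + log_prior(length(s)))
    cache[[key]] <- rec
    rec
  }

  if (method == "exhaustive") {
    for (size in 0:K) {
      combos <- utils::combn(K, size, simplify = FALSE)
      for (s in combos) evaluate(s)
    }
  } else {
    set.seed(seed)
    evaluate(integer(0))
    for (k in seq_len(K)) evaluate(k)
    singles <- vapply(seq_len(K), function(k) cache[[subset_key(k)]]$log_post_unnorm,
                      numeric(1))
    current <- which.max(singles)
    n_eval <- K + 1L
    stall <- 0L
    iter <- 0L
    while (n_eval < search_budget && stall < 100L && iter < 10L * search_budget) {
      iter <- iter + 1L
      n_eval_before <- n_eval
      in_s <- current
      out_s <- setdiff(seq_len(K), in_s)
      neighbors <- c(
        lapply(out_s, function(j) sort(c(in_s, j))),
        lapply(in_s, function(i) setdiff(in_s, i)),
        unlist(lapply(in_s, function(i) {
          lapply(out_s, function(j) sort(c(setdiff(in_s, i), j)))
        }), recursive = FALSE)
      )
      lp <- vapply(neighbors, function(s) {
        key <- subset_key(s)
        if (is.null(cache[[key]])) {
          if (n_eval >= search_budget) return(NA_real_)
          n_eval <<- n_eval + 1L
        }
        evaluate(s)$log_post_unnorm
      }, numeric(1))
      ok <- !is.na(lp)
      if (!any(ok)) break
      wts <- exp(lp[ok] - max(lp[ok]))
      current <- neighbors[ok][[sample.int(sum(ok), 1, prob = wts)]]
      stall <- if (n_eval == n_eval_before) stall + 1L else 0L
      if (length(ls(cache)) >= 2^K) break
    }
  }

  recs <- as.list(cache)
  lpu <- vapply(recs, function(r) r$log_post_unnorm, numeric(1))
  post <- exp(lpu - logsumexp(lpu))
  post <- post / sum(post)

  mip <- setNames(rep(0, K), input$exposure_ids)
  mace <- setNames(rep(0, K), input$exposure_ids)
  for (i in seq_along(recs)) {
    s <- recs[[i]]$subset
    if (length(s) > 0) {
      mip[s] <- mip[s] + post[i]
      mace[s] <- mace[s] + post[i] * recs[[i]]$estimates
    }
  }
  ranking <- tibble(exposure_id = input$exposure_ids,
                    mip = unname(mip), mace = unname(mace)) %>%
    arrange(dplyr::desc(.data$mip)) %>%
    mutate(rank = row_number(),
           mip_above_threshold = .data$mip > mip_threshold,
           top_k = .data$rank <= !!top_k)

  models <- tibble(
    model = vapply(recs, function(r) subset_key(r$subset), character(1)),
    size = vapply(recs, function(r) length(r$subset), integer(1)),
    log_evidence = vapply(recs, function(r) r$log_evidence, numeric(1)),
    posterior = post,
    estimates = lapply(recs, function(r) r$estimates)
  ) %>% arrange(dplyr::desc(.data$posterior))

  structure(list(ranking = ranking, models = models,
                 hyper = list(prior_prob = prior_prob, prior_sd = prior_sd,
                              search_budget = search_budget, seed = seed,
                              method = method, mip_threshold = mip_threshold,
                              top_k = top_k),
                 input = input),
            class = "bma_result")
}

#' Influence diagnostics for the top posterior models
#'
#' For each of the `top_models` highest-posterior (nonempty) models,
#' computes per-variant Cook's distances from the whitened weighted fit
#' and the per-variant heterogeneity contribution (squared whitened
#' residual).  Variants with Cook's distance above `cd_threshold`
#' (default 4/J) are flagged as influence points; re-run the averaging
#' without them via `bma_rank(..., exclude_variants = )`.
#'
#' @param input A `bma_input`.
#' @param result A `bma_result` from [bma_rank()].
#' @param top_models Number of top models to examine (default 3).
#' @param cd_threshold Cook's-distance flag threshold (default `4/J`).
#' @return A tibble: model, posterior, variant_id, cooks_d,
#'   q_contribution, influential.
#' @export
bma_diagnostics <- function(input, result, top_models = 3,
                            cd_threshold = NULL) {
  J <- nrow(input$X)
  cd_threshold <- cd_threshold %||% (4 / J)
  models <- result$models %>% filter(.data$size > 0) %>% head(top_models)
  yt <- input$beta_y / input$se_y
  purrr::map(seq_len(nrow(models)), function(i) {
    idx <- as.integer(strsplit(models$model[i], ",")[[1]])
    Xt <- input$X[, idx, drop = FALSE] / input$se_y
    fit <- lm(yt ~ Xt - 1)
    tibble(model = models$model[i], posterior = models$posterior[i],
           variant_id = input$variant_ids,
           cooks_d = unname(cooks.distance(fit)),
           q_contribution = unname(stats::residuals(fit)^2),
           influential = unname(cooks.distance(fit)) > cd_threshold)
  }) %>% list_rbind()
}

#' @method tidy bma_result
#' @export
tidy.bma_result <- function(x, ...) x$ranking

#' @method glance bma_result
#' @export
glance.bma_result <- function(x, ...) {
  tibble(n_exposures = length(x$input$exposure_ids),
         n_models_evaluated = nrow(x$models),
         method = x$hyper$method,
         top_model = x$models$model[1],
         top_model_posterior = x$models$posterior[1])
}

#' @export
print.bma_result <- function(x, ...) {
  cat(sprintf("MR model averaging over %d exposures (%s, %d models)\n",
              length(x$input$exposure_ids), x$hyper$method, nrow(x$models)))
  print(x$ranking)
  invisible(x)
}

#' MIP bar chart for a model-averaging result
#'
#' @param object A `bma_result`.
#' @param ... Unused.
#' @method autoplot bma_result
#' @export
autoplot.bma_result <- function(object, ...) {
  df <- object$ranking
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$exposure_id, .data$mip), y = .data$mip,
    fill = .data$mip_above_threshold)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$hyper$mip_threshold,
                        linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Marginal inclusion probability",
                  fill = sprintf("MIP > %.2g", object$hyper$mip_threshold)) +
    ggplot2::theme_minimal()
}
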