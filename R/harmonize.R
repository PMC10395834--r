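#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome dataset onto the exposure's effect alleles so that
#' every estimator downstream sees per-variant effect pairs expressed for
#' the same allele.  Variants are matched by id; outcome effects are
#' sign-flipped (and frequencies complemented) when the outcome reports
#' the opposite allele, strand-complement pairs are complemented before
#' alignment, and palindromic (A/T, C/G) variants — where allele letters
#' cannot resolve strand — are aligned by allele-frequency matching when
#' the minor-allele frequency is informative, and excluded as ambiguous
#' when `min(eaf, 1-eaf) > palindrome_maf_limit` (default 0.3) or the
#' frequency is missing.  Weak instruments (`F < f_min`) are excluded
#' after alignment.
#'
#' Every input variant from either dataset appears exactly once across
#' the retained set and the exclusion log (`exclusion_log()`), with reason
#' codes `unmatched`, `palindrome_ambiguous`, `allele_mismatch`,
#' `weak_instrument`.
#'
#' @param exposure,outcome `summary_dataset` objects.
#' @param palindrome_maf_limit Palindromes with minor-allele frequency
#'   above this are dropped as strand-ambiguous; in (0, 0.5].
#' @param f_min Minimum instrument F statistic; `0` disables the filter.
#' @return A `harmonized_set` tibble with columns `variant_id`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `eaf`, `beta_x`, `se_x`,
#'   `pval_x`, `beta_y`, `se_y`, `pval_y`, `f_stat`; attributes
#'   `exposure_id`, `outcome_id`, `n_exposure`, `n_outcome`, `exclusions`.
#' @export
harmonize <- function(exposure, outcome, palindrome_maf_limit = 0.3,
                      f_min = 10) {
  stopifnot(palindrome_maf_limit > 0, palindrome_maf_limit <= 0.5)
  ex <- as_tibble(exposure)
  out <- as_tibble(outcome)

  excl <- list()
  note <- function(ids, reason) {
    if (length(ids) > 0) {
      excl[[length(excl) + 1L]] <<- tibble(variant_id = ids, reason = reason)
    }
  }
  note(setdiff(ex$variant_id, out$variant_id), "unmatched")
  note(setdiff(out$variant_id, ex$variant_id), "unmatched")

  m <- dplyr::inner_join(
    ex %>% select("variant_id", "chrom", "pos", "effect_allele",
                  "other_allele", "eaf",
                  beta_x = "beta", se_x = "se", pval_x = "pval", n_x = "n"),
    out %>% select("variant_id", ea_y = "effect_allele", oa_y = "other_allele",
                   eaf_y = "eaf", beta_y = "beta", se_y = "se",
                   pval_y = "pval", n_y = "n"),
    by = "variant_id"
  )

  if (nrow(m) > 0) {
    pal <- is_palindromic(m$effect_allele, m$other_allele)
    comp_ea <- allele_complement(m$ea_y)
    comp_oa <- allele_complement(m$oa_y)

    same <- m$ea_y == m$effect_allele & m$oa_y == m$other_allele
    swap <- m$ea_y == m$other_allele & m$oa_y == m$effect_allele
    csame <- comp_ea == m$effect_allele & comp_oa == m$other_allele
    cswap <- comp_ea == m$other_allele & comp_oa == m$effect_allele

    status <- rep("ok", nrow(m))
    flip <- rep(FALSE, nrow(m))

    # Non-palindromic: allele letters determine orientation uniquely.
    np <- !pal
    flip[np] <- (swap | cswap)[np]
    status[np & !(same | swap | csame | cswap)] <- "allele_mismatch"

    # Palindromic: letters are strand-ambiguous; the pair must still be the
    # same letter pair, and frequency matching resolves orientation for
    # low-frequency variants only.
    pair_ok <- same | swap | csame | cswap
    status[pal & !pair_ok] <- "allele_mismatch"
    maf <- pmin(m$eaf, 1 - m$eaf)
    amb <- pal & pair_ok & (is.na(m$eaf) | is.na(m$eaf_y) | maf > palindrome_maf_limit)
    status[amb] <- "palindrome_ambiguous"
    freq_ok <- pal & pair_ok & !amb
    flip[freq_ok] <- ((m$eaf - 0.5) * (m$eaf_y - 0.5) < 0)[freq_ok]

    m$beta_y <- ifelse(flip, -m$beta_y, m$beta_y)
    m$eaf_y <- ifelse(flip, 1 - m$eaf_y, m$eaf_y)

    note(m$variant_id[status == "allele_mismatch"], "allele_mismatch")
    note(m$variant_id[status == "palindrome_ambiguous"], "palindrome_ambiguous")
    m <- m[status == "ok", , drop = FALSE]
  }

  m$f_stat <- if (nrow(m) > 0) f_statistic(m$beta_x, m$se_x) else numeric(0)
  if (f_min > 0 && nrow(m) > 0) {
    weak <- m$f_stat < f_min
    note(m$variant_id[weak], "weak_instrument")
    m <- m[!weak, , drop = FALSE]
  }

  exclusions <- if (length(excl) > 0) bind_rows(excl) else {
    tibble(variant_id = character(0), reason = character(0))
  }
  res <- m %>%
    select("variant_id", "chrom", "pos", "effect_allele", "other_allele",
           "eaf", "beta_x", "se_x", "pval_x", "beta_y", "se_y", "pval_y",
           "f_stat", "n_x", "n_y")
  structure(res,
            exposure_id = attr(exposure, "trait_id"),
            outcome_id = attr(outcome, "trait_id"),
            exclusions = exclusions,
            class = c("harmonized_set", class(tibble())))
}

#' @rdname harmonize
#' @param hset A `harmonized_set`.
#' @export
exclusion_log <- function(hset) attr(hset, "exclusions")

#' Convert one side of a harmonized set back to a summary dataset
#'
#' Convenience for re-running harmonization or feeding a harmonized side
#' into a different pairing (used when building mediation triads).
#'
#' @param hset A `harmonized_set`.
#' @param side `"exposure"` or `"outcome"`.
#' @export
as_summary_dataset <- function(hset, side = c("exposure", "outcome")) {
  side <- rlang::arg_match(side)
  b <- if (side == "exposure") hset$beta_x else hset$beta_y
  s <- if (side == "exposure") hset$se_x else hset$se_y
  p <- if (side == "exposure") hset$pval_x else hset$pval_y
  n <- if (side == "exposure") hset$n_x else hset$n_y
  summary_dataset(
    tibble(variant_id = hset$variant_id, chrom = hset$chrom, pos = hset$pos,
           effect_allele = hset$effect_allele, other_allele = hset$other_allele,
           eaf = hset$eaf, beta = b, se = s, pval = p, n = n),
    trait_id = attr(hset, if (side == "exposure") "exposure_id" else "outcome_id"),
    trait_type = if (side == "exposure") "exposure" else "outcome"
  )
}
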