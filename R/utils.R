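#' Internal helpers shared across modules
#'
#' @noRd
NULL

VALID_ALLELES <- c("A", "C", "G", "T")

allele_complement <- function(a) {
  chartr("ACGT", "TGCA", a)
}

#' Is an allele pair palindromic?
#'
#' A palindromic (ambiguous-strand) variant has alleles that are reverse
#' complements of each other, i.e. the pair is \{A,T\} or \{C,G\}.  Such
#' variants cannot be strand-aligned between two datasets from allele
#' letters alone.
#'
#' @param effect_allele,other_allele Single-nucleotide alleles (A/C/G/T),
#'   vectorized.
#' @return Logical vector.
#' @examples
#' is_palindromic("A", "T")
#' is_palindromic(c("A", "C"), c("G", "G"))
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  check_alleles(effect_allele)
  check_alleles(other_allele)
  allele_complement(effect_allele) == other_allele
}

check_alleles <- function(a, arg = rlang::caller_arg(a)) {
  bad <- !(a %in% VALID_ALLELES)
  if (any(bad)) {
    abort_mrscreen(
      sprintf("`%s` contains non-ACGT alleles: %s", arg,
              paste(unique(a[bad]), collapse = ", ")),
      class = "mrscreen_allele_error"
    )
  }
  invisible(a)
}

abort_mrscreen <- function(message, class = "mrscreen_error", ...) {
  rlang::abort(message, class = c(class, "mrscreen_error"), ...)
}

#' @noRd
# Numerically stable log(sum(exp(x))).
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @noRd
# log(exp(a) - exp(b)) for a >= b, stable.
logdiffexp <- function(a, b) {
  if (b > a) return(NaN)
  if (b == -Inf) return(a)
  a + log1p(-exp(b - a))
}

#' @noRd
# Derive a reproducible sub-seed from a root seed and a stream label.
# Keeps results independent across pipeline stages while remaining a pure
# function of (seed, stream).  Stays below 2^31 - 1.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483629)
}

#' @noRd
# GWAS standard-error model for a standardized trait: se = 1/sqrt(2 n p (1-p)).
se_from_n_eaf <- function(n, eaf) {
  1 / sqrt(2 * n * eaf * (1 - eaf))
}

#' @noRd
# Two-sided normal p-value, floored so extreme z-scores never underflow to
# an invalid p = 0.
pval_from_z <- function(z) {
  pmax(2 * pnorm(-abs(z)), .Machine$double.xmin)
}

#' @noRd
round_half_away <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' @noRd
`%||%` <- rlang::`%||%`
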