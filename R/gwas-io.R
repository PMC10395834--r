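#' GWAS summary-statistics tables
#'
#' A summary dataset is a tibble with one row per variant and the canonical
#' columns `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#' `eaf`, `beta`, `se`, `pval`, `n`, carrying the trait identity in
#' attributes.  `beta` is the additive per-allele effect of the effect
#' allele (log-odds for binary traits), `se` its standard error, `eaf` the
#' effect-allele frequency.
#'
#' Rows violating the per-variant invariants (`se > 0`, alleles in A/C/G/T
#' and distinct, `eaf` in (0,1) or missing, `pval` in (0,1]) are dropped
#' and tallied in the `audit` attribute rather than raising an error, so a
#' messy public download never aborts a screen.
#'
#' @param x A data frame with the canonical columns (extra columns kept).
#' @param trait_id Trait identifier, e.g. a GWAS accession.
#' @param trait_type One of `"exposure"`, `"outcome"`, `"mediator"`.
#' @return A `summary_dataset` tibble; attributes `trait_id`, `trait_type`
#'   and `audit` (a tibble of drop reasons and counts).
#' @export
summary_dataset <- function(x, trait_id = "trait", trait_type = "exposure") {
  trait_type <- rlang::arg_match(trait_type, c("exposure", "outcome", "mediator"))
  x <- as_tibble(x)
  required <- c("variant_id", "effect_allele", "other_allele", "beta", "se", "pval")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort_mrscreen(
      sprintf("missing required column(s): %s", paste(missing_cols, collapse = ", ")),
      class = "mrscreen_format_error"
    )
  }
  for (opt in c("chrom", "pos", "eaf", "n")) {
    if (!opt %in% names(x)) x[[opt]] <- NA
  }
  x$chrom <- as.character(x$chrom)
  x$variant_id <- as.character(x$variant_id)

  reasons <- character(0)
  flag <- function(bad, reason) {
    reasons <<- c(reasons, rep(reason, sum(bad, na.rm = TRUE)))
    bad & !is.na(bad)
  }
  drop <- rep(FALSE, nrow(x))
  drop <- drop | flag(is.na(x$variant_id) | is.na(x$beta) | is.na(x$se) |
                        is.na(x$pval), "missing_fields")
  drop <- drop | flag(!(x$effect_allele %in% VALID_ALLELES) |
                        !(x$other_allele %in% VALID_ALLELES), "bad_allele")
  drop <- drop | flag(x$effect_allele == x$other_allele, "identical_alleles")
  drop <- drop | flag(x$se <= 0, "nonpositive_se")
  drop <- drop | flag(x$pval <= 0 | x$pval > 1, "bad_pvalue")
  drop <- drop | flag(!is.na(x$eaf) & (x$eaf <= 0 | x$eaf >= 1), "bad_eaf")
  x <- x[!drop, , drop = FALSE]
  dup <- duplicated(x$variant_id)
  if (any(dup)) {
    reasons <- c(reasons, rep("duplicate_variant", sum(dup)))
    x <- x[!dup, , drop = FALSE]
  }

  audit <- if (length(reasons) > 0) {
    as_tibble(table(reason = reasons)) %>% rename(n_dropped = n)
  } else {
    tibble(reason = character(0), n_dropped = integer(0))
  }
  canonical <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                 "eaf", "beta", "se", "pval", "n")
  x <- x[, c(canonical, setdiff(names(x), canonical)), drop = FALSE]
  structure(x,
            trait_id = trait_id, trait_type = trait_type, audit = audit,
            class = c("summary_dataset", class(tibble())))
}

#' @rdname summary_dataset
#' @param dataset A `summary_dataset`.
#' @export
audit_log <- function(dataset) attr(dataset, "audit")

#' @rdname summary_dataset
#' @export
trait_id <- function(dataset) attr(dataset, "trait_id")

# Preserve dataset attributes through dplyr-style subsetting done internally.
restamp <- function(new, old, audit = attr(old, "audit")) {
  structure(as_tibble(new),
            trait_id = attr(old, "trait_id"),
            trait_type = attr(old, "trait_type"),
            audit = audit,
            class = c("summary_dataset", class(tibble())))
}

#' Read and write GWAS summary statistics
#'
#' Reads a delimited text table with a header row into a validated
#' [summary_dataset()].  `column_map` translates arbitrary header dialects
#' (OpenGWAS, FinnGen exports, ...) onto the canonical names: a named
#' character vector `c(canonical = "file_header", ...)`.
#'
#' @param path Path to a delimited text file.
#' @param column_map Optional named character vector mapping canonical
#'   column names to the file's header names.
#' @param trait_id,trait_type Passed to [summary_dataset()].
#' @param delim Field delimiter (default tab).
#' @return A `summary_dataset`; invalid rows are dropped and counted in
#'   `audit_log()`.
#' @export
read_summary_stats <- function(path, column_map = NULL, trait_id = NULL,
                               trait_type = "exposure", delim = "\t") {
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  if (nrow(x) == 0) {
    abort_mrscreen(sprintf("empty summary-statistics table: %s", path),
                   class = "mrscreen_empty_input_error")
  }
  if (!is.null(column_map)) {
    missing_src <- setdiff(unname(column_map), names(x))
    if (length(missing_src) > 0) {
      abort_mrscreen(
        sprintf("column_map refers to absent column(s): %s",
                paste(missing_src, collapse = ", ")),
        class = "mrscreen_format_error"
      )
    }
    for (canon in names(column_map)) {
      x[[canon]] <- x[[column_map[[canon]]]]
    }
    x <- x[, unique(c(names(column_map), setdiff(names(x), unname(column_map)))),
           drop = FALSE]
  }
  summary_dataset(x, trait_id = trait_id %||% basename(path),
                  trait_type = trait_type)
}

#' @rdname read_summary_stats
#' @param dataset A `summary_dataset` to write.
#' @export
write_summary_stats <- function(dataset, path, delim = "\t") {
  readr::write_delim(as_tibble(dataset), path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Genome-wide significance filter for instrument selection
#'
#' Retains variants with `pval < p_threshold`.  The study design uses
#' 1e-5 for microbial exposures (few microbial associations reach
#' conventional genome-wide significance) and 5e-8 for dietary and other
#' well-powered traits.
#'
#' @param dataset A `summary_dataset`.
#' @param p_threshold Significance level in (0, 1).
#' @return The filtered `summary_dataset` (possibly empty).
#' @export
select_instruments <- function(dataset, p_threshold = 1e-5) {
  stopifnot(p_threshold > 0, p_threshold <= 1)
  restamp(dataset[dataset$pval < p_threshold, , drop = FALSE], dataset)
}

#' Remove a user-supplied list of variants
#'
#' Models manual pleiotropy screens (e.g. secondary-trait lookups in an
#' external catalogue) as an exclusion list: listed variants are removed
#' and logged with the supplied reason; absent ids are a logged no-op.
#'
#' @param dataset A `summary_dataset`.
#' @param excluded_ids Character vector of variant ids to drop.
#' @param reason Reason string recorded in the audit log.
#' @export
apply_exclusion_list <- function(dataset, excluded_ids, reason = "manual_exclusion") {
  hit <- dataset$variant_id %in% excluded_ids
  audit <- bind_rows(
    attr(dataset, "audit"),
    tibble(reason = reason, n_dropped = sum(hit)),
    tibble(reason = paste0(reason, "_not_found"),
           n_dropped = sum(!excluded_ids %in% dataset$variant_id))
  )
  restamp(dataset[!hit, , drop = FALSE], dataset, audit = audit)
}

#' Instrument-strength F statistic
#'
#' Per-variant approximate F statistic `(beta/se)^2`; values below ~10 are
#' conventionally treated as weak instruments.
#'
#' @param beta_x,se_x SNP-exposure effect and its standard error.
#' @return Numeric vector of F values.
#' @export
f_statistic <- function(beta_x, se_x) {
  stopifnot(all(se_x > 0))
  (beta_x / se_x)^2
}
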