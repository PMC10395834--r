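#' LD matrix container
#'
#' Pairwise variant correlations plus genomic positions, as supplied by an
#' external reference panel (this package never computes LD from
#' genotypes).
#'
#' @param r Square numeric matrix of correlations in \[-1, 1\] with variant
#'   ids as dimnames; symmetric with unit diagonal.
#' @param positions Data frame with columns `variant_id`, `chrom`, `pos`
#'   covering every variant in `r`.
#' @return An `ld_matrix` object (list of `r`, `positions`).
#' @export
ld_matrix <- function(r, positions) {
  stopifnot(is.matrix(r), nrow(r) == ncol(r))
  ids <- rownames(r)
  if (is.null(ids) || !identical(ids, colnames(r))) {
    abort_mrscreen("LD matrix must have matching variant-id dimnames",
                   class = "mrscreen_config_error")
  }
  if (max(abs(r - t(r))) > 1e-8 || max(abs(diag(r) - 1)) > 1e-8) {
    abort_mrscreen("LD matrix must be symmetric with unit diagonal",
                   class = "mrscreen_config_error")
  }
  positions <- as_tibble(positions)
  missing_pos <- setdiff(ids, positions$variant_id)
  if (length(missing_pos) > 0) {
    abort_mrscreen(sprintf("positions missing for variant(s): %s",
                           paste(head(missing_pos, 5), collapse = ", ")),
                   class = "mrscreen_config_error")
  }
  positions$chrom <- as.character(positions$chrom)
  structure(list(r = r, positions = positions), class = "ld_matrix")
}

#' Read an LD matrix from a tab-separated file
#'
#' Expects a square matrix with a variant-id header row and first column,
#' plus a positions sidecar with columns `variant_id chrom pos`.
#'
#' @param path Matrix file path.
#' @param positions_path Positions sidecar path.
#' @export
read_ld_matrix <- function(path, positions_path) {
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- as.character(m[[1]])
  r <- as.matrix(m[, -1, drop = FALSE])
  rownames(r) <- ids
  pos <- readr::read_tsv(positions_path, show_col_types = FALSE, progress = FALSE)
  ld_matrix(r, pos)
}

#' Greedy LD clumping
#'
#' Repeatedly keeps the remaining variant with the smallest p-value and
#' removes every remaining variant on the same chromosome within
#' `window_kb` whose squared correlation with it is at least
#' `r2_threshold`.  Defaults mirror common microbial-GWAS practice:
#' r-squared 0.01 within a 10,000 kb window.  Ties on p-value break by
#' (chromosome, position, variant id) so the output is deterministic.
#'
#' @param dataset A `summary_dataset`; every variant must be present in
#'   `ld`.
#' @param ld An [ld_matrix()].
#' @param r2_threshold Squared-correlation bound in (0, 1).
#' @param window_kb Window size in kilobases.
#' @return The clumped `summary_dataset`; removed variants are recorded in
#'   the `clump_log` attribute as `(variant_id, index_variant)` pairs.
#' @export
ld_clump <- function(dataset, ld, r2_threshold = 0.01, window_kb = 10000) {
  stopifnot(inherits(ld, "ld_matrix"), r2_threshold > 0, r2_threshold < 1,
            window_kb > 0)
  ids <- dataset$variant_id
  missing_ld <- setdiff(ids, rownames(ld$r))
  if (length(missing_ld) > 0) {
    abort_mrscreen(sprintf("variant(s) absent from LD matrix: %s",
                           paste(head(missing_ld, 5), collapse = ", ")),
                   class = "mrscreen_config_error")
  }
  pos <- ld$positions[match(ids, ld$positions$variant_id), ]
  ord <- order(dataset$pval, pos$chrom, pos$pos, ids)

  keep <- character(0)
  removed <- tibble(variant_id = character(0), index_variant = character(0))
  alive <- rep(TRUE, length(ids))
  names(alive) <- ids
  for (i in ord) {
    id <- ids[i]
    if (!alive[id]) next
    keep <- c(keep, id)
    others <- ids[alive & ids != id]
    if (length(others) > 0) {
      same_chr <- pos$chrom[match(others, ids)] == pos$chrom[i]
      near <- abs(pos$pos[match(others, ids)] - pos$pos[i]) <= window_kb * 1000
      r2 <- ld$r[id, others]^2
      kill <- others[same_chr & near & r2 >= r2_threshold]
      if (length(kill) > 0) {
        alive[kill] <- FALSE
        removed <- bind_rows(removed,
                             tibble(variant_id = kill, index_variant = id))
      }
    }
    alive[id] <- FALSE
  }
  res <- restamp(dataset[match(keep, ids), , drop = FALSE], dataset)
  attr(res, "clump_log") <- removed
  res
}
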