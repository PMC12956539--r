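#' Instrument selection configuration
#'
#' Thresholds governing which cis-eQTLs qualify as instruments: the
#' association significance cutoff, the LD-clumping r-squared cutoff, and
#' the minimum F-statistic for instrument strength. Defaults follow the
#' usual single-cell eQTL MR practice: candidate instruments at
#' P < 5e-5, clumping at r-squared 0.001, and exclusion of instruments with
#' F below the conventional weak-instrument threshold of 10.
#'
#' @param p_threshold Significance cutoff; variants with `pvalue <
#'   p_threshold` are candidates (default `5e-5`).
#' @param clump_r2 Maximum squared correlation allowed between retained
#'   variants (default `0.001`).
#' @param f_min Minimum F-statistic; variants are kept iff `F >= f_min`
#'   (default `10`).
#' @return A list of class `instrument_config`.
#' @export
instrument_config <- function(p_threshold = 5e-5, clump_r2 = 0.001,
                              f_min = 10) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            clump_r2 >= 0, clump_r2 <= 1, f_min >= 0)
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 f_min = f_min), class = "instrument_config")
}

#' Instrument F-statistic
#'
#' Strength of a genetic instrument from its marginal effect and standard
#' error, `F = (beta / se)^2` (the square of the association z-score).
#'
#' @param beta Effect size(s).
#' @param se Standard error(s), all positive.
#' @return Numeric vector of F-statistics.
#' @seealso [f_statistic_r2()] for the variance-explained form.
#' @export
f_statistic <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop("se must be positive and finite", call. = FALSE)
  }
  (beta / se)^2
}

#' F-statistic from variance explained
#'
#' Alternative instrument-strength form `F = (n - 2) * r2 / (1 - r2)` for a
#' variant explaining a fraction `r2` of exposure variance in a sample of
#' size `n`. Equivalent to [f_statistic()] to first order when `r2` derives
#' from the same marginal regression.
#'
#' @param r2 Variance explained, in `[0, 1)`.
#' @param n Sample size, `>= 3`.
#' @return Numeric vector of F-statistics.
#' @export
f_statistic_r2 <- function(r2, n) {
  stopifnot(all(r2 >= 0), all(r2 < 1), all(n >= 3))
  (n - 2) * r2 / (1 - r2)
}

#' Greedy LD clumping
#'
#' Prunes correlated variants: associations are ranked by ascending p-value
#' (ties broken lexicographically on `variant_id`) and accepted greedily; a
#' variant is retained iff its squared correlation with every
#' already-retained variant is `<= clump_r2`. The retained set is therefore
#' independent of input ordering.
#'
#' @param associations Data frame with `variant_id` and `pvalue` columns.
#' @param ld Square correlation matrix. With dimnames, rows/columns are
#'   matched by variant id; without, its order must match `associations`.
#' @param clump_r2 Squared-correlation cutoff.
#' @return Character vector of retained variant ids (in acceptance order).
#' @export
ld_clump <- function(associations, ld, clump_r2 = 0.001) {
  associations <- as.data.frame(associations)
  k <- nrow(associations)
  if (!is.matrix(ld) || nrow(ld) != ncol(ld)) {
    stop("ld must be a square matrix", call. = FALSE)
  }
  if (nrow(ld) != k) {
    stop(sprintf("ld dimension (%d) does not match associations (%d)",
                 nrow(ld), k), call. = FALSE)
  }
  if (is.null(dimnames(ld))) {
    dimnames(ld) <- list(associations$variant_id, associations$variant_id)
  } else if (!setequal(rownames(ld), associations$variant_id)) {
    stop("ld dimnames do not match association variant ids", call. = FALSE)
  }
  ord <- order(associations$pvalue, associations$variant_id)
  ids <- associations$variant_id[ord]
  retained <- character(0)
  for (id in ids) {
    if (length(retained) == 0L ||
        all(ld[id, retained]^2 <= clump_r2)) {
      retained <- c(retained, id)
    }
  }
  retained
}

#' Select genetic instruments for one gene and cell type
#'
#' Applies the three-stage instrument filter to a cis-association set:
#' (1) significance, `pvalue < p_threshold`; (2) greedy LD clumping at
#' `clump_r2` (skipped when no LD matrix is supplied, i.e. variants are
#' treated as uncorrelated, as for pre-pruned conditionally independent
#' eQTLs); (3) strength, `F >= f_min`. An audit records the count entering
#' and surviving each stage. An empty result is legal and flagged, not an
#' error.
#'
#' @param dataset An [exposure_dataset()].
#' @param ld Optional correlation matrix over the dataset's variants
#'   (dimnames = variant ids).
#' @param config An [instrument_config()].
#' @return List of class `instrument_selection` with elements `dataset`
#'   (filtered `exposure_dataset`, or `NULL` when empty), `ld` (subset
#'   matrix or `NULL`), and `audit` (stage counts, logical `empty`).
#' @export
select_instruments <- function(dataset, ld = NULL,
                               config = instrument_config()) {
  stopifnot(inherits(dataset, "exposure_dataset"),
            inherits(config, "instrument_config"))
  assoc <- as.data.frame(dataset$associations)
  n_input <- nrow(assoc)

  assoc <- assoc[assoc$pvalue < config$p_threshold, , drop = FALSE]
  n_after_p <- nrow(assoc)

  if (!is.null(ld) && n_after_p > 0L) {
    if (is.null(dimnames(ld))) {
      stop("ld matrix must carry variant ids as dimnames", call. = FALSE)
    }
    sub <- ld[assoc$variant_id, assoc$variant_id, drop = FALSE]
    keep_ids <- ld_clump(assoc, sub, config$clump_r2)
    assoc <- assoc[match(keep_ids, assoc$variant_id), , drop = FALSE]
  }
  n_after_clump <- nrow(assoc)

  if (n_after_clump > 0L) {
    f <- f_statistic(assoc$beta, assoc$se)
    assoc <- assoc[f >= config$f_min, , drop = FALSE]
  }
  n_after_f <- nrow(assoc)

  audit <- list(
    gene = dataset$gene, cell_type = dataset$cell_type,
    n_input = n_input, n_after_p = n_after_p,
    n_after_clump = n_after_clump, n_after_f = n_after_f,
    removed_p = n_input - n_after_p,
    removed_clump = n_after_p - n_after_clump,
    removed_f = n_after_clump - n_after_f,
    empty = n_after_f == 0L
  )
  out_ld <- NULL
  out_ds <- NULL
  if (n_after_f > 0L) {
    assoc <- assoc[order(assoc$pvalue, assoc$variant_id), , drop = FALSE]
    out_ds <- exposure_dataset(dataset$gene, dataset$cell_type, assoc)
    if (!is.null(ld)) {
      out_ld <- ld[assoc$variant_id, assoc$variant_id, drop = FALSE]
    }
  }
  structure(list(dataset = out_ds, ld = out_ld, audit = audit),
            class = "instrument_selection")
}

#' @export
print.instrument_selection <- function(x, ...) {
  a <- x$audit
  cat(sprintf(
    "<instrument_selection> %s / %s: %d -> %d (p) -> %d (clump) -> %d (F)%s\n",
    a$gene, a$cell_type, a$n_input, a$n_after_p, a$n_after_clump,
    a$n_after_f, if (a$empty) " [empty]" else ""))
  invisible(x)
}
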