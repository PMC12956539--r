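#' Run the full MR pipeline over gene-by-cell-type exposures
#'
#' For each exposure dataset: harmonize against the outcome, apply the
#' three-stage instrument filter (significance, LD clumping, F-statistic),
#' apply Steiger directionality filtering, then dispatch the estimator --
#' Wald ratio for a single instrument, IVW for independent instruments,
#' LD-aware IVW when an LD matrix is available. When at least three
#' instruments survive, the MR-Egger intercept test and (when `seed` is
#' given) the weighted-median estimate are attached as sensitivity columns.
#' Untestable combinations are emitted as rows with a `skip_reason` rather
#' than dropped. Benjamini-Hochberg adjusted p-values are appended at two
#' levels: within each cell type and across all tests.
#'
#' @param exposures List of [exposure_dataset()] objects.
#' @param outcome Outcome association table ([read_sumstats()] with
#'   `role = "outcome"`).
#' @param ld Optional named list of per-locus LD correlation matrices keyed
#'   `"gene|cell_type"` (dimnames = variant ids).
#' @param config An [instrument_config()].
#' @param tiering A [tier_config()].
#' @param palindrome_policy,freq_tolerance Passed to [harmonize()].
#' @param steiger Apply Steiger directionality filtering (default `TRUE`).
#' @param second_order_wald Use the second-order Wald-ratio standard error.
#' @param seed Optional seed enabling the weighted-median bootstrap
#'   sensitivity columns.
#' @param n_boot Weighted-median bootstrap resamples (default 200 in the
#'   pipeline; use [mr_weighted_median()] directly for larger runs).
#' @return Tibble with one row per gene-by-cell-type pair: estimate columns
#'   (`method`, `n_snps`, `beta`, `se`, `pvalue`, `tier`), sensitivity
#'   columns (`egger_intercept*`, `wm_beta`, `wm_se`, `wm_p`, `q_*`),
#'   audit columns (`steiger_kept`, `steiger_removed`, `skip_reason`), and
#'   BH columns (`bh_p_celltype`, `bh_p_global`). The per-stage instrument
#'   audit is attached as `attr(, "audit")`.
#' @export
run_mr <- function(exposures, outcome, ld = NULL,
                   config = instrument_config(), tiering = tier_config(),
                   palindrome_policy = c("drop", "freq"),
                   freq_tolerance = 0.08, steiger = TRUE,
                   second_order_wald = FALSE, seed = NULL, n_boot = 200L) {
  palindrome_policy <- match.arg(palindrome_policy)
  if (inherits(exposures, "exposure_dataset")) exposures <- list(exposures)

  skip_row <- function(gene, cell_type, reason, k = 0L,
                       kept = NA_integer_, removed = NA_integer_) {
    row <- mr_result(gene, cell_type, NA_character_, k, NA_real_, NA_real_,
                     NA_real_)
    row$steiger_kept <- kept
    row$steiger_removed <- removed
    row$skip_reason <- reason
    row
  }

  rows <- list(); audits <- list()
  for (ds in exposures) {
    key <- paste(ds$gene, ds$cell_type, sep = "|")
    ld_i <- if (!is.null(ld)) ld[[key]] else NULL

    h <- tryCatch(
      harmonize(ds, outcome, palindrome_policy = palindrome_policy,
                freq_tolerance = freq_tolerance, ld = ld_i),
      error = function(e) NULL)
    if (is.null(h) || nrow(h$data) == 0L) {
      rows[[key]] <- skip_row(ds$gene, ds$cell_type, "no overlapping variants")
      next
    }

    # instrument selection on the harmonized exposure side
    assoc <- tibble::tibble(
      variant_id = h$data$variant_id, chrom = NA_character_, pos = 0,
      effect_allele = h$data$effect_allele,
      other_allele = h$data$other_allele, eaf = h$data$eaf_exp,
      beta = h$data$beta_exp, se = h$data$se_exp,
      pvalue = h$data$pval_exp, n = h$n_exp
    )
    sel <- select_instruments(
      exposure_dataset(ds$gene, ds$cell_type, assoc), ld = h$ld,
      config = config)
    audits[[key]] <- tibble::as_tibble(sel$audit)
    if (sel$audit$empty) {
      rows[[key]] <- skip_row(ds$gene, ds$cell_type, "no valid instruments")
      next
    }
    ids <- sel$dataset$associations$variant_id
    h$data <- h$data[match(ids, h$data$variant_id), , drop = FALSE]
    if (!is.null(h$ld)) h$ld <- h$ld[ids, ids, drop = FALSE]

    kept <- nrow(h$data); removed <- 0L
    if (steiger) {
      st <- steiger_filter(h)
      h <- st$harmonized
      kept <- sum(st$report$pass); removed <- st$n_removed
      if (st$status == "all_removed") {
        rows[[key]] <- skip_row(ds$gene, ds$cell_type,
                                "no directionally valid instruments",
                                kept = kept, removed = removed)
        next
      }
    }

    k <- nrow(h$data)
    row <- if (k == 1L) {
      mr_wald_ratio(h, second_order = second_order_wald, tiering = tiering)
    } else if (!is.null(h$ld)) {
      mr_ivw_correlated(h, tiering = tiering)
    } else {
      mr_ivw(h, tiering = tiering)
    }
    row$steiger_kept <- kept
    row$steiger_removed <- removed
    row$skip_reason <- NA_character_
    if (k >= 3L) {
      eg <- mr_egger(h, tiering = tiering)
      row$egger_intercept <- eg$egger_intercept
      row$egger_intercept_se <- eg$egger_intercept_se
      row$egger_intercept_p <- eg$egger_intercept_p
      if (!is.null(seed)) {
        wm <- mr_weighted_median(h, n_boot = n_boot,
                                 seed = derive_seed(seed, key),
                                 tiering = tiering)
        row$wm_beta <- wm$beta; row$wm_se <- wm$se; row$wm_p <- wm$pvalue
      }
    }
    rows[[key]] <- row
  }

  out <- do.call(rbind, lapply(rows, function(r) {
    for (col in c("wm_beta", "wm_se", "wm_p")) {
      if (is.null(r[[col]])) r[[col]] <- NA_real_
    }
    if (is.null(r[["skip_reason"]])) r$skip_reason <- NA_character_
    if (is.null(r[["steiger_kept"]])) r$steiger_kept <- NA_integer_
    if (is.null(r[["steiger_removed"]])) r$steiger_removed <- NA_integer_
    r
  }))
  rownames(out) <- NULL
  out$bh_p_celltype <- NA_real_
  out$bh_p_global <- NA_real_
  ok <- !is.na(out$pvalue)
  if (any(ok)) {
    out$bh_p_celltype[ok] <- bh_adjust(out$pvalue[ok],
                                       group = out$cell_type[ok])
    out$bh_p_global[ok] <- bh_adjust(out$pvalue[ok])
  }
  attr(out, "audit") <- if (length(audits)) do.call(rbind, audits) else NULL
  out
}

#' Write an MR result table
#'
#' Tab-delimited export of a [run_mr()] result (6 significant digits for
#' numeric columns).
#'
#' @param results Tibble from [run_mr()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_mr_results <- function(results, path) {
  df <- as.data.frame(results)
  num <- vapply(df, is.numeric, logical(1L)) & names(df) != "n_snps"
  df[num] <- lapply(df[num], signif, digits = 6L)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
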