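#' Normalized Shannon entropy of a gene's MR effect profile
#'
#' Quantifies how concentrated a gene's causal effect is across immune
#' lineages. Absolute effect magnitudes `|beta_i|` over the `n` cell types
#' in which the gene was tested are normalized to proportions
#' `p_i = |beta_i| / sum(|beta_j|)` and scored as
#' `H = -sum(p_i * log2(p_i)) / log2(n)` with the `0 * log(0) = 0`
#' convention. `H` ranges from 0 (all effect in one lineage) to 1 (uniform
#' across lineages). Genes with `H < 0.5` are classified lineage-specific
#' and `H > 0.8` diffuse; the band between is labeled intermediate.
#' Missing entries (`NA`: gene untested in that lineage) are excluded from
#' both the sum and `n` -- a zero effect and an untested lineage are
#' different things.
#'
#' @param abs_beta Numeric vector of effect magnitudes over cell types;
#'   signed values are accepted and their absolute value taken; `NA` marks
#'   untested lineages. At least two non-missing entries, at least one
#'   positive.
#' @param cell_types Optional cell-type labels (default `names(abs_beta)`).
#' @param gene Optional gene symbol carried into the profile.
#' @return List of class `entropy_profile`: `gene`, `cell_types`, `p`
#'   (proportions over non-missing entries), `n` (lineages counted), `H`,
#'   `top_cell_type`, `mean_abs_beta`, `class`, and `highly_specific`
#'   (reporting flag, `H < 0.2`).
#' @export
entropy_profile <- function(abs_beta, cell_types = names(abs_beta),
                            gene = NA_character_) {
  b <- abs(as.numeric(abs_beta))
  if (is.null(cell_types)) {
    cell_types <- paste0("cell_type_", seq_along(b))
  }
  stopifnot(length(cell_types) == length(b))
  ok <- !is.na(b)
  n <- sum(ok)
  if (n < 2L) {
    stop("entropy needs at least two non-missing lineages", call. = FALSE)
  }
  b <- b[ok]; ct <- cell_types[ok]
  total <- sum(b)
  if (total == 0) {
    stop("undefined entropy: all effect magnitudes are zero", call. = FALSE)
  }
  p <- b / total
  terms <- ifelse(p > 0, p * log2(p), 0)
  H <- -sum(terms) / log2(n) + 0  # + 0 normalizes IEEE negative zero
  cls <- if (H < 0.5) "lineage_specific" else if (H > 0.8) "diffuse" else
    "intermediate"
  structure(
    list(gene = gene, cell_types = ct, p = stats::setNames(p, ct), n = n,
         H = H, top_cell_type = ct[which.max(p)],
         mean_abs_beta = mean(b), class = cls,
         highly_specific = H < 0.2),
    class = "entropy_profile"
  )
}

#' @export
print.entropy_profile <- function(x, ...) {
  cat(sprintf("<entropy_profile> %s: H = %.4f over %d lineages (%s; top %s)\n",
              x$gene, x$H, x$n, x$class, x$top_cell_type))
  invisible(x)
}

#' Entropy profiles from an MR result table
#'
#' Builds one [entropy_profile()] per gene from a [run_mr()] result table,
#' using the absolute causal estimates of rows in the selected significance
#' tiers (default: both globally significant and potentially relevant,
#' i.e. p < 0.003). Genes tested in fewer than two qualifying cell types
#' are skipped.
#'
#' @param results Tibble from [run_mr()] (needs `gene`, `cell_type`,
#'   `beta`, `tier`).
#' @param tiers Tiers whose rows feed the profile (default
#'   `c("global", "potential")`).
#' @return Named list of `entropy_profile` objects.
#' @export
mr_entropy <- function(results, tiers = c("global", "potential")) {
  df <- results[!is.na(results$tier) & results$tier %in% tiers &
                  !is.na(results$beta), , drop = FALSE]
  out <- list()
  for (g in unique(df$gene)) {
    sub <- df[df$gene == g, , drop = FALSE]
    if (nrow(sub) < 2L || sum(abs(sub$beta)) == 0) next
    out[[g]] <- entropy_profile(stats::setNames(abs(sub$beta),
                                                sub$cell_type), gene = g)
  }
  out
}

#' Rank genes by cell-type specificity
#'
#' Orders entropy profiles ascending by `H` (most lineage-restricted
#' first); ties are broken by descending mean `|beta|`, then gene symbol.
#'
#' @param profiles List of [entropy_profile()] objects.
#' @param k Number of genes to return (default all). Requesting more than
#'   available returns everything with `attr(, "truncated") = FALSE` and a
#'   flag.
#' @return Tibble of gene, `H`, `mean_abs_beta`, `top_cell_type`, `class`,
#'   `highly_specific`, with a `rank` column.
#' @export
rank_specific_genes <- function(profiles, k = length(profiles)) {
  stopifnot(length(profiles) > 0L)
  tab <- do.call(rbind, lapply(profiles, function(p) {
    tibble::tibble(gene = p$gene, H = p$H, mean_abs_beta = p$mean_abs_beta,
                   top_cell_type = p$top_cell_type, class = p$class,
                   highly_specific = p$highly_specific)
  }))
  ord <- order(tab$H, -tab$mean_abs_beta, tab$gene)
  tab <- tab[ord, , drop = FALSE]
  short <- k > nrow(tab)
  tab <- utils::head(tab, k)
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  attr(tab, "requested_more_than_available") <- short
  tab
}
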