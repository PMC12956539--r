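#' Assemble a colocalization input
#'
#' Aligned per-variant effect estimates and their variances for two traits
#' at one locus (trait 1: expression; trait 2: outcome), plus the prior
#' probabilities that a variant is causal for trait 1 only (`p1`), trait 2
#' only (`p2`), or both (`p12`), and the prior effect standard deviation
#' used in the approximate Bayes factors: `0.15 * sdY` for a quantitative
#' trait and `0.2` on the log-odds scale for a case-control trait.
#'
#' @param variant_id Character vector of shared variant ids.
#' @param beta1,varbeta1 Effect sizes and their variances for trait 1
#'   (variances strictly positive).
#' @param beta2,varbeta2 Effect sizes and variances for trait 2.
#' @param type1,type2 `"quant"` or `"cc"` per trait.
#' @param sdY1,sdY2 Trait standard deviations for quantitative traits
#'   (default 1, i.e. standardized phenotypes).
#' @param p1,p2,p12 Priors (defaults `1e-4`, `1e-4`, `1e-5`); must satisfy
#'   `p1 + p2 + p12 < 1`.
#' @param gene,cell_type Optional labels carried into results.
#' @return An object of class `coloc_input`.
#' @export
coloc_input <- function(variant_id, beta1, varbeta1, beta2, varbeta2,
                        type1 = c("quant", "cc"), type2 = c("quant", "cc"),
                        sdY1 = 1, sdY2 = 1,
                        p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                        gene = NA_character_, cell_type = NA_character_) {
  type1 <- match.arg(type1); type2 <- match.arg(type2)
  k <- length(variant_id)
  stopifnot(k >= 1L,
            length(beta1) == k, length(varbeta1) == k,
            length(beta2) == k, length(varbeta2) == k)
  if (any(varbeta1 <= 0) || any(varbeta2 <= 0)) {
    stop("varbeta must be strictly positive", call. = FALSE)
  }
  if (anyDuplicated(variant_id)) {
    stop("variant ids must be unique", call. = FALSE)
  }
  stopifnot(p1 > 0, p2 > 0, p12 > 0)
  if (p1 + p2 + p12 >= 1) {
    stop("priors must satisfy p1 + p2 + p12 < 1", call. = FALSE)
  }
  prior_sd <- function(type, sdY) if (type == "quant") 0.15 * sdY else 0.2
  structure(
    list(variant_id = as.character(variant_id),
         beta1 = as.numeric(beta1), varbeta1 = as.numeric(varbeta1),
         beta2 = as.numeric(beta2), varbeta2 = as.numeric(varbeta2),
         prior_w1 = prior_sd(type1, sdY1)^2,
         prior_w2 = prior_sd(type2, sdY2)^2,
         p1 = p1, p2 = p2, p12 = p12,
         gene = gene, cell_type = cell_type),
    class = "coloc_input"
  )
}

#' Wakefield log approximate Bayes factor
#'
#' Log Bayes factor comparing "this variant has a nonzero effect" against
#' the null for one association, from its estimate and variance under a
#' normal effect prior with variance `prior_w`. With shrinkage
#' `r = prior_w / (prior_w + varbeta)` and `z = beta / sqrt(varbeta)`:
#' `lABF = 0.5 * (log(1 - r) + r * z^2)`.
#'
#' @param beta Effect estimate(s).
#' @param varbeta Variance(s) of the estimate, strictly positive.
#' @param prior_w Prior effect variance, strictly positive.
#' @return Numeric vector of log approximate Bayes factors.
#' @export
wakefield_labf <- function(beta, varbeta, prior_w) {
  if (any(varbeta <= 0) || any(!is.finite(varbeta))) {
    stop("varbeta must be positive and finite", call. = FALSE)
  }
  if (any(prior_w <= 0)) stop("prior_w must be positive", call. = FALSE)
  r <- prior_w / (prior_w + varbeta)
  z2 <- beta^2 / varbeta
  0.5 * (log1p(-r) + r * z2)
}

#' Bayesian colocalization by approximate Bayes factors
#'
#' Enumerates the five causal configurations for a pair of traits at one
#' locus -- H0 no association, H1/H2 one trait only, H3 two distinct causal
#' variants, H4 one shared causal variant -- assuming at most one causal
#' variant per trait. Per-variant Wakefield log-ABFs for each trait are
#' combined in log space (log-sum-exp throughout):
#' `H1 ~ p1 * S1`, `H2 ~ p2 * S2`, `H3 ~ p1 * p2 * (S1 * S2 - S12)`,
#' `H4 ~ p12 * S12`, `H0 ~ 1`, where `S1`, `S2` sum each trait's ABFs and
#' `S12` sums the products at the same variant. Posteriors are the
#' normalized weights. A single-variant locus leaves the H3 sum empty; the
#' result then reports `PPH3 = 0` with a warning flag.
#'
#' @param input A [coloc_input()].
#' @param pph4_min Evidence bar above which the locus is labeled
#'   colocalized (default 0.8).
#' @return List of class `coloc_result`: `pph` (named `PPH0`..`PPH4`,
#'   summing to 1), `n_variants`, `h4_weights` (per-variant posterior for
#'   the shared-variant configuration), `colocalized`, `priors`, and
#'   `single_variant` flag.
#' @export
coloc_abf <- function(input, pph4_min = 0.8) {
  stopifnot(inherits(input, "coloc_input"))
  k <- length(input$variant_id)
  l1 <- wakefield_labf(input$beta1, input$varbeta1, input$prior_w1)
  l2 <- wakefield_labf(input$beta2, input$varbeta2, input$prior_w2)
  s1 <- log_sum_exp(l1)
  s2 <- log_sum_exp(l2)
  s12 <- log_sum_exp(l1 + l2)
  lh <- c(
    H0 = 0,
    H1 = log(input$p1) + s1,
    H2 = log(input$p2) + s2,
    H3 = NA_real_,
    H4 = log(input$p12) + s12
  )
  single <- k == 1L
  if (single) {
    lh["H3"] <- -Inf
    warning("single-variant locus: H3 has no support and PPH3 is 0",
            call. = FALSE)
  } else {
    # S1*S2 - S12 = sum over i != j of exp(l1_i + l2_j), positive for k >= 2
    diff <- s12 - (s1 + s2)
    lh["H3"] <- if (diff >= 0) -Inf else {
      log(input$p1) + log(input$p2) + s1 + s2 + log1p(-exp(diff))
    }
  }
  denom <- log_sum_exp(lh)
  pph <- exp(lh - denom)
  names(pph) <- paste0("PP", names(lh))
  h4_weights <- exp(l1 + l2 - s12)
  names(h4_weights) <- input$variant_id
  structure(
    list(pph = pph, n_variants = k, h4_weights = h4_weights,
         colocalized = unname(pph["PPH4"] > pph4_min),
         priors = c(p1 = input$p1, p2 = input$p2, p12 = input$p12),
         gene = input$gene, cell_type = input$cell_type,
         single_variant = single),
    class = "coloc_result"
  )
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %d variant(s); %s\n", x$n_variants,
              paste(sprintf("%s=%.3f", names(x$pph), x$pph),
                    collapse = " ")))
  cat(sprintf("  colocalized: %s\n", x$colocalized))
  invisible(x)
}

#' Tabulate colocalization results
#'
#' Binds a list of [coloc_abf()] results into one tidy table.
#'
#' @param results List of `coloc_result` objects.
#' @return Tibble with gene, cell_type, n_variants, PPH0..PPH4, and the
#'   colocalized flag.
#' @export
coloc_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    tibble::tibble(gene = r$gene, cell_type = r$cell_type,
                   n_variants = r$n_variants,
                   PPH0 = r$pph[["PPH0"]], PPH1 = r$pph[["PPH1"]],
                   PPH2 = r$pph[["PPH2"]], PPH3 = r$pph[["PPH3"]],
                   PPH4 = r$pph[["PPH4"]], colocalized = r$colocalized)
  }))
}
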