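#' Significance tier configuration
#'
#' The two-level decision rule used to grade MR associations: estimates with
#' `p < global_threshold` are globally significant; those with
#' `global_threshold <= p < potential_threshold` carry potential biological
#' relevance; the rest are non-significant. Defaults are the printed
#' Bonferroni-style divisions 0.05/150 -> 0.0003 (across all tested genes)
#' and 0.05/14 -> 0.003 (within each of 14 immune cell types).
#'
#' @param global_threshold Global significance cutoff (default `3e-4`).
#' @param potential_threshold Potential-relevance cutoff (default `3e-3`).
#' @return A list of class `tier_config`.
#' @seealso [tier_config_from_counts()] to derive the thresholds from test
#'   counts.
#' @export
tier_config <- function(global_threshold = 3e-4, potential_threshold = 3e-3) {
  stopifnot(global_threshold > 0,
            global_threshold < potential_threshold,
            potential_threshold < 1)
  structure(list(global_threshold = global_threshold,
                 potential_threshold = potential_threshold),
            class = "tier_config")
}

#' Derive tier thresholds from test counts
#'
#' Reconstructs the two-level thresholds as `alpha` divided by the number of
#' cell types (per-cell-type level) and by the number of genes (global
#' level), each reported to one significant digit rounded toward zero --
#' the convention under which 0.05/14 reads 0.003 and 0.05/150 reads 0.0003.
#'
#' @param alpha Family-wise alpha (default 0.05).
#' @param n_cell_types Number of cell types tested (default 14).
#' @param n_genes Number of genes tested (default 150).
#' @return A [tier_config()].
#' @export
tier_config_from_counts <- function(alpha = 0.05, n_cell_types = 14,
                                    n_genes = 150) {
  floor_signif1 <- function(x) {
    e <- floor(log10(x))
    floor(x / 10^e) * 10^e
  }
  tier_config(global_threshold = floor_signif1(alpha / n_genes),
              potential_threshold = floor_signif1(alpha / n_cell_types))
}

#' Assign significance tiers
#'
#' Maps p-values to the three-tier labels of the two-level decision rule.
#'
#' @param pvalue Numeric vector of p-values in (0, 1].
#' @param config A [tier_config()].
#' @return Character vector: `"global"`, `"potential"`, or
#'   `"nonsignificant"`.
#' @export
assign_tier <- function(pvalue, config = tier_config()) {
  stopifnot(inherits(config, "tier_config"))
  if (any(is.na(pvalue)) || any(pvalue <= 0) || any(pvalue > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  ifelse(pvalue < config$global_threshold, "global",
         ifelse(pvalue < config$potential_threshold, "potential",
                "nonsignificant"))
}

#' Benjamini-Hochberg adjustment, optionally within groups
#'
#' Step-up BH adjusted p-values, computed across all tests or separately
#' within groups (e.g. within each cell type).
#'
#' @param pvalues Numeric vector in (0, 1].
#' @param group Optional grouping vector of the same length; adjustment is
#'   performed within each group.
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(pvalues, group = NULL) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(group)) return(stats::p.adjust(pvalues, method = "BH"))
  stopifnot(length(group) == length(pvalues))
  out <- numeric(length(pvalues))
  for (g in unique(group)) {
    idx <- which(group == g)
    out[idx] <- stats::p.adjust(pvalues[idx], method = "BH")
  }
  out
}

# One-row MR result tibble with the full column set; estimators fill what
# applies.
mr_result <- function(gene, cell_type, method, n_snps, beta, se, pvalue,
                      egger_intercept = NA_real_,
                      egger_intercept_se = NA_real_,
                      egger_intercept_p = NA_real_,
                      q_stat = NA_real_, q_df = NA_real_, q_p = NA_real_,
                      steiger_pass = NA, tier = NA_character_,
                      tiering = tier_config()) {
  if (is.na(tier) && !is.na(pvalue)) tier <- assign_tier(pvalue, tiering)
  tibble::tibble(
    gene = gene, cell_type = cell_type, method = method,
    n_snps = as.integer(n_snps), beta = beta, se = se, pvalue = pvalue,
    egger_intercept = egger_intercept,
    egger_intercept_se = egger_intercept_se,
    egger_intercept_p = egger_intercept_p,
    q_stat = q_stat, q_df = q_df, q_p = q_p,
    steiger_pass = steiger_pass, tier = tier
  )
}

h_check <- function(h, min_k = 1L) {
  stopifnot(inherits(h, "harmonized_set"))
  k <- nrow(h$data)
  if (k < min_k) {
    stop(sprintf("estimator needs at least %d instrument(s), got %d",
                 min_k, k), call. = FALSE)
  }
  k
}

#' Wald ratio estimator
#'
#' Single-instrument causal estimate: `beta = beta_out / beta_exp`. The
#' default standard error is the first-order delta approximation
#' `se_out / |beta_exp|`; `second_order = TRUE` adds the exposure-noise
#' term, `sqrt(se_out^2 / beta_exp^2 + beta_out^2 * se_exp^2 /
#' beta_exp^4)`. The two-sided p-value comes from a standard-normal Wald
#' test.
#'
#' @param h A `harmonized_set` with exactly one variant.
#' @param second_order Use the second-order delta standard error.
#' @param tiering A [tier_config()] for the significance tier.
#' @return One-row MR result tibble (`method = "wald"`).
#' @export
mr_wald_ratio <- function(h, second_order = FALSE, tiering = tier_config()) {
  k <- h_check(h, 1L)
  if (k != 1L) stop("wald ratio requires exactly one instrument", call. = FALSE)
  bx <- h$data$beta_exp; by <- h$data$beta_out
  sx <- h$data$se_exp; sy <- h$data$se_out
  if (bx == 0) stop("degenerate instrument: exposure beta is zero",
                    call. = FALSE)
  beta <- by / bx
  se <- if (second_order) {
    sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  } else {
    sy / abs(bx)
  }
  pvalue <- 2 * stats::pnorm(-abs(beta / se))
  mr_result(h$gene, h$cell_type, "wald", 1L, beta, se, pvalue,
            tiering = tiering)
}

# Shared IVW/GLS tail: multiplicative dispersion scaling and t(k-1)
# inference (see the methods vignette for why the scale is not floored
# at 1).
ivw_inference <- function(beta, se_fixed, Q, k) {
  df <- k - 1L
  sigma2 <- max(Q / df, .Machine$double.eps)
  se <- se_fixed * sqrt(sigma2)
  pvalue <- 2 * stats::pt(-abs(beta / se), df = df)
  list(se = se, pvalue = pvalue, q_stat = Q, q_df = df,
       q_p = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' Inverse-variance weighted estimator
#'
#' Weighted regression of outcome betas on exposure betas through the
#' origin with weights `1 / se_out^2`:
#' `beta = sum(w x y) / sum(w x^2)`. The standard error is the fixed-effect
#' value `sqrt(1 / sum(w x^2))` scaled multiplicatively by the residual
#' dispersion `sqrt(Q / (k - 1))` (Cochran's Q over its degrees of
#' freedom), and inference uses a t distribution on `k - 1` degrees of
#' freedom -- the exact weighted-least-squares test. With a single
#' instrument the call delegates to [mr_wald_ratio()].
#'
#' @param h A `harmonized_set` (k >= 1).
#' @param tiering A [tier_config()].
#' @return One-row MR result tibble (`method = "ivw"`, or `"wald"` when
#'   k = 1) including Cochran's Q, its df, and Q p-value.
#' @export
mr_ivw <- function(h, tiering = tier_config()) {
  k <- h_check(h, 1L)
  if (k == 1L) return(mr_wald_ratio(h, tiering = tiering))
  bx <- h$data$beta_exp; by <- h$data$beta_out; sy <- h$data$se_out
  if (any(sy <= 0)) stop("outcome SEs must be positive", call. = FALSE)
  w <- 1 / sy^2
  beta <- sum(w * bx * by) / sum(w * bx^2)
  se_fixed <- sqrt(1 / sum(w * bx^2))
  Q <- sum(w * (by - beta * bx)^2)
  inf <- ivw_inference(beta, se_fixed, Q, k)
  mr_result(h$gene, h$cell_type, "ivw", k, beta, inf$se, inf$pvalue,
            q_stat = inf$q_stat, q_df = inf$q_df, q_p = inf$q_p,
            tiering = tiering)
}

# Cholesky-solve helper with ridge escalation on the LD matrix.
# Returns list(Rinv_mult = function(m) solve(Sigma, m), lambda).
ld_ridge_solve <- function(R, D, lambdas = c(0, 1e-6, 1e-5, 1e-4, 1e-3),
                           kappa_max = 1e10) {
  for (lambda in lambdas) {
    Rr <- R + diag(lambda, nrow(R))
    Sigma <- D %*% Rr %*% D
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) next
    d <- diag(ch)
    if ((max(d) / min(d))^2 > kappa_max) next
    return(list(chol = ch, lambda = lambda))
  }
  stop("ill-conditioned LD: covariance not positive-definite after ridge",
       call. = FALSE)
}

#' IVW accounting for correlated instruments
#'
#' Generalized least squares through the origin with outcome covariance
#' `Sigma = D R D`, where `D = diag(se_out)` and `R` is the instrument LD
#' correlation matrix: `beta = (x' Sigma^-1 x)^-1 x' Sigma^-1 y`. Near-
#' singular LD is handled by adding a ridge to the diagonal of `R`,
#' starting at 1e-6 and escalating tenfold up to 1e-3 before failing.
#' Dispersion scaling and t inference follow [mr_ivw()]; with `R = I` the
#' result equals [mr_ivw()] exactly.
#'
#' @param h A `harmonized_set` with an `ld` matrix.
#' @param tiering A [tier_config()].
#' @return One-row MR result tibble (`method = "ivw_correlated"`).
#' @export
mr_ivw_correlated <- function(h, tiering = tier_config()) {
  k <- h_check(h, 1L)
  if (is.null(h$ld)) stop("harmonized set carries no LD matrix", call. = FALSE)
  if (k == 1L) return(mr_wald_ratio(h, tiering = tiering))
  bx <- h$data$beta_exp; by <- h$data$beta_out; sy <- h$data$se_out
  D <- diag(sy, k)
  sol <- ld_ridge_solve(h$ld, D)
  # GLS via the Cholesky factor: solve Sigma z = v as two triangular solves
  sigma_solve <- function(v) backsolve(sol$chol,
                                       forwardsolve(t(sol$chol), v))
  Si_x <- sigma_solve(bx)
  xtSix <- sum(bx * Si_x)
  beta <- sum(Si_x * by) / xtSix
  se_fixed <- sqrt(1 / xtSix)
  r <- by - beta * bx
  Q <- sum(r * sigma_solve(r))
  inf <- ivw_inference(beta, se_fixed, Q, k)
  mr_result(h$gene, h$cell_type, "ivw_correlated", k, beta, inf$se,
            inf$pvalue, q_stat = inf$q_stat, q_df = inf$q_df, q_p = inf$q_p,
            tiering = tiering)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome betas on exposure betas with a
#' free intercept (weights `1 / se_out^2`), after orienting every
#' instrument so its exposure beta is non-negative. The slope is the causal
#' estimate; the intercept, its standard error, and its p-value constitute
#' the directional-pleiotropy test. Coefficient standard errors carry the
#' regression's residual dispersion; p-values use t distributions on
#' `k - 2` degrees of freedom. With an exact linear fit the coefficient
#' standard errors are zero and p-values are reported as `NA`.
#'
#' @param h A `harmonized_set` with at least three variants.
#' @param tiering A [tier_config()].
#' @return One-row MR result tibble (`method = "egger"`) with
#'   `egger_intercept`, `egger_intercept_se`, `egger_intercept_p` filled.
#' @export
mr_egger <- function(h, tiering = tier_config()) {
  k <- h_check(h, 3L)
  flip <- sign(h$data$beta_exp)
  flip[flip == 0] <- 1
  bx <- h$data$beta_exp * flip
  by <- h$data$beta_out * flip
  w <- 1 / h$data$se_out^2
  fit <- stats::lm(by ~ bx, weights = w)
  cf <- summary(fit)$coefficients
  slope <- cf["bx", "Estimate"]; slope_se <- cf["bx", "Std. Error"]
  icpt <- cf["(Intercept)", "Estimate"]
  icpt_se <- cf["(Intercept)", "Std. Error"]
  tp <- function(est, se) {
    if (!is.finite(se) || se <= 0) return(NA_real_)
    2 * stats::pt(-abs(est / se), df = k - 2L)
  }
  mr_result(h$gene, h$cell_type, "egger", k, slope, slope_se,
            tp(slope, slope_se),
            egger_intercept = icpt, egger_intercept_se = icpt_se,
            egger_intercept_p = tp(icpt, icpt_se),
            tiering = tiering)
}

# Weighted median of `x` with weights `w`: linear interpolation of the
# empirical weighted CDF (midpoint convention) at cumulative weight 0.5.
weighted_median_value <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w) - w / (2 * sum(w))
  if (0.5 <= cw[1L]) return(x[1L])
  if (0.5 >= cw[length(cw)]) return(x[length(x)])
  stats::approx(cw, x, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimator
#'
#' Robust causal estimate: per-instrument Wald ratios
#' `beta_out_j / beta_exp_j` are weighted by the inverse variance of each
#' ratio (first order, `beta_exp_j^2 / se_out_j^2`) and the estimate is the
#' weighted median (linear interpolation of the weighted CDF at cumulative
#' weight 0.5). Consistent when at least half the total weight comes from
#' valid instruments. The standard error is a parametric bootstrap:
#' instrument betas are resampled from their reported normal sampling
#' distributions `n_boot` times under `seed`.
#'
#' @param h A `harmonized_set` with at least three variants.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap; required, no silent default.
#' @param tiering A [tier_config()].
#' @return One-row MR result tibble (`method = "weighted_median"`).
#' @export
mr_weighted_median <- function(h, n_boot = 1000L, seed, tiering = tier_config()) {
  k <- h_check(h, 3L)
  if (missing(seed)) stop("`seed` is required for the bootstrap", call. = FALSE)
  bx <- h$data$beta_exp; by <- h$data$beta_out
  sx <- h$data$se_exp; sy <- h$data$se_out
  if (any(bx == 0)) {
    stop("degenerate ratio: an exposure beta is zero", call. = FALSE)
  }
  ratios <- by / bx
  w <- bx^2 / sy^2
  beta <- weighted_median_value(ratios, w)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx_b <- stats::rnorm(k, bx, sx)
      by_b <- stats::rnorm(k, by, sy)
      ok <- bx_b != 0
      weighted_median_value(by_b[ok] / bx_b[ok], bx_b[ok]^2 / sy[ok]^2)
    }, numeric(1L))
  })
  se <- stats::sd(boots)
  pvalue <- 2 * stats::pnorm(-abs(beta / se))
  mr_result(h$gene, h$cell_type, "weighted_median", k, beta, se, pvalue,
            tiering = tiering)
}

#' Steiger directionality filter
#'
#' Per-variant check that the instrument explains more variance in the
#' exposure than in the outcome, guarding against reverse causation. With
#' `z = beta / se`, the variance explained is approximated by
#' `r2 = z^2 / (z^2 + n - 2)` for each trait; a variant passes iff
#' `r2_exp > r2_out` (strict, so ties fail). Failing variants are removed
#' from the harmonized set and recorded with both r-squared values.
#'
#' @param h A `harmonized_set`.
#' @param n_exp,n_out Sample sizes (default: the set's recorded sizes);
#'   both must be at least 10.
#' @return List of class `steiger_result`: `harmonized` (filtered set, may
#'   have zero variants), `report` (per-variant tibble with `r2_exp`,
#'   `r2_out`, `pass`), `n_removed`, and `status` (`"ok"` or
#'   `"all_removed"`).
#' @export
steiger_filter <- function(h, n_exp = h$n_exp, n_out = h$n_out) {
  h_check(h, 1L)
  if (is.na(n_exp) || is.na(n_out) || n_exp < 10 || n_out < 10) {
    stop("sample sizes must be at least 10", call. = FALSE)
  }
  z_exp <- h$data$beta_exp / h$data$se_exp
  z_out <- h$data$beta_out / h$data$se_out
  r2_exp <- z_exp^2 / (z_exp^2 + n_exp - 2)
  r2_out <- z_out^2 / (z_out^2 + n_out - 2)
  pass <- r2_exp > r2_out
  report <- tibble::tibble(variant_id = h$data$variant_id,
                           r2_exp = r2_exp, r2_out = r2_out, pass = pass)
  out <- h
  out$data <- h$data[pass, , drop = FALSE]
  if (!is.null(h$ld)) {
    ids <- out$data$variant_id
    out$ld <- h$ld[ids, ids, drop = FALSE]
  }
  structure(list(harmonized = out, report = report,
                 n_removed = sum(!pass),
                 status = if (any(pass)) "ok" else "all_removed"),
            class = "steiger_result")
}

#' @export
print.steiger_result <- function(x, ...) {
  cat(sprintf("<steiger_result> %d/%d variant(s) pass directionality (%s)\n",
              sum(x$report$pass), nrow(x$report), x$status))
  invisible(x)
}
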