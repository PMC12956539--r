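#' Default immune cell-type labels
#'
#' Fourteen peripheral immune cell populations typical of a single-cell
#' PBMC eQTL resource: naive and effector CD4/CD8 T-cell subsets, NK
#' subsets, naive and memory B cells, plasma cells, classical and
#' non-classical monocytes, and dendritic cells.
#'
#' @format Character vector of length 14.
#' @export
immune_cell_types <- c(
  "CD4_NC", "CD4_ET", "CD4_SOX4", "CD8_ET", "CD8_NC", "CD8_S100B",
  "NK", "NK_R", "B_IN", "B_Mem", "Plasma", "Mono_C", "Mono_NC", "DC"
)

#' Simulation configuration
#'
#' Parameters of the synthetic summary-statistics generator. Defaults
#' mirror the study setting the package targets: 14 immune cell types, a
#' cis window of `m_variants` variants with AR(1)-style LD, an eQTL cohort
#' of 982 donors, and an outcome GWAS scaled to a desk-friendly 50,000
#' participants (the real outcome cohort, 484,598 participants, is
#' reachable by setting `n_gwas`). Effects are on standardized scales
#' (expression variance 1, genotypes standardized), so each causal cis
#' variant explains `eqtl_var` of expression variance and `theta` is the
#' effect of one SD of expression on the outcome.
#'
#' @param n_genes Number of genes (default 20).
#' @param n_cell_types Number of cell types, labels taken from
#'   [immune_cell_types] (default 14).
#' @param m_variants Variants per cis locus (default 30).
#' @param ld_rho AR(1) adjacent-variant correlation in [0, 1) (default
#'   0.5).
#' @param maf_range Minor-allele-frequency range, within (0, 0.5]
#'   (default `c(0.05, 0.5)`).
#' @param n_eqtl eQTL sample size (default 982).
#' @param n_gwas Outcome GWAS sample size (default 50000).
#' @param theta True causal effect of expression on the outcome: a scalar
#'   (all gene-cell pairs) or a vector of length `n_genes` (per gene,
#'   shared across cell types). Default 0 (global null).
#' @param n_causal_eqtl Causal cis variants per gene-cell pair (default 3).
#' @param eqtl_var Expression variance explained by each causal variant
#'   (default 0.05, i.e. z of about 7 at n = 982).
#' @param pleiotropy_frac Fraction of variants given direct outcome
#'   effects, bypassing expression (default 0).
#' @param pleiotropy_sd SD of the direct effects (default 0.05).
#' @param seed RNG seed; required, no silent default.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 20L, n_cell_types = 14L, m_variants = 30L,
                       ld_rho = 0.5, maf_range = c(0.05, 0.5),
                       n_eqtl = 982L, n_gwas = 50000L, theta = 0,
                       n_causal_eqtl = 3L, eqtl_var = 0.05,
                       pleiotropy_frac = 0, pleiotropy_sd = 0.05, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(n_genes >= 1, n_cell_types >= 1,
            n_cell_types <= length(immune_cell_types),
            m_variants >= 1, ld_rho >= 0, ld_rho < 1,
            length(maf_range) == 2L, maf_range[1L] > 0,
            maf_range[2L] <= 0.5, maf_range[1L] <= maf_range[2L],
            n_eqtl >= 10, n_gwas >= 10,
            all(is.finite(theta)),
            length(theta) == 1L || length(theta) == n_genes,
            n_causal_eqtl >= 1, n_causal_eqtl <= m_variants,
            eqtl_var > 0, eqtl_var < 1,
            pleiotropy_frac >= 0, pleiotropy_frac <= 1, pleiotropy_sd >= 0)
  structure(
    list(n_genes = as.integer(n_genes),
         n_cell_types = as.integer(n_cell_types),
         cell_types = immune_cell_types[seq_len(n_cell_types)],
         m_variants = as.integer(m_variants), ld_rho = ld_rho,
         maf_range = maf_range, n_eqtl = as.integer(n_eqtl),
         n_gwas = as.integer(n_gwas), theta = theta,
         n_causal_eqtl = as.integer(n_causal_eqtl), eqtl_var = eqtl_var,
         pleiotropy_frac = pleiotropy_frac, pleiotropy_sd = pleiotropy_sd,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' AR(1) linkage-disequilibrium matrix
#'
#' Correlation matrix `R[i, j] = rho^|i - j|`, the first-order
#' autoregressive structure that mimics the decay of LD with distance
#' along a cis region; positive-definite for any `rho` in [0, 1).
#'
#' @param m Number of variants.
#' @param rho Adjacent-variant correlation in [0, 1).
#' @return `m` by `m` correlation matrix.
#' @export
simulate_ld <- function(m, rho) {
  stopifnot(m >= 1)
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  rho^abs(outer(seq_len(m), seq_len(m), "-"))
}

# Draw one MVN vector with covariance scale^2 * R given R's Cholesky factor.
mvn_noise <- function(chol_R, scale) {
  as.numeric(crossprod(chol_R, stats::rnorm(nrow(chol_R)))) * scale
}

theta_for_gene <- function(config, gene_index) {
  if (length(config$theta) == 1L) config$theta else config$theta[gene_index]
}

#' Simulate one cis locus with known ground truth
#'
#' Generates exposure (eQTL) and outcome (GWAS) summary statistics for one
#' gene in one cell type under a linear causal model, without individual-
#' level data. `n_causal_eqtl` variants receive standardized expression
#' effects of magnitude `sqrt(eqtl_var)` (random sign); marginal effects
#' propagate through the AR(1) LD as `R %*% b`. Standard errors follow the
#' large-sample form `1 / sqrt(n)` on the standardized scale, and sampling
#' noise is drawn from `MVN(0, R / n)` so that the observed statistics are
#' consistent with their reported SEs. Outcome effects are
#' `theta * (marginal exposure effect)` plus, for a `pleiotropy_frac`
#' fraction of variants, direct effects of SD `pleiotropy_sd` (also
#' propagated through LD), plus GWAS-scale noise. Fully deterministic: the
#' locus stream is derived from `config$seed` and the gene/cell-type
#' labels.
#'
#' @param config A [sim_config()].
#' @param gene Gene label (default `"G1"`).
#' @param cell_type Cell-type label (default the config's first).
#' @param gene_index Index into a vector-valued `theta` (default 1).
#' @return List: `exposure` (an [exposure_dataset()]), `outcome`
#'   (association tibble on the same variants), `ld` (the correlation
#'   matrix, dimnames = variant ids), and `truth` (list: `theta`,
#'   `causal_ids`, `pleiotropic_ids`, `beta_exp_true`, `beta_out_true`).
#' @export
simulate_locus <- function(config, gene = "G1",
                           cell_type = config$cell_types[1L],
                           gene_index = 1L) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$m_variants
  th <- theta_for_gene(config, gene_index)
  with_seed(derive_seed(config$seed, "locus", gene, cell_type), {
    maf <- stats::runif(m, config$maf_range[1L], config$maf_range[2L])
    R <- simulate_ld(m, config$ld_rho)
    chol_R <- chol(R)
    causal <- sort(sample.int(m, config$n_causal_eqtl))
    b <- numeric(m)
    b[causal] <- sqrt(config$eqtl_var) * sample(c(-1, 1),
                                                config$n_causal_eqtl,
                                                replace = TRUE)
    beta_exp_true <- as.numeric(R %*% b)
    se_exp <- rep(1 / sqrt(config$n_eqtl), m)
    beta_exp <- beta_exp_true + mvn_noise(chol_R, se_exp[1L])

    n_pleio <- round(config$pleiotropy_frac * m)
    delta <- numeric(m)
    pleio <- integer(0)
    if (n_pleio > 0L) {
      pleio <- sort(sample.int(m, n_pleio))
      delta[pleio] <- stats::rnorm(n_pleio, 0, config$pleiotropy_sd)
    }
    beta_out_true <- th * beta_exp_true + as.numeric(R %*% delta)
    se_out <- rep(1 / sqrt(config$n_gwas), m)
    beta_out <- beta_out_true + mvn_noise(chol_R, se_out[1L])

    ids <- sprintf("%s_%s_v%03d", gene, cell_type, seq_len(m))
    dimnames(R) <- list(ids, ids)
    assoc <- function(beta, se, n) {
      tibble::tibble(
        variant_id = ids, chrom = "1", pos = seq_len(m) * 1000,
        effect_allele = "A", other_allele = "G", eaf = maf,
        beta = beta, se = se,
        pvalue = pmax(2 * stats::pnorm(-abs(beta / se)),
                      .Machine$double.xmin),
        n = n
      )
    }
    list(
      exposure = exposure_dataset(gene, cell_type,
                                  assoc(beta_exp, se_exp, config$n_eqtl)),
      outcome = assoc(beta_out, se_out, config$n_gwas),
      ld = R,
      truth = list(theta = th, causal_ids = ids[causal],
                   pleiotropic_ids = ids[pleio],
                   beta_exp_true = beta_exp_true,
                   beta_out_true = beta_out_true)
    )
  })
}

#' Simulate a colocalization test pair
#'
#' Builds a [coloc_input()] for one locus where either a single variant
#' drives both traits (`shared = TRUE`, ground truth H4) or two
#' LD-separated variants (pairwise r-squared below 0.01) drive one trait
#' each (`shared = FALSE`, ground truth H3). Causal z-scores are set to 8
#' and propagate through the LD; observed z-scores add MVN(0, R) noise.
#'
#' @param shared Logical: shared causal variant or distinct ones.
#' @param config A [sim_config()] (uses `m_variants`, `ld_rho`, `n_eqtl`,
#'   `n_gwas`, `seed`).
#' @param z_causal Causal-variant z-score (default 8).
#' @param replicate Integer tag separating the RNG streams of repeated
#'   draws (default 1).
#' @return List: `input` (a `coloc_input`), `truth` (`"H4"` or `"H3"`),
#'   `causal1`, `causal2` (variant indices).
#' @export
simulate_coloc_pair <- function(shared, config, z_causal = 8,
                                replicate = 1L) {
  stopifnot(inherits(config, "sim_config"), is.logical(shared))
  m <- config$m_variants
  with_seed(derive_seed(config$seed, "coloc", shared, replicate), {
    R <- simulate_ld(m, config$ld_rho)
    chol_R <- chol(R)
    c1 <- sample.int(m, 1L)
    if (shared) {
      c2 <- c1
    } else {
      # candidates in negligible LD with the first causal variant
      ok <- which(R[c1, ]^2 < 0.01)
      if (length(ok) == 0L) {
        stop("locus too small to separate causal variants at r2 < 0.01",
             call. = FALSE)
      }
      c2 <- if (length(ok) == 1L) ok else sample(ok, 1L)
    }
    z1_true <- z_causal * R[, c1]
    z2_true <- z_causal * R[, c2]
    z1 <- z1_true + mvn_noise(chol_R, 1)
    z2 <- z2_true + mvn_noise(chol_R, 1)
    se1 <- 1 / sqrt(config$n_eqtl)
    se2 <- 1 / sqrt(config$n_gwas)
    ids <- sprintf("cv%03d", seq_len(m))
    list(
      input = coloc_input(ids, beta1 = z1 * se1, varbeta1 = rep(se1^2, m),
                          beta2 = z2 * se2, varbeta2 = rep(se2^2, m)),
      truth = if (shared) "H4" else "H3",
      causal1 = c1, causal2 = c2
    )
  })
}

#' Simulate annotation tables and a protein-interaction edge list
#'
#' Seeded random evidence tables feeding the prioritization and network
#' stages: a drug-gene interaction snapshot, a disease-evidence table, a
#' pathway-membership table, and a STRING-style weighted edge list from a
#' random-graph model with planted hubs (the first `n_hubs` genes receive
#' roughly `hub_boost` times the background degree).
#'
#' @param genes Character vector of gene symbols.
#' @param config A [sim_config()] (for the seed).
#' @param drug_freq,disease_freq,pathway_freq Marginal probabilities that a
#'   gene has drug rows / disease evidence / pathway membership.
#' @param druggable_freq Probability that a drugged gene's rows carry a
#'   druggable class.
#' @param base_degree Expected background degree of the interaction graph
#'   (default 4).
#' @param n_hubs Number of planted hubs (default 3).
#' @param hub_boost Hub degree multiplier (default 3).
#' @return List: `drug_table`, `disease_table`, `pathway_table`, `edges`,
#'   `hubs` (planted hub symbols).
#' @export
simulate_annotations <- function(genes, config, drug_freq = 0.5,
                                 disease_freq = 0.3, pathway_freq = 0.4,
                                 druggable_freq = 0.5, base_degree = 4,
                                 n_hubs = 3L, hub_boost = 3) {
  stopifnot(inherits(config, "sim_config"), length(genes) >= 2L,
            n_hubs >= 0L, n_hubs <= length(genes))
  n <- length(genes)
  with_seed(derive_seed(config$seed, "annotations"), {
    drugged <- genes[stats::runif(n) < drug_freq]
    drug_table <- if (length(drugged) > 0L) {
      do.call(rbind, lapply(drugged, function(g) {
        nd <- sample.int(3L, 1L)
        tibble::tibble(
          gene = g, drug_id = sprintf("DRUG_%s_%d", g, seq_len(nd)),
          interaction_type = sample(c("inhibitor", "agonist", "binder"),
                                    nd, replace = TRUE),
          source = "synthetic_snapshot",
          druggable_class = if (stats::runif(1L) < druggable_freq)
            "small_molecule" else ""
        )
      }))
    } else {
      tibble::tibble(gene = character(0), drug_id = character(0),
                     interaction_type = character(0), source = character(0),
                     druggable_class = character(0))
    }
    disease_table <- tibble::tibble(
      gene = genes[stats::runif(n) < disease_freq],
      evidence = "gwas_locus")
    pw_genes <- genes[stats::runif(n) < pathway_freq]
    pathway_table <- tibble::tibble(
      gene = pw_genes,
      pathway = sample(c("inflammatory_signaling", "ecm_remodeling",
                         "bone_metabolism", "mechanotransduction"),
                       length(pw_genes), replace = TRUE))

    hubs <- if (n_hubs > 0L) genes[seq_len(n_hubs)] else character(0)
    p_base <- min(1, base_degree / (n - 1))
    p_hub <- min(1, hub_boost * base_degree / (n - 1))
    pairs <- utils::combn(n, 2L)
    pa <- genes[pairs[1L, ]]; pb <- genes[pairs[2L, ]]
    p_edge <- ifelse(pa %in% hubs | pb %in% hubs, p_hub, p_base)
    on <- stats::runif(length(p_edge)) < p_edge
    edges <- tibble::tibble(
      protein1 = pa[on], protein2 = pb[on],
      combined_score = round(stats::runif(sum(on), 700, 999))
    )
    list(drug_table = drug_table, disease_table = disease_table,
         pathway_table = pathway_table, edges = edges, hubs = hubs)
  })
}

#' Simulate a full study bundle
#'
#' Generates the complete input set for an end-to-end pipeline run: one
#' locus per gene-by-cell-type pair ([simulate_locus()]), a combined
#' outcome association table, per-locus LD matrices keyed
#' `"gene|cell_type"`, and the ground-truth records.
#'
#' @param config A [sim_config()].
#' @return List: `exposures` (list of exposure datasets), `outcome`
#'   (tibble), `ld` (named list of matrices), `truth` (named list),
#'   `genes`, `cell_types`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- sprintf("G%d", seq_len(config$n_genes))
  exposures <- list(); ld <- list(); truth <- list(); outcomes <- list()
  for (i in seq_along(genes)) {
    for (ct in config$cell_types) {
      loc <- simulate_locus(config, gene = genes[i], cell_type = ct,
                            gene_index = i)
      key <- paste(genes[i], ct, sep = "|")
      exposures[[key]] <- loc$exposure
      ld[[key]] <- loc$ld
      truth[[key]] <- loc$truth
      outcomes[[key]] <- loc$outcome
    }
  }
  list(exposures = exposures, outcome = do.call(rbind, outcomes),
       ld = ld, truth = truth, genes = genes,
       cell_types = config$cell_types)
}
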