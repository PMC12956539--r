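# In-code fixtures and independent oracles shared across the suite.

# Minimal association tibble with sensible defaults.
make_assoc <- function(variant_id, beta, se, pvalue = NULL,
                       effect_allele = "A", other_allele = "G",
                       eaf = 0.3, n = 1000, pos = seq_along(variant_id)) {
  k <- length(variant_id)
  if (is.null(pvalue)) pvalue <- 2 * pnorm(-abs(beta / se))
  pvalue <- pmax(pvalue, .Machine$double.xmin)
  tibble::tibble(
    variant_id = variant_id, chrom = "1", pos = pos,
    effect_allele = rep_len(effect_allele, k),
    other_allele = rep_len(other_allele, k),
    eaf = rep_len(eaf, k), beta = beta, se = rep_len(se, k),
    pvalue = pvalue, n = rep_len(n, k)
  )
}

# Build a harmonized_set directly, bypassing file IO and allele matching.
make_h <- function(beta_exp, se_exp, beta_out, se_out, ld = NULL,
                   n_exp = 982, n_out = 50000, gene = "G1",
                   cell_type = "CD4_NC") {
  k <- length(beta_exp)
  ids <- sprintf("v%03d", seq_len(k))
  if (!is.null(ld)) dimnames(ld) <- list(ids, ids)
  structure(
    list(gene = gene, cell_type = cell_type,
         data = tibble::tibble(
           variant_id = ids, effect_allele = "A", other_allele = "G",
           beta_exp = beta_exp, se_exp = rep_len(se_exp, k),
           pval_exp = pmax(2 * pnorm(-abs(beta_exp / rep_len(se_exp, k))),
                           .Machine$double.xmin),
           eaf_exp = 0.3,
           beta_out = beta_out, se_out = rep_len(se_out, k),
           pval_out = pmax(2 * pnorm(-abs(beta_out / rep_len(se_out, k))),
                           .Machine$double.xmin),
           eaf_out = 0.3),
         ld = ld, n_exp = n_exp, n_out = n_out,
         dropped = tibble::tibble(variant_id = character(0),
                                  reason = character(0))),
    class = "harmonized_set"
  )
}

# --- independent oracles -------------------------------------------------

# BH step-up from its max-min definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  sorted <- p[ord]
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * sorted[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Brute-force normalized betweenness by enumerating all simple paths.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  nodes <- seq_len(n)
  all_paths <- function(from, to) {
    paths <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == to) { paths[[length(paths) + 1L]] <<- path; return() }
      for (nb in nodes[adj[last, ] == 1]) {
        if (!nb %in% path) walk(c(path, nb))
      }
    }
    walk(from)
    paths
  }
  bc <- numeric(n)
  for (s in nodes) for (t in nodes) {
    if (s >= t) next
    paths <- all_paths(s, t)
    if (length(paths) == 0L) next
    lens <- vapply(paths, length, integer(1L))
    geo <- paths[lens == min(lens)]
    for (g in geo) {
      inner <- setdiff(g, c(s, t))
      bc[inner] <- bc[inner] + 1 / length(geo)
    }
  }
  if (n > 2) bc / ((n - 1) * (n - 2) / 2) else rep(0, n)
}

# Colocalization posteriors by direct enumeration in plain arithmetic:
# ABFs evaluated as ratios of normal marginal likelihoods, hypothesis
# sums accumulated with explicit loops.
oracle_coloc <- function(input) {
  abf <- function(beta, varbeta, W) {
    dnorm(beta, 0, sqrt(varbeta + W)) / dnorm(beta, 0, sqrt(varbeta))
  }
  b1 <- abf(input$beta1, input$varbeta1, input$prior_w1)
  b2 <- abf(input$beta2, input$varbeta2, input$prior_w2)
  k <- length(b1)
  s1 <- sum(b1); s2 <- sum(b2)
  s12 <- sum(b1 * b2)
  h3 <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j) h3 <- h3 + b1[i] * b2[j]
  }
  w <- c(H0 = 1, H1 = input$p1 * s1, H2 = input$p2 * s2,
         H3 = input$p1 * input$p2 * h3, H4 = input$p12 * s12)
  w / sum(w)
}

# Weighted median via explicit breakpoint scan of the weighted CDF.
oracle_weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  cw <- cumsum(w) - w / 2
  if (0.5 <= cw[1]) return(x[1])
  if (0.5 >= cw[length(cw)]) return(x[length(x)])
  j <- max(which(cw < 0.5))
  x[j] + (x[j + 1] - x[j]) * (0.5 - cw[j]) / (cw[j + 1] - cw[j])
}
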