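#' Weighted drug-target priority score
#'
#' Composite evidence score over four criteria: (i) prior disease-associated
#' genetic evidence, weight +2; (ii) membership in a disease-relevant
#' pathway, +1; (iii) an approved or investigational drug targeting the
#' protein, +1; (iv) classification as druggable, +0.5. Total scores map to
#' tiers exactly as the bands are printed: `>= 4` high, `3`-`3.5` medium,
#' `<= 2.5` low -- a partition of every reachable score in
#' `{0, 0.5, ..., 4.5}`.
#'
#' @param disease_locus,pathway_member,has_drug,druggable Logical vectors
#'   (recycled to a common length).
#' @param gene Optional gene symbols.
#' @return Tibble with the four flags, `score`, and `tier`.
#' @export
priority_score <- function(disease_locus, pathway_member, has_drug,
                           druggable, gene = NULL) {
  n <- max(length(disease_locus), length(pathway_member),
           length(has_drug), length(druggable))
  f1 <- rep_len(as.logical(disease_locus), n)
  f2 <- rep_len(as.logical(pathway_member), n)
  f3 <- rep_len(as.logical(has_drug), n)
  f4 <- rep_len(as.logical(druggable), n)
  if (any(is.na(c(f1, f2, f3, f4)))) {
    stop("evidence flags must be TRUE or FALSE", call. = FALSE)
  }
  score <- 2 * f1 + 1 * f2 + 1 * f3 + 0.5 * f4
  tier <- ifelse(score >= 4, "high", ifelse(score >= 3, "medium", "low"))
  out <- tibble::tibble(disease_locus = f1, pathway_member = f2,
                        has_drug = f3, druggable = f4,
                        score = score, tier = tier)
  if (!is.null(gene)) out <- cbind(tibble::tibble(gene = gene), out)
  tibble::as_tibble(out)
}

#' Annotate genes with drug-interaction evidence
#'
#' Looks genes up in a static drug-gene annotation table (a snapshot of a
#' drug-gene interaction resource). `has_drug` is true when any interaction
#' row exists for the gene; `druggable` when any of its rows carries a
#' non-empty `druggable_class`. Genes absent from the table get both flags
#' false and the annotation `"undrugged"`.
#'
#' @param genes Character vector of gene symbols.
#' @param drug_table Data frame with columns `gene`, `drug_id`,
#'   `interaction_type`, `source`, `druggable_class`.
#' @return Tibble with `gene`, `has_drug`, `druggable`, `n_drugs`, and
#'   `annotation` (`"drugged"` / `"undrugged"`).
#' @export
annotate_druggability <- function(genes, drug_table) {
  drug_table <- as.data.frame(drug_table)
  required <- c("gene", "drug_id", "interaction_type", "source",
                "druggable_class")
  missing_cols <- setdiff(required, names(drug_table))
  if (length(missing_cols) > 0L) {
    stop("malformed drug table: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  nonempty <- function(x) !is.na(x) & trimws(as.character(x)) != ""
  out <- lapply(genes, function(g) {
    rows <- drug_table[drug_table$gene == g & nonempty(drug_table$drug_id), ,
                       drop = FALSE]
    has_drug <- nrow(rows) > 0L
    tibble::tibble(
      gene = g, has_drug = has_drug,
      druggable = has_drug && any(nonempty(rows$druggable_class)),
      n_drugs = length(unique(rows$drug_id)),
      annotation = if (has_drug) "drugged" else "undrugged"
    )
  })
  do.call(rbind, out)
}

#' Prioritize candidate genes from evidence tables
#'
#' Derives the four evidence flags from static annotation tables -- disease
#' evidence (column `gene`), pathway membership (column `gene`), and the
#' drug-interaction snapshot consumed by [annotate_druggability()] -- and
#' scores each gene with [priority_score()].
#'
#' @param genes Character vector of gene symbols to score.
#' @param disease_table Data frame with a `gene` column listing genes with
#'   prior disease-associated genetic evidence.
#' @param pathway_table Data frame with a `gene` column listing members of
#'   disease-relevant pathways.
#' @param drug_table Drug-gene annotation table (see
#'   [annotate_druggability()]).
#' @return Tibble: `gene`, four flags, `n_drugs`, `annotation`, `score`,
#'   `tier`.
#' @export
prioritize_genes <- function(genes, disease_table, pathway_table,
                             drug_table) {
  drug <- annotate_druggability(genes, drug_table)
  flags <- priority_score(
    disease_locus = genes %in% as.data.frame(disease_table)$gene,
    pathway_member = genes %in% as.data.frame(pathway_table)$gene,
    has_drug = drug$has_drug,
    druggable = drug$druggable,
    gene = genes
  )
  flags$n_drugs <- drug$n_drugs
  flags$annotation <- drug$annotation
  flags[, c("gene", "disease_locus", "pathway_member", "has_drug",
            "druggable", "n_drugs", "annotation", "score", "tier")]
}
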