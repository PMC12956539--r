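#' Build a high-confidence interaction graph
#'
#' Filters a weighted protein-interaction edge list to high-confidence
#' edges and assembles an undirected graph. Scores may be given on the
#' [0, 1] scale or as STRING-style 0-1000 integers (auto-detected: any
#' score above 1 triggers division by 1000). Self-loops are removed,
#' duplicate undirected edges collapse to the maximum score, and -- when a
#' gene universe is supplied -- edges touching genes outside it are
#' dropped. Unmapped genes (universe members absent from the edge list) and
#' isolated nodes (present only via sub-threshold edges) are reported.
#'
#' @param edges Data frame whose first three columns are interpreted as
#'   gene A, gene B, score (column names `protein1`, `protein2`,
#'   `combined_score` are also recognized anywhere in the table).
#' @param genes Optional gene universe restricting the graph.
#' @param min_score Minimum confidence score to retain an edge (default
#'   0.7, i.e. edges with score `>= 0.7` are kept).
#' @return List of class `interaction_graph`: `graph` (igraph object,
#'   unweighted; scores kept as the `score` edge attribute), `edges`
#'   (retained edge tibble), `min_score`, `unmapped`, `isolated`.
#' @export
build_graph <- function(edges, genes = NULL, min_score = 0.7) {
  edges <- as.data.frame(edges)
  std <- c("protein1", "protein2", "combined_score")
  if (all(std %in% names(edges))) {
    edges <- edges[std]
  } else {
    edges <- edges[, 1:3, drop = FALSE]
  }
  names(edges) <- c("gene_a", "gene_b", "score")
  edges$gene_a <- as.character(edges$gene_a)
  edges$gene_b <- as.character(edges$gene_b)
  edges$score <- as.numeric(edges$score)
  if (any(is.na(edges$score))) {
    stop("interaction scores must be numeric", call. = FALSE)
  }
  if (any(edges$score > 1)) edges$score <- edges$score / 1000
  if (any(edges$score < 0 | edges$score > 1)) {
    stop("interaction scores must lie in [0, 1] (or STRING's 0-1000)",
         call. = FALSE)
  }
  edges <- edges[edges$gene_a != edges$gene_b, , drop = FALSE]
  seen <- unique(c(edges$gene_a, edges$gene_b))
  if (!is.null(genes)) {
    edges <- edges[edges$gene_a %in% genes & edges$gene_b %in% genes, ,
                   drop = FALSE]
    unmapped <- sort(setdiff(genes, seen))
  } else {
    unmapped <- character(0)
  }
  # canonical undirected key; keep max score per pair
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  edges$gene_a <- a; edges$gene_b <- b
  key <- paste(a, b, sep = "\r")
  edges <- edges[order(key, -edges$score), , drop = FALSE]
  edges <- edges[!duplicated(paste(edges$gene_a, edges$gene_b, sep = "\r")), ,
                 drop = FALSE]
  pre_nodes <- unique(c(edges$gene_a, edges$gene_b))
  retained <- edges[edges$score >= min_score, , drop = FALSE]
  rownames(retained) <- NULL
  nodes <- sort(unique(c(retained$gene_a, retained$gene_b)))
  isolated <- sort(setdiff(pre_nodes, nodes))
  g <- igraph::graph_from_data_frame(
    retained[c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = nodes)
  )
  if (nrow(retained) > 0L) {
    igraph::E(g)$score <- retained$score
  }
  structure(
    list(graph = g, edges = tibble::as_tibble(retained),
         min_score = min_score, unmapped = unmapped, isolated = isolated),
    class = "interaction_graph"
  )
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf(
    "<interaction_graph> %d node(s), %d edge(s) at score >= %.2f; %d unmapped, %d isolated\n",
    igraph::vcount(x$graph), igraph::ecount(x$graph), x$min_score,
    length(x$unmapped), length(x$isolated)))
  invisible(x)
}

#' Betweenness centrality of graph nodes
#'
#' Unweighted shortest-path betweenness (endpoints excluded), normalized by
#' the number of vertex pairs excluding the node itself --
#' `(n - 1)(n - 2) / 2` for an undirected graph -- so values lie in
#' [0, 1]. Deterministic; confidence scores do not act as path lengths.
#'
#' @param graph An [build_graph()] result or a bare igraph object.
#' @return Named numeric vector of centralities (empty for an empty graph).
#' @export
graph_betweenness <- function(graph) {
  g <- if (inherits(graph, "interaction_graph")) graph$graph else graph
  if (igraph::vcount(g) == 0L) return(stats::setNames(numeric(0), character(0)))
  bc <- igraph::betweenness(g, directed = FALSE, weights = NA,
                            normalized = igraph::vcount(g) > 2L)
  if (igraph::vcount(g) <= 2L) bc[] <- 0
  stats::setNames(as.numeric(bc), igraph::V(g)$name)
}

#' Rank hub genes by betweenness centrality
#'
#' Orders nodes descending by betweenness; ties are broken by descending
#' degree, then gene symbol. The top ten ranked genes are the conventional
#' core-candidate set.
#'
#' @param graph An [build_graph()] result or igraph object.
#' @param k Number of hubs to return (default 10). Requesting more than
#'   available returns all nodes, flagged via
#'   `attr(, "requested_more_than_available")`.
#' @return Tibble: `gene`, `betweenness`, `degree`, `rank`.
#' @export
rank_hubs <- function(graph, k = 10L) {
  g <- if (inherits(graph, "interaction_graph")) graph$graph else graph
  bc <- graph_betweenness(g)
  if (length(bc) == 0L) {
    out <- tibble::tibble(gene = character(0), betweenness = numeric(0),
                          degree = integer(0), rank = integer(0))
    attr(out, "requested_more_than_available") <- k > 0L
    return(out)
  }
  deg <- igraph::degree(g)
  tab <- tibble::tibble(gene = names(bc), betweenness = as.numeric(bc),
                        degree = as.integer(deg[names(bc)]))
  tab <- tab[order(-tab$betweenness, -tab$degree, tab$gene), , drop = FALSE]
  short <- k > nrow(tab)
  tab <- utils::head(tab, k)
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  attr(tab, "requested_more_than_available") <- short
  tab
}

#' Combine hub ranking, prioritization, and colocalization
#'
#' Final candidate selection: the intersection of ranked hub genes with
#' high- or medium-priority genes, annotated with each gene's posterior
#' probability of a shared causal variant (PPH4) and a colocalized flag
#' (`PPH4 > pph4_min`). Ordered by betweenness. Hub genes excluded for
#' lacking priority support are reported via `attr(, "excluded")`.
#'
#' @param hubs Tibble from [rank_hubs()].
#' @param priorities Tibble from [prioritize_genes()] (needs `gene`,
#'   `tier`).
#' @param coloc Optional tibble from [coloc_table()] (needs `gene`,
#'   `PPH4`); when a gene appears for several cell types its maximum PPH4
#'   is used.
#' @param pph4_min Colocalization evidence bar (default 0.8).
#' @param keep_tiers Priority tiers eligible for candidacy (default
#'   `c("high", "medium")`).
#' @return Tibble of candidates: hub columns plus `score`, `tier`, `PPH4`,
#'   `colocalized`. Empty (zero rows) when the intersection is empty.
#' @export
core_candidates <- function(hubs, priorities, coloc = NULL, pph4_min = 0.8,
                            keep_tiers = c("high", "medium")) {
  priorities <- as.data.frame(priorities)
  eligible <- priorities[priorities$tier %in% keep_tiers, , drop = FALSE]
  keep <- hubs$gene %in% eligible$gene
  excluded <- hubs$gene[!keep]
  out <- hubs[keep, , drop = FALSE]
  out$score <- eligible$score[match(out$gene, eligible$gene)]
  out$tier <- eligible$tier[match(out$gene, eligible$gene)]
  if (!is.null(coloc)) {
    coloc <- as.data.frame(coloc)
    pph4 <- tapply(coloc$PPH4, coloc$gene, max)
    out$PPH4 <- as.numeric(pph4[out$gene])
    out$colocalized <- !is.na(out$PPH4) & out$PPH4 > pph4_min
  } else {
    out$PPH4 <- NA_real_
    out$colocalized <- NA
  }
  out <- out[order(-out$betweenness, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "status") <- if (nrow(out) == 0L) "empty_intersection" else "ok"
  out
}
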