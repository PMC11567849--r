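#' Load a STRING-dialect protein-protein interaction edge table
#'
#' Reads a TSV with two node columns and a combined score column. Scores are
#' auto-detected: any value greater than 1 means the table uses STRING's
#' integer dialect and all scores are divided by 1000. Edges below
#' `min_score` (after normalization) are dropped; self-loops are removed;
#' symmetric duplicates are merged keeping the maximum score.
#'
#' @param path path to a TSV file with columns `node1`, `node2`,
#'   `combined_score` (or the first three columns in that order).
#' @param min_score minimum normalized interaction score (default 0.7, the
#'   STRING "high confidence" cut).
#' @return an undirected simple `igraph` graph with edge attribute
#'   `combined_score` in `[0, 1]`.
#' @export
load_edge_table <- function(path, min_score = 0.7) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  cols <- c("node1", "node2", "combined_score")
  if (!all(cols %in% names(tab))) {
    if (ncol(tab) < 3L) stop("edge table needs at least 3 columns")
    tab <- tab[, 1:3]
    names(tab) <- cols
  } else tab <- tab[, cols]
  score <- suppressWarnings(as.numeric(tab$combined_score))
  bad <- which(is.na(score) | !nzchar(trimws(tab$node1)) | !nzchar(trimws(tab$node2)))
  if (length(bad))
    stop(sprintf("malformed edge table row at line %d", bad[1] + 1L))
  tab$combined_score <- score
  ppi_graph(tab, min_score = min_score)
}

#' Build a PPI graph from an edge data frame
#'
#' Same normalization and filtering rules as [load_edge_table()], for edge
#' tables already in memory (e.g. from [generate_ppi_background()]).
#'
#' @param edges data.frame with columns `node1`, `node2`, `combined_score`.
#' @param min_score minimum normalized score (default 0.7).
#' @return an undirected simple `igraph` graph.
#' @export
ppi_graph <- function(edges, min_score = 0.7) {
  score <- as.numeric(edges$combined_score)
  if (length(score) && any(score > 1)) score <- score / 1000
  if (length(score) && (any(score < 0) || any(score > 1)))
    stop("combined scores outside both the [0,1] and the 0-999 dialect range")
  edges$combined_score <- score
  keep <- score >= min_score & edges$node1 != edges$node2
  edges <- edges[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = list(combined_score = "max"))
}

#' Candidate-gene PPI subnetwork
#'
#' Induced subgraph on the candidate genes, re-filtered at a (usually
#' stricter) score threshold, with isolated nodes removed. The retained node
#' count is the number of candidate genes that form an interconnected
#' network.
#'
#' @param graph an `igraph` PPI graph with edge attribute `combined_score`.
#' @param gene_set character vector of candidate gene symbols (nonempty).
#' @param min_score score threshold for subnetwork edges (default 0.9).
#' @return the filtered induced subgraph (possibly empty, with a warning).
#' @export
candidate_subnetwork <- function(graph, gene_set, min_score = 0.9) {
  if (length(gene_set) == 0L) stop("gene_set is empty")
  keep <- intersect(unique(as.character(gene_set)), igraph::V(graph)$name)
  sub <- igraph::induced_subgraph(graph, keep)
  if (igraph::ecount(sub) > 0) {
    drop <- igraph::E(sub)[igraph::E(sub)$combined_score < min_score]
    sub <- igraph::delete_edges(sub, drop)
  }
  sub <- igraph::delete_vertices(sub, igraph::V(sub)[igraph::degree(sub) == 0])
  if (igraph::vcount(sub) == 0L)
    warning("no candidate genes form an interconnected network at this threshold")
  sub
}

#' Edge-count enrichment of a gene set against a random-gene-set null
#'
#' Counts the edges induced by the gene set in the PPI graph and compares
#' with the induced-edge counts of equally sized node sets drawn uniformly
#' from all graph nodes. `method = "sample"` draws `n_null` random sets and
#' reports the add-one permutation p-value `(k + 1) / (n_null + 1)`;
#' `method = "exhaustive"` enumerates every subset (only sensible for toy
#' graphs) and reports the exact tail proportion.
#'
#' @param graph an `igraph` PPI graph.
#' @param gene_set character vector; at least 2 members must be graph nodes.
#' @param n_null number of null draws (default 10000; ignored when
#'   exhaustive).
#' @param rng_seed integer seed for the null draws.
#' @param method `"sample"` (default) or `"exhaustive"`.
#' @return object of class `enrichment_report`: `observed_edges`,
#'   `expected_edges`, `p_enrich`, `n_null_draws`, `connected_node_count`,
#'   `set_size`, `method`.
#' @export
edge_enrichment <- function(graph, gene_set, n_null = 10000L, rng_seed = 1L,
                            method = c("sample", "exhaustive")) {
  method <- match.arg(method)
  nodes <- igraph::V(graph)$name
  set <- intersect(unique(as.character(gene_set)), nodes)
  if (length(set) < 2L) stop("fewer than 2 gene-set members are graph nodes")
  if (length(unique(as.character(gene_set))) > length(nodes))
    stop("gene_set is larger than the graph background")
  A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  idx <- match(set, nodes)
  count_edges <- function(ii) sum(A[ii, ii]) / 2
  observed <- count_edges(idx)
  sub <- igraph::induced_subgraph(graph, set)
  connected <- sum(igraph::degree(sub) > 0)

  k <- length(idx); n <- length(nodes)
  if (method == "exhaustive") {
    sets <- utils::combn(n, k)
    null_counts <- apply(sets, 2L, count_edges)
    p <- mean(null_counts >= observed)
    draws <- ncol(sets)
  } else {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(rng_seed)
    null_counts <- vapply(seq_len(n_null),
                          function(i) count_edges(sample.int(n, k)), numeric(1))
    p <- (sum(null_counts >= observed) + 1) / (n_null + 1)
    draws <- n_null
  }
  structure(list(observed_edges = observed, expected_edges = mean(null_counts),
                 p_enrich = p, n_null_draws = draws,
                 connected_node_count = connected, set_size = k,
                 method = method),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf(paste0("edge enrichment: %d observed vs %.1f expected edges ",
                     "(set of %d nodes, %d connected); p = %.3g [%s, %d draws]\n"),
              x$observed_edges, x$expected_edges, x$set_size,
              x$connected_node_count, x$p_enrich, x$method, x$n_null_draws))
  invisible(x)
}

#' Hub genes by degree
#'
#' Ranks nodes by degree (descending), breaking ties lexicographically by
#' symbol, and returns the top `ceiling(fraction * node count)`.
#'
#' @param graph an `igraph` graph (nonempty).
#' @param fraction top fraction of nodes to call hubs (default 0.10).
#' @return character vector of hub gene symbols, in rank order; degrees as
#'   the `degree` attribute.
#' @export
hub_genes <- function(graph, fraction = 0.10) {
  nv <- igraph::vcount(graph)
  if (nv == 0L) stop("graph is empty")
  deg <- igraph::degree(graph)
  nm <- igraph::V(graph)$name
  ord <- order(-deg, nm)
  n_hub <- ceiling(fraction * nv)
  hubs <- nm[ord][seq_len(n_hub)]
  attr(hubs, "degree") <- deg[ord][seq_len(n_hub)]
  hubs
}
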