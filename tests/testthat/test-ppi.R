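test_that("edge tables are normalized, filtered and merged per the STRING dialect", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("node1\tnode2\tcombined_score",
               "A\tB\t950",
               "B\tA\t800",
               "A\tC\t690",
               "C\tD\t901",
               "D\tD\t999"), f)
  g <- load_edge_table(f, min_score = 0.7)
  el <- igraph::as_data_frame(g)
  # integer dialect detected, scores divided by 1000
  ab <- el[(el$from == "A" & el$to == "B") | (el$from == "B" & el$to == "A"), ]
  expect_equal(nrow(ab), 1L)               # symmetric duplicate merged
  expect_equal(ab$combined_score, 0.95)    # max of 0.95 / 0.80 kept
  expect_false(any(el$combined_score < 0.7))  # 0.69 dropped
  expect_equal(igraph::ecount(g), 2L)      # A-B, C-D; self-loop D-D removed
  # malformed score errors with the line number
  writeLines(c("node1\tnode2\tcombined_score", "A\tB\t950", "B\tC\tx"), f)
  expect_error(load_edge_table(f), "line 3")
  # fractional dialect passes through unscaled
  g2 <- ppi_graph(data.frame(node1 = "A", node2 = "B", combined_score = 0.69),
                  min_score = 0.5)
  expect_equal(igraph::E(g2)$combined_score, 0.69)
})

test_that("candidate subnetwork induces, refilters and drops isolated nodes", {
  g <- ppi_graph(data.frame(node1 = c("A", "A", "B", "C"),
                            node2 = c("B", "C", "C", "D"),
                            combined_score = c(0.95, 0.95, 0.95, 0.92)))
  # triangle A-B-C at 0.95; gene set {A, B}: single edge, 2 nodes
  sub <- candidate_subnetwork(g, c("A", "B"), min_score = 0.9)
  expect_equal(igraph::vcount(sub), 2L)
  expect_equal(igraph::ecount(sub), 1L)
  # disjoint gene set: empty graph with a warning
  expect_warning(empty <- candidate_subnetwork(g, c("X", "Y")), "no candidate")
  expect_equal(igraph::vcount(empty), 0L)
  # random toy graphs against a brute-force filter oracle
  set.seed(53)
  for (i in 1:5) {
    tab <- generate_ppi_background(15, 0.4, rng_seed = i)
    gg <- ppi_graph(tab, min_score = 0.4)
    genes <- sprintf("G%04d", sample(15, 8))
    sub <- candidate_subnetwork(gg, genes, min_score = 0.7)
    el <- igraph::as_data_frame(gg)
    keep <- el$from %in% genes & el$to %in% genes & el$combined_score >= 0.7
    expect_equal(igraph::ecount(sub), sum(keep))
    expect_equal(sort(igraph::V(sub)$name),
                 sort(unique(c(el$from[keep], el$to[keep]))))
    # degree sum is twice the edge count on every constructed graph
    expect_equal(sum(igraph::degree(sub)), 2 * igraph::ecount(sub))
    # raising min_score never increases node or edge counts
    sub9 <- candidate_subnetwork(gg, genes, min_score = 0.9)
    expect_lte(igraph::ecount(sub9), igraph::ecount(sub))
    expect_lte(igraph::vcount(sub9), igraph::vcount(sub))
  }
})

test_that("edge enrichment matches exhaustive enumeration on the toy graph", {
  g <- toy_ppi_graph()   # 6 nodes, 7 edges
  expect_equal(igraph::vcount(g), 6L)
  expect_equal(igraph::ecount(g), 7L)
  rep_ <- edge_enrichment(g, c("A", "B", "C"), method = "exhaustive")
  # independent oracle: enumerate all C(6,3) = 20 subsets
  nodes <- igraph::V(g)$name
  el <- igraph::as_data_frame(g)
  count_set <- function(s) sum(el$from %in% s & el$to %in% s)
  sets <- combn(nodes, 3)
  counts <- apply(sets, 2, count_set)
  expect_equal(ncol(sets), 20L)
  expect_equal(rep_$observed_edges, count_set(c("A", "B", "C")))
  expect_equal(rep_$expected_edges, mean(counts))
  expect_equal(rep_$p_enrich, mean(counts >= rep_$observed_edges))
  # gene_set = all nodes: observed equals expected, p = 1
  all_rep <- edge_enrichment(g, nodes, n_null = 200, rng_seed = 1)
  expect_equal(all_rep$observed_edges, all_rep$expected_edges)
  expect_equal(all_rep$p_enrich, 1)
  # p invariant to node relabeling (exhaustive mode)
  g2 <- g
  igraph::V(g2)$name <- rev(igraph::V(g)$name)  # F<->A, E<->B, D<->C
  rep2 <- edge_enrichment(g2, c("F", "E", "D"), method = "exhaustive")
  expect_equal(rep2$p_enrich, rep_$p_enrich)
  expect_equal(rep2$expected_edges, rep_$expected_edges)
  expect_error(edge_enrichment(g, c("A", "X")), "fewer than 2")
})

test_that("a planted dense module is detected as edge enrichment", {
  tab <- generate_ppi_background(100, 0.05,
                                 planted_module = list(nodes = 1:20,
                                                       within_prob = 0.5),
                                 rng_seed = 61)
  g <- ppi_graph(tab, min_score = 0.4)
  rep_ <- edge_enrichment(g, attr(tab, "module_nodes"), n_null = 2000,
                          rng_seed = 8)
  expect_lt(rep_$p_enrich, 0.01)
  expect_gt(rep_$observed_edges, rep_$expected_edges)
})

test_that("hub genes are the top decile by degree with lexicographic ties", {
  g <- ppi_graph(data.frame(
    node1 = c("HUB", "HUB", "HUB", "HUB", "HUB", "B", "B", "B", "C"),
    node2 = c("B", "C", "D", "E", "F", "C", "D", "E", "D"),
    combined_score = 0.9))
  # degrees: HUB 5, B 4, C 3, D 3, E 2, F 1; fraction 0.10 of 6 -> 1 hub
  expect_equal(as.character(hub_genes(g, 0.10)), "HUB")
  # ceiling rule: fraction 0.4 of 6 nodes -> 3 hubs; C before D at equal degree
  expect_equal(as.character(hub_genes(g, 0.4)), c("HUB", "B", "C"))
  # all degrees equal: lexicographically first nodes
  ring <- igraph::make_ring(10)
  igraph::V(ring)$name <- sprintf("N%02d", 10:1)
  expect_equal(as.character(hub_genes(ring, 0.2)), c("N01", "N02"))
  # larger graph against an explicit sort oracle, 376 nodes -> 38 hubs
  tab <- generate_ppi_background(400, 0.02, rng_seed = 71)
  g2 <- ppi_graph(tab, min_score = 0.4)
  g2 <- igraph::delete_vertices(g2, igraph::V(g2)[igraph::degree(g2) == 0])
  g2 <- igraph::induced_subgraph(g2, igraph::V(g2)$name[seq_len(376)])
  hubs <- hub_genes(g2, 0.10)
  expect_length(hubs, 38L)
  deg <- igraph::degree(g2)
  oracle <- names(deg)[order(-deg, names(deg))][1:38]
  expect_equal(as.character(hubs), oracle)
})
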