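mk_de <- function(genes, sig_genes, lfc = 3) {
  data.frame(gene = genes,
             log2fc = ifelse(genes %in% sig_genes, lfc, 0.5),
             adj_p = ifelse(genes %in% sig_genes, 0.01, 0.5))
}

test_that("consensus DE: >=3-dataset rule, union mode, eligibility", {
  genes <- paste0("g", 1:10)
  tabs <- list(mk_de(genes, c("g1", "g2")), mk_de(genes, c("g1", "g2")),
               mk_de(genes, "g1"), mk_de(genes, character()),
               mk_de(genes, character()), mk_de(genes, character()))
  out <- consensus_de(tabs, expr_tables = NULL)
  expect_true(out$consensus[out$gene == "g1"])    # 3 of 6
  expect_false(out$consensus[out$gene == "g2"])   # 2 of 6
  # union mode over two tables: significant in one suffices
  u <- consensus_de(tabs[3:4], expr_tables = NULL, mode = "union")
  expect_true(u$consensus[u$gene == "g1"])
  expect_error(consensus_de(tabs[1:2], expr_tables = NULL),
               "min_datasets")
  # fold-ratio boundary: |log2FC| must exceed 2
  tb2 <- mk_de(genes, "g1", lfc = 2)
  low <- consensus_de(list(tb2, tb2, tb2), expr_tables = NULL)
  expect_false(low$consensus[low$gene == "g1"])
})

test_that("expression prefilter requires upper-half expression in >=3 datasets", {
  genes <- paste0("g", 1:10)
  tabs <- replicate(3, mk_de(genes, "g1"), simplify = FALSE)
  lowexp <- data.frame(gene = genes, expr = c(0.01, 2:10))  # g1 below median
  hiexp <- data.frame(gene = genes, expr = c(9, 1:9))
  out <- consensus_de(tabs, expr_tables = list(lowexp, lowexp, hiexp))
  expect_false(out$consensus[out$gene == "g1"])
  out2 <- consensus_de(tabs, expr_tables = list(hiexp, hiexp, hiexp))
  expect_true(out2$consensus[out2$gene == "g1"])
})

test_that("DTU consensus keeps genes called in at least half the datasets", {
  flags <- list(c("a", "b"), c("a", "c"), c("a", "b"), "d", "d", "e")
  expect_setequal(consensus_dtu(flags), "a")  # a: 3 of 6; b and d: only 2
  expect_setequal(consensus_dtu(list(c("x", "y"))), c("x", "y"))
})

test_that("interaction merging applies per-source confidence rules", {
  rec <- data.frame(
    node_a = c("A", "A", "B", "B", "C", "C", "A"),
    node_b = c("B", "B", "C", "C", "D", "D", "B"),
    source = c("source1", "source1", "source2", "source2", "source3",
               "source3", "source2"),
    confidence = c(0.65, 0.75, NA, 0.2, 0.65, 0.75, 0.5))
  out <- merge_interactions(rec)
  key <- paste(out$node_a, out$node_b)
  expect_true("A B" %in% key)     # source1 at 0.75 kept (0.65 dropped)
  expect_true("B C" %in% key)     # source2 with any confidence kept
  expect_true("C D" %in% key)     # source3 at 0.75 kept
  # duplicate pair from two sources collapses with both labels
  expect_equal(out$sources[key == "A B"], "source1,source2")
  # absent-confidence source2 record contributed nothing
  expect_equal(nrow(out), 3)
})

test_that("integrative network filters by evidence and DTU composition", {
  # component 1: 10 nodes, 8 DTU-only (80% > 75%) -> dropped
  # component 2: nodes with proteome evidence -> kept, largest returned
  e1 <- data.frame(node_a = paste0("d", 1:9), node_b = paste0("d", 2:10))
  e2 <- data.frame(node_a = paste0("p", 1:4), node_b = paste0("p", 2:5))
  e3 <- data.frame(node_a = "q1", node_b = "q2")
  hits <- list(proteome = c(paste0("p", 1:5), "q1", "q2", "d1", "d2"),
               dtu = paste0("d", 1:10))
  g <- build_integrative_network(rbind(e1, e2, e3), hits)
  expect_setequal(igraph::V(g)$name, paste0("p", 1:5))
  # an edge with a non-significant endpoint is excluded
  e4 <- data.frame(node_a = c("p1", "p2"), node_b = c("p2", "zz"))
  g4 <- build_integrative_network(e4, list(proteome = c("p1", "p2")))
  expect_setequal(igraph::V(g4)$name, c("p1", "p2"))
  expect_null(suppressMessages(
    build_integrative_network(e3, list(proteome = "nope"))))
})

test_that("current-flow betweenness: path, star, tree equivalence", {
  p4 <- igraph::make_graph(~ a - b, b - c, c - d)
  s <- current_flow_betweenness(p4)
  expect_equal(unname(s[c("a", "b", "c", "d")]), c(0, 2, 2, 0))
  star <- igraph::make_star(4, mode = "undirected", center = 1)
  ss <- current_flow_betweenness(star)
  expect_equal(unname(ss), c(3, 0, 0, 0))
  # on trees all current follows the unique path: equals shortest-path
  # betweenness
  set.seed(3)
  tr <- igraph::sample_tree(12)
  expect_equal(unname(current_flow_betweenness(tr)),
               unname(igraph::betweenness(tr)), tolerance = 1e-9)
  expect_error(current_flow_betweenness(
    igraph::make_graph(~ a - b, c - d)), "disconnected")
})

test_that("current-flow betweenness matches the brute-force oracle", {
  set.seed(99)
  for (i in 1:30) {
    n <- sample(4:6, 1)
    repeat {
      g <- igraph::sample_gnp(n, 0.6)
      if (igraph::is_connected(g)) break
    }
    igraph::V(g)$name <- letters[seq_len(n)]
    expect_equal(current_flow_betweenness(g), cfb_oracle(g),
                 tolerance = 1e-8)
  }
})

test_that("centrality is invariant under node relabeling", {
  set.seed(5)
  repeat {
    g <- igraph::sample_gnp(8, 0.4)
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- paste0("n", 1:8)
  perm <- sample(8)
  g2 <- igraph::permute(g, perm)
  s1 <- current_flow_betweenness(g)
  s2 <- current_flow_betweenness(g2)
  expect_equal(s1[names(s2)], s2, tolerance = 1e-9)
})

test_that("module detection separates two cliques and is seed-stable", {
  g <- igraph::make_graph(c(t(rbind(
    igraph::as_edgelist(igraph::make_full_graph(6)),
    igraph::as_edgelist(igraph::make_full_graph(6)) + 6))),
    directed = FALSE)
  g <- igraph::add_edges(g, c(1, 7))
  igraph::V(g)$name <- paste0("v", 1:12)
  part <- detect_modules(g, target_avg_degree = 5, min_module_size = 3,
                         seed = 2)
  expect_equal(length(part$sizes), 2)
  expect_equal(part$sizes, c(6L, 6L))
  part2 <- detect_modules(g, target_avg_degree = 5, min_module_size = 3,
                          seed = 2)
  expect_identical(part$membership, part2$membership)
})
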