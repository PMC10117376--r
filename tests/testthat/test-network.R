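test_that("build_graph enforces score threshold, channels, and simplicity", {
  nodes <- c("A", "B", "C", "D")
  edges <- rbind(
    data.frame(protein_a = "A", protein_b = "B", combined_score = 0.699,
               channels = "experimental"),
    data.frame(protein_a = "A", protein_b = "C", combined_score = 0.700,
               channels = "experimental"),
    data.frame(protein_a = "B", protein_b = "C", combined_score = 0.95,
               channels = "textmining"),
    data.frame(protein_a = "C", protein_b = "A", combined_score = 0.9,
               channels = "database"),                        # duplicate of A-C
    data.frame(protein_a = "D", protein_b = "D", combined_score = 0.9,
               channels = "database"))                        # self-loop
  g <- build_graph(nodes, edges)
  expect_equal(igraph::vcount(g), 4L)
  expect_equal(igraph::ecount(g), 1L)                          # only A-C
  expect_true(igraph::are_adjacent(g, "A", "C"))
  # empty edge table -> all nodes isolated
  g0 <- build_graph(nodes, edges[0, ])
  expect_equal(igraph::vcount(g0), 4L)
  expect_equal(igraph::ecount(g0), 0L)
  # unknown endpoints dropped with a warning
  expect_warning(
    gu <- build_graph(c("A", "B"),
                      data.frame(protein_a = "A", protein_b = "Z",
                                 combined_score = 0.9, channels = "database")),
    "outside the node list")
  expect_equal(igraph::ecount(gu), 0L)
  expect_error(build_graph(nodes, transform(edges, combined_score = 2)), "\\[0, 1\\]")
})

test_that("rebuilding from a graph's own edge list is a fixed point", {
  se <- gen_string_edges(sprintf("N%02d", 1:15),
                         tiny_cfg(planted_clusters = list(c(5, 1)),
                                  background_edge_prob = 0.2))
  g1 <- build_graph(sprintf("N%02d", 1:15), se$edges)
  el <- igraph::as_data_frame(g1, what = "edges")
  edges2 <- data.frame(protein_a = el$from, protein_b = el$to,
                       combined_score = el$combined_score,
                       channels = "experimental")
  g2 <- build_graph(igraph::V(g1)$name, edges2)
  expect_identical(sort(igraph::V(g1)$name), sort(igraph::V(g2)$name))
  expect_identical(igraph::ecount(g1), igraph::ecount(g2))
})

test_that("component summary matches a hand-rolled BFS oracle", {
  # two planted cliques K5, K3 plus two isolated nodes
  nodes <- c(sprintf("A%d", 1:5), sprintf("B%d", 1:3), "X1", "X2")
  edges <- edge_df(c(clique_pairs(sprintf("A%d", 1:5)),
                     clique_pairs(sprintf("B%d", 1:3))))
  g <- build_graph(nodes, edges)
  cs <- component_summary(g)
  expect_equal(cs$component_sizes, c(5L, 3L, 1L, 1L))
  og <- edges_to_oracle(nodes, edges)
  expect_identical(cs$components, oracle_components(og))
  expect_equal(cs$mean_degree, 2 * cs$n_edges / cs$n_nodes)
  expect_equal(sum(cs$component_sizes), cs$n_nodes)
  expect_equal(cs$n_isolated, 2L)
  expect_equal(cs$hubs$protein[1], "A1")  # degree ties break lexicographically
  # edgeless graph
  cs0 <- component_summary(build_graph(nodes, edges[0, ]))
  expect_true(all(cs0$component_sizes == 1L))
  expect_equal(cs0$mean_degree, 0)
})

test_that("MCODE vertex weights agree with the brute-force k-core oracle", {
  # K4 with a pendant, a 5-leaf star, and an isolated node
  nodes <- c(sprintf("K%d", 1:4), "P", "S0", sprintf("S%d", 1:5), "I")
  edges <- edge_df(c(clique_pairs(sprintf("K%d", 1:4)), "K1-P",
                     paste0("S0-S", 1:5)))
  g <- build_graph(nodes, edges)
  og <- edges_to_oracle(nodes, edges)
  expect_equal(mcode_vertex_weight(g, "I"), 0)
  expect_equal(mcode_vertex_weight(g, "K2"), 3)     # 3-core K4, density 1
  expect_equal(mcode_vertex_weight(g, "S0"), 1 * (2 * 5) / (6 * 5))
  expect_equal(mcode_vertex_weight(g, "S1"), 0)     # degree below cutoff
  for (v in nodes) {
    expect_equal(mcode_vertex_weight(g, v), oracle_vertex_weight(og, v),
                 info = v)
  }
  expect_error(mcode_vertex_weight(g, "NOPE"), "unknown node")
})

test_that("MCODE recovers separated planted cliques and nothing from paths", {
  expect_length(mcode_complexes(build_graph(character(), edge_df(character(0)))), 0)
  # two disjoint 6-cliques
  nodes <- c(sprintf("A%d", 1:6), sprintf("B%d", 1:6))
  g <- build_graph(nodes, edge_df(c(clique_pairs(sprintf("A%d", 1:6)),
                                    clique_pairs(sprintf("B%d", 1:6)))))
  cl <- mcode_complexes(g)
  expect_length(cl, 2)
  expect_setequal(cl[[1]]$members, sprintf("A%d", 1:6))
  expect_setequal(cl[[2]]$members, sprintf("B%d", 1:6))
  expect_equal(cl[[1]]$score, 6)                     # density 1 x size 6
  # a bare path has no 2-core: the haircut removes everything
  pn <- sprintf("P%02d", 1:10)
  gp <- build_graph(pn, edge_df(path_pairs(pn)))
  expect_length(mcode_complexes(gp), 0)
})

test_that("two 6-cliques joined by a bridge expand into one complex", {
  # All twelve vertices carry the same weight (their closed neighborhoods
  # all contain a 5-core of density 1), so the seeded expansion crosses
  # the bridge: the canonical algorithm reports one complex of 12, not
  # two of 6. Verified against a by-hand trace of the expansion rule.
  nodes <- c(sprintf("A%d", 1:6), sprintf("B%d", 1:6))
  g <- build_graph(nodes, edge_df(c(clique_pairs(sprintf("A%d", 1:6)),
                                    clique_pairs(sprintf("B%d", 1:6)),
                                    "A1-B1")))
  for (v in nodes) expect_equal(mcode_vertex_weight(g, v), 5)
  cl <- mcode_complexes(g)
  expect_length(cl, 1)
  expect_setequal(cl[[1]]$members, nodes)
})

test_that("MCODE is deterministic and order-independent", {
  set.seed(71)
  nodes <- sprintf("N%02d", 1:12)
  pairs <- utils::combn(nodes, 2)
  keep <- runif(ncol(pairs)) < 0.35
  edges <- data.frame(protein_a = pairs[1, keep], protein_b = pairs[2, keep],
                      combined_score = 0.9, channels = "experimental")
  g1 <- build_graph(nodes, edges)
  shuffled <- edges[sample(nrow(edges)), c(2, 1, 3, 4)]
  names(shuffled) <- names(edges)
  g2 <- build_graph(rev(nodes), shuffled)
  expect_identical(mcode_complexes(g1), mcode_complexes(g2))
})

test_that("on small planted-clique fixtures MCODE matches the exhaustive densest-subgraph oracle", {
  fixtures <- list(
    list(nodes = c(sprintf("A%d", 1:5), "T1", "T2"),
         pairs = c(clique_pairs(sprintf("A%d", 1:5)), "A1-T1", "T1-T2")),
    list(nodes = c(sprintf("A%d", 1:4), sprintf("Z%d", 1:3)),
         pairs = c(clique_pairs(sprintf("A%d", 1:4)),
                   clique_pairs(sprintf("Z%d", 1:3)))),
    list(nodes = c(sprintf("Q%d", 1:5), "L1", "L2", "L3"),
         pairs = c(clique_pairs(sprintf("Q%d", 1:5)),
                   "Q1-L1", "L1-L2", "L2-L3")))
  for (fx in fixtures) {
    edges <- edge_df(fx$pairs)
    g <- build_graph(fx$nodes, edges)
    og <- edges_to_oracle(fx$nodes, edges)
    clusters <- mcode_complexes(g)
    comps <- oracle_components(og)
    for (cl in clusters) {
      comp <- comps[[which(vapply(comps, function(cc) cl$members[1] %in% cc,
                                  logical(1)))]]
      best <- oracle_densest_subgraph(og, comp)
      expect_identical(cl$members, best$members)
      expect_equal(cl$density, best$density)
      # no strict superset within the component is denser
      others <- setdiff(comp, cl$members)
      if (length(others) > 0) {
        for (size in seq_along(others)) {
          for (extra in utils::combn(others, size, simplify = FALSE)) {
            expect_lte(oracle_density(og, c(cl$members, extra)), cl$density)
          }
        }
      }
    }
  }
})
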