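two_cell_table <- function(dist_um) {
  cell_table(data.frame(cell_id = c("a", "b"),
                        x_um = c(0, dist_um), y_um = c(0, 0),
                        cell_type = "lymphocyte", stringsAsFactors = FALSE))
}

graph_edge_keys <- function(g) {
  if (nrow(g$edges) == 0) character(0) else
    sort(paste(g$edges$u, g$edges$v, sep = "|"))
}

test_that("the 25 um threshold removes kNN edges beyond interaction range", {
  # two lymphocytes 30 um apart are mutual nearest neighbours, but the edge
  # exceeds the interaction radius and must be dropped
  g_far <- build_pair_graph(two_cell_table(30), graph_config("lymphocyte", k = 1))
  expect_equal(nrow(g_far$nodes), 2)
  expect_equal(nrow(g_far$edges), 0)

  g_near <- build_pair_graph(two_cell_table(10), graph_config("lymphocyte", k = 1))
  expect_equal(nrow(g_near$edges), 1)
  expect_equal(g_near$edges$length_um, 10)

  # boundary: an edge exactly at the threshold is kept (<=)
  g_edge <- build_pair_graph(two_cell_table(25), graph_config("lymphocyte", k = 1))
  expect_equal(nrow(g_edge$edges), 1)
})

test_that("graph construction matches the O(n^2) oracle, same and cross type", {
  for (seed in 1:5) {
    ct <- random_cell_table(50, seed = seed)
    for (k in c(1, 3)) {
      for (pair in list(c("lymphocyte", "lymphocyte"),
                        c("lymphocyte", "stromal"))) {
        g <- build_pair_graph(ct, graph_config(pair, k = k, max_edge_um = 25))
        want <- bf_pair_edges(ct, pair[1], pair[2], k, 25)
        expect_equal(graph_edge_keys(g), want,
                     info = sprintf("seed %d k %d pair %s", seed, k,
                                    paste(pair, collapse = "-")))
      }
    }
  }
})

test_that("graph construction is invariant to input row order", {
  ct <- random_cell_table(60, seed = 99)
  cfg <- graph_config(c("lymphocyte", "stromal"), k = 3)
  g1 <- build_pair_graph(ct, cfg)
  set.seed(1)
  shuffled <- cell_table(as.data.frame(ct)[sample(nrow(ct)), ])
  g2 <- build_pair_graph(shuffled, cfg)
  expect_equal(graph_edge_keys(g1), graph_edge_keys(g2))
  expect_equal(g1$nodes, g2$nodes)
})

test_that("raising k or max_edge_um never removes edges", {
  ct <- random_cell_table(80, seed = 7, side = 120)
  base <- graph_edge_keys(build_pair_graph(ct, graph_config("lymphocyte", k = 2,
                                                            max_edge_um = 20)))
  more_k <- graph_edge_keys(build_pair_graph(ct, graph_config("lymphocyte", k = 4,
                                                              max_edge_um = 20)))
  more_r <- graph_edge_keys(build_pair_graph(ct, graph_config("lymphocyte", k = 2,
                                                              max_edge_um = 35)))
  expect_true(all(base %in% more_k))
  expect_true(all(base %in% more_r))
})

test_that("connected components: closed forms and union-find oracle", {
  # edgeless graph: every cell its own component
  ct <- random_cell_table(5, types = "lymphocyte", side = 1000, seed = 2)
  g <- build_pair_graph(ct, graph_config("lymphocyte", k = 1, max_edge_um = 1))
  cc <- connected_components(g)
  expect_equal(cc$Nsubgraph, rep(1L, 5))
  expect_equal(length(unique(cc$component)), 5)

  # one triangle plus one isolated cell
  ct2 <- cell_table(data.frame(
    cell_id = c("t1", "t2", "t3", "iso"),
    x_um = c(0, 10, 5, 500), y_um = c(0, 0, 8, 500),
    cell_type = "lymphocyte", stringsAsFactors = FALSE))
  g2 <- build_pair_graph(ct2, graph_config("lymphocyte", k = 2))
  cc2 <- connected_components(g2)
  expect_equal(sort(cc2$Nsubgraph), c(1L, 3L, 3L, 3L))

  # random graphs vs union-find
  for (seed in 1:5) {
    ct3 <- random_cell_table(40, seed = seed, side = 100)
    g3 <- build_pair_graph(ct3, graph_config(c("lymphocyte", "stromal"), k = 2))
    cc3 <- connected_components(g3)
    oracle <- bf_components(g3$nodes$cell_id, g3$edges)
    # same partition up to component relabelling
    expect_equal(as.integer(table(cc3$component)[cc3$component]),
                 as.integer(table(oracle)[oracle]))
    expect_true(all(tapply(oracle, cc3$component,
                           function(v) length(unique(v))) == 1))
  }
})

test_that("node features: closed forms on triangle and path graphs", {
  tri <- cell_table(data.frame(
    cell_id = c("a", "b", "c"), x_um = c(0, 10, 5), y_um = c(0, 0, 8),
    cell_type = "lymphocyte", stringsAsFactors = FALSE))
  nf <- node_features(build_pair_graph(tri, graph_config("lymphocyte", k = 2)))
  expect_equal(nf$ClusteringCoefficient, rep(1, 3))
  expect_equal(nf$Betweenness, rep(0, 3))
  expect_equal(nf$Degree, rep(2L, 3))
  expect_equal(nf$Nsubgraph, rep(3L, 3))
  # edge lengths of the 0-10 / 0-5,8 / 10-5,8 triangle
  expect_equal(nf$MinEdgeLength[nf$cell_id == "a"],
               min(10, sqrt(5^2 + 8^2)))

  # 3-node path: middle node carries the single s-t shortest path
  path <- cell_table(data.frame(
    cell_id = c("p1", "mid", "p3"), x_um = c(0, 10, 20), y_um = 0,
    cell_type = "lymphocyte", stringsAsFactors = FALSE))
  nfp <- node_features(build_pair_graph(path, graph_config("lymphocyte", k = 1)))
  mid <- nfp[nfp$cell_id == "mid", ]
  expect_equal(mid$Degree, 2L)
  expect_equal(mid$Betweenness, 1)          # normalized by (n-1)(n-2)/2 = 1
  expect_equal(mid$BetweennessRaw, 1)
  expect_equal(nfp$Betweenness[nfp$cell_id == "p1"], 0)

  # isolated node: undefined edge lengths, Nsubgraph 1, everything else 0
  iso <- cell_table(data.frame(
    cell_id = c("x", "y"), x_um = c(0, 400), y_um = 0,
    cell_type = "lymphocyte", stringsAsFactors = FALSE))
  nfi <- node_features(build_pair_graph(iso, graph_config("lymphocyte", k = 1)))
  expect_true(all(is.na(nfi$MinEdgeLength)))
  expect_true(all(is.na(nfi$MeanEdgeLength)))
  expect_equal(nfi$Degree, c(0L, 0L))
  expect_equal(nfi$Nsubgraph, c(1L, 1L))
})

test_that("all node features match the brute-force oracle on random graphs", {
  for (seed in 1:8) {
    ct <- random_cell_table(30, seed = seed, side = 90)
    g <- build_pair_graph(ct, graph_config(c("lymphocyte", "stromal"), k = 3))
    got <- node_features(g)
    want <- bf_node_features(g$nodes$cell_id, g$edges)
    expect_equal(got$Degree, want$Degree)
    expect_equal(got$Nsubgraph, want$Nsubgraph)
    expect_equal(got$MinEdgeLength, want$MinEdgeLength, tolerance = 1e-12)
    expect_equal(got$MeanEdgeLength, want$MeanEdgeLength, tolerance = 1e-12)
    expect_equal(got$ClusteringCoefficient, want$ClusteringCoefficient,
                 tolerance = 1e-9)
    expect_equal(got$Betweenness, want$Betweenness, tolerance = 1e-9)
    expect_equal(got$BetweennessRaw, want$BetweennessRaw, tolerance = 1e-9)
  }
})

test_that("feature aggregation summarises per region with exclusion counts", {
  ct <- cell_table(data.frame(
    cell_id = c("a", "b", "c"),
    x_um = c(0, 10, 1000), y_um = 0,
    cell_type = "lymphocyte",
    region = c("core", "core", "peri_1cm"),
    stringsAsFactors = FALSE))
  g <- build_pair_graph(ct, graph_config("lymphocyte", k = 1))
  agg <- aggregate_features(node_features(g), ct, group_by = "region")
  core_deg <- agg[agg$region == "core" & agg$feature == "Degree", ]
  expect_equal(core_deg$mean, 1)
  expect_equal(core_deg$n, 2)
  # the isolated peri cell has undefined edge lengths: excluded, counted
  peri_mel <- agg[agg$region == "peri_1cm" & agg$feature == "MeanEdgeLength", ]
  expect_true(is.na(peri_mel$mean))
  expect_equal(peri_mel$n_excluded, 1)
  # empty region still yields rows, with n = 0
  p3 <- agg[agg$region == "peri_3cm" & agg$feature == "Degree", ]
  expect_equal(p3$n, 0)
  expect_true(is.na(p3$mean))
})
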