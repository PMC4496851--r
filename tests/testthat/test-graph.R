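test_that("build_graph creates one fully weighted edge per best-hit pair", {
  fx <- three_scenario_fixture()
  node_info <- data.frame(
    id = c("fullA", "fullB", "fragC", "fragD"),
    organism = c("orgA", "orgB", "orgA", "orgB"),
    group = "g1", stringsAsFactors = FALSE
  )
  g <- build_graph(best_hits(fx$hits), fx$self_scores, fx$stats,
                   node_info = node_info)
  expect_s3_class(g, "homology_graph")
  expect_equal(nrow(g$nodes), 4L)
  expect_equal(nrow(g$edges), 3L)
  expect_equal(g$normalization, "raw")
  expect_true(all(g$edges$id1 < g$edges$id2))
  for (m in metric_names()) expect_true(all(g$edges[[m]] > 0))
  # empty input -> empty graph
  g0 <- build_graph(bgmcl:::empty_hits(), fx$self_scores, fx$stats)
  expect_equal(nrow(g0$nodes), 0L)
  expect_equal(nrow(g0$edges), 0L)
})

test_that("inter-organism normalization rescales to the global mean", {
  # pair A-B edges {2, 2}, pair A-C edges {4, 4}: global mean 3, all -> 3
  nodes <- data.frame(id = c("a1", "a2", "b1", "b2", "c1", "c2"),
                      organism = c("A", "A", "B", "B", "C", "C"),
                      group = NA_character_, stringsAsFactors = FALSE)
  edges <- data.frame(id1 = c("a1", "a2", "a1", "a2"),
                      id2 = c("b1", "b2", "c1", "c2"),
                      bs = c(2, 2, 4, 4), nle = c(2, 2, 4, 4),
                      bsr = c(2, 2, 4, 4), bal = c(2, 2, 4, 4),
                      stringsAsFactors = FALSE)
  g <- bgmcl:::new_homology_graph(nodes, edges, "raw")
  gn <- normalize_inter_organism(g)
  expect_equal(gn$edges$bs, rep(3, 4))
  expect_equal(gn$normalization, "inter_organism")
  expect_equal(g$edges$bs, c(2, 2, 4, 4))  # input untouched
  # the literal reciprocal variant inverts the ratios
  gr <- normalize_inter_organism(g, direction = "pair_over_global")
  expect_equal(gr$edges$bs, c(2, 2, 4, 4)^2 / 3)
})

test_that("after normalization every organism-pair mean equals the old global mean", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 12
    g <- random_graph(n, p = 0.5, weights = NULL)
    g$nodes$organism <- sample(c("A", "B", "C"), n, replace = TRUE)
    g$edges[metric_names()] <- lapply(metric_names(), function(m) runif(nrow(g$edges), 0.5, 20))
    if (nrow(g$edges) < 3) next
    old_global <- vapply(metric_names(), function(m) mean(g$edges[[m]]), numeric(1))
    gn <- normalize_inter_organism(g)
    pm <- organism_pair_means(gn)
    for (m in metric_names()) {
      expect_equal(unname(pm$pair_means[[m]]),
                   rep(unname(old_global[[m]]), nrow(pm$pair_means)),
                   tolerance = 1e-9)
    }
  }
})

test_that("normalization with a single organism pair is the identity", {
  g <- random_graph(6, p = 0.6)
  if (nrow(g$edges) > 0) {
    gn <- normalize_inter_organism(g)
    expect_equal(gn$edges$bs, g$edges$bs)
  }
})

test_that("connected components match a transitive-closure oracle", {
  # spec example: edges {a-b, b-c, d-e}
  nodes <- data.frame(id = c("a", "b", "c", "d", "e"), organism = "o",
                      group = NA_character_, stringsAsFactors = FALSE)
  edges <- data.frame(id1 = c("a", "b", "d"), id2 = c("b", "c", "e"),
                      bs = 1, nle = 1, bsr = 1, bal = 1,
                      stringsAsFactors = FALSE)
  g <- bgmcl:::new_homology_graph(nodes, edges, "raw")
  cc <- connected_components(g)
  expect_equal(canon(cc$clusters), list(c("a", "b", "c"), c("d", "e")))
  # empty graph
  g0 <- bgmcl:::new_homology_graph(nodes[0, ], edges[0, ], "raw")
  expect_length(connected_components(g0)$clusters, 0L)
  # random graphs up to 8 nodes vs oracle; singletons form singleton clusters
  set.seed(33)
  for (n in c(2, 4, 6, 8)) {
    for (rep in 1:10) {
      g <- random_graph(n, p = runif(1, 0.1, 0.6))
      expect_equal(canon(connected_components(g)$clusters),
                   oracle_components(g))
    }
  }
})

test_that("component structure is invariant under the metric chosen", {
  set.seed(5)
  g <- random_graph(10, p = 0.25)
  g$edges$bs <- runif(nrow(g$edges), 1, 100)
  g$edges$nle <- runif(nrow(g$edges), 1, 100)
  expect_equal(canon(connected_components(g)$clusters), oracle_components(g))
})

test_that("ABC export round-trips pairs and weights at >= 6 significant digits", {
  set.seed(9)
  g <- random_graph(8, p = 0.5)
  g$edges$bsr <- runif(nrow(g$edges), 0.01, 1.2)
  path <- withr::local_tempfile(fileext = ".abc")
  write_abc(g, "bsr", path)
  g2 <- read_abc(path)
  expect_equal(g2$edges[, c("id1", "id2")], g$edges[, c("id1", "id2")])
  expect_equal(g2$edges$weight, g$edges$bsr, tolerance = 1e-7)
  # exact identity for representable decimals
  writeLines(c("a\tb\t2.0", "b\tc\t0.125"), path)
  g3 <- read_abc(path)
  expect_equal(g3$edges$weight, c(2, 0.125))
  writeLines("a\tb", path)
  expect_error(read_abc(path), "line 1")
})

test_that("GML output parses and carries node/cluster annotations", {
  fx <- three_scenario_fixture()
  node_info <- data.frame(id = c("fullA", "fullB", "fragC", "fragD"),
                          organism = c("orgA", "orgB", "orgA", "orgB"),
                          group = "g1", stringsAsFactors = FALSE)
  g <- build_graph(best_hits(fx$hits), fx$self_scores, fx$stats,
                   node_info = node_info)
  cl <- connected_components(g)
  path <- withr::local_tempfile(fileext = ".gml")
  write_gml(g, path, metric = "bs", clustering = cl,
            reference = setNames(rep("g1", 4), node_info$id))
  ig <- igraph::read_graph(path, format = "gml")
  expect_equal(igraph::vcount(ig), 4)
  expect_equal(igraph::ecount(ig), 3)
  expect_setequal(igraph::vertex_attr(ig, "eck"), "g1")
  expect_true("cluster" %in% igraph::vertex_attr_names(ig))
  expect_setequal(round(igraph::edge_attr(ig, "weight")), c(600, 300, 150))
  # no clustering/reference: still valid GML
  write_gml(g, path)
  expect_silent(igraph::read_graph(path, format = "gml"))
})

test_that("edge TSV uses the fixed four-metric column order", {
  g <- random_graph(5, p = 0.8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_graph_tsv(g, path)
  tab <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(names(tab), c("id1", "id2", "bs", "nle", "bsr", "bal"))
  expect_equal(nrow(tab), nrow(g$edges))
})
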