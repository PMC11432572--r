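test_that("shortest-path counts match known small-graph values", {
  c4 <- fixture("C4")$network
  apsp <- all_pairs_shortest_paths(c4)
  expect_equal(apsp$dist["a", "c"], 2) # opposite corners
  expect_equal(apsp$sigma["a", "c"], 2) # two symmetric routes
  p3 <- fixture("P3")$network
  apsp3 <- all_pairs_shortest_paths(p3)
  expect_equal(apsp3$dist["a", "c"], 2)
  expect_equal(apsp3$sigma["a", "c"], 1)
  expect_equal(sum(paths_through(apsp3, "b")) / 2, 1) # sigma_ac(b) = 1
})

test_that("clustering coefficient follows CI = 2n/(k(k-1)) with CI = 0 below degree 2", {
  expect_equal(unname(node_clustering(fixture("K3")$network)), rep(1, 3))
  expect_equal(node_clustering(fixture("P3")$network)[["b"]], 0)
  # neighbors {a,b,c} of x, one edge a-b among them: CI = 2*1/(3*2)
  net <- molecular_network(data.frame(
    source = c("x", "x", "x", "a"), target = c("a", "b", "c", "b"),
    stringsAsFactors = FALSE
  ))
  expect_equal(node_clustering(net)[["x"]], 1 / 3)
})

test_that("fixture networks reproduce their closed-form metric values", {
  for (nm in c("P3", "S4", "K3", "C4")) {
    fx <- fixture(nm)
    net <- fx$network
    ex <- fx$expected
    m <- node_metrics(net)
    rownames(m) <- m$node
    if (!is.null(ex$betweenness)) {
      expect_equal(m[names(ex$betweenness), "betweenness"], unname(ex$betweenness),
                   tolerance = 1e-12, info = nm)
    }
    if (!is.null(ex$closeness)) {
      expect_equal(m[names(ex$closeness), "closeness"], unname(ex$closeness),
                   tolerance = 1e-12, info = nm)
    }
    if (!is.null(ex$stress)) {
      expect_equal(m[names(ex$stress), "stress"], unname(ex$stress), info = nm)
    }
    if (!is.null(ex$eccentricity) && length(ex$eccentricity) > 1) {
      expect_equal(m[names(ex$eccentricity), "eccentricity"], unname(ex$eccentricity), info = nm)
    }
    if (!is.null(ex$radiality) && length(ex$radiality) > 1) {
      expect_equal(m[names(ex$radiality), "radiality"], unname(ex$radiality), info = nm)
    }
  }
})

test_that("eccentricity and radiality use the component diameter scale", {
  er <- eccentricity_radiality(fixture("K3")$network)
  expect_equal(er$eccentricity, rep(1, 3))
  expect_equal(er$radiality, rep(1, 3)) # (1 + 1 - 1)/1
  er3 <- eccentricity_radiality(fixture("P3")$network)
  rownames(er3) <- er3$node
  expect_equal(er3["a", "radiality"], 0.75) # (2 + 1 - 1.5)/2
  expect_equal(er3["b", "radiality"], 1) # (2 + 1 - 1)/2
})

test_that("neighborhood connectivity and topological coefficient match hand values", {
  p3 <- fixture("P3")$network
  nc <- neighborhood_connectivity(p3)
  expect_equal(nc[["a"]], 2)
  expect_equal(nc[["b"]], 1)
  tc <- topological_coefficient(p3)
  expect_equal(tc[["a"]], 1) # J(a,c) = 1 shared neighbor, degree 1
  expect_equal(unname(topological_coefficient(fixture("K3")$network)), rep(1, 3))
  s4 <- fixture("S4")$network
  expect_equal(topological_coefficient(s4)[["l1"]], 1)
  iso <- molecular_network(data.frame(source = "a", target = "b"), nodes = "z")
  expect_equal(neighborhood_connectivity(iso)[["z"]], 0)
})

test_that("centralities agree with the exhaustive enumeration oracle", {
  withr::local_seed(101)
  for (i in 1:30) {
    net <- random_connected_net()
    o <- oracle_metrics(net)
    apsp <- all_pairs_shortest_paths(net)
    expect_equal(apsp$dist, o$dist)
    expect_equal(apsp$sigma, o$sigma)
    expect_equal(betweenness_centrality(net, apsp), o$betweenness, tolerance = 1e-9)
    expect_equal(closeness_centrality(net, apsp), o$closeness, tolerance = 1e-9)
    expect_equal(stress_centrality(net, apsp), o$stress, tolerance = 1e-9)
  }
})

test_that("centralities cross-check against igraph on larger random graphs", {
  withr::local_seed(7)
  for (i in 1:3) {
    net <- generate_ba(60, 2, seed = i)
    g <- igraph::graph_from_data_frame(net$records[net$records$source != net$records$target,
                                                   c("source", "target")],
                                       directed = FALSE, vertices = net$nodes)
    g <- igraph::simplify(g)
    apsp <- all_pairs_shortest_paths(net)
    n <- length(net$nodes)
    raw <- betweenness_centrality(net, apsp) * (n - 1) * (n - 2) / 2
    ig_b <- igraph::betweenness(g, directed = FALSE)[net$nodes]
    expect_equal(raw, ig_b, tolerance = 1e-9)
    ig_c <- igraph::closeness(g)[net$nodes] * (n - 1)
    expect_equal(closeness_centrality(net, apsp), ig_c, tolerance = 1e-9)
    tr <- igraph::transitivity(g, type = "local", vids = net$nodes)
    names(tr) <- net$nodes
    tr[is.nan(tr)] <- 0
    expect_equal(node_clustering(net), tr, tolerance = 1e-9)
  }
})

test_that("metrics are invariant under node relabeling", {
  withr::local_seed(55)
  net <- random_connected_net()
  perm <- sample(net$nodes)
  relabel <- stats::setNames(sprintf("w%02d", seq_along(perm)), perm)
  rec2 <- net$records
  rec2$source <- unname(relabel[rec2$source])
  rec2$target <- unname(relabel[rec2$target])
  net2 <- molecular_network(rec2)
  m1 <- node_metrics(net)
  m2 <- node_metrics(net2)
  rownames(m1) <- unname(relabel[m1$node])
  rownames(m2) <- m2$node
  for (col in setdiff(names(m1), "node")) {
    expect_equal(m2[rownames(m1), col], m1[[col]], tolerance = 1e-9, info = col)
  }
})

test_that("unreachable pairs are excluded from averages, not set to infinity", {
  two <- molecular_network(data.frame(source = c("a", "x"), target = c("b", "y"),
                                      stringsAsFactors = FALSE))
  m <- node_metrics(two)
  rownames(m) <- m$node
  expect_equal(m["a", "closeness"], 1) # average within its component only
  expect_equal(m["a", "avg_shortest_path_length"], 1)
  s <- network_summary(two)
  expect_equal(s$connected_components, 2)
  expect_equal(s$diameter, 1)
})

test_that("network summary matches closed forms and its own invariants", {
  s <- network_summary(fixture("K3")$network)
  expect_equal(s$connected_components, 1)
  expect_equal(s$characteristic_path_length, 1)
  expect_equal(s$diameter, 1)
  expect_equal(s$clustering_coefficient, 1)
  expect_equal(s$avg_neighbors, 2)

  s3 <- network_summary(fixture("P3")$network)
  expect_equal(s3$characteristic_path_length, 4 / 3)
  expect_equal(s3$diameter, 2)

  expect_error(network_summary(molecular_network(
    data.frame(source = character(0), target = character(0))
  )), "empty")

  withr::local_seed(11)
  for (i in 1:10) {
    net <- random_connected_net()
    s <- network_summary(net)
    expect_lte(s$characteristic_path_length, s$diameter)
    expect_equal(s$avg_neighbors, sum(lengths(net$adj)) / length(net$nodes))
    b <- betweenness_centrality(net)
    cc <- closeness_centrality(net)
    expect_true(all(b >= 0 & b <= 1))
    expect_true(all(cc >= 0 & cc <= 1))
    deg1 <- names(node_degree(net))[node_degree(net) == 1]
    expect_true(all(b[deg1] == 0))
  }
})

test_that("clustering average convention is switchable", {
  s4 <- fixture("S4")$network # center degree 3 (CI 0), leaves degree 1
  expect_equal(network_summary(s4, "all")$clustering_coefficient, 0)
  expect_equal(network_summary(s4, "deg2plus")$clustering_coefficient, 0)
  net <- molecular_network(data.frame(
    source = c("a", "b", "c", "c"), target = c("b", "c", "a", "d"),
    stringsAsFactors = FALSE
  )) # triangle + pendant: CI = (1, 1, 1/3, 0)
  expect_equal(network_summary(net, "all")$clustering_coefficient, (1 + 1 + 1 / 3) / 4)
  expect_equal(network_summary(net, "deg2plus")$clustering_coefficient, (1 + 1 + 1 / 3) / 3)
})
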