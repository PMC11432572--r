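#' All-pairs shortest paths with path counts
#'
#' Breadth-first search from every node of the simple (undirected,
#' unweighted) graph. Distances are hop counts; `sigma[s, t]` counts the
#' distinct shortest paths between `s` and `t`. Unreachable pairs have
#' distance `Inf` and path count 0.
#'
#' @param net a `molecular_network`.
#' @return a list with `nodes`, `dist` (numeric matrix, hops) and
#'   `sigma` (numeric matrix of shortest-path counts).
#' @export
all_pairs_shortest_paths <- function(net) {
  adj <- adj_index(net)
  n <- length(adj)
  dist <- matrix(Inf, n, n, dimnames = list(net$nodes, net$nodes))
  sigma <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  for (s in seq_len(n)) {
    d <- rep(Inf, n)
    sg <- numeric(n)
    d[s] <- 0
    sg[s] <- 1
    frontier <- s
    level <- 0
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (!is.finite(d[w])) {
            d[w] <- level + 1
            nxt <- c(nxt, w)
          }
          if (d[w] == level + 1) sg[w] <- sg[w] + sg[v]
        }
      }
      frontier <- unique(nxt)
      level <- level + 1
    }
    dist[s, ] <- d
    sigma[s, ] <- sg
  }
  list(nodes = net$nodes, dist = dist, sigma = sigma)
}

#' Per-node shortest-path counts
#'
#' `sigma_st(n)`: the number of shortest s-t paths passing through `node`
#' as an interior vertex, for every pair (s, t), given a precomputed
#' [all_pairs_shortest_paths()] result.
#'
#' @param apsp an [all_pairs_shortest_paths()] result.
#' @param node node identifier.
#' @return numeric matrix (s by t) of path counts; zero where `node` is
#'   an endpoint or not interior.
#' @export
paths_through <- function(apsp, node) {
  i <- match(node, apsp$nodes)
  if (is.na(i)) stop("unknown node: ", node)
  D <- apsp$dist
  through <- outer(D[, i], D[i, ], `+`) == D
  through[!is.finite(D)] <- FALSE
  through[i, ] <- FALSE
  through[, i] <- FALSE
  diag(through) <- FALSE
  cnt <- outer(apsp$sigma[, i], apsp$sigma[i, ])
  cnt[!through] <- 0
  cnt
}

#' Clustering coefficient of every node
#'
#' `CI = 2 nI / (kI (kI - 1))` where `nI` is the number of edges among the
#' `kI` distinct neighbors of node I; nodes with fewer than two neighbors
#' get 0.
#'
#' @param net a `molecular_network`.
#' @return named numeric vector in `[0, 1]`.
#' @export
node_clustering <- function(net) {
  adj <- adj_index(net)
  out <- vapply(seq_along(adj), function(i) {
    nb <- adj[[i]]
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0L
    for (a in seq_len(k - 1)) {
      links <- links + sum(adj[[nb[a]]] %in% nb[(a + 1):k])
    }
    2 * links / (k * (k - 1))
  }, numeric(1))
  stats::setNames(out, net$nodes)
}

#' Betweenness centrality, normalized per connected component
#'
#' `Cb(n) = sum over pairs s<t (s,t != n) of sigma_st(n) / sigma_st`,
#' divided by the number of node pairs excluding n, `(N-1)(N-2)/2`, where
#' `N` is the size of n's connected component. Values lie in `[0, 1]`;
#' computed on the simple graph (duplicate records and self-loops never
#' contribute).
#'
#' @param net a `molecular_network`.
#' @param apsp optional precomputed [all_pairs_shortest_paths()] result.
#' @return named numeric vector.
#' @export
betweenness_centrality <- function(net, apsp = all_pairs_shortest_paths(net)) {
  comp <- components_of(net)
  csize <- table(comp)
  n <- length(net$nodes)
  S <- apsp$sigma
  out <- numeric(n)
  for (i in seq_len(n)) {
    cnt <- paths_through(apsp, net$nodes[i])
    frac <- cnt / S
    frac[cnt == 0] <- 0
    raw <- sum(frac[upper.tri(frac)])
    N <- csize[[as.character(comp[i])]]
    norm <- (N - 1) * (N - 2) / 2
    out[i] <- if (norm > 0) raw / norm else 0
  }
  stats::setNames(out, net$nodes)
}

#' Closeness centrality
#'
#' `Cc(n) = 1 / avg(L(n, m))`, the inverse of the mean shortest-path length
#' from n to the nodes reachable from it; isolated nodes get 0.
#'
#' @inheritParams betweenness_centrality
#' @return named numeric vector in `[0, 1]`.
#' @export
closeness_centrality <- function(net, apsp = all_pairs_shortest_paths(net)) {
  avg <- avg_path_length_per_node(apsp)
  stats::setNames(ifelse(avg > 0, 1 / avg, 0), net$nodes)
}

# mean distance to reachable nodes; 0 for isolated nodes
avg_path_length_per_node <- function(apsp) {
  D <- apsp$dist
  vapply(seq_len(nrow(D)), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (length(d)) mean(d) else 0
  }, numeric(1))
}

#' Stress centrality
#'
#' The number of shortest paths, over all unordered pairs `s < t` with
#' `s != n != t`, on which node n lies as an interior vertex (raw counts,
#' not fractions).
#'
#' @inheritParams betweenness_centrality
#' @return named numeric vector of non-negative integers.
#' @export
stress_centrality <- function(net, apsp = all_pairs_shortest_paths(net)) {
  out <- vapply(net$nodes, function(v) {
    cnt <- paths_through(apsp, v)
    sum(cnt[upper.tri(cnt)])
  }, numeric(1))
  stats::setNames(out, net$nodes)
}

#' Eccentricity and radiality
#'
#' Eccentricity is the maximum hop distance to a reachable node. Radiality
#' is `(D + 1 - avg(L(n, m))) / D` with `D` the diameter of n's connected
#' component; nodes in singleton components get 0 for both.
#'
#' @inheritParams betweenness_centrality
#' @return data.frame with columns `node`, `eccentricity`, `radiality`.
#' @export
eccentricity_radiality <- function(net, apsp = all_pairs_shortest_paths(net)) {
  comp <- components_of(net)
  D <- apsp$dist
  n <- length(net$nodes)
  # component diameters
  cdiam <- vapply(sort(unique(comp)), function(cc) {
    idx <- which(comp == cc)
    d <- D[idx, idx, drop = FALSE]
    d <- d[is.finite(d)]
    if (length(d)) max(d) else 0
  }, numeric(1))
  names(cdiam) <- sort(unique(comp))
  avg <- avg_path_length_per_node(apsp)
  ecc <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (length(d)) max(d) else 0
  }, numeric(1))
  rad <- vapply(seq_len(n), function(i) {
    dd <- cdiam[[as.character(comp[i])]]
    if (dd > 0) (dd + 1 - avg[i]) / dd else 0
  }, numeric(1))
  data.frame(node = net$nodes, eccentricity = ecc, radiality = rad,
             stringsAsFactors = FALSE)
}

#' Neighborhood connectivity
#'
#' Mean degree of a node's distinct neighbors; 0 for isolated nodes.
#'
#' @param net a `molecular_network`.
#' @return named numeric vector.
#' @export
neighborhood_connectivity <- function(net) {
  deg <- node_degree(net)
  out <- vapply(net$nodes, function(v) {
    nb <- net$adj[[v]]
    if (length(nb)) mean(deg[nb]) else 0
  }, numeric(1))
  stats::setNames(out, net$nodes)
}

#' Topological coefficient
#'
#' For node n, let M be the nodes (other than n) sharing at least one
#' neighbor with n, and `J(n, m)` the number of shared neighbors plus one
#' if n and m are directly linked. `T(n) = mean(J(n, m)) / degree(n)`;
#' nodes with no such partner get 0.
#'
#' @param net a `molecular_network`.
#' @return named numeric vector in `[0, 1]`.
#' @export
topological_coefficient <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  for (i in seq_len(n)) A[i, net$adj[[i]]] <- 1
  shared <- A %*% A # shared[i, m] = number of common neighbors
  out <- vapply(seq_len(n), function(i) {
    k <- sum(A[i, ])
    if (k < 1) return(0)
    partners <- which(shared[i, ] > 0)
    partners <- partners[partners != i]
    if (!length(partners)) return(0)
    mean(shared[i, partners] + A[i, partners]) / k
  }, numeric(1))
  stats::setNames(out, net$nodes)
}

#' The full node-level metric table
#'
#' One row per node with the ten standard topological parameters used to
#' profile molecular interaction networks.
#'
#' @inheritParams betweenness_centrality
#' @return data.frame with columns `node`, `degree`,
#'   `clustering_coefficient`, `betweenness`, `closeness`,
#'   `avg_shortest_path_length`, `eccentricity`, `radiality`, `stress`,
#'   `neighborhood_connectivity`, `topological_coefficient`.
#' @export
node_metrics <- function(net, apsp = all_pairs_shortest_paths(net)) {
  er <- eccentricity_radiality(net, apsp)
  data.frame(
    node = net$nodes,
    degree = as.numeric(node_degree(net)),
    clustering_coefficient = as.numeric(node_clustering(net)),
    betweenness = as.numeric(betweenness_centrality(net, apsp)),
    closeness = as.numeric(closeness_centrality(net, apsp)),
    avg_shortest_path_length = avg_path_length_per_node(apsp),
    eccentricity = er$eccentricity,
    radiality = er$radiality,
    stress = as.numeric(stress_centrality(net, apsp)),
    neighborhood_connectivity = as.numeric(neighborhood_connectivity(net)),
    topological_coefficient = as.numeric(topological_coefficient(net)),
    stringsAsFactors = FALSE
  )
}

#' Network-level summary statistics
#'
#' Connected components, node and record counts, average number of distinct
#' neighbors, network clustering coefficient (mean node clustering
#' coefficient), diameter and characteristic path length (maximum and mean
#' shortest-path distance over unordered connected node pairs).
#'
#' @param net a `molecular_network`.
#' @param clustering_nodes `"all"` averages the clustering coefficient over
#'   every node (degree < 2 contributing 0); `"deg2plus"` averages only
#'   over nodes with at least two neighbors.
#' @param apsp optional precomputed [all_pairs_shortest_paths()] result.
#' @return an object of class `network_summary`.
#' @export
network_summary <- function(net, clustering_nodes = c("all", "deg2plus"),
                            apsp = all_pairs_shortest_paths(net)) {
  clustering_nodes <- match.arg(clustering_nodes)
  if (length(net$nodes) == 0) stop("empty network")
  comp <- components_of(net)
  deg <- node_degree(net)
  ci <- node_clustering(net)
  cc_net <- if (clustering_nodes == "all") mean(ci) else {
    keep <- deg >= 2
    if (any(keep)) mean(ci[keep]) else 0
  }
  D <- apsp$dist
  up <- D[upper.tri(D)]
  up <- up[is.finite(up)]
  structure(
    list(
      connected_components = length(unique(comp)),
      num_nodes = length(net$nodes),
      num_edge_records = nrow(net$records),
      avg_neighbors = mean(deg),
      clustering_coefficient = cc_net,
      diameter = if (length(up)) max(up) else 0,
      characteristic_path_length = if (length(up)) mean(up) else 0,
      clustering_nodes = clustering_nodes
    ),
    class = "network_summary"
  )
}

#' @export
print.network_summary <- function(x, ...) {
  df <- summary_table(x)
  cat(paste(format(df$Parameter, width = 28), df$Value, collapse = "\n"), "\n")
  invisible(x)
}

#' Summary as a two-column parameter table
#'
#' @param x a `network_summary`.
#' @return data.frame with columns `Parameter` and `Value`, using the
#'   conventional NetworkAnalyzer-style parameter names.
#' @export
summary_table <- function(x) {
  stopifnot(inherits(x, "network_summary"))
  data.frame(
    Parameter = c("Connected components", "Number of nodes", "Number of edges",
                  "Averaged number of neighbors", "Clustering coefficient",
                  "Network diameter", "Characteristic path length"),
    Value = c(x$connected_components, x$num_nodes, x$num_edge_records,
              round(x$avg_neighbors, 3), round(x$clustering_coefficient, 3),
              x$diameter, round(x$characteristic_path_length, 3)),
    stringsAsFactors = FALSE
  )
}
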