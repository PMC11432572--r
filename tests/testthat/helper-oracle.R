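# Independent brute-force oracle: enumerates every simple path between each
# node pair by depth-first search and keeps the shortest ones. Deliberately
# shares no code with the package's BFS/accumulation implementation.

oracle_shortest_paths <- function(adj, s, t) {
  paths <- list()
  dfs <- function(v, visited) {
    if (v == t) {
      paths[[length(paths) + 1]] <<- visited
      return(invisible(NULL))
    }
    for (w in adj[[v]]) {
      if (!(w %in% visited)) dfs(w, c(visited, w))
    }
  }
  dfs(s, s)
  if (!length(paths)) return(list())
  len <- vapply(paths, length, integer(1))
  paths[len == min(len)]
}

# Full oracle metric set from exhaustive enumeration: distances, path
# counts, raw/normalized betweenness, closeness, stress.
oracle_metrics <- function(net) {
  nodes <- net$nodes
  n <- length(nodes)
  dist <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(dist) <- 0
  sigma <- matrix(0, n, n, dimnames = list(nodes, nodes))
  diag(sigma) <- 1
  raw_b <- stats::setNames(numeric(n), nodes)
  stress <- stats::setNames(numeric(n), nodes)
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        sp <- oracle_shortest_paths(net$adj, nodes[i], nodes[j])
        if (!length(sp)) next
        d <- length(sp[[1]]) - 1
        dist[i, j] <- dist[j, i] <- d
        sigma[i, j] <- sigma[j, i] <- length(sp)
        interior <- unlist(lapply(sp, function(p) p[-c(1, length(p))]))
        if (length(interior)) {
          cnt <- table(interior)
          raw_b[names(cnt)] <- raw_b[names(cnt)] + as.numeric(cnt) / length(sp)
          stress[names(cnt)] <- stress[names(cnt)] + as.numeric(cnt)
        }
      }
    }
  }
  # component sizes from reachability, for the betweenness normalizer
  csize <- vapply(seq_len(n), function(i) sum(is.finite(dist[i, ])), numeric(1))
  bet <- vapply(seq_len(n), function(i) {
    norm <- (csize[i] - 1) * (csize[i] - 2) / 2
    if (norm > 0) raw_b[i] / norm else 0
  }, numeric(1))
  clo <- vapply(seq_len(n), function(i) {
    d <- dist[i, -i]
    d <- d[is.finite(d)]
    if (length(d)) 1 / mean(d) else 0
  }, numeric(1))
  list(dist = dist, sigma = sigma,
       betweenness = stats::setNames(bet, nodes),
       closeness = stats::setNames(clo, nodes),
       stress = stress)
}

# Seeded random connected graph on <= max_n nodes (connectivity checked
# via igraph, independent of the package's traversal code).
random_connected_net <- function(max_n = 8, p = 0.4) {
  repeat {
    n <- sample(4:max_n, 1)
    ids <- sprintf("v%02d", seq_len(n))
    pairs <- t(utils::combn(ids, 2))
    keep <- stats::runif(nrow(pairs)) < p
    if (sum(keep) < n - 1) next
    el <- pairs[keep, , drop = FALSE]
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    if (igraph::vcount(g) == n && igraph::is_connected(g)) {
      return(molecular_network(
        data.frame(source = el[, 1], target = el[, 2], stringsAsFactors = FALSE)
      ))
    }
  }
}

# Random labeled tree on n nodes (each node attaches to a uniform earlier
# node) -- shortest-path trees on trees are unique, so the bottleneck
# oracle below is tie-break independent.
random_tree_net <- function(n) {
  ids <- sprintf("t%02d", sample(seq_len(n)))
  src <- ids[-1]
  tgt <- vapply(2:n, function(i) ids[sample(i - 1, 1)], character(1))
  molecular_network(data.frame(source = src, target = tgt, stringsAsFactors = FALSE))
}

# Bottleneck oracle for acyclic graphs: the unique s->t paths come from
# exhaustive enumeration; ps(v) = 1 iff the number of root-to-target paths
# containing v (v != root) exceeds |V|/4.
oracle_bottleneck_tree <- function(net, count_target = TRUE) {
  nodes <- net$nodes
  bn <- stats::setNames(rep(0L, length(nodes)), nodes)
  for (s in nodes) {
    cnt <- stats::setNames(rep(0L, length(nodes)), nodes)
    for (t in setdiff(nodes, s)) {
      sp <- oracle_shortest_paths(net$adj, s, t)
      stopifnot(length(sp) == 1) # tree: unique path
      members <- setdiff(sp[[1]], s)
      if (!count_target) members <- setdiff(members, t)
      cnt[members] <- cnt[members] + 1L
    }
    hit <- cnt > length(nodes) / 4
    hit[s] <- FALSE
    bn[hit] <- bn[hit] + 1L
  }
  bn
}
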