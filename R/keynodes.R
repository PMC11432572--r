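#' Identify hub nodes
#'
#' Hubs are the hyper-connected nodes: those whose degree ND satisfies
#' `ND > mu + sigma`, where `mu` is the mean node degree and `sigma` its
#' standard deviation. The inequality is strict, so a network in which all
#' degrees are equal (sigma = 0) has no hubs.
#'
#' @param net a `molecular_network`.
#' @param sd `"sample"` (n-1 denominator, default) or `"population"`
#'   (n denominator); the convention used is recorded in the report.
#' @return an object of class `hub_report` with fields `mu`, `sigma`,
#'   `threshold`, `sd_type` and `hubs` (data.frame node/degree, sorted by
#'   descending degree).
#' @export
find_hubs <- function(net, sd = c("sample", "population")) {
  sd <- match.arg(sd)
  deg <- node_degree(net)
  if (length(deg) < 2) stop("hub identification needs at least 2 nodes")
  mu <- mean(deg)
  sigma <- if (sd == "sample") stats::sd(deg) else sqrt(mean((deg - mu)^2))
  threshold <- mu + sigma
  hub_nodes <- names(deg)[deg > threshold]
  hubs <- data.frame(node = hub_nodes, degree = as.integer(deg[hub_nodes]),
                     stringsAsFactors = FALSE)
  hubs <- hubs[order(-hubs$degree, hubs$node), , drop = FALSE]
  rownames(hubs) <- NULL
  structure(
    list(mu = mu, sigma = sigma, threshold = threshold, sd_type = sd, hubs = hubs),
    class = "hub_report"
  )
}

#' @export
print.hub_report <- function(x, ...) {
  cat(sprintf("hub report: ND > mu + sigma = %.3f + %.3f = %.3f (%s sd)\n",
              x$mu, x$sigma, x$threshold, x$sd_type))
  if (nrow(x$hubs)) {
    for (i in seq_len(nrow(x$hubs))) {
      cat(sprintf("  %s (ND = %d)\n", x$hubs$node[i], x$hubs$degree[i]))
    }
  } else {
    cat("  no hubs\n")
  }
  invisible(x)
}

#' Shortest-path tree rooted at a node
#'
#' Breadth-first tree over the root's connected component. BFS trees are
#' not unique; for reproducibility each non-root node's parent is its
#' lexicographically smallest neighbor at the previous level.
#'
#' @param net a `molecular_network`.
#' @param root root node identifier.
#' @return a list with `root`, `nodes` (BFS order) and `parent` (named
#'   character vector; `NA` for the root).
#' @export
shortest_path_tree <- function(net, root) {
  if (!root %in% net$nodes) stop("unknown root node: ", root)
  dist <- stats::setNames(rep(NA_integer_, length(net$nodes)), net$nodes)
  dist[root] <- 0L
  frontier <- root
  order_visited <- root
  parent <- stats::setNames(rep(NA_character_, length(net$nodes)), net$nodes)
  level <- 0L
  while (length(frontier)) {
    frontier <- sort(frontier)
    nxt <- character(0)
    for (v in frontier) {
      for (w in net$adj[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- level + 1L
          parent[w] <- v # first discoverer wins; frontier sorted => smallest id
          nxt <- c(nxt, w)
        }
      }
    }
    nxt <- unique(nxt)
    order_visited <- c(order_visited, sort(nxt))
    frontier <- nxt
    level <- level + 1L
  }
  in_tree <- order_visited
  list(root = root, nodes = in_tree, parent = parent[in_tree])
}

# number of tree nodes in the subtree rooted at each node (including itself)
subtree_sizes <- function(tree) {
  size <- stats::setNames(rep(1L, length(tree$nodes)), tree$nodes)
  for (v in rev(tree$nodes)) {
    p <- tree$parent[[v]]
    if (!is.na(p)) size[p] <- size[p] + size[v]
  }
  size
}

#' Bottleneck scores
#'
#' For each root `s`, build the shortest-path tree `Ts` and count, for
#' every other node `v`, the root-to-target paths of `Ts` that contain `v`
#' (with `v` allowed to be the target itself, never the root). In a tree
#' this count is the size of `v`'s subtree. Set `ps(v) = 1` when the count
#' exceeds `|V(Ts)| / 4`, else 0, and score `BN(v) = sum over roots s of
#' ps(v)`. High-BN nodes control the flow of information through the
#' network.
#'
#' @param net a `molecular_network`.
#' @param count_target when `TRUE` (default) a path "meets" its own
#'   endpoint, so the count for `v` is its full subtree size; when `FALSE`
#'   only strictly interior memberships count (subtree size minus one).
#' @return an object of class `bottleneck_report`: data.frame `scores`
#'   with columns `node`, `bn`, `rank` (descending BN, ties by node id),
#'   plus the recorded tree policy.
#' @export
bottleneck_scores <- function(net, count_target = TRUE) {
  bn <- stats::setNames(rep(0L, length(net$nodes)), net$nodes)
  for (s in net$nodes) {
    tree <- shortest_path_tree(net, s)
    if (length(tree$nodes) < 2) next
    size <- subtree_sizes(tree)
    cutoff <- length(tree$nodes) / 4
    for (v in tree$nodes) {
      if (v == s) next
      cnt <- if (count_target) size[[v]] else size[[v]] - 1L
      if (cnt > cutoff) bn[v] <- bn[v] + 1L
    }
  }
  scores <- data.frame(node = names(bn), bn = as.integer(bn), stringsAsFactors = FALSE)
  scores <- scores[order(-scores$bn, scores$node), , drop = FALSE]
  scores$rank <- seq_len(nrow(scores))
  rownames(scores) <- NULL
  structure(
    list(scores = scores, count_target = count_target,
         tie_break = "parent = smallest-identifier neighbor at previous level"),
    class = "bottleneck_report"
  )
}

#' @export
print.bottleneck_report <- function(x, ...) {
  cat("bottleneck report (", x$tie_break, ")\n", sep = "")
  top <- utils::head(x$scores, 10)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %2d. %s  BN = %d\n", top$rank[i], top$node[i], top$bn[i]))
  }
  invisible(x)
}
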