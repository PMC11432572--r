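#' Construct a molecular interaction network
#'
#' A `molecular_network` is an undirected graph over molecule identifiers.
#' The original interaction records are preserved verbatim (including
#' duplicate edges and self-loops), while a derived *simple* adjacency --
#' self-loops dropped, duplicates collapsed -- backs every topological
#' computation. This mirrors curated-database practice: the record list is
#' the evidence trail, the simple graph is the analysis object.
#'
#' @param records a data.frame with at least columns `source` and `target`
#'   (character); optional `interaction_type` and `provenance` columns are
#'   carried along.
#' @param nodes optional character vector of declared node identifiers;
#'   identifiers appearing only here become isolated nodes.
#' @param labels optional named character vector mapping node identifiers to
#'   a compartment, one of `"glycemic_control"`, `"fertility"`,
#'   `"immunity"`; unlisted nodes are `"unlabeled"`.
#' @return an object of class `molecular_network` with fields `nodes`,
#'   `compartment`, `records` and `adj` (named list of neighbor sets).
#' @export
molecular_network <- function(records, nodes = NULL, labels = NULL) {
  stopifnot(is.data.frame(records))
  if (!all(c("source", "target") %in% names(records))) {
    stop("records must have 'source' and 'target' columns")
  }
  records$source <- trimws(as.character(records$source))
  records$target <- trimws(as.character(records$target))
  if (nrow(records) > 0 && any(!nzchar(records$source) | !nzchar(records$target))) {
    stop("empty source or target identifier in interaction records")
  }
  if (is.null(records$interaction_type)) records$interaction_type <- rep(NA_character_, nrow(records))
  if (is.null(records$provenance)) records$provenance <- rep(NA_character_, nrow(records))
  records <- records[, c("source", "target", "interaction_type", "provenance")]
  rownames(records) <- NULL

  node_set <- unique(c(records$source, records$target, trimws(as.character(nodes))))
  node_set <- node_set[nzchar(node_set)]

  adj <- stats::setNames(rep(list(character(0)), length(node_set)), node_set)
  keep <- records$source != records$target
  if (any(keep)) {
    pairs <- unique(data.frame(
      a = pmin(records$source[keep], records$target[keep]),
      b = pmax(records$source[keep], records$target[keep]),
      stringsAsFactors = FALSE
    ))
    for (i in seq_len(nrow(pairs))) {
      adj[[pairs$a[i]]] <- c(adj[[pairs$a[i]]], pairs$b[i])
      adj[[pairs$b[i]]] <- c(adj[[pairs$b[i]]], pairs$a[i])
    }
  }
  adj <- lapply(adj, function(x) sort(unique(x)))

  compartment <- stats::setNames(rep("unlabeled", length(node_set)), node_set)
  if (!is.null(labels)) {
    labels <- labels[names(labels) %in% node_set]
    bad <- setdiff(unique(labels), c("glycemic_control", "fertility", "immunity", "unlabeled"))
    if (length(bad)) stop("unknown compartment label(s): ", paste(bad, collapse = ", "))
    compartment[names(labels)] <- labels
  }

  structure(
    list(nodes = node_set, compartment = compartment, records = records, adj = adj),
    class = "molecular_network"
  )
}

#' @export
print.molecular_network <- function(x, ...) {
  npairs <- sum(lengths(x$adj)) / 2
  cat(sprintf(
    "molecular_network: %d nodes, %d interaction records (%d distinct neighbor pairs)\n",
    length(x$nodes), nrow(x$records), npairs
  ))
  lab <- table(x$compartment)
  if (length(lab) > 1 || names(lab)[1] != "unlabeled") {
    cat("compartments:", paste(sprintf("%s=%d", names(lab), lab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Build a network from a curated database
#'
#' @param db a `curated_database` as returned by [read_database()].
#' @param labels optional named character vector of compartment labels
#'   (see [molecular_network()]).
#' @return a `molecular_network`; the record list is preserved verbatim.
#' @export
build_network <- function(db, labels = NULL) {
  stopifnot(inherits(db, "curated_database"))
  if (nrow(db$interactions) < 1) stop("curated database has no interactions")
  molecular_network(db$interactions, labels = labels)
}

# number of distinct (unordered, non-loop) neighbor pairs
n_simple_edges <- function(net) sum(lengths(net$adj)) / 2

#' Degrees of all nodes
#'
#' Degree counts *distinct* neighbors: duplicate records and self-loops do
#' not inflate it.
#'
#' @param net a `molecular_network`.
#' @return named integer vector.
#' @export
node_degree <- function(net) {
  stats::setNames(lengths(net$adj), net$nodes)
}

# internal: integer-indexed adjacency for fast traversal
adj_index <- function(net) {
  idx <- stats::setNames(seq_along(net$nodes), net$nodes)
  lapply(net$adj, function(nb) unname(idx[nb]))
}

# internal: connected component membership (1-based component ids)
components_of <- function(net) {
  adj <- adj_index(net)
  n <- length(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (w in adj[[v]]) {
        if (comp[w] == 0L) {
          comp[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  stats::setNames(comp, net$nodes)
}

# internal: convert to an igraph object on the simple graph (plumbing only)
as_igraph_simple <- function(net) {
  n <- length(net$nodes)
  idx <- stats::setNames(seq_len(n), net$nodes)
  el <- matrix(integer(0), ncol = 2)
  if (n > 0) {
    pairs <- do.call(rbind, lapply(seq_len(n), function(i) {
      nb <- unname(idx[net$adj[[i]]])
      nb <- nb[nb > i]
      if (length(nb)) cbind(i, nb) else NULL
    }))
    if (!is.null(pairs)) el <- pairs
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, t(el))
  igraph::V(g)$name <- net$nodes
  igraph::V(g)$compartment <- unname(net$compartment[net$nodes])
  g
}
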