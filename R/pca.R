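# Fixed column order of the ten node-level parameters used for PCA.
PCA_FEATURES <- c(
  "avg_shortest_path_length", "betweenness", "closeness",
  "clustering_coefficient", "degree", "eccentricity",
  "neighborhood_connectivity", "radiality", "stress",
  "topological_coefficient"
)

#' Build the node-by-metric feature matrix
#'
#' One row per node of the largest connected component, ten columns in a
#' fixed order (average shortest path length, betweenness, closeness,
#' clustering coefficient, degree, eccentricity, neighborhood connectivity,
#' radiality, stress, topological coefficient). Constant columns are kept
#' but flagged, since they are degenerate under standardization.
#'
#' @param net a `molecular_network`.
#' @param metrics optional precomputed [node_metrics()] table.
#' @return an object of class `feature_matrix`: numeric matrix `x`
#'   (rownames = node ids), `constant` (logical per column), and
#'   `dropped_nodes` (nodes outside the largest component).
#' @export
build_feature_matrix <- function(net, metrics = node_metrics(net)) {
  comp <- components_of(net)
  csize <- table(comp)
  main <- as.integer(names(csize)[which.max(csize)])
  keep_nodes <- names(comp)[comp == main]
  dropped <- setdiff(net$nodes, keep_nodes)
  if (length(dropped)) {
    message("feature matrix: using largest component only (",
            length(dropped), " node(s) dropped)")
  }
  m <- metrics[match(keep_nodes, metrics$node), , drop = FALSE]
  x <- as.matrix(m[, PCA_FEATURES])
  rownames(x) <- keep_nodes
  constant <- apply(x, 2, function(col) stats::var(col) == 0)
  structure(
    list(x = x, constant = constant, dropped_nodes = dropped),
    class = "feature_matrix"
  )
}

#' Principal component analysis of the node metrics
#'
#' Eigendecomposition of the correlation matrix (default) or covariance
#' matrix of the feature columns. Constant columns are dropped from the
#' decomposition and reported. Signs follow a deterministic convention:
#' within each component, the loading with the largest magnitude is made
#' positive. Explained-variance fractions are eigenvalue shares and sum
#' to 1.
#'
#' @param fm a `feature_matrix` from [build_feature_matrix()].
#' @param standardize when `TRUE` (default) columns are centered and
#'   scaled (correlation-matrix PCA); when `FALSE` only centered
#'   (covariance-matrix PCA).
#' @return an object of class `pca_result` with `loadings`
#'   (metric x component), `scores` (node x component),
#'   `explained` (variance fractions), `standardize`, `dropped_columns`.
#' @export
run_pca <- function(fm, standardize = TRUE) {
  stopifnot(inherits(fm, "feature_matrix"))
  x <- fm$x
  if (nrow(x) < 3) stop("PCA needs at least 3 rows")
  keep <- !fm$constant
  if (sum(keep) < 2) stop("PCA needs at least 2 non-constant columns")
  x <- x[, keep, drop = FALSE]
  xc <- scale(x, center = TRUE, scale = standardize)
  cmat <- if (standardize) stats::cor(x) else stats::cov(x)
  eig <- eigen(cmat, symmetric = TRUE)
  loadings <- eig$vectors
  # deterministic sign: largest-magnitude loading positive in each component
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) loadings[, j] <- -loadings[, j]
  }
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(ncol(loadings))))
  scores <- xc %*% loadings
  explained <- eig$values / sum(eig$values)
  structure(
    list(
      loadings = loadings,
      scores = scores,
      explained = explained,
      standardize = standardize,
      dropped_columns = names(fm$constant)[fm$constant]
    ),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA (%s matrix): %d nodes x %d metrics\n",
              if (x$standardize) "correlation" else "covariance",
              nrow(x$scores), nrow(x$loadings)))
  ev <- utils::head(x$explained, 4)
  cat("  explained variance:",
      paste(sprintf("PC%d %.1f%%", seq_along(ev), 100 * ev), collapse = ", "), "\n")
  if (length(x$dropped_columns)) {
    cat("  constant columns dropped:", paste(x$dropped_columns, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Flag PCA outlier nodes by confidence ellipse
#'
#' A node is an outlier when its (PC1, PC2) score lies outside the
#' chi-square confidence ellipse of the 2-D score covariance -- the
#' bivariate-normal region expected to contain `confidence` of the nodes.
#' Nodes outside the ellipse are the ones a score plot would show
#' separated from the central cloud.
#'
#' @param result a `pca_result`.
#' @param confidence ellipse coverage, default 0.95.
#' @return named logical vector, `TRUE` for outliers.
#' @export
flag_outliers <- function(result, confidence = 0.95) {
  stopifnot(inherits(result, "pca_result"))
  stopifnot(confidence > 0, confidence < 1)
  sc <- result$scores[, 1:2, drop = FALSE]
  S <- stats::cov(sc)
  flags <- stats::setNames(rep(FALSE, nrow(sc)), rownames(sc))
  if (any(!is.finite(S)) || det(S) <= .Machine$double.eps) {
    return(flags) # degenerate cloud (e.g., identical scores): nothing is outside
  }
  ctr <- colMeans(sc)
  md2 <- stats::mahalanobis(sc, ctr, S)
  flags[md2 > stats::qchisq(confidence, df = 2)] <- TRUE
  flags
}
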