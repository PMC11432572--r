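#' Degree distribution
#'
#' Counts `N(k)`, the number of nodes with `k` distinct neighbors, for each
#' occurring degree `k >= 1`. Zero-degree nodes are excluded (they carry no
#' information about attachment structure and would break the log-log fit).
#'
#' @param net a `molecular_network`.
#' @return an object of class `degree_distribution`: a data.frame with
#'   strictly increasing `k` and positive integer `count`.
#' @export
degree_distribution <- function(net) {
  deg <- node_degree(net)
  deg <- deg[deg >= 1]
  tab <- table(deg)
  out <- data.frame(k = as.integer(names(tab)), count = as.integer(tab))
  out <- out[order(out$k), ]
  rownames(out) <- NULL
  class(out) <- c("degree_distribution", "data.frame")
  out
}

# build a degree_distribution from raw (k, count) pairs
as_degree_distribution <- function(k, count) {
  out <- data.frame(k = k, count = count)
  out <- out[order(out$k), ]
  rownames(out) <- NULL
  class(out) <- c("degree_distribution", "data.frame")
  out
}

#' Fit a power law to a degree distribution
#'
#' Ordinary least squares of `log10 N(k)` on `log10 k`, the straight-line
#' fit on doubly logarithmic axes: `N(k) = a * k^gamma` with
#' `a = 10^intercept` and `gamma` the slope. The Pearson correlation `r`
#' and the coefficient of determination `R^2 = r^2` are reported on the
#' logged data. Raw counts are used directly (no probabilities, no
#' log-binning); degrees with zero count simply do not appear.
#'
#' @param dist a `degree_distribution`.
#' @return an object of class `power_law_fit` with fields `a`, `gamma`,
#'   `pearson_r`, `r_squared`, `n_points`.
#' @export
fit_power_law <- function(dist) {
  stopifnot(inherits(dist, "degree_distribution") || is.data.frame(dist))
  d <- dist[dist$count > 0, , drop = FALSE]
  if (length(unique(d$k)) < 2) {
    stop("power-law fit needs at least 2 distinct degrees with positive counts")
  }
  x <- log10(d$k)
  y <- log10(d$count)
  fit <- stats::lm(y ~ x)
  # constant counts: slope 0, no linear association (cor undefined)
  r <- if (stats::var(y) == 0) 0 else stats::cor(x, y)
  structure(
    list(
      a = 10^unname(stats::coef(fit)[1]),
      gamma = unname(stats::coef(fit)[2]),
      pearson_r = r,
      r_squared = r^2,
      n_points = nrow(d)
    ),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power-law fit: N(k) = %.4g * k^%.4g  (r = %.4f, R^2 = %.4f, %d support points)\n",
              x$a, x$gamma, x$pearson_r, x$r_squared, x$n_points))
  invisible(x)
}

#' Degree-clustering independence check
#'
#' `R^2` of the ordinary least-squares regression of the clustering
#' coefficient on the degree, over all nodes with degree >= 1, on
#' untransformed values. A value near zero means clustering is independent
#' of degree -- one of the conditions for a Barabasi-Albert scale-free
#' topology.
#'
#' @param metrics a node-metric table from [node_metrics()] (needs columns
#'   `degree` and `clustering_coefficient`).
#' @return a single `R^2` value in `[0, 1]`.
#' @export
degree_clustering_correlation <- function(metrics) {
  d <- metrics[metrics$degree >= 1, , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 nodes with degree >= 1")
  if (stats::var(d$clustering_coefficient) == 0 || stats::var(d$degree) == 0) return(0)
  stats::cor(d$degree, d$clustering_coefficient)^2
}

#' Scale-free classification
#'
#' A network is called Barabasi-Albert scale-free when (1) its degree
#' distribution is well described by a power law (log-log fit `R^2` at or
#' above `fit_threshold`), (2) the clustering coefficient is uncorrelated
#' with degree (`R^2` at or below `independence_threshold`), and (3) hubs
#' exist (hyper-connected nodes with degree above the mean plus one
#' standard deviation). All inputs and thresholds are echoed in the result
#' so the verdict is a pure function of what is recorded.
#'
#' @param net a `molecular_network`.
#' @param metrics optional precomputed [node_metrics()] table (only the
#'   `degree` and `clustering_coefficient` columns are used; they are
#'   recomputed cheaply when absent).
#' @param fit_threshold minimum power-law fit `R^2` (default 0.6).
#' @param independence_threshold maximum degree-clustering `R^2`
#'   (default 0.1).
#' @param sd hub rule standard-deviation convention, see [find_hubs()].
#' @return an object of class `scale_free_assessment`.
#' @export
classify_scale_free <- function(net, metrics = NULL,
                                fit_threshold = 0.6,
                                independence_threshold = 0.1,
                                sd = c("sample", "population")) {
  sd <- match.arg(sd)
  if (is.null(metrics)) {
    metrics <- data.frame(
      node = net$nodes,
      degree = as.numeric(node_degree(net)),
      clustering_coefficient = as.numeric(node_clustering(net)),
      stringsAsFactors = FALSE
    )
  }
  dist <- degree_distribution(net)
  fit <- tryCatch(fit_power_law(dist), error = function(e) NULL)
  dc_r2 <- tryCatch(degree_clustering_correlation(metrics), error = function(e) NA_real_)
  hubs <- find_hubs(net, sd = sd)
  has_hubs <- nrow(hubs$hubs) > 0
  fit_ok <- !is.null(fit) && fit$r_squared >= fit_threshold
  indep_ok <- !is.na(dc_r2) && dc_r2 <= independence_threshold
  structure(
    list(
      fit = fit,
      degree_clustering_r_squared = dc_r2,
      has_hubs = has_hubs,
      hub_report = hubs,
      fit_threshold = fit_threshold,
      independence_threshold = independence_threshold,
      verdict = isTRUE(fit_ok && indep_ok && has_hubs)
    ),
    class = "scale_free_assessment"
  )
}

#' @export
print.scale_free_assessment <- function(x, ...) {
  cat("scale-free assessment\n")
  if (!is.null(x$fit)) {
    cat(sprintf("  power-law fit R^2     : %.4f (threshold >= %.2f)\n",
                x$fit$r_squared, x$fit_threshold))
  } else {
    cat("  power-law fit         : degenerate (too few support points)\n")
  }
  cat(sprintf("  degree~clustering R^2 : %.4f (threshold <= %.2f)\n",
              x$degree_clustering_r_squared, x$independence_threshold))
  cat(sprintf("  hubs present          : %s (%d)\n", x$has_hubs, nrow(x$hub_report$hubs)))
  cat(sprintf("  verdict               : %s\n",
              if (x$verdict) "Barabasi-Albert scale-free" else "not scale-free"))
  invisible(x)
}
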