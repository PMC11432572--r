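#' Run the full network-analysis pipeline
#'
#' Orchestrates the complete workflow: ingest (or generate) a network,
#' export it, compute the node-metric table and network summary, classify
#' the topology as scale-free or not, identify hubs and bottlenecks, run
#' the PCA outlier analysis, and write every result as plain CSV plus a
#' human-readable summary. All conventions and thresholds are surfaced as
#' arguments and the resolved configuration is written beside the outputs,
#' so a run is reproducible from its own output directory.
#'
#' @param input path to a network file (workbook, CSV/TSV edge list, or
#'   SIF), or `NULL` to use `generator`.
#' @param dialect input format hint, see [read_database()].
#' @param generator `NULL`, `"afirnet_like"`, or `"ba"` -- used when
#'   `input` is `NULL`.
#' @param n,m Barabasi-Albert generator parameters (when
#'   `generator = "ba"`).
#' @param seed integer seed for generators.
#' @param labels optional named character vector of compartment labels.
#' @param out_dir output directory (created if missing).
#' @param clustering_nodes network clustering convention, see
#'   [network_summary()].
#' @param sd hub-rule standard-deviation convention, see [find_hubs()].
#' @param count_target bottleneck path semantics, see
#'   [bottleneck_scores()].
#' @param fit_threshold,independence_threshold scale-free thresholds, see
#'   [classify_scale_free()].
#' @param standardize PCA standardization flag, see [run_pca()].
#' @param ellipse_level PCA outlier confidence-ellipse level, see
#'   [flag_outliers()].
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with all computed objects: `network`,
#'   `summary`, `metrics`, `assessment`, `hubs`, `bottlenecks`, `pca`,
#'   `outliers`, `out_dir`.
#' @export
run_pipeline <- function(input = NULL, dialect = "auto",
                         generator = NULL, n = 1000, m = 2, seed = 1,
                         labels = NULL,
                         out_dir,
                         clustering_nodes = "all",
                         sd = "sample",
                         count_target = TRUE,
                         fit_threshold = 0.6,
                         independence_threshold = 0.1,
                         standardize = TRUE,
                         ellipse_level = 0.95,
                         quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  note <- function(...) if (!quiet) message(...)
  done <- function(stage) {
    manifest <<- c(manifest, stage)
    writeLines(manifest, file.path(out_dir, "MANIFEST"))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  config <- list(
    input = input, dialect = dialect, generator = generator, n = n, m = m,
    seed = seed, clustering_nodes = clustering_nodes, sd = sd,
    count_target = count_target, fit_threshold = fit_threshold,
    independence_threshold = independence_threshold, standardize = standardize,
    ellipse_level = ellipse_level
  )
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)

  net <- stage("ingest", {
    if (!is.null(input)) {
      db <- read_database(input, dialect = dialect)
      build_network(db, labels = labels)
    } else if (identical(generator, "afirnet_like")) {
      generate_afirnet_like(seed)
    } else if (identical(generator, "ba")) {
      generate_ba(n, m, seed)
    } else if (is.character(generator) && startsWith(generator, "fixture:")) {
      fixture(sub("^fixture:", "", generator))$network
    } else {
      stop("either 'input' or a generator ('afirnet_like', 'ba') is required")
    }
  })
  note("ingest: ", length(net$nodes), " nodes, ", nrow(net$records), " records")
  done("ingest")

  stage("export", {
    write_sif(net, file.path(out_dir, "network.sif"))
    write_graphml(net, file.path(out_dir, "network.graphml"))
  })
  done("export")

  apsp <- stage("shortest_paths", all_pairs_shortest_paths(net))
  metrics <- stage("metrics", node_metrics(net, apsp))
  smry <- stage("summary", network_summary(net, clustering_nodes, apsp))
  stage("metrics_out", {
    write_node_table(metrics, file.path(out_dir, "node_metrics.csv"))
    utils::write.csv(summary_table(smry), file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
  })
  done("metrics")

  assessment <- stage("scale_free", {
    classify_scale_free(net, metrics, fit_threshold = fit_threshold,
                        independence_threshold = independence_threshold, sd = sd)
  })
  stage("scale_free_out", {
    utils::write.csv(degree_distribution(net),
                     file.path(out_dir, "degree_distribution.csv"),
                     row.names = FALSE)
    fit <- assessment$fit
    if (is.null(fit)) fit <- list(a = NA_real_, gamma = NA_real_,
                                  pearson_r = NA_real_, r_squared = NA_real_)
    utils::write.csv(
      data.frame(
        key = c("a", "gamma", "pearson_r", "r_squared",
                "degree_clustering_r_squared", "has_hubs",
                "fit_threshold", "independence_threshold", "verdict"),
        value = c(fit$a, fit$gamma, fit$pearson_r, fit$r_squared,
                  assessment$degree_clustering_r_squared,
                  as.numeric(assessment$has_hubs),
                  fit_threshold, independence_threshold,
                  as.numeric(assessment$verdict))
      ),
      file.path(out_dir, "scale_free.csv"), row.names = FALSE
    )
  })
  done("scale_free")

  hubs <- assessment$hub_report
  stage("hubs_out", {
    utils::write.csv(hubs$hubs, file.path(out_dir, "hubs.csv"), row.names = FALSE)
  })
  done("hubs")

  bottlenecks <- stage("bottlenecks", bottleneck_scores(net, count_target))
  stage("bottlenecks_out", {
    utils::write.csv(bottlenecks$scores, file.path(out_dir, "bottlenecks.csv"),
                     row.names = FALSE)
  })
  done("bottlenecks")

  fm <- stage("pca", build_feature_matrix(net, metrics))
  pca <- stage("pca", run_pca(fm, standardize = standardize))
  outliers <- stage("pca", flag_outliers(pca, confidence = ellipse_level))
  stage("pca_out", {
    utils::write.csv(data.frame(node = rownames(pca$scores),
                                round(pca$scores, 9)),
                     file.path(out_dir, "pca_scores.csv"), row.names = FALSE)
    utils::write.csv(data.frame(metric = rownames(pca$loadings),
                                round(pca$loadings, 9)),
                     file.path(out_dir, "pca_loadings.csv"), row.names = FALSE)
    utils::write.csv(data.frame(component = paste0("PC", seq_along(pca$explained)),
                                explained = round(pca$explained, 9)),
                     file.path(out_dir, "pca_variance.csv"), row.names = FALSE)
    utils::write.csv(data.frame(node = names(outliers)[outliers]),
                     file.path(out_dir, "pca_outliers.csv"), row.names = FALSE)
  })
  done("pca")

  stage("report", {
    con <- file(file.path(out_dir, "summary.txt"), "w")
    on.exit(close(con))
    tbl <- summary_table(smry)
    fit <- assessment$fit
    if (is.null(fit)) fit <- list(a = NA_real_, gamma = NA_real_,
                                  pearson_r = NA_real_, r_squared = NA_real_)
    writeLines(c(
      "network analysis summary",
      "========================",
      sprintf("%-30s %s", tbl$Parameter, format(tbl$Value)),
      "",
      sprintf("power-law fit: N(k) = %.4g * k^%.4g (r = %.4f, R^2 = %.4f)",
              fit$a, fit$gamma, fit$pearson_r, fit$r_squared),
      sprintf("degree~clustering R^2 = %.4f", assessment$degree_clustering_r_squared),
      sprintf("scale-free verdict: %s",
              if (assessment$verdict) "Barabasi-Albert scale-free" else "not scale-free"),
      sprintf("hubs (ND > %.3f, %s sd): %s", hubs$threshold, hubs$sd_type,
              if (nrow(hubs$hubs)) paste(hubs$hubs$node, collapse = ", ") else "none"),
      sprintf("top bottlenecks: %s",
              paste(utils::head(bottlenecks$scores$node, 5), collapse = ", ")),
      sprintf("PCA outliers (%.1f%% ellipse): %s", 100 * ellipse_level,
              if (any(outliers)) paste(names(outliers)[outliers], collapse = ", ") else "none")
    ), con)
  })
  done("report")

  invisible(list(network = net, summary = smry, metrics = metrics,
                 assessment = assessment, hubs = hubs,
                 bottlenecks = bottlenecks, pca = pca, outliers = outliers,
                 out_dir = out_dir))
}
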