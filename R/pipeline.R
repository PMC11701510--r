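#' Run the full temporal-trajectory workflow
#'
#' Orchestrates the analysis stages in order on one cohort table: Timer
#' transform ([timer_transform()]), autofluorescence-aware clustering
#' ([precision_cluster()]), Timer-constrained ordination ([tocky_cca()]),
#' cluster network at the minimal connecting threshold ([build_network()]),
#' angle-constrained pathfinding ([dijkstra_tocky()]), and — when the
#' cohort has `sample_id`/`group` columns — locus composition and group
#' statistics along the found trajectory. Each stage consumes the previous
#' stage's output and nothing else, so stages can equally be run one by
#' one; reruns with the same inputs and seed are identical.
#'
#' @param cells Cohort tibble (e.g. from [read_cohort()] or
#'   [simulate_cohort()]): panel channels plus optional `sample_id`,
#'   `group`.
#' @param panel A [tocky_panel()].
#' @param k Number of k-means clusters. Default 8.
#' @param seed Integer seed for clustering restarts.
#' @param source,destination Cluster ids for pathfinding; by default the
#'   nodes with the smallest and largest mean Timer Angle.
#' @param norm_quantile Timer normalisation quantile, see
#'   [timer_transform()].
#' @param var_target PCA variance target, see [precision_cluster()].
#' @param cca_mode Timer standardisation mode, see [standardize_timer()].
#' @param network_mode Threshold mode, see [build_network()].
#' @param epsilon Angle slack for pathfinding, see [dijkstra_tocky()].
#' @param n_restarts k-means restarts. Default 25.
#' @return List of class `tocky_pipeline`: `cells` (transformed table with
#'   a `cluster` column), `timer_positive` (its Timer-positive slice with
#'   wa scores `CCA1`, `CCA2`), `clusters`, `cca`, `network`, `path`, and
#'   when group labels are available `locus_stats` (list with
#'   `composition` and `comparison`) and `abundance_stats`.
#' @export
run_pipeline <- function(cells, panel, k = 8, seed = 1,
                         source = NULL, destination = NULL,
                         norm_quantile = 0.95, var_target = 0.9,
                         cca_mode = "default", network_mode = "exact",
                         epsilon = 0, n_restarts = 25) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("Pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  transformed <- stage("transform",
                       timer_transform(cells, panel,
                                       norm_quantile = norm_quantile))
  clusters <- stage("cluster",
                    precision_cluster(transformed, panel, k = k, seed = seed,
                                      n_restarts = n_restarts,
                                      var_target = var_target))
  transformed$cluster <- clusters$labels

  pos <- transformed$timer_positive
  cca_data <- clusters$normalized[pos, , drop = FALSE]
  attr(cca_data, "markers") <- clusters$markers
  cca <- stage("cca", tocky_cca(cca_data, mode = cca_mode))

  tp <- transformed[pos, , drop = FALSE]
  tp$CCA1 <- cca$wa_scores[, 1]
  tp$CCA2 <- cca$wa_scores[, 2]

  nodes <- stage("network-nodes",
                 cluster_centroids(tp, tp$cluster, markers = panel$markers))
  network <- stage("network", build_network(nodes, mode = network_mode))

  if (is.null(source)) {
    source <- nodes$cluster[which.min(nodes$mean_angle)]
  }
  if (is.null(destination)) {
    destination <- nodes$cluster[which.max(nodes$mean_angle)]
  }
  path <- stage("path", dijkstra_tocky(network, source, destination,
                                       epsilon = epsilon))

  out <- list(cells = transformed, timer_positive = tp, clusters = clusters,
              cca = cca, network = network, path = path, panel = panel,
              k = k, seed = seed)

  if (all(c("sample_id", "group") %in% names(transformed)) &&
      path$reachable) {
    path_cells <- tp[tp$cluster %in% path$node_sequence, , drop = FALSE]
    parent <- table(tp$sample_id)
    parent_counts <- stats::setNames(as.numeric(parent), names(parent))
    comp <- stage("locus-stats",
                  locus_composition(path_cells, parent_counts))
    out$locus_stats <- list(
      composition = comp,
      comparison = if (length(unique(transformed$group)) == 2) {
        compare_groups(comp, unit = "locus", value = "percentage")
      } else NULL
    )
    if (length(unique(transformed$group)) == 2) {
      out$abundance_stats <- stage(
        "abundance-stats",
        cluster_abundance_stats(transformed, clusters)
      )
    }
  }
  structure(out, class = "tocky_pipeline")
}

#' @export
print.tocky_pipeline <- function(x, ...) {
  cat("<tocky_pipeline>\n")
  cat("  cells:    ", nrow(x$cells), " (",
      sum(x$cells$timer_positive), " Timer-positive)\n", sep = "")
  cat("  clusters: k =", x$clusters$k, "\n")
  cat("  network:  ", nrow(x$network$nodes), "nodes,",
      nrow(x$network$edges), "edges\n")
  print(x$path)
  invisible(x)
}
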