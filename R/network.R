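#' Cluster node table in the CCA space
#'
#' Summarises each cluster's Timer-positive members into a network node:
#' the wa-score centroid (arithmetic mean of member wa scores), the mean
#' Timer Angle and Intensity, the member count, and — when present in
#' `data` — per-marker MFIs. Clusters with no Timer-positive members carry
#' no temporal information and are dropped with a warning.
#'
#' @param data Tibble of cells carrying `timer_positive`, `timer_angle`,
#'   `timer_intensity` and the wa-score columns `CCA1`, `CCA2` (e.g. the
#'   Timer-positive slice of a pipeline table).
#' @param clusters A `tocky_clusters` object or integer label vector aligned
#'   with the rows of `data`.
#' @param markers Optional marker columns to average into per-node MFIs.
#' @return Tibble with one row per retained cluster: `cluster`, `CCA1`,
#'   `CCA2`, `mean_angle`, `mean_intensity`, `n_cells`, then any marker
#'   MFI columns.
#' @export
cluster_centroids <- function(data, clusters, markers = NULL) {
  labels <- if (inherits(clusters, "tocky_clusters")) clusters$labels
            else as.integer(clusters)
  stopifnot(length(labels) == nrow(data),
            all(c("CCA1", "CCA2", "timer_angle", "timer_intensity")
                %in% names(data)))
  dat <- tibble::as_tibble(data)
  dat$.cluster <- labels
  if ("timer_positive" %in% names(dat)) {
    dat <- dplyr::filter(dat, .data$timer_positive)
  }
  all_ids <- sort(unique(labels))
  nodes <- dat |>
    dplyr::group_by(cluster = .data$.cluster) |>
    dplyr::summarise(
      CCA1 = mean(.data$CCA1),
      CCA2 = mean(.data$CCA2),
      mean_angle = mean(.data$timer_angle),
      mean_intensity = mean(.data$timer_intensity),
      n_cells = dplyr::n(),
      dplyr::across(dplyr::all_of(markers), mean),
      .groups = "drop"
    )
  dropped <- setdiff(all_ids, nodes$cluster)
  if (length(dropped)) {
    warning("Cluster(s) with no Timer-positive members dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  nodes
}

#' Build the cluster network at the minimal connecting threshold
#'
#' Forms the complete graph on cluster centroids with Euclidean wa-space
#' distances as weights, then keeps every pair at or below the smallest
#' distance threshold for which the graph is connected. That threshold is
#' the bottleneck of the minimum spanning tree — the largest MST edge —
#' because a distance graph first becomes connected exactly when its
#' threshold reaches the largest MST edge. Its percentile among all
#' pairwise distances is reported, matching the "lowest connecting
#' percentile" reading; `mode = "grid"` instead scans integer percentiles
#' 1..100 and keeps the lowest connecting one, reproducing the coarser
#' behaviour.
#'
#' @param nodes Node tibble from [cluster_centroids()] (needs `cluster`,
#'   `CCA1`, `CCA2`).
#' @param mode `"exact"` (default, bottleneck value) or `"grid"` (integer
#'   percentiles of the distance distribution).
#' @return Object of class `tocky_network`: list with `nodes`, `edges`
#'   (tibble `from`, `to`, `weight`, including all ties at the threshold),
#'   `threshold`, `threshold_percentile`.
#' @export
build_network <- function(nodes, mode = c("exact", "grid")) {
  mode <- match.arg(mode)
  stopifnot(all(c("cluster", "CCA1", "CCA2") %in% names(nodes)))
  m <- nrow(nodes)
  if (m < 1) stop("Empty node table.", call. = FALSE)
  if (m == 1) {
    warning("Single node: trivial network with no edges.", call. = FALSE)
    return(structure(
      list(nodes = nodes,
           edges = tibble::tibble(from = integer(), to = integer(),
                                  weight = numeric()),
           threshold = NA_real_, threshold_percentile = NA_real_),
      class = "tocky_network"
    ))
  }
  D <- as.matrix(stats::dist(as.matrix(nodes[c("CCA1", "CCA2")])))
  all_d <- D[upper.tri(D)]

  if (mode == "exact") {
    # explicit edge list: zero-weight edges (coincident centroids) must
    # survive, which an adjacency-matrix graph would drop
    pairs_all <- t(utils::combn(m, 2))
    g <- igraph::graph_from_edgelist(pairs_all, directed = FALSE)
    igraph::E(g)$weight <- D[pairs_all]
    mst <- igraph::mst(g, weights = igraph::E(g)$weight)
    threshold <- max(igraph::E(mst)$weight)
  } else {
    threshold <- NA_real_
    for (pct in 1:100) {
      cand <- stats::quantile(all_d, pct / 100, names = FALSE)
      adj <- D <= cand
      if (graph_connected(adj)) {
        threshold <- cand
        break
      }
    }
  }
  pairs <- which(upper.tri(D) & D <= threshold, arr.ind = TRUE)
  edges <- tibble::tibble(
    from = nodes$cluster[pairs[, 1]],
    to = nodes$cluster[pairs[, 2]],
    weight = D[pairs]
  ) |> dplyr::arrange(.data$from, .data$to)
  structure(
    list(nodes = nodes, edges = edges, threshold = threshold,
         threshold_percentile = 100 * mean(all_d <= threshold)),
    class = "tocky_network"
  )
}

# connectivity of a logical adjacency matrix, by flood fill
graph_connected <- function(adj) {
  m <- nrow(adj)
  seen <- logical(m)
  frontier <- 1L
  seen[1L] <- TRUE
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' @export
print.tocky_network <- function(x, ...) {
  cat("<tocky_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges\n", sep = "")
  cat("  connecting threshold: ", format(x$threshold, digits = 4),
      " (percentile ", format(x$threshold_percentile, digits = 3), ")\n",
      sep = "")
  invisible(x)
}

#' Node and edge tables of a network
#'
#' @param x A `tocky_network` object.
#' @param ... Unused.
#' @return `tidy()` returns the edge tibble; the node tibble is `x$nodes`.
#' @method tidy tocky_network
#' @export
tidy.tocky_network <- function(x, ...) x$edges

#' Plot a cluster network in CCA space
#'
#' Nodes at their wa centroids (sized by cell count, coloured by mean Timer
#' Angle), edges drawn for every pair within the connecting threshold; an
#' optional trajectory is highlighted.
#'
#' @param object A `tocky_network`.
#' @param path Optional `tocky_path` to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tocky_network
#' @export
autoplot.tocky_network <- function(object, path = NULL, ...) {
  nodes <- object$nodes
  seg <- object$edges |>
    dplyr::left_join(nodes[c("cluster", "CCA1", "CCA2")],
                     by = c(from = "cluster")) |>
    dplyr::left_join(nodes[c("cluster", "CCA1", "CCA2")],
                     by = c(to = "cluster"), suffix = c("", "_to"))
  p <- ggplot2::ggplot(nodes, ggplot2::aes(.data$CCA1, .data$CCA2)) +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$CCA1, y = .data$CCA2,
                   xend = .data$CCA1_to, yend = .data$CCA2_to),
      colour = "grey70"
    ) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_cells,
                                     colour = .data$mean_angle)) +
    ggplot2::scale_colour_viridis_c(name = "Mean Timer Angle") +
    ggplot2::geom_text(ggplot2::aes(label = .data$cluster), vjust = -1) +
    ggplot2::theme_minimal()
  if (!is.null(path) && isTRUE(path$reachable)) {
    idx <- match(path$node_sequence, nodes$cluster)
    traj <- nodes[idx, ]
    p <- p + ggplot2::geom_path(data = traj, colour = "deeppink",
                                linewidth = 1)
  }
  p
}
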