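#' Autofluorescence-thresholded marker normalisation
#'
#' Flow cytometers are set up so that reporter-negative cells span a wide
#' range of values; everything at or below the per-marker autofluorescence
#' threshold is biologically meaningless. This transform maps each marker to
#' `max(0, x - threshold) / span`, where `span` is the distance from the
#' threshold to the `span_quantile` quantile of the raw marker, so that
#' sub-threshold values become exactly 0 and a typical bright cell sits near
#' 1. Markers whose span is not positive (constant at or below threshold)
#' are dropped with a warning.
#'
#' @param cells Data frame containing the panel's marker columns.
#' @param panel A [tocky_panel()].
#' @param span_quantile Quantile of the raw marker defining the top of the
#'   normalisation span. Default 0.99.
#' @return `cells` with marker columns replaced by their normalised values.
#'   Attributes: `markers` (kept markers), `thresholds`, `spans`,
#'   `dropped_markers`.
#' @export
threshold_normalize <- function(cells, panel, span_quantile = 0.99) {
  stopifnot(is.data.frame(cells), inherits(panel, "tocky_panel"))
  missing <- setdiff(panel$markers, names(cells))
  if (length(missing)) {
    stop("Marker channel(s) not in `cells`: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(cells)
  spans <- numeric(0)
  kept <- character(0)
  dropped <- character(0)
  for (m in panel$markers) {
    theta <- panel$marker_thresholds[[m]]
    x <- out[[m]]
    span <- stats::quantile(x, span_quantile, names = FALSE) - theta
    if (!is.finite(span) || span <= .Machine$double.eps) {
      dropped <- c(dropped, m)
      out[[m]] <- NULL
      next
    }
    out[[m]] <- pmax(0, x - theta) / span
    spans[m] <- span
    kept <- c(kept, m)
  }
  if (length(dropped)) {
    warning("Dropped marker(s) with no signal above threshold: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (!length(kept)) {
    stop("No marker has signal above its autofluorescence threshold.",
         call. = FALSE)
  }
  attr(out, "markers") <- kept
  attr(out, "thresholds") <- panel$marker_thresholds[kept]
  attr(out, "spans") <- spans
  attr(out, "dropped_markers") <- dropped
  out
}

#' Principal component embedding of normalised markers
#'
#' Centred (not rescaled) PCA of the normalised marker matrix; the
#' thresholded scale already puts markers on comparable units, so rescaling
#' would re-amplify autofluorescence noise.
#'
#' @param data Data frame carrying the marker columns (e.g. the output of
#'   [threshold_normalize()]).
#' @param markers Character vector of marker column names; defaults to the
#'   `markers` attribute of `data`.
#' @param n_components Number of components to keep; default all.
#' @return List with `scores` (n x d matrix), `loadings` (p x d, orthonormal
#'   columns) and `variance_fraction` (length d, non-increasing).
#' @export
pca_embed <- function(data, markers = attr(data, "markers"),
                      n_components = NULL) {
  if (is.null(markers)) {
    stop("Supply `markers` or use data from threshold_normalize().",
         call. = FALSE)
  }
  X <- as.matrix(data[markers])
  p <- ncol(X)
  if (is.null(n_components)) n_components <- p
  stopifnot(n_components >= 1, n_components <= p,
            nrow(X) > n_components)
  if (all(apply(X, 2, stats::sd) == 0)) {
    stop("Marker matrix has zero variance; nothing to embed.", call. = FALSE)
  }
  fit <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  d <- n_components
  list(
    scores = fit$x[, seq_len(d), drop = FALSE],
    loadings = fit$rotation[, seq_len(d), drop = FALSE],
    variance_fraction = (fit$sdev^2 / sum(fit$sdev^2))[seq_len(d)]
  )
}

#' Seeded, restarted k-means on PC scores
#'
#' Runs `n_restarts` k-means fits from centres sampled (without replacement)
#' among the distinct rows of `scores` and keeps the solution with the
#' lowest total within-cluster sum of squares. Thresholded cytometry data
#' contain large blocks of identical rows (all-autofluorescent cells map to
#' the zero vector), so centres are drawn from distinct rows to keep every
#' start valid. Deterministic given `(seed, n_restarts)`.
#'
#' @param scores Numeric matrix, one row per cell.
#' @param k Number of clusters, `1 <= k <=` number of cells.
#' @param seed Integer seed.
#' @param n_restarts Number of random restarts. Default 25.
#' @param iter_max Maximum iterations per fit. Default 100.
#' @return Object of class `tocky_clusters`: list with `labels` (integer
#'   vector in `1..k`), `k`, `centers`, `tot_withinss`, `seed`.
#' @export
kmeans_cluster <- function(scores, k, seed, n_restarts = 25, iter_max = 100) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (k < 1 || k > n) {
    stop("`k` must lie between 1 and the number of cells (", n, ").",
         call. = FALSE)
  }
  if (k == 1) {
    ctr <- matrix(colMeans(scores), nrow = 1)
    return(structure(
      list(labels = rep(1L, n), k = 1L, centers = ctr,
           tot_withinss = sum(sweep(scores, 2, ctr[1, ])^2), seed = seed),
      class = "tocky_clusters"
    ))
  }
  distinct <- unique(scores)
  if (nrow(distinct) < k) {
    stop("Only ", nrow(distinct), " distinct cell profiles; cannot form ",
         k, " clusters.", call. = FALSE)
  }
  best <- NULL
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  for (r in seq_len(n_restarts)) {
    centers <- distinct[sample.int(nrow(distinct), k), , drop = FALSE]
    km <- tryCatch(
      suppressWarnings(stats::kmeans(scores, centers = centers,
                                     iter.max = iter_max)),
      error = function(e) NULL
    )
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) {
    stop("k-means failed on every restart.", call. = FALSE)
  }
  structure(
    list(labels = as.integer(best$cluster), k = as.integer(k),
         centers = best$centers, tot_withinss = best$tot.withinss,
         seed = seed),
    class = "tocky_clusters"
  )
}

#' @export
print.tocky_clusters <- function(x, ...) {
  cat("<tocky_clusters> k =", x$k, "over", length(x$labels), "cells;",
      "total within-SS =", format(x$tot_withinss), "\n")
  invisible(x)
}

#' Autofluorescence-aware PCA/k-means clustering
#'
#' The full precision-clustering pipeline: threshold-normalise the markers
#' ([threshold_normalize()]), embed by PCA ([pca_embed()]), keep the leading
#' components up to `var_target` cumulative variance, and cluster the PC
#' scores with seeded, restarted k-means ([kmeans_cluster()]). Zeroing the
#' sub-threshold range prevents k-means from carving clusters out of
#' autofluorescence structure.
#'
#' @inheritParams threshold_normalize
#' @inheritParams kmeans_cluster
#' @param k Number of clusters.
#' @param var_target Cumulative variance fraction determining how many PCs
#'   feed k-means (capped at the number of markers). Default 0.9.
#' @return A `tocky_clusters` object extended with `pc_scores`,
#'   `pc_loadings`, `variance_fraction`, `n_components` and `markers`.
#' @export
precision_cluster <- function(cells, panel, k, seed, n_restarts = 25,
                              var_target = 0.9, span_quantile = 0.99) {
  norm <- threshold_normalize(cells, panel, span_quantile = span_quantile)
  emb <- pca_embed(norm)
  d <- which(cumsum(emb$variance_fraction) >= var_target)[1]
  if (is.na(d)) d <- length(emb$variance_fraction)
  cl <- kmeans_cluster(emb$scores[, seq_len(d), drop = FALSE], k = k,
                       seed = seed, n_restarts = n_restarts)
  cl$pc_scores <- emb$scores
  cl$pc_loadings <- emb$loadings
  cl$variance_fraction <- emb$variance_fraction
  cl$n_components <- d
  cl$markers <- attr(norm, "markers")
  cl$normalized <- norm
  cl
}

#' Per-cluster marker and locus summaries
#'
#' For each cluster and marker, the mean raw fluorescence (MFI) and the
#' percentage of member cells strictly above the marker's autofluorescence
#' threshold; plus per-cluster cell counts, per-sample composition (when a
#' `sample_id` column is present) and Tocky-locus composition over the
#' cluster's Timer-positive members (when `timer_transform()` columns are
#' present).
#'
#' @param cells Data frame of raw cells, optionally already carrying
#'   `sample_id` and the [timer_transform()] columns.
#' @param clusters A `tocky_clusters` object (or an integer label vector)
#'   aligned with the rows of `cells`.
#' @param panel A [tocky_panel()].
#' @return List of class `tocky_cluster_summary` with tibbles
#'   `marker_stats` (`cluster`, `marker`, `mfi`, `pct_positive`), `counts`
#'   (`cluster`, `n_cells`), optionally `sample_composition` and
#'   `locus_composition`.
#' @export
summarize_clusters <- function(cells, clusters, panel) {
  labels <- if (inherits(clusters, "tocky_clusters")) clusters$labels
            else as.integer(clusters)
  stopifnot(length(labels) == nrow(cells))
  k <- max(labels)
  dat <- tibble::as_tibble(cells)
  dat$.cluster <- factor(labels, levels = seq_len(k))

  marker_stats <- dat |>
    dplyr::select(dplyr::all_of(c(".cluster", panel$markers))) |>
    tidyr::pivot_longer(dplyr::all_of(panel$markers),
                        names_to = "marker", values_to = "value") |>
    dplyr::mutate(threshold = panel$marker_thresholds[.data$marker]) |>
    dplyr::group_by(cluster = .data$.cluster, .data$marker) |>
    dplyr::summarise(
      mfi = mean(.data$value),
      pct_positive = 100 * mean(.data$value > .data$threshold),
      .groups = "drop"
    ) |>
    tidyr::complete(cluster = factor(seq_len(k), levels = seq_len(k)),
                    marker = panel$markers) |>
    dplyr::mutate(cluster = as.integer(as.character(.data$cluster)))

  counts <- dat |>
    dplyr::count(cluster = .data$.cluster, .drop = FALSE, name = "n_cells") |>
    dplyr::mutate(cluster = as.integer(as.character(.data$cluster)))
  if (any(counts$n_cells == 0)) {
    warning("Empty cluster(s): ",
            paste(counts$cluster[counts$n_cells == 0], collapse = ", "),
            "; summary rows are NA.", call. = FALSE)
  }

  out <- list(marker_stats = marker_stats, counts = counts)

  if ("sample_id" %in% names(dat)) {
    out$sample_composition <- dat |>
      dplyr::count(.data$sample_id, cluster = .data$.cluster,
                   .drop = FALSE, name = "n") |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::mutate(percentage = 100 * .data$n / sum(.data$n)) |>
      dplyr::ungroup() |>
      dplyr::mutate(cluster = as.integer(as.character(.data$cluster)))
  }
  if ("locus" %in% names(dat)) {
    out$locus_composition <- dat |>
      dplyr::filter(.data$timer_positive) |>
      dplyr::count(cluster = .data$.cluster, .data$locus,
                   .drop = FALSE, name = "n") |>
      dplyr::group_by(.data$cluster) |>
      dplyr::mutate(fraction = .data$n / pmax(1, sum(.data$n))) |>
      dplyr::ungroup() |>
      dplyr::mutate(cluster = as.integer(as.character(.data$cluster)))
  }
  structure(out, class = "tocky_cluster_summary")
}

#' Spike-in recovery metrics for a clustering
#'
#' Scores how well a clustering isolates known target (spiked-in) cells:
#' clusters whose target fraction strictly exceeds `enrich_fraction` are
#' called enriched, every member of an enriched cluster is predicted
#' positive, and accuracy, precision, sensitivity and specificity follow
#' from the resulting confusion matrix.
#'
#' @param clusters A `tocky_clusters` object or integer label vector.
#' @param truth Logical vector flagging true target cells, aligned with the
#'   labels.
#' @param enrich_fraction Minimum (strict) target fraction for a cluster to
#'   count as enriched. Default 0.20.
#' @return One-row tibble: `accuracy`, `precision`, `sensitivity`,
#'   `specificity`, `n_enriched_clusters`, plus the confusion counts.
#'   Degenerate denominators yield `NA`.
#' @export
evaluate_spike_recovery <- function(clusters, truth, enrich_fraction = 0.20) {
  labels <- if (inherits(clusters, "tocky_clusters")) clusters$labels
            else as.integer(clusters)
  truth <- as.logical(truth)
  stopifnot(length(labels) == length(truth), !anyNA(truth))
  frac <- tapply(truth, labels, mean)
  enriched <- as.integer(names(frac)[frac > enrich_fraction])
  predicted <- labels %in% enriched
  tp <- sum(predicted & truth)
  fp <- sum(predicted & !truth)
  fn <- sum(!predicted & truth)
  tn <- sum(!predicted & !truth)
  div <- function(num, den) if (den > 0) num / den else NA_real_
  tibble::tibble(
    accuracy = div(tp + tn, tp + fp + fn + tn),
    precision = div(tp, tp + fp),
    sensitivity = div(tp, tp + fn),
    specificity = div(tn, tn + fp),
    n_enriched_clusters = length(enriched),
    tp = tp, fp = fp, fn = fn, tn = tn
  )
}
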