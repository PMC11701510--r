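#' Tocky-locus composition of trajectory cells
#'
#' For each sample, the percentage of trajectory cells falling in each of
#' the five Tocky loci, relative to a declared parent population:
#' `100 * (trajectory cells in locus) / (parent count)`. The default parent
#' is all Timer-positive cells of the sample; pass `parent_counts` to use a
#' biology-specific parent gate counted upstream. Samples with zero parent
#' cells yield `NA` with a warning.
#'
#' @param path_cells Tibble of cells on a trajectory with columns
#'   `sample_id` and `locus` (and optionally `group`, carried through).
#' @param parent_counts Named numeric vector or two-column data frame
#'   (`sample_id`, `parent_n`) of parent population sizes per sample.
#' @return Tibble with one row per (sample, locus): `sample_id`, `locus`,
#'   `n`, `percentage` (plus `group` when supplied), complete over the five
#'   loci with zero counts filled in.
#' @export
locus_composition <- function(path_cells, parent_counts) {
  stopifnot(all(c("sample_id", "locus") %in% names(path_cells)))
  if (is.data.frame(parent_counts)) {
    pc <- stats::setNames(parent_counts$parent_n, parent_counts$sample_id)
  } else {
    pc <- parent_counts
  }
  samples <- names(pc)
  grp <- NULL
  if ("group" %in% names(path_cells)) {
    grp <- dplyr::distinct(path_cells, .data$sample_id, .data$group)
  }
  out <- path_cells |>
    dplyr::mutate(
      sample_id = factor(.data$sample_id, levels = samples),
      locus = factor(.data$locus, levels = tocky_loci())
    ) |>
    dplyr::count(.data$sample_id, .data$locus, .drop = FALSE, name = "n") |>
    dplyr::mutate(
      sample_id = as.character(.data$sample_id),
      parent_n = unname(pc[.data$sample_id])
    )
  small <- out$parent_n < tapply(out$n, out$sample_id, sum)[out$sample_id]
  if (any(small, na.rm = TRUE)) {
    stop("Parent count smaller than trajectory cell count for sample(s): ",
         paste(unique(out$sample_id[small]), collapse = ", "), call. = FALSE)
  }
  if (any(out$parent_n == 0)) {
    warning("Zero parent count; percentages are NA for sample(s): ",
            paste(unique(out$sample_id[out$parent_n == 0]), collapse = ", "),
            call. = FALSE)
  }
  out$percentage <- ifelse(out$parent_n > 0, 100 * out$n / out$parent_n,
                           NA_real_)
  out$parent_n <- NULL
  if (!is.null(grp)) out <- dplyr::left_join(out, grp, by = "sample_id")
  out
}

#' Per-locus marker MFI along a trajectory
#'
#' Arithmetic mean of raw marker fluorescence per (sample, locus, marker)
#' among trajectory cells; `NA` where a sample has no cells in a locus.
#'
#' @inheritParams locus_composition
#' @param markers Character vector of raw marker columns in `path_cells`.
#' @return Long tibble: `sample_id`, `locus`, `marker`, `mfi` (plus `group`
#'   when present), complete over the five loci.
#' @export
locus_marker_profiles <- function(path_cells, markers) {
  stopifnot(all(c("sample_id", "locus") %in% names(path_cells)),
            all(markers %in% names(path_cells)))
  grp <- NULL
  if ("group" %in% names(path_cells)) {
    grp <- dplyr::distinct(path_cells, .data$sample_id, .data$group)
  }
  out <- path_cells |>
    tidyr::pivot_longer(dplyr::all_of(markers), names_to = "marker",
                        values_to = "value") |>
    dplyr::group_by(.data$sample_id, .data$locus, .data$marker) |>
    dplyr::summarise(mfi = mean(.data$value), .groups = "drop") |>
    tidyr::complete(
      sample_id = unique(path_cells$sample_id),
      locus = factor(tocky_loci(), levels = tocky_loci()),
      marker = markers
    ) |>
    dplyr::mutate(locus = factor(.data$locus, levels = tocky_loci()))
  if (!is.null(grp)) out <- dplyr::left_join(out, grp, by = "sample_id")
  out
}

#' Two-group Mann-Whitney comparison across a family of readouts
#'
#' For each unit (a locus, a cluster, ...) compares the per-sample values of
#' exactly two groups with a two-sided Mann-Whitney U test — exact when the
#' combined sample size is at most 20 and there are no ties, otherwise the
#' normal approximation with tie and continuity correction — and adjusts
#' p-values across the family of units by Benjamini-Hochberg. The log2 fold
#' change is `log2((mean_exp + pseudocount) / (mean_ctrl + pseudocount))`
#' with the experimental group in the numerator.
#'
#' @param data Tibble with one row per (unit, sample): columns named by
#'   `unit`, `value`, `group`.
#' @param unit Name of the column identifying the tested unit. Default
#'   `"locus"`.
#' @param value Name of the value column. Default `"percentage"`.
#' @param experimental Group label treated as experimental (numerator of
#'   the fold change). Default: the second group in `sort(unique(group))`.
#' @param pseudocount Added to both group means before the log ratio.
#'   Default 0.
#' @return Tibble, one row per unit: group medians and means, `log2fc`,
#'   `p_value`, `p_adjusted` (BH over the units), `method`.
#' @examples
#' d <- tibble::tibble(
#'   locus = rep("Arrested", 4),
#'   sample_id = paste0("s", 1:4),
#'   group = c("ctrl", "ctrl", "ko", "ko"),
#'   percentage = c(1, 2, 3, 4)
#' )
#' compare_groups(d)
#' @export
compare_groups <- function(data, unit = "locus", value = "percentage",
                           experimental = NULL, pseudocount = 0) {
  stopifnot(all(c(unit, value, "group") %in% names(data)))
  groups <- sort(unique(as.character(data$group)))
  if (length(groups) != 2) {
    stop("Exactly two groups are required; found: ",
         paste(groups, collapse = ", "), call. = FALSE)
  }
  if (is.null(experimental)) experimental <- groups[2]
  if (!experimental %in% groups) {
    stop("`experimental` must be one of: ", paste(groups, collapse = ", "),
         call. = FALSE)
  }
  control <- setdiff(groups, experimental)
  dat <- tibble::as_tibble(data)
  dat$.unit <- dat[[unit]]
  dat$.value <- dat[[value]]

  res <- dat |>
    dplyr::group_by(unit = .data$.unit) |>
    dplyr::group_modify(function(d, key) {
      x <- d$.value[d$group == experimental]
      y <- d$.value[d$group == control]
      if (length(x) < 2 || length(y) < 2) {
        stop("Need at least 2 samples per group for unit '", key$unit, "'.",
             call. = FALSE)
      }
      mw <- mann_whitney_p(x, y)
      tibble::tibble(
        n_experimental = length(x), n_control = length(y),
        median_experimental = stats::median(x),
        median_control = stats::median(y),
        mean_experimental = mean(x), mean_control = mean(y),
        log2fc = {
          num <- mean(x) + pseudocount
          den <- mean(y) + pseudocount
          if (num > 0 && den > 0) log2(num / den) else NA_real_
        },
        p_value = mw$p, method = mw$method
      )
    }) |>
    dplyr::ungroup()
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  names(res)[names(res) == "unit"] <- unit
  attr(res, "experimental") <- experimental
  attr(res, "control") <- control
  res
}

# Two-sided Mann-Whitney p; exact when small and tie-free, else normal
# approximation. Identical constant data carry no evidence -> p = 1.
mann_whitney_p <- function(x, y) {
  if (length(unique(c(x, y))) == 1) {
    return(list(p = 1, method = "degenerate"))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 20 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  list(p = unname(wt$p.value),
       method = if (exact) "exact" else "normal approximation")
}

#' Per-cluster abundance statistics between two groups
#'
#' Counts each sample's cells per cluster, converts to within-sample
#' percentages, compares the two groups cluster-by-cluster with
#' Mann-Whitney U tests (BH-adjusted across clusters), and reports the
#' log2 fold change of mean cell numbers with a pseudocount guarding
#' empty clusters: `log2((mean_n_exp + eps) / (mean_n_ctrl + eps))`.
#'
#' @param cells Tibble with `sample_id` and `group` columns, one row per
#'   cell.
#' @param clusters A `tocky_clusters` object or integer label vector
#'   aligned with `cells`.
#' @param experimental Experimental group label; default the second sorted
#'   group.
#' @param pseudocount Cells added to both group mean counts in the fold
#'   change. Default 0.5.
#' @return Tibble, one row per cluster: the [compare_groups()] columns on
#'   percentages plus `log2fc_counts`.
#' @export
cluster_abundance_stats <- function(cells, clusters, experimental = NULL,
                                    pseudocount = 0.5) {
  labels <- if (inherits(clusters, "tocky_clusters")) clusters$labels
            else as.integer(clusters)
  stopifnot(length(labels) == nrow(cells),
            all(c("sample_id", "group") %in% names(cells)))
  k <- max(labels)
  per_sample <- tibble::tibble(
    sample_id = cells$sample_id,
    group = cells$group,
    cluster = factor(labels, levels = seq_len(k))
  ) |>
    dplyr::count(.data$sample_id, .data$group, .data$cluster,
                 .drop = FALSE, name = "n") |>
    dplyr::filter(!is.na(.data$group)) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(percentage = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(cluster = as.integer(as.character(.data$cluster)))

  res <- compare_groups(per_sample, unit = "cluster", value = "percentage",
                        experimental = experimental, pseudocount = 0)
  exp_lab <- attr(res, "experimental")
  fc <- per_sample |>
    dplyr::group_by(.data$cluster,
                    side = ifelse(.data$group == exp_lab, "exp", "ctrl")) |>
    dplyr::summarise(mean_n = mean(.data$n), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "side", values_from = "mean_n") |>
    dplyr::mutate(log2fc_counts = log2((.data$exp + pseudocount) /
                                         (.data$ctrl + pseudocount)))
  out <- dplyr::left_join(res, fc[c("cluster", "log2fc_counts")],
                          by = "cluster")
  out$per_sample <- NULL
  attr(out, "experimental") <- exp_lab
  attr(out, "control") <- attr(res, "control")
  attr(out, "per_sample") <- per_sample
  out
}

#' Locus composition line plot
#'
#' Mean +/- s.d. of the per-sample locus percentages by group, in locus
#' (temporal) order — the standard way of reading locus dynamics along a
#' trajectory.
#'
#' @param composition Output of [locus_composition()] including a `group`
#'   column.
#' @return A ggplot object.
#' @export
plot_locus_composition <- function(composition) {
  stopifnot(all(c("locus", "percentage", "group") %in% names(composition)))
  summ <- composition |>
    dplyr::group_by(.data$locus, .data$group) |>
    dplyr::summarise(mean = mean(.data$percentage, na.rm = TRUE),
                     sd = stats::sd(.data$percentage, na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$locus, .data$mean,
                                     colour = .data$group,
                                     group = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::labs(x = "Tocky locus", y = "% of parent population") +
    ggplot2::theme_minimal()
}
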