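#' Standardise the Timer explanatory matrix
#'
#' Builds the n x 2 explanatory matrix `Z` with columns `Angle` and
#' `Intensity` from Timer-positive cells. In the default mode each column is
#' centred to mean 0 and divided by its sample standard deviation; the
#' literal mode divides by the standard deviation only, leaving the column
#' means in place (kept for fidelity with descriptions that name only the
#' scaling step). Centring prevents the grand mean of the marker matrix
#' leaking into the constrained space, so it is the default.
#'
#' @param data Data frame with `timer_angle` and `timer_intensity` columns
#'   (Timer-positive rows, e.g. `dplyr::filter(x, timer_positive)`).
#' @param mode `"default"` (centre and scale) or `"literal"` (scale only).
#' @return Numeric n x 2 matrix with columns `Angle`, `Intensity`.
#' @export
standardize_timer <- function(data, mode = c("default", "literal")) {
  mode <- match.arg(mode)
  stopifnot(all(c("timer_angle", "timer_intensity") %in% names(data)))
  Z <- cbind(Angle = data$timer_angle, Intensity = data$timer_intensity)
  if (anyNA(Z)) {
    stop("Timer Angle/Intensity contain NA; restrict to Timer-positive cells.",
         call. = FALSE)
  }
  if (nrow(Z) < 3) {
    stop("Need at least 3 Timer-positive cells.", call. = FALSE)
  }
  sds <- apply(Z, 2, stats::sd)
  if (any(sds == 0)) {
    stop("Constant explanatory column(s): ",
         paste(colnames(Z)[sds == 0], collapse = ", "),
         "; the Timer matrix is degenerate.", call. = FALSE)
  }
  if (mode == "default") Z <- sweep(Z, 2, colMeans(Z))
  sweep(Z, 2, sds, "/")
}

#' Centre and scale the marker matrix
#'
#' Each marker column is centred to mean 0 and scaled to sample standard
#' deviation 1. Constant markers carry no contrast and are dropped with a
#' warning naming them.
#'
#' @param data Data frame carrying the marker columns.
#' @param markers Marker column names; defaults to the `markers` attribute
#'   (set by [threshold_normalize()]).
#' @return Numeric n x p matrix with column names.
#' @export
scale_markers <- function(data, markers = attr(data, "markers")) {
  if (is.null(markers)) {
    stop("Supply `markers` or use data from threshold_normalize().",
         call. = FALSE)
  }
  S <- as.matrix(data[markers])
  sds <- apply(S, 2, stats::sd)
  if (all(sds == 0)) {
    stop("All markers are constant; cannot scale.", call. = FALSE)
  }
  if (any(sds == 0)) {
    warning("Dropped constant marker(s): ",
            paste(markers[sds == 0], collapse = ", "), call. = FALSE)
    S <- S[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  sweep(sweep(S, 2, colMeans(S)), 2, sds, "/")
}

#' Projection-based canonical correspondence analysis on Timer coordinates
#'
#' Constrained ordination of a scaled marker matrix `S` (n cells x p
#' markers) on the standardised Timer matrix `Z` (n x 2: Angle, Intensity).
#' `S` is projected onto the column space of `Z` with the hat matrix
#' `H = Z (Z'Z)^-1 Z'`, giving `S* = H S` — the part of every marker
#' explainable by Timer progression — which is then decomposed by thin SVD,
#' `S* = U D V'`, keeping the (at most two) constrained axes. Marker scores
#' are the columns of `V`; weighted-average cell scores are `wa = S V`;
#' linear-combination cell scores are `lc = S* V = U D`. Explanatory arrows
#' are the Pearson correlations of each `Z` column with each wa-score axis,
#' so they live in \[-1, 1\]. Unlike classical correspondence-analysis CCA
#' there is no chi-square weighting: fluorescence is not count data, so the
#' projection acts on the standardised matrix directly (equivalently,
#' `S*` equals the fitted values of column-wise least squares of `S` on
#' `Z`). The sign of each axis is fixed by making the largest-magnitude
#' entry of each `V` column positive.
#'
#' @param x For the data-frame method: a tibble of Timer-positive cells with
#'   `timer_angle`, `timer_intensity` and normalised marker columns. For the
#'   matrix method: the scaled marker matrix `S`.
#' @param ... Passed between methods.
#' @return Object of class `tocky_cca`: list with `S`, `Z`, `S_star`,
#'   `singular_values`, `U`, `V`, `wa_scores`, `lc_scores`, `arrows`,
#'   `axis_variance`, `rank`, `mode`.
#' @examples
#' set.seed(1)
#' S <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("A", "B", "C")))
#' Z <- cbind(Angle = rnorm(20), Intensity = rnorm(20))
#' fit <- tocky_cca(scale(S), scale(Z))
#' fit$axis_variance
#' @export
tocky_cca <- function(x, ...) UseMethod("tocky_cca")

#' @rdname tocky_cca
#' @param markers Marker column names (data-frame method); defaults to the
#'   `markers` attribute.
#' @param mode Timer standardisation mode, see [standardize_timer()].
#' @param ridge Non-negative ridge added to `Z'Z` as `ridge * I` when the
#'   Timer columns are close to collinear. Default 0.
#' @export
tocky_cca.data.frame <- function(x, markers = attr(x, "markers"),
                                 mode = c("default", "literal"),
                                 ridge = 0, ...) {
  mode <- match.arg(mode)
  if ("timer_positive" %in% names(x) && !all(x$timer_positive)) {
    x <- dplyr::filter(x, .data$timer_positive)
  }
  Z <- standardize_timer(x, mode = mode)
  S <- scale_markers(x, markers = markers)
  fit <- tocky_cca.matrix(S, Z, ridge = ridge)
  fit$mode <- mode
  fit
}

#' @rdname tocky_cca
#' @param Z The standardised n x 2 Timer matrix (matrix method).
#' @export
tocky_cca.matrix <- function(x, Z, ridge = 0, ...) {
  S <- x
  Z <- as.matrix(Z)
  stopifnot(nrow(S) == nrow(Z), ncol(Z) == 2, ridge >= 0)
  ZtZ <- crossprod(Z) + diag(ridge, 2)
  cond <- tryCatch(rcond(ZtZ), error = function(e) 0)
  if (!is.finite(cond) || cond < 1e-12) {
    stop("Z'Z is (near-)singular: Timer Angle and Intensity are collinear. ",
         "Consider a small `ridge` (adds ridge * I to Z'Z).", call. = FALSE)
  }
  # S* = Z (Z'Z)^-1 Z' S : fitted values of column-wise OLS of S on Z
  coef <- solve(ZtZ, crossprod(Z, S))
  S_star <- Z %*% coef

  sv <- svd(S_star)
  keep <- seq_len(min(2, length(sv$d)))
  d <- sv$d[keep]
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  rownames(V) <- colnames(S)
  # reproducible sign: largest-|entry| of each marker-score column positive
  for (j in seq_along(keep)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) {
      V[, j] <- -V[, j]
      U[, j] <- -U[, j]
    }
  }
  axes <- paste0("CCA", keep)
  colnames(U) <- colnames(V) <- axes
  wa <- S %*% V
  lc <- S_star %*% V
  colnames(wa) <- colnames(lc) <- axes
  arrows <- stats::cor(Z, wa)
  total <- sum(d^2)
  structure(
    list(
      S = S, Z = Z, S_star = S_star,
      singular_values = d, U = U, V = V,
      wa_scores = wa, lc_scores = lc,
      arrows = arrows,
      axis_variance = if (total > 0) d^2 / total else rep(NA_real_, length(d)),
      rank = sum(sv$d > max(sv$d[1], .Machine$double.eps) * 1e-8),
      mode = "matrix"
    ),
    class = "tocky_cca"
  )
}

#' @export
print.tocky_cca <- function(x, ...) {
  cat("<tocky_cca> ", nrow(x$S), " cells x ", ncol(x$S), " markers, ",
      "constrained by Timer Angle & Intensity\n", sep = "")
  cat("  singular values:", format(x$singular_values, digits = 4), "\n")
  cat("  axis variance:  ",
      paste0(format(100 * x$axis_variance, digits = 3), "%"), "\n")
  invisible(x)
}

#' Cell scores of a Tocky-CCA fit as a tibble
#'
#' @param fit A `tocky_cca` object.
#' @param type `"wa"` (weighted-average scores, `S V`) or `"lc"`
#'   (linear-combination scores, `S* V`).
#' @return Tibble with columns `CCA1`, `CCA2`.
#' @export
cca_scores <- function(fit, type = c("wa", "lc")) {
  stopifnot(inherits(fit, "tocky_cca"))
  type <- match.arg(type)
  tibble::as_tibble(if (type == "wa") fit$wa_scores else fit$lc_scores)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Marker scores of a Tocky-CCA fit
#'
#' @param x A `tocky_cca` object.
#' @param ... Unused.
#' @return Tibble with one row per marker: `marker`, `CCA1`, `CCA2`.
#' @method tidy tocky_cca
#' @export
tidy.tocky_cca <- function(x, ...) {
  tibble::tibble(
    marker = rownames(x$V),
    CCA1 = x$V[, 1],
    CCA2 = if (ncol(x$V) > 1) x$V[, 2] else NA_real_
  )
}

#' One-row summary of a Tocky-CCA fit
#'
#' @inheritParams tidy.tocky_cca
#' @return Tibble: `n_cells`, `n_markers`, singular values and per-axis
#'   variance fractions.
#' @method glance tocky_cca
#' @export
glance.tocky_cca <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$S),
    n_markers = ncol(x$S),
    sv1 = x$singular_values[1],
    sv2 = if (length(x$singular_values) > 1) x$singular_values[2] else NA_real_,
    axis1_variance = x$axis_variance[1],
    axis2_variance = if (length(x$axis_variance) > 1) x$axis_variance[2] else NA_real_
  )
}

#' Biplot of a Tocky-CCA solution
#'
#' Cells at their wa scores, coloured by Timer Angle (recovered from the
#' first `Z` column when available), with the Timer Angle and Intensity
#' correlation arrows overlaid.
#'
#' @param object A `tocky_cca` object.
#' @param type Which cell scores to draw. Default `"wa"`.
#' @param arrow_scale Multiplier applied to the unit-box arrows so they are
#'   visible at the score scale. Default: 80% of the score range.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tocky_cca
#' @export
autoplot.tocky_cca <- function(object, type = c("wa", "lc"),
                               arrow_scale = NULL, ...) {
  type <- match.arg(type)
  sc <- cca_scores(object, type)
  sc$angle <- object$Z[, "Angle"]
  if (is.null(arrow_scale)) {
    arrow_scale <- 0.8 * max(abs(as.matrix(sc[c("CCA1", "CCA2")])))
  }
  arr <- tibble::tibble(
    variable = rownames(object$arrows),
    x = object$arrows[, 1] * arrow_scale,
    y = object$arrows[, 2] * arrow_scale
  )
  ggplot2::ggplot(sc, ggplot2::aes(.data$CCA1, .data$CCA2)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$angle),
                        size = 0.4, alpha = 0.6) +
    ggplot2::scale_colour_viridis_c(name = "Std. Timer Angle") +
    ggplot2::geom_segment(
      data = arr,
      ggplot2::aes(x = 0, y = 0, xend = .data$x, yend = .data$y),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.2, "cm")),
      inherit.aes = FALSE
    ) +
    ggplot2::geom_text(
      data = arr,
      ggplot2::aes(.data$x, .data$y, label = .data$variable),
      vjust = -0.5, inherit.aes = FALSE
    ) +
    ggplot2::labs(x = "CCA1", y = "CCA2") +
    ggplot2::theme_minimal()
}
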