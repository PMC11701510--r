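#' Define a cytometry panel with autofluorescence and Timer thresholds
#'
#' A panel declares which channels of an exported cell table are surface
#' markers and which two carry the Fluorescent Timer blue and red signals,
#' together with the per-marker autofluorescence thresholds and the Timer
#' positivity thresholds. Thresholds are in the raw fluorescence units of the
#' export; values at or below a threshold are treated as background.
#'
#' @param markers Character vector of marker channel names.
#' @param timer_blue,timer_red Names of the Timer blue and red channels.
#' @param marker_thresholds Named numeric vector of autofluorescence
#'   thresholds, one per marker (raw fluorescence units, finite, >= 0).
#' @param timer_thresholds Numeric length-2 vector `c(blue, red)` of Timer
#'   positivity thresholds (raw units).
#'
#' @return An object of class `tocky_panel`.
#' @examples
#' tocky_panel(
#'   markers = c("CD4", "CD8"),
#'   timer_blue = "Timer.Blue", timer_red = "Timer.Red",
#'   marker_thresholds = c(CD4 = 1000, CD8 = 1000),
#'   timer_thresholds = c(400, 400)
#' )
#' @export
tocky_panel <- function(markers, timer_blue, timer_red,
                        marker_thresholds, timer_thresholds) {
  stopifnot(is.character(markers), length(markers) >= 1)
  if (!is.character(timer_blue) || !is.character(timer_red) ||
      length(timer_blue) != 1 || length(timer_red) != 1) {
    stop("`timer_blue` and `timer_red` must be single channel names.",
         call. = FALSE)
  }
  if (timer_blue == timer_red ||
      any(c(timer_blue, timer_red) %in% markers)) {
    stop("Timer channels must be distinct from each other and from markers.",
         call. = FALSE)
  }
  if (anyDuplicated(markers)) {
    stop("Marker channel names must be unique.", call. = FALSE)
  }
  marker_thresholds <- unlist(marker_thresholds)
  if (is.null(names(marker_thresholds)) ||
      !all(names(marker_thresholds) %in% markers)) {
    stop("Every name in `marker_thresholds` must be a declared marker.",
         call. = FALSE)
  }
  if (!all(markers %in% names(marker_thresholds))) {
    stop("A threshold is required for every marker; missing: ",
         paste(setdiff(markers, names(marker_thresholds)), collapse = ", "),
         call. = FALSE)
  }
  timer_thresholds <- unname(unlist(timer_thresholds))
  thr <- c(marker_thresholds, timer_thresholds)
  if (length(timer_thresholds) != 2 || !is.numeric(thr) ||
      any(!is.finite(thr)) || any(thr < 0)) {
    stop("All thresholds must be finite, non-negative numbers; ",
         "`timer_thresholds` must have length 2 (blue, red).", call. = FALSE)
  }
  structure(
    list(
      markers = markers,
      timer_blue = timer_blue,
      timer_red = timer_red,
      marker_thresholds = marker_thresholds[markers],
      timer_thresholds = c(blue = timer_thresholds[1],
                           red = timer_thresholds[2])
    ),
    class = "tocky_panel"
  )
}

#' @export
print.tocky_panel <- function(x, ...) {
  cat("<tocky_panel>\n")
  cat("  markers:    ", paste(x$markers, collapse = ", "), "\n")
  cat("  timer blue: ", x$timer_blue,
      " (threshold ", x$timer_thresholds[["blue"]], ")\n", sep = "")
  cat("  timer red:  ", x$timer_red,
      " (threshold ", x$timer_thresholds[["red"]], ")\n", sep = "")
  invisible(x)
}

#' All channels of a panel, markers first
#' @param panel A [tocky_panel()].
#' @return Character vector of channel names.
#' @export
panel_channels <- function(panel) {
  stopifnot(inherits(panel, "tocky_panel"))
  c(panel$markers, panel$timer_blue, panel$timer_red)
}

#' Read or write a panel configuration file
#'
#' Panels are stored as YAML with keys `markers`, `timer_blue`, `timer_red`,
#' `marker_thresholds` (a mapping) and `timer_thresholds` (`blue`, `red`).
#' The file replaces the interactive threshold-window sessions of manual
#' gating workflows with a declarative, versionable record.
#'
#' @param path Path to a YAML panel file.
#' @return `read_panel()` returns a [tocky_panel()]; `write_panel()` returns
#'   `path` invisibly.
#' @export
read_panel <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("markers", "timer_blue", "timer_red",
            "marker_thresholds", "timer_thresholds")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    stop("Panel file is missing fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tt <- cfg$timer_thresholds
  if (!is.null(names(tt))) tt <- c(tt[["blue"]], tt[["red"]])
  tocky_panel(
    markers = unlist(cfg$markers),
    timer_blue = cfg$timer_blue,
    timer_red = cfg$timer_red,
    marker_thresholds = unlist(cfg$marker_thresholds),
    timer_thresholds = unlist(tt)
  )
}

#' @rdname read_panel
#' @param panel A [tocky_panel()] to serialise.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "tocky_panel"))
  yaml::write_yaml(
    list(
      markers = as.list(panel$markers),
      timer_blue = panel$timer_blue,
      timer_red = panel$timer_red,
      marker_thresholds = as.list(panel$marker_thresholds),
      timer_thresholds = list(blue = unname(panel$timer_thresholds[["blue"]]),
                              red = unname(panel$timer_thresholds[["red"]]))
    ),
    path
  )
  invisible(path)
}
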