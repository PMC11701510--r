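#' Timer positivity from raw blue/red fluorescence
#'
#' A cell is Timer-positive when its blue fluorescence exceeds the blue
#' threshold or its red fluorescence exceeds the red threshold. The
#' comparison is strictly greater-than: thresholds mark the top of the
#' reporter-negative (wild-type) distribution, so a cell sitting exactly at
#' the threshold is still negative.
#'
#' @param blue,red Numeric vectors of raw Timer fluorescence, same length.
#' @param thresholds Numeric length-2 vector `c(blue, red)`, both >= 0.
#' @return Logical vector, one entry per cell.
#' @export
classify_timer_positive <- function(blue, red, thresholds) {
  if (length(blue) != length(red)) {
    stop("`blue` and `red` must have the same length.", call. = FALSE)
  }
  thresholds <- unname(unlist(thresholds))
  if (length(thresholds) != 2 || any(!is.finite(thresholds)) ||
      any(thresholds < 0)) {
    stop("`thresholds` must be two finite, non-negative numbers (blue, red).",
         call. = FALSE)
  }
  blue > thresholds[1] | red > thresholds[2]
}

#' Tocky locus of a Timer Angle
#'
#' Partitions the Timer Angle range into the five Tocky loci: `New` at
#' exactly 0 degrees (blue-only cells, transcription just begun), `NPt`
#' (New-to-Persistent transitional) strictly between 0 and 30, `Persistent`
#' from 30 to 60 inclusive, `PAt` (Persistent-to-Arrested transitional)
#' strictly between 60 and 90, and `Arrested` at exactly 90 degrees
#' (red-only cells, transcription ceased long ago). The five categories are
#' mutually exclusive and cover all of \[0, 90\].
#'
#' @param angle Numeric vector of Timer Angles in degrees; `NA` passes
#'   through. Values outside \[0, 90\] are an error.
#' @return Factor with levels `New`, `NPt`, `Persistent`, `PAt`, `Arrested`.
#' @examples
#' assign_tocky_locus(c(0, 15, 45, 75, 90))
#' @export
assign_tocky_locus <- function(angle) {
  ok <- is.na(angle) | (angle >= 0 & angle <= 90)
  if (!all(ok)) {
    stop("Timer Angle must lie in [0, 90] degrees; offending value: ",
         angle[!ok][1], call. = FALSE)
  }
  lab <- rep(NA_character_, length(angle))
  lab[angle == 0] <- "New"
  lab[angle > 0 & angle < 30] <- "NPt"
  lab[angle >= 30 & angle <= 60] <- "Persistent"
  lab[angle > 60 & angle < 90] <- "PAt"
  lab[angle == 90] <- "Arrested"
  factor(lab, levels = tocky_loci())
}

#' The five Tocky locus labels, in temporal order
#' @return Character vector of length 5.
#' @export
tocky_loci <- function() {
  c("New", "NPt", "Persistent", "PAt", "Arrested")
}

#' Transform Timer fluorescence into Timer Angle and Intensity
#'
#' Normalises the Timer blue and red channels and applies the trigonometric
#' transform: each channel has its positivity threshold subtracted, is
#' floored at zero, and is divided by the `norm_quantile` quantile of its
#' above-threshold values pooled across the whole table, so both channels
#' share a common unit scale and 45 degrees corresponds to balanced
#' blue/red signal. For Timer-positive cells the Timer Angle is the angle
#' from the blue axis in the normalised blue-red plane
#' (`atan2(red_norm, blue_norm)` in degrees, 0 = pure blue = newly
#' transcribing, 90 = pure red = arrested) and the Timer Intensity is the
#' Euclidean norm `sqrt(blue_norm^2 + red_norm^2)`, a correlate of
#' cumulative transcriptional activity. Timer-negative cells get `NA`
#' angle, intensity and locus.
#'
#' @param cells A data frame with the panel's Timer channels (e.g. from
#'   [read_cohort()]).
#' @param panel A [tocky_panel()].
#' @param norm_quantile Quantile of above-threshold values used as the
#'   per-channel scale. Default 0.95.
#' @return `cells` with columns `blue_norm`, `red_norm`, `timer_positive`,
#'   `timer_angle`, `timer_intensity` and `locus` appended.
#' @export
timer_transform <- function(cells, panel, norm_quantile = 0.95) {
  stopifnot(is.data.frame(cells), inherits(panel, "tocky_panel"))
  for (ch in c(panel$timer_blue, panel$timer_red)) {
    if (!ch %in% names(cells)) {
      stop("Timer channel '", ch, "' not found in `cells`.", call. = FALSE)
    }
  }
  blue <- cells[[panel$timer_blue]]
  red <- cells[[panel$timer_red]]
  thr <- panel$timer_thresholds
  positive <- classify_timer_positive(blue, red, thr)

  norm_channel <- function(x, theta) {
    clipped <- pmax(0, x - theta)
    above <- clipped[x > theta]
    if (length(above) == 0) {
      return(rep(0, length(x)))
    }
    scale <- stats::quantile(above, norm_quantile, names = FALSE)
    if (scale <= 0) scale <- max(above)
    clipped / scale
  }
  blue_norm <- norm_channel(blue, thr[["blue"]])
  red_norm <- norm_channel(red, thr[["red"]])

  out <- cells
  out$blue_norm <- blue_norm
  out$red_norm <- red_norm
  # a cell whose both normalised channels are 0 carries no Timer signal
  positive <- positive & (blue_norm > 0 | red_norm > 0)
  out$timer_positive <- positive

  angle <- rep(NA_real_, nrow(out))
  intensity <- rep(NA_real_, nrow(out))
  if (!any(positive)) {
    warning("No Timer-positive cells; angle, intensity and locus are all NA.",
            call. = FALSE)
  } else {
    angle[positive] <- atan2(red_norm[positive], blue_norm[positive]) * 180 / pi
    intensity[positive] <- sqrt(blue_norm[positive]^2 + red_norm[positive]^2)
  }
  out$timer_angle <- angle
  out$timer_intensity <- intensity
  out$locus <- assign_tocky_locus(angle)
  tibble::as_tibble(out)
}
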