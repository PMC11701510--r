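#' Parameters of the Fluorescent Timer kinetics simulator
#'
#' The Fast-FT reporter is modelled by two coupled first-order processes:
#' newly translated blue protein `B` is produced at the transcription rate
#' `k(t)` and irreversibly matures into red protein `R` with rate
#' `m = ln(2) / maturation_half_life`; the mature red protein decays with
#' rate `delta = ln(2) / decay_half_life`. The defaults are the Fast-FT
#' constants: maturation half-life 4.1 h, red decay half-life 122 h. The
#' transcription program is a single piecewise-constant window: rate `rate`
#' from `onset` until `stop` (or ongoing when `stop = Inf`). An optional
#' extra blue degradation rate (default 0, i.e. blue loss is maturation
#' only) is folded into the blue decay term.
#'
#' @param maturation_half_life Blue-to-red maturation half-life, hours.
#'   Default 4.1.
#' @param decay_half_life Red decay half-life, hours. Default 122.
#' @param blue_decay_half_life Optional additional blue degradation
#'   half-life, hours; `Inf` (default) disables it.
#' @param onset Transcription onset time, hours.
#' @param rate Transcription rate, molecules per hour, >= 0.
#' @param stop Transcription stop time, hours (`Inf` = persistent).
#' @param gain Fluorescence units per molecule. Default 1.
#' @param noise_sigma Lognormal noise sigma applied multiplicatively to
#'   each observed channel. Default 0 (noiseless).
#' @param autofluorescence_mean,autofluorescence_sd Additive Gaussian
#'   background per channel. Defaults 0 (none).
#' @return List of class `timer_kinetics_params`.
#' @export
timer_kinetics_params <- function(maturation_half_life = 4.1,
                                  decay_half_life = 122,
                                  blue_decay_half_life = Inf,
                                  onset = 0, rate = 100, stop = Inf,
                                  gain = 1, noise_sigma = 0,
                                  autofluorescence_mean = 0,
                                  autofluorescence_sd = 0) {
  if (maturation_half_life <= 0 || decay_half_life <= 0 ||
      blue_decay_half_life <= 0) {
    stop("Half-lives must be positive.", call. = FALSE)
  }
  if (rate < 0) stop("Transcription rate must be >= 0.", call. = FALSE)
  if (stop < onset) stop("`stop` must not precede `onset`.", call. = FALSE)
  structure(
    list(
      maturation_half_life = maturation_half_life,
      decay_half_life = decay_half_life,
      blue_decay_half_life = blue_decay_half_life,
      m = log(2) / maturation_half_life,
      delta = log(2) / decay_half_life,
      onset = onset, rate = rate, stop = stop,
      gain = gain, noise_sigma = noise_sigma,
      autofluorescence_mean = autofluorescence_mean,
      autofluorescence_sd = autofluorescence_sd
    ),
    class = "timer_kinetics_params"
  )
}

# Propagate (B0, R0) over an interval of length dt with constant
# transcription rate k, using the closed-form solution of
#   dB/dt = k - a B,   dR/dt = m B - delta R
# where a = m + extra blue decay. Vectorised over dt.
timer_step <- function(B0, R0, k, dt, m, delta, a = m) {
  Bss <- if (a > 0) k / a else k * dt # a = 0 never occurs (m > 0)
  eB <- exp(-a * dt)
  eD <- exp(-delta * dt)
  B <- Bss + (B0 - Bss) * eB
  if (abs(delta - a) > 1e-10 * max(delta, a)) {
    trans <- (B0 - Bss) * (eB - eD) / (delta - a)
  } else {
    trans <- (B0 - Bss) * dt * eB
  }
  R <- R0 * eD + m * (Bss * (1 - eD) / delta + trans)
  list(B = B, R = R)
}

#' Blue/red Timer state for cells with heterogeneous programs
#'
#' Closed-form molecule counts at observation time for cells that switched
#' transcription on `age` hours ago, kept it running for `on_duration`
#' hours, and have been silent since. Vectorised over cells.
#'
#' @param age Hours since transcription onset (per cell, >= 0).
#' @param on_duration Hours of active transcription (per cell,
#'   `0 <= on_duration <= age`; `on_duration = age` means still
#'   transcribing).
#' @param rate Transcription rate, molecules/hour (scalar or per cell).
#' @param params A [timer_kinetics_params()] (its `onset`/`stop`/`rate`
#'   fields are ignored here; only the kinetic constants are used).
#' @return Tibble with columns `blue_molecules`, `red_molecules`.
#' @export
timer_state <- function(age, on_duration, rate,
                        params = timer_kinetics_params()) {
  stopifnot(inherits(params, "timer_kinetics_params"),
            all(age >= 0), all(on_duration >= 0),
            all(on_duration <= age + 1e-9))
  m <- params$m
  delta <- params$delta
  a <- m + log(2) / params$blue_decay_half_life
  on <- timer_step(0, 0, rate, on_duration, m, delta, a)
  off <- timer_step(on$B, on$R, 0, age - on_duration, m, delta, a)
  tibble::tibble(blue_molecules = off$B, red_molecules = off$R)
}

#' Simulate a Timer kinetics time course
#'
#' Solves the Timer ODE system under the params' transcription window with
#' the piecewise closed form and returns molecule trajectories together
#' with observed fluorescence (gain x molecules x lognormal noise +
#' additive autofluorescence). With `noise_sigma = 0` and no
#' autofluorescence the observed channels equal the noiseless solution.
#'
#' @param times Numeric vector of observation times (hours), each `>=`
#'   `params$onset`.
#' @param params A [timer_kinetics_params()].
#' @return Tibble: `time`, `blue_molecules`, `red_molecules`, `blue`,
#'   `red`.
#' @examples
#' p <- timer_kinetics_params(onset = -48, rate = 100, stop = 0)
#' simulate_timer_kinetics(c(0, 4.1, 8.2), p)
#' @export
simulate_timer_kinetics <- function(times, params = timer_kinetics_params()) {
  stopifnot(inherits(params, "timer_kinetics_params"))
  if (any(times < params$onset)) {
    stop("Observation times must not precede the transcription onset.",
         call. = FALSE)
  }
  m <- params$m
  delta <- params$delta
  a <- m + log(2) / params$blue_decay_half_life
  age <- times - params$onset
  on_dur <- pmin(age, max(0, params$stop - params$onset))
  st <- timer_state(age, on_dur, params$rate, params)
  noise <- function(n) {
    if (params$noise_sigma > 0) {
      stats::rlnorm(n, meanlog = -params$noise_sigma^2 / 2,
                    sdlog = params$noise_sigma)
    } else rep(1, n)
  }
  af <- function(n) {
    if (params$autofluorescence_sd > 0 || params$autofluorescence_mean != 0) {
      stats::rnorm(n, params$autofluorescence_mean, params$autofluorescence_sd)
    } else rep(0, n)
  }
  n <- length(times)
  tibble::tibble(
    time = times,
    blue_molecules = st$blue_molecules,
    red_molecules = st$red_molecules,
    blue = params$gain * st$blue_molecules * noise(n) + af(n),
    red = params$gain * st$red_molecules * noise(n) + af(n)
  )
}

#' Half-life from a log-linear fit to a decay curve
#'
#' Fits `log(y) ~ t` by ordinary least squares over the strictly positive
#' part of the curve and returns `-log(2) / slope`.
#'
#' @param time,value Numeric vectors of equal length.
#' @return Fitted half-life (hours).
#' @export
fit_half_life <- function(time, value) {
  keep <- is.finite(value) & value > 0
  if (sum(keep) < 3) {
    stop("Need at least 3 positive observations to fit a half-life.",
         call. = FALSE)
  }
  fit <- stats::lm(log(value[keep]) ~ time[keep])
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) {
    stop("Curve is not decaying; cannot report a half-life.", call. = FALSE)
  }
  -log(2) / slope
}
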