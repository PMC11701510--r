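#' Gaussian spike-in clustering benchmark
#'
#' Emulates the standard benchmark for autofluorescence-aware clustering:
#' most cells are drawn from multivariate-Gaussian background components —
#' several purely autofluorescent modes whose structure lives entirely
#' below the per-marker thresholds, plus genuinely positive populations —
#' and a small fraction of target cells is spiked in with a bright
#' signature on the last two markers. The per-cell ground truth makes
#' recovery scoring ([evaluate_spike_recovery()]) exact.
#'
#' @param n_cells Total number of cells. Default 10000.
#' @param n_markers Number of markers (>= 3). Default 5.
#' @param n_background Number of background components; the first
#'   `ceiling(2/3 * n_background)` are autofluorescence modes, the rest are
#'   positive populations. Default 6.
#' @param spike_fraction Fraction of cells that are targets, in (0, 1).
#'   Default 0.02; the spike count is `round(spike_fraction * n_cells)`.
#' @param spike_mean,spike_sd Raw-unit location and spread of the spike
#'   signature on its bright markers. Defaults 3000 and 400: clearly above
#'   threshold and separated from the sub-threshold background.
#' @param bimodal When `TRUE` the spike signature has two modes (at
#'   `spike_mean` +/- 700). Default `FALSE`.
#' @param threshold Per-marker autofluorescence threshold (raw units).
#'   Default 1000.
#' @param seed Integer seed; same seed and arguments give identical output.
#' @return List with `cells` (tibble of marker columns `M1..Mp` plus dummy
#'   Timer channels), `truth` (tibble: `cell`, `is_spike`, `component`),
#'   and `panel` (a [tocky_panel()] with the thresholds used).
#' @export
simulate_spikein_benchmark <- function(n_cells = 10000, n_markers = 5,
                                       n_background = 6,
                                       spike_fraction = 0.02,
                                       spike_mean = 3000, spike_sd = 400,
                                       bimodal = FALSE, threshold = 1000,
                                       seed = 1) {
  stopifnot(n_markers >= 3, n_background >= 2,
            spike_fraction > 0, spike_fraction < 1)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  p <- n_markers
  markers <- paste0("M", seq_len(p))

  n_spike <- round(spike_fraction * n_cells)
  n_bg <- n_cells - n_spike
  n_af <- ceiling(2 / 3 * n_background)
  n_pos <- n_background - n_af

  # autofluorescence modes: sub-threshold by construction (their spread is
  # clipped just under the threshold), with mode-specific means and a
  # shared per-cell brightness factor. The resulting correlated,
  # multi-modal sub-threshold structure is what an unthresholded
  # clustering wastes clusters on; thresholding maps all of it to zero.
  # Positive populations are bright on a sliding marker pair.
  af_means <- matrix(stats::runif(n_af * p, 0.1 * threshold, 0.7 * threshold),
                     n_af, p)
  clip_af <- function(x) pmin(pmax(x, 0), 0.98 * threshold)
  pos_means <- matrix(0.4 * threshold, n_pos, p)
  for (i in seq_len(n_pos)) {
    bright <- ((i - 1) %% max(1, p - 2)) + c(1, 2)
    pos_means[i, bright] <- stats::runif(2, 2.5, 4) * threshold
  }
  # autofluorescent cells dominate, as in real panels
  weights <- c(rep(0.7 / n_af, n_af), rep(0.3 / max(1, n_pos), n_pos))
  comp <- sample.int(n_background, n_bg, replace = TRUE, prob = weights)
  is_af <- comp <= n_af
  brightness <- ifelse(is_af, stats::rlnorm(n_bg, 0, 0.3), 1)
  X_bg <- rbind(af_means, pos_means)[comp, , drop = FALSE] * brightness *
    matrix(stats::rlnorm(n_bg * p, 0, 0.25), n_bg, p)
  X_bg[is_af, ] <- clip_af(X_bg[is_af, , drop = FALSE])

  # spike signature: bright on the last two markers only, autofluorescent
  # elsewhere
  spike_cols <- c(p - 1, p)
  sp_base <- stats::runif(p, 0.1 * threshold, 0.7 * threshold)
  X_sp <- clip_af(
    matrix(sp_base, n_spike, p, byrow = TRUE) *
      stats::rlnorm(n_spike, 0, 0.3) *
      matrix(stats::rlnorm(n_spike * p, 0, 0.25), n_spike, p)
  )
  centre <- if (bimodal) {
    sample(c(spike_mean - 700, spike_mean + 700), n_spike, replace = TRUE)
  } else rep(spike_mean, n_spike)
  for (j in spike_cols) {
    X_sp[, j] <- centre + stats::rnorm(n_spike, sd = spike_sd)
  }

  X <- rbind(X_bg, X_sp)
  colnames(X) <- markers
  ord <- sample.int(n_cells)
  X <- X[ord, , drop = FALSE]
  truth <- tibble::tibble(
    cell = seq_len(n_cells),
    is_spike = c(rep(FALSE, n_bg), rep(TRUE, n_spike))[ord],
    component = c(comp, rep(n_background + 1L, n_spike))[ord]
  )
  cells <- tibble::as_tibble(X)
  cells$Timer.Blue <- stats::rnorm(n_cells, 100, 50)
  cells$Timer.Red <- stats::rnorm(n_cells, 100, 50)
  panel <- tocky_panel(
    markers = markers,
    timer_blue = "Timer.Blue", timer_red = "Timer.Red",
    marker_thresholds = stats::setNames(rep(threshold, p), markers),
    timer_thresholds = c(400, 400)
  )
  list(cells = cells, truth = truth, panel = panel)
}

#' Default archetype chain for the cohort simulator
#'
#' Five developmental archetypes forming a chain in marker space with
#' progressively older transcription-onset ages: early cells transcribe
#' persistently (blue-dominant, New/NPt loci), middle cells have matured
#' red signal alongside blue (Persistent locus), and late archetypes have
#' switched transcription off long enough ago that blue has decayed
#' (PAt/Arrested loci). The chain is encoded by a sliding bright-marker
#' pair over six markers: archetype i is bright (mean 3500) on markers
#' `M<i>` and `M<i+1>` and at autofluorescence level (mean 300, threshold
#' 1000) elsewhere, so consecutive archetypes share one bright marker and
#' sit at a constant marker-space distance while any skip is strictly
#' farther — the geometry of a planted developmental trajectory.
#' Onset/stop ages are hours before the observation.
#'
#' @return Tibble, one row per archetype: `archetype`, `weight`, marker
#'   mean columns `M1..M6`, `age_min`, `age_max`, `off_min`, `off_max`.
#' @export
cohort_archetypes <- function() {
  bright <- 3500
  base <- 300
  means <- matrix(base, 5, 6, dimnames = list(NULL, paste0("M", 1:6)))
  for (i in 1:5) means[i, c(i, i + 1)] <- bright
  dplyr::bind_cols(
    tibble::tibble(archetype = 1:5,
                   weight = c(0.24, 0.22, 0.20, 0.18, 0.16)),
    tibble::as_tibble(means),
    tibble::tibble(
      age_min = c(2, 12, 36, 90, 160),
      age_max = c(12, 36, 90, 180, 300),
      off_min = c(0, 0, 0, 2, 24),  # hours since transcription stopped
      off_max = c(0, 0, 0, 8, 60)
    )
  )
}

#' Simulate a two-group Timer cohort with a planted trajectory
#'
#' Generates per-sample cell tables for a control and a knockout (KO)
#' group. Each cell belongs to one archetype of a developmental chain
#' (see [cohort_archetypes()]): its markers are drawn from the archetype's
#' Gaussian, and its Timer blue/red fluorescence follows the Fast-FT
#' kinetics ([timer_state()]) for an onset age drawn from the archetype's
#' age window, so later archetypes carry larger Timer Angles. KO samples
#' multiply the abundance of the last (latest) archetype by
#' `ko_multiplier`, planting a late-locus accumulation of known direction.
#' Marker and Timer channels receive multiplicative lognormal noise and
#' additive Gaussian autofluorescence.
#'
#' @param n_control,n_ko Samples per group. Defaults 6 and 8.
#' @param cells_per_sample Cells per sample. Default 1000.
#' @param ko_multiplier Abundance multiplier (>= 1) applied to the last
#'   archetype in KO samples. Default 3.
#' @param archetypes Archetype table, see [cohort_archetypes()].
#' @param rate Transcription rate while active, molecules/h. Default 200.
#' @param noise_sigma Lognormal channel noise sigma. Default 0.25.
#' @param marker_sd Additive Gaussian marker noise, raw units. Default 300.
#' @param seed Integer seed.
#' @param write_dir Optional directory; when given, per-sample CSVs and a
#'   `manifest.csv` are written there (the CSV dialect of
#'   [read_cell_table()]) and their paths recorded in the manifest.
#' @param params Kinetic constants, a [timer_kinetics_params()].
#' @return List with `cells` (all samples bound, with `sample_id` and
#'   `group`), `manifest`, `truth` (per-cell `archetype`, `onset_age`,
#'   `on_duration`), `panel`, and `write_dir`.
#' @export
simulate_cohort <- function(n_control = 6, n_ko = 8,
                            cells_per_sample = 1000, ko_multiplier = 3,
                            archetypes = cohort_archetypes(), rate = 200,
                            noise_sigma = 0.25, marker_sd = 300, seed = 1,
                            write_dir = NULL,
                            params = timer_kinetics_params()) {
  stopifnot(n_control >= 1, n_ko >= 1, ko_multiplier >= 1,
            nrow(archetypes) >= 2)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  arch <- archetypes
  n_arch <- nrow(arch)
  markers <- setdiff(names(arch),
                     c("archetype", "weight", "age_min", "age_max",
                       "off_min", "off_max"))
  af_mean <- 150
  af_sd <- 80

  sample_tbl <- tibble::tibble(
    sample_id = c(sprintf("ctrl_%02d", seq_len(n_control)),
                  sprintf("ko_%02d", seq_len(n_ko))),
    group = c(rep("control", n_control), rep("KO", n_ko))
  )

  one_sample <- function(sample_id, group) {
    w <- arch$weight
    if (group == "KO") w[n_arch] <- w[n_arch] * ko_multiplier
    w <- w / sum(w)
    a <- sample.int(n_arch, cells_per_sample, replace = TRUE, prob = w)
    age <- stats::runif(cells_per_sample, arch$age_min[a], arch$age_max[a])
    off <- stats::runif(cells_per_sample, arch$off_min[a], arch$off_max[a])
    off <- pmin(off, age)
    st <- timer_state(age, age - off, rate, params)
    lnoise <- function(n) stats::rlnorm(n, -noise_sigma^2 / 2, noise_sigma)
    af <- function(n) stats::rnorm(n, af_mean, af_sd)
    n <- cells_per_sample
    out <- tibble::tibble(sample_id = rep(sample_id, n),
                          group = rep(group, n))
    for (mk in markers) {
      out[[mk]] <- arch[[mk]][a] * lnoise(n) +
        stats::rnorm(n, 0, marker_sd)
    }
    out$Timer.Blue <- st$blue_molecules * lnoise(n) + af(n)
    out$Timer.Red <- st$red_molecules * lnoise(n) + af(n)
    list(cells = out,
         truth = tibble::tibble(sample_id = sample_id, archetype = a,
                                onset_age = age, on_duration = age - off))
  }

  sims <- purrr::pmap(sample_tbl, one_sample)
  cells <- dplyr::bind_rows(purrr::map(sims, "cells"))
  truth <- dplyr::bind_rows(purrr::map(sims, "truth"))

  panel <- tocky_panel(
    markers = markers,
    timer_blue = "Timer.Blue", timer_red = "Timer.Red",
    marker_thresholds = stats::setNames(rep(1000, length(markers)), markers),
    timer_thresholds = c(400, 400)
  )
  manifest <- tibble::tibble(
    file = paste0(sample_tbl$sample_id, ".csv"),
    sample = sample_tbl$sample_id,
    group = sample_tbl$group
  )
  if (!is.null(write_dir)) {
    dir.create(write_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(manifest))) {
      sub <- cells[cells$sample_id == manifest$sample[i],
                   c(markers, "Timer.Blue", "Timer.Red")]
      readr::write_csv(sub, file.path(write_dir, manifest$file[i]),
                       progress = FALSE)
    }
    readr::write_csv(manifest, file.path(write_dir, "manifest.csv"),
                     progress = FALSE)
  }
  list(cells = cells, manifest = manifest, truth = truth, panel = panel,
       write_dir = write_dir)
}
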