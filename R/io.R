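#' Read one exported cell table
#'
#' Reads a flow-cytometry export (comma-separated, header row of channel
#' names, UTF-8, `.` decimal — the scale-value CSV dialect) and returns the
#' declared panel channels in declared order, markers first. Extra columns in
#' the file are dropped; row order is preserved. Compensation, doublet
#' exclusion and live/dead gating are assumed done upstream, and values are
#' treated as linear raw fluorescence units.
#'
#' @param path Path to a CSV file with one row per cell and one column per
#'   channel.
#' @param panel A [tocky_panel()]; every panel channel must be present.
#' @return A tibble with one row per cell and the panel's channels as
#'   columns, all numeric.
#' @export
read_cell_table <- function(path, panel) {
  stopifnot(inherits(panel, "tocky_panel"))
  if (!file.exists(path)) {
    stop("Cell table not found: ", path, call. = FALSE)
  }
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         name_repair = "minimal")
  if (nrow(dat) == 0 && ncol(dat) == 0) {
    stop("Empty cell table: ", path, call. = FALSE)
  }
  chans <- panel_channels(panel)
  missing <- setdiff(chans, names(dat))
  if (length(missing)) {
    stop("Cell table ", path, " lacks declared channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dat <- dat[chans]
  bad <- !vapply(dat, is.numeric, logical(1))
  if (any(bad)) {
    col <- names(dat)[bad][1]
    row <- which(is.na(suppressWarnings(as.numeric(dat[[col]]))) |
                   !grepl("^\\s*-?[0-9.eE+]+\\s*$", as.character(dat[[col]])))[1]
    stop("Non-numeric value in ", path, " column '", col, "'",
         if (!is.na(row)) paste0(", row ", row), call. = FALSE)
  }
  if (anyNA(dat) || !all(vapply(dat, function(x) all(is.finite(x)), logical(1)))) {
    stop("Cell table ", path, " contains missing or non-finite values.",
         call. = FALSE)
  }
  tibble::as_tibble(dat)
}

#' Read a cohort manifest
#'
#' A manifest is a CSV with columns `file`, `sample` and `group` listing each
#' sample's cell-table export, a unique sample id, and its experimental group
#' label. Referenced files are not opened here; unreadable paths surface when
#' the cohort is loaded.
#'
#' @param path Path to the manifest CSV.
#' @return A tibble with columns `file`, `sample`, `group` (entries in file
#'   order) and attribute `groups` holding the distinct group labels.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop("Manifest not found: ", path, call. = FALSE)
  }
  man <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("file", "sample", "group")
  missing <- setdiff(need, names(man))
  if (length(missing)) {
    stop("Manifest must have columns file, sample, group; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  man <- man[need]
  if (nrow(man) < 1) stop("Manifest has no entries.", call. = FALSE)
  if (anyDuplicated(man$sample)) {
    stop("Duplicated sample id(s): ",
         paste(unique(man$sample[duplicated(man$sample)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(man$group)) || any(!nzchar(man$group))) {
    stop("Group labels must be non-empty strings.", call. = FALSE)
  }
  attr(man, "groups") <- unique(man$group)
  man
}

#' Load every sample of a cohort into one cell table
#'
#' Reads each manifest entry with [read_cell_table()] and binds the samples
#' into a single tibble with `sample_id` and `group` columns prepended. Paths
#' in the manifest are resolved relative to `base_dir` unless absolute.
#'
#' @param manifest A manifest tibble from [read_manifest()] (or any data
#'   frame with columns `file`, `sample`, `group`).
#' @param panel A [tocky_panel()].
#' @param base_dir Directory against which relative manifest paths are
#'   resolved. Default `"."`.
#' @return A tibble: `sample_id`, `group`, then the panel channels.
#' @export
read_cohort <- function(manifest, panel, base_dir = ".") {
  stopifnot(is.data.frame(manifest),
            all(c("file", "sample", "group") %in% names(manifest)))
  purrr::pmap(manifest[c("file", "sample", "group")],
              function(file, sample, group) {
                p <- if (grepl("^(/|[A-Za-z]:)", file)) file
                     else file.path(base_dir, file)
                cells <- read_cell_table(p, panel)
                dplyr::bind_cols(
                  tibble::tibble(sample_id = sample, group = group,
                                 .rows = nrow(cells)),
                  cells
                )
              }) |>
    dplyr::bind_rows()
}
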