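# Ingest: CSV readers for the four input tables and placement of all series
# on the common 15-minute grid.

read_table_checked <- function(path, columns, required, what) {
  if (!file.exists(path)) stop(sprintf("%s file not found: %s", what, path))
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tbl) == 0) stop(sprintf("empty %s file: %s", what, path))
  for (std in names(columns)) {
    src <- columns[[std]]
    if (src %in% names(tbl)) names(tbl)[names(tbl) == src] <- std
  }
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    stop(sprintf("column %s absent from %s file", missing[1], what))
  }
  tbl
}

parse_timestamps <- function(x, what) {
  if (inherits(x, "POSIXct")) {
    out <- as.POSIXct(format(x, tz = "UTC"), tz = "UTC")
  } else {
    out <- as.POSIXct(as.character(x), tz = "UTC",
                      tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                                     "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                     "%Y-%m-%d"),
                      optional = TRUE)
  }
  n_bad <- sum(is.na(out) & !is.na(x))
  if (n_bad > 0) message(sprintf("%s: %d unparseable timestamp(s) dropped", what, n_bad))
  out
}

#' Read a band-logger record table
#'
#' Expects a CSV with one row per logger sample: tree id, timestamp, sensor
#' position (mm, relative scale) and band temperature (degC). Duplicate
#' timestamps within a tree are collapsed keep-last; unparseable timestamps
#' are dropped and counted.
#'
#' @param path CSV file path.
#' @param columns named list mapping standard names (`tree_id`, `timestamp`,
#'   `position`, `band_temp`) to the file's column names; defaults to the
#'   standard names themselves.
#' @return tibble with columns `tree_id`, `timestamp` (POSIXct), `position`,
#'   `band_temp`, sorted and strictly increasing in time per tree.
#' @export
read_band_log <- function(path, columns = list()) {
  std <- list(tree_id = "tree_id", timestamp = "timestamp",
              position = "position", band_temp = "band_temp")
  std[names(columns)] <- columns
  columns <- setNames(unlist(std), names(std))
  tbl <- read_table_checked(path, columns,
                            c("tree_id", "timestamp", "position"), "band log")
  tbl$timestamp <- parse_timestamps(tbl$timestamp, "band log")
  tbl <- tbl[!is.na(tbl$timestamp), , drop = FALSE]
  if (!"band_temp" %in% names(tbl)) tbl$band_temp <- NA_real_
  tbl$position <- as.numeric(tbl$position)
  tbl$position[!is.finite(tbl$position)] <- NA_real_
  tbl <- dplyr::arrange(tbl, .data$tree_id, .data$timestamp)
  n0 <- nrow(tbl)
  tbl <- dplyr::slice_tail(
    dplyr::group_by(tbl, .data$tree_id, .data$timestamp), n = 1)
  tbl <- dplyr::ungroup(tbl)
  n_dup <- n0 - nrow(tbl)
  if (n_dup > 0) message(sprintf("band log: %d duplicate timestamp(s) collapsed keep-last", n_dup))
  attr(tbl, "n_duplicates") <- n_dup
  tibble::as_tibble(tbl[, c("tree_id", "timestamp", "position", "band_temp")])
}

#' Read manual caliper checks of the band measurement window
#'
#' @inheritParams read_band_log
#' @param columns mapping for `tree_id`, `visit_time`, `window_width`.
#' @return tibble `tree_id`, `visit_time`, `window_width` (mm, > 0).
#' @export
read_manual_checks <- function(path, columns = list()) {
  std <- list(tree_id = "tree_id", visit_time = "visit_time",
              window_width = "window_width")
  std[names(columns)] <- columns
  tbl <- read_table_checked(path, std,
                            c("tree_id", "visit_time", "window_width"),
                            "manual checks")
  tbl$visit_time <- parse_timestamps(tbl$visit_time, "manual checks")
  tbl$window_width <- as.numeric(tbl$window_width)
  bad <- is.na(tbl$visit_time) | !is.finite(tbl$window_width) | tbl$window_width <= 0
  if (any(bad)) warning(sprintf("manual checks: %d invalid row(s) dropped", sum(bad)))
  tibble::as_tibble(dplyr::arrange(tbl[!bad, c("tree_id", "visit_time", "window_width")],
                                   .data$tree_id, .data$visit_time))
}

#' Read a weather / biomicrometeorology table
#'
#' Required columns: `timestamp`, `t_air` (degC), `rh` (%), `ppt` (mm per
#' interval), `rad` (W m-2). Optional: `et`, and any number of per-probe sap
#' flux columns named `sf_<genus>_<probe>` (genus must not contain an
#' underscore). Rows violating unit ranges (rh outside 0-100, negative ppt
#' or rad) are rejected with a warning.
#'
#' @inheritParams read_band_log
#' @return tibble; attribute `sf_present` flags whether sap-flux columns exist.
#' @export
read_met <- function(path, columns = list()) {
  std <- list(timestamp = "timestamp", t_air = "t_air", rh = "rh",
              ppt = "ppt", rad = "rad", et = "et")
  std[names(columns)] <- columns
  tbl <- read_table_checked(path, std,
                            c("timestamp", "t_air", "rh", "ppt", "rad"), "met")
  tbl$timestamp <- parse_timestamps(tbl$timestamp, "met")
  tbl <- tbl[!is.na(tbl$timestamp), , drop = FALSE]
  for (v in intersect(c("t_air", "rh", "ppt", "rad", "et"), names(tbl))) {
    tbl[[v]] <- as.numeric(tbl[[v]])
  }
  bad <- (!is.na(tbl$rh) & (tbl$rh < 0 | tbl$rh > 100)) |
    (!is.na(tbl$ppt) & tbl$ppt < 0) |
    (!is.na(tbl$rad) & tbl$rad < 0)
  if (any(bad)) warning(sprintf("met: %d row(s) outside unit ranges rejected", sum(bad)))
  tbl <- tbl[!bad, , drop = FALSE]
  sf_cols <- grep("^sf_", names(tbl), value = TRUE)
  out <- tibble::as_tibble(dplyr::arrange(tbl, .data$timestamp))
  attr(out, "sf_present") <- length(sf_cols) > 0 && any(!is.na(unlist(tbl[sf_cols])))
  out
}

#' Read tree metadata
#'
#' @inheritParams read_band_log
#' @return tibble `tree_id`, `site`, `species`, `dbh` (cm), `status`
#'   (live/dead), `bark_class` (thin/thick, may be NA for dead trees),
#'   `irrigated` (logical).
#' @export
read_meta <- function(path, columns = list()) {
  std <- list(tree_id = "tree_id", site = "site", species = "species",
              dbh = "dbh", status = "status", bark_class = "bark_class",
              irrigated = "irrigated")
  std[names(columns)] <- columns
  tbl <- read_table_checked(path, std, c("tree_id", "site", "dbh", "status"),
                            "metadata")
  if (!"species" %in% names(tbl)) tbl$species <- NA_character_
  if (!"bark_class" %in% names(tbl)) tbl$bark_class <- NA_character_
  if (!"irrigated" %in% names(tbl)) tbl$irrigated <- FALSE
  tbl$dbh <- as.numeric(tbl$dbh)
  tbl$irrigated <- as.logical(tbl$irrigated) %na0% FALSE
  bad <- !is.finite(tbl$dbh) | tbl$dbh <= 0 | !tbl$status %in% c("live", "dead")
  if (any(bad)) warning(sprintf("metadata: %d invalid row(s) dropped", sum(bad)))
  tibble::as_tibble(tbl[!bad, c("tree_id", "site", "species", "dbh", "status",
                                "bark_class", "irrigated")])
}

#' Resample a timestamped series onto the 15-minute grid
#'
#' Lower-frequency sources are linearly interpolated; higher-frequency
#' sources are aggregated into the half-open interval (t - 15 min, t]
#' assigned to grid point t (mean for state variables, sum for
#' precipitation). Interpolation never extrapolates: grid points outside the
#' source span are gaps.
#'
#' @param time source timestamps (sorted).
#' @param value source values.
#' @param grid target grid from [band_grid()].
#' @param mode one of `"interpolate"`, `"aggregate_mean"`, `"aggregate_sum"`.
#' @return numeric vector along `grid`, NA at gaps.
#' @export
resample_to_grid <- function(time, value,
                             grid, mode = c("interpolate", "aggregate_mean",
                                            "aggregate_sum")) {
  mode <- match.arg(mode)
  keep <- !is.na(time) & !is.na(value)
  if (!any(keep)) {
    warning("resample_to_grid: empty source series, returning all gaps")
    return(rep(NA_real_, length(grid)))
  }
  time <- time[keep]; value <- value[keep]
  ord <- order(time)
  time <- time[ord]; value <- value[ord]
  dup <- duplicated(time, fromLast = TRUE)
  time <- time[!dup]; value <- value[!dup]
  if (mode == "interpolate") {
    if (length(time) == 1) {
      out <- rep(NA_real_, length(grid))
      hit <- which(abs(as.numeric(grid) - as.numeric(time)) < 1e-6)
      out[hit] <- value
      return(out)
    }
    return(approx(as.numeric(time), value, xout = as.numeric(grid),
                  method = "linear", rule = 1)$y)
  }
  secs <- as.numeric(time) - (as.numeric(grid[1]) - GRID_STEP_SEC)
  idx <- ceiling(secs / GRID_STEP_SEC - 1e-9)
  ok <- idx >= 1 & idx <= length(grid)
  out <- rep(NA_real_, length(grid))
  if (any(ok)) {
    f <- if (mode == "aggregate_sum") sum else mean
    agg <- tapply(value[ok], idx[ok], f)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  out
}

#' Per-genus ensemble sap flux (median across probes)
#'
#' Takes a met table whose sap-flux columns follow the `sf_<genus>_<probe>`
#' convention and returns, per timestamp and genus, the median across that
#' genus's probes ignoring gaps.
#'
#' @param met tibble from [read_met()] (or any table with `timestamp` and
#'   `sf_*` columns).
#' @return tibble with `timestamp` and one `sf_<genus>` column per genus, or
#'   NULL if no sap-flux columns are present.
#' @export
genus_ensemble_sf <- function(met) {
  sf_cols <- grep("^sf_[^_]+_", names(met), value = TRUE)
  if (!length(sf_cols)) return(NULL)
  genus <- sub("^sf_([^_]+)_.*$", "\\1", sf_cols)
  out <- tibble::tibble(timestamp = met$timestamp)
  for (g in unique(genus)) {
    cols <- sf_cols[genus == g]
    m <- as.matrix(met[, cols, drop = FALSE])
    med <- apply(m, 1, function(r) {
      r <- r[!is.na(r)]
      if (!length(r)) NA_real_ else median(r)
    })
    out[[paste0("sf_", g)]] <- med
  }
  out
}
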