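#' One tree's band record on the regular 15-minute grid
#'
#' Container for a single tree's gridded sensor position and band
#' temperature with a per-sample QC mask (`masked = TRUE` means the sample
#' is excluded from analysis; NA position is an instrument gap).
#'
#' @param tree_id tree identifier.
#' @param time grid timestamps ([band_grid()]); spacing must be exactly 15 min.
#' @param position sensor position (mm), NA at gaps.
#' @param band_temp band temperature (degC), NA where absent.
#' @param masked logical QC mask, same length as the grid.
#' @return object of class `band_series`.
#' @export
band_series <- function(tree_id, time, position, band_temp = NULL,
                        masked = NULL) {
  n <- length(time)
  if (n < 2 || any(diff(as.numeric(time)) != GRID_STEP_SEC)) {
    stop("band_series: grid spacing must be exactly 15 minutes")
  }
  if (length(position) != n) stop("band_series: position length != grid length")
  band_temp <- band_temp %||% rep(NA_real_, n)
  masked <- masked %||% rep(FALSE, n)
  if (length(masked) != n) stop("band_series: qc mask length != grid length")
  structure(list(tree_id = as.character(tree_id), time = time,
                 position = as.numeric(position),
                 band_temp = as.numeric(band_temp),
                 masked = as.logical(masked)),
            class = "band_series")
}

#' Place raw logger records for one tree onto a grid
#'
#' Snaps each record to the nearest grid sample (+/- 7.5 min); keep-last on
#' collisions.
#'
#' @param records tibble from [read_band_log()] (one tree's rows).
#' @param grid timestamps from [band_grid()].
#' @param tree_id tree identifier (defaults to the single id in `records`).
#' @return a [band_series()].
#' @export
as_band_series <- function(records, grid, tree_id = NULL) {
  tree_id <- tree_id %||% unique(records$tree_id)[1]
  pos <- rep(NA_real_, length(grid))
  temp <- rep(NA_real_, length(grid))
  idx <- snap_to_grid(records$timestamp, grid)
  ok <- !is.na(idx)
  pos[idx[ok]] <- records$position[ok]
  if ("band_temp" %in% names(records)) temp[idx[ok]] <- records$band_temp[ok]
  band_series(tree_id, grid, pos, temp)
}

#' @export
print.band_series <- function(x, ...) {
  cat(sprintf("<band_series> tree %s: %d samples (%s to %s), %d gaps, %d masked\n",
              x$tree_id, length(x$time), format(min(x$time)), format(max(x$time)),
              sum(is.na(x$position)), sum(x$masked)))
  invisible(x)
}

usable_fraction <- function(band) {
  mean(!band$masked & !is.na(band$position))
}
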