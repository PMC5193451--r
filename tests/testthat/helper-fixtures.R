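# shared fixture builders (everything generated in code; no stored data)

fix_start <- as.Date("2015-06-19")

make_grid <- function(n_days, start = fix_start) {
  band_grid(start, start + n_days - 1)
}

# band with a pure diurnal sinusoid of given peak-to-peak amplitude (mm)
sine_band <- function(n_days = 20, p2p = 0.3, noise = 0, p0 = 10,
                      tree_id = "X1", seed = 1, start = fix_start) {
  grid <- make_grid(n_days, start)
  h <- as.POSIXlt(grid, tz = "UTC")$hour + as.POSIXlt(grid, tz = "UTC")$min / 60
  pos <- p0 + (p2p / 2) * sin(2 * pi * (h - 8) / 24)
  if (noise > 0) pos <- pos + withr::with_seed(seed, rnorm(length(grid), 0, noise))
  band_series(tree_id, grid, pos, band_temp = 20 + 4 * cos(2 * pi * (h - 14) / 24))
}

write_temp_csv <- function(df) {
  f <- tempfile(fileext = ".csv")
  readr::write_csv(df, f)
  f
}

# manual checks bracketing the window for one tree, widths following `pos_at`
make_checks <- function(tree_id, times, widths) {
  tibble::tibble(tree_id = tree_id, visit_time = times, window_width = widths)
}
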