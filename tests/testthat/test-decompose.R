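test_that("delta_c is referenced to the first usable sample", {
  grid <- make_grid(1)[1:3]
  # short grids are rejected by the constructor, so build manually
  b <- structure(list(tree_id = "X", time = make_grid(1),
                      position = c(5.0, 5.1, 5.3, rep(5.3, 93)),
                      band_temp = rep(NA_real_, 96),
                      masked = rep(FALSE, 96)), class = "band_series")
  expect_equal(compute_delta_c(b)[1:3], c(0, 0.1, 0.3))

  b$masked[1] <- TRUE
  dc <- compute_delta_c(b)
  expect_true(is.na(dc[1]))
  expect_equal(dc[2], 0)             # origin shifts to the second sample
  expect_equal(dc[3], 0.2)

  b$position <- rep(7, 96)
  b$masked[] <- FALSE
  expect_true(all(compute_delta_c(b) == 0))

  b$masked[] <- TRUE
  expect_error(compute_delta_c(b), "no usable data")
})

test_that("spline trend with df = n_days reproduces lines and rejects bad df", {
  grid <- make_grid(60)
  x_days <- as.numeric(grid - grid[1], units = "days")
  line <- 0.1 * x_days
  sp <- fit_spline_trend(grid, line, n_days = 60)
  expect_lt(max(abs(sp$trend - line)), 1e-6)
  expect_lt(abs(sp$edf - 60), 0.5)

  # line + 1-day sinusoid (0.2 mm p2p): midnight values near the
  # least-squares line oracle
  y <- line + 0.1 * sin(2 * pi * x_days)
  sp2 <- fit_spline_trend(grid, y, n_days = 60)
  ls <- lm(y ~ x_days)
  oracle <- predict(ls, newdata = data.frame(x_days = 0:60))
  dev <- abs(sp2$midnights$value - oracle)
  expect_lt(max(dev[2:60]), 0.02)   # interior midnights track the line
  # boundary midnights carry spline edge bias up to the sinusoid amplitude
  expect_lt(max(dev), 0.1)

  expect_error(fit_spline_trend(grid[1:300], line[1:300], n_days = 400),
               "insufficient|exceeds")
})

test_that("daily increment is the midnight-to-midnight trend difference", {
  m <- tibble::tibble(date = fix_start + 0:2, value = c(10.00, 10.12, 10.12))
  inc <- daily_increment(m)
  expect_equal(inc$I, c(0.12, 0))
  expect_equal(inc$date, fix_start + 0:1)
  expect_error(daily_increment(m[1, ]), "two midnights")
})

test_that("daily amplitude is max - min of residuals with a coverage gate", {
  grid <- make_grid(2)
  h <- as.POSIXlt(grid, tz = "UTC")$hour + as.POSIXlt(grid, tz = "UTC")$min / 60
  a <- 0.1
  dcr_signal <- a * sin(2 * pi * h / 24)
  trend <- rep(0, length(grid))
  ra <- residual_amplitude(dcr_signal, trend, grid)
  # closed form: range of a sinusoid sampled at 96/day
  oracle <- max(dcr_signal[1:96]) - min(dcr_signal[1:96])
  expect_equal(ra$daily$A, rep(oracle, 2))
  expect_lt(abs(oracle - 2 * a), 0.001)

  # day 2 at 50% coverage -> gap
  dcr2 <- dcr_signal
  dcr2[97:144] <- NA
  ra2 <- residual_amplitude(dcr2, trend, grid, min_coverage = 0.75)
  expect_true(is.na(ra2$daily$A[2]))
  expect_false(is.na(ra2$daily$A[1]))
})

test_that("decomposition reconstructs delta_c exactly and is shift-invariant", {
  met <- generate_weather(16, seed = 31)
  tr <- tree_truth("R1", growth_rate = 0.08, alpha0 = 0.25, sigma = 0.01)
  sim <- generate_tree_series(tr, met, seed = 32)
  grid <- make_grid(16)
  b <- as_band_series(sim$band, grid)
  d <- decompose_tree(b)
  err <- abs(d$samples$delta_c - d$samples$trend - d$samples$delta_c_r)
  expect_lt(max(err, na.rm = TRUE), 1e-9)

  b_shift <- b
  b_shift$position <- b$position + 3.21
  d2 <- decompose_tree(b_shift)
  expect_equal(d2$daily$I, d$daily$I, tolerance = 1e-8)
  expect_equal(d2$daily$A, d$daily$A, tolerance = 1e-8)
  expect_true(all(d$daily$A >= 0, na.rm = TRUE))
})

test_that("ensemble band temperature removes IQR outliers per time-of-day bin", {
  grid <- make_grid(2)
  temps <- c(20, 21, 22, 60)
  bands <- lapply(seq_along(temps), function(i) {
    band_series(sprintf("T%d", i), grid, rep(10, length(grid)),
                band_temp = rep(temps[i], length(grid)))
  })
  ens <- ensemble_band_temp(bands)
  # oracle with linear-interpolation quartiles on the pooled bin {20,21,22,60} x 2
  v <- rep(temps, each = 2)
  q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  keep <- v >= q[1] - 1.5 * diff(q) & v <= q[2] + 1.5 * diff(q)
  expect_false(any(keep[v == 60]))
  expect_equal(unique(ens$t_band), median(c(20, 21, 22)))

  # single tree -> its own series; identical trees -> that series
  expect_equal(ensemble_band_temp(bands[2])$t_band, bands[[2]]$band_temp)
  expect_equal(ensemble_band_temp(list(bands[[1]], bands[[1]]))$t_band,
               bands[[1]]$band_temp)
})
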