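test_that("read_band_log parses, deduplicates keep-last, and enforces columns", {
  f <- write_temp_csv(tibble::tibble(
    tree_id = "A", timestamp = c("2015-06-19T00:00:00Z", "2015-06-19T00:15:00Z",
                                 "2015-06-19T00:30:00Z"),
    position = c(10, 10.1, 10.2), band_temp = 20))
  tbl <- read_band_log(f)
  expect_equal(nrow(tbl), 3)
  expect_s3_class(tbl$timestamp, "POSIXct")
  expect_equal(tbl$position, c(10, 10.1, 10.2))

  fdup <- write_temp_csv(tibble::tibble(
    tree_id = "A", timestamp = c("2015-06-19T00:00:00Z", "2015-06-19T00:00:00Z",
                                 "2015-06-19T00:15:00Z"),
    position = c(9.9, 10, 10.1), band_temp = 20))
  expect_message(tbl2 <- read_band_log(fdup), "duplicate")
  expect_equal(nrow(tbl2), 2)
  expect_equal(attr(tbl2, "n_duplicates"), 1)
  expect_equal(tbl2$position[1], 10)  # keep-last

  fmiss <- write_temp_csv(tibble::tibble(
    tree_id = "A", timestamp = "2015-06-19T00:00:00Z", band_temp = 20))
  expect_error(read_band_log(fmiss), "column position absent")
})

test_that("read_met rejects out-of-range rows and flags sap-flux presence", {
  f <- write_temp_csv(tibble::tibble(
    timestamp = sprintf("2015-06-19T0%d:00:00Z", 0:3),
    t_air = 25, rh = c(60, 150, 70, 80), ppt = 0, rad = 100))
  expect_warning(met <- read_met(f), "unit ranges")
  expect_equal(nrow(met), 3)
  expect_false(attr(met, "sf_present"))

  f2 <- write_temp_csv(tibble::tibble(
    timestamp = "2015-06-19T00:00:00Z", t_air = 25, rh = 60, ppt = 0,
    rad = 100, sf_Quercus_p1 = 0.2))
  expect_true(attr(read_met(f2), "sf_present"))
})

test_that("read_meta keeps dead trees without bark class", {
  f <- write_temp_csv(tibble::tibble(
    tree_id = c("A", "B"), site = "S", species = c("Quercus alba", NA),
    dbh = c(40, 55), status = c("live", "dead"),
    bark_class = c("thin", NA), irrigated = c(FALSE, NA)))
  meta <- read_meta(f)
  expect_equal(nrow(meta), 2)
  expect_true(is.na(meta$bark_class[meta$status == "dead"]))
  expect_false(meta$irrigated[2])
})

test_that("resample_to_grid interpolates without extrapolating", {
  grid <- make_grid(1)
  src_t <- grid[1] + c(0, 1800)
  out <- resample_to_grid(src_t, c(10, 12), grid, "interpolate")
  expect_equal(out[2], 11)            # linear midpoint at t = 15 min
  expect_equal(out[1], 10)
  expect_true(all(is.na(out[4:96])))  # beyond source span -> gaps

  # exact on affine inputs
  src <- grid[1] + seq(0, 86000, by = 3600)
  vals <- 2.5 + 0.001 * as.numeric(src - grid[1])
  got <- resample_to_grid(src, vals, grid, "interpolate")
  truth <- 2.5 + 0.001 * as.numeric(grid - grid[1])
  inside <- !is.na(got)
  expect_lt(max(abs(got[inside] - truth[inside])), 1e-9)
})

test_that("aggregate_sum assigns (t-15, t] and conserves totals", {
  grid <- make_grid(1)
  src_t <- grid[1] + seq(60, 900, by = 60)    # 15 one-minute samples
  out <- resample_to_grid(src_t, rep(0.1, 15), grid, "aggregate_sum")
  expect_equal(out[2], 1.5)

  src2 <- grid[1] + sort(withr::with_seed(5, sample(1:85500, 500)))
  vals2 <- withr::with_seed(6, runif(500))
  got <- resample_to_grid(src2, vals2, grid, "aggregate_sum")
  expect_equal(sum(got, na.rm = TRUE), sum(vals2))

  expect_warning(e <- resample_to_grid(grid[0], numeric(0), grid, "interpolate"),
                 "empty source")
  expect_true(all(is.na(e)))
})

test_that("genus_ensemble_sf matches a brute-force median oracle", {
  met <- tibble::tibble(timestamp = make_grid(1)[1:4],
                        sf_Oak_p1 = c(1, 1, 1, NA),
                        sf_Oak_p2 = c(2, NA, 2, NA),
                        sf_Oak_p3 = c(10, 3, NA, NA),
                        sf_Fir_p1 = c(5, 5, 5, 5))
  ens <- genus_ensemble_sf(met)
  expect_equal(ens$sf_Oak[1], 2)      # median of {1, 2, 10}
  expect_equal(ens$sf_Oak[2], 2)      # gap-ignoring median of {1, 3}
  expect_true(is.na(ens$sf_Oak[4]))
  expect_equal(ens$sf_Fir, rep(5, 4)) # single probe -> identity

  # randomized table vs sort-and-pick oracle
  withr::with_seed(11, {
    m <- matrix(runif(60), 12, 5)
    m[sample(60, 12)] <- NA
  })
  met2 <- tibble::tibble(timestamp = make_grid(1)[1:12])
  for (j in 1:5) met2[[sprintf("sf_G_p%d", j)]] <- m[, j]
  ens2 <- genus_ensemble_sf(met2)
  oracle <- apply(m, 1, function(r) {
    r <- sort(r[!is.na(r)])
    n <- length(r)
    if (!n) NA_real_
    else if (n %% 2 == 1) r[(n + 1) / 2] else (r[n / 2] + r[n / 2 + 1]) / 2
  })
  expect_equal(ens2$sf_G, oracle)
})
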