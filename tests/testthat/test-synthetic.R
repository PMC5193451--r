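test_that("weather generation is deterministic and respects its knobs", {
  w1 <- generate_weather(10, seed = 81)
  w2 <- generate_weather(10, seed = 81)
  expect_identical(w1, w2)

  # degenerate dry chain: zero rain days
  dry <- generate_weather(20, weather_truth(p_wet_dry = 0, p_wet_wet = 0),
                          seed = 82)
  expect_equal(sum(dry$ppt), 0)
  expect_length(attr(dry, "rain_days"), 0)

  # configured mean recovered over 60 days
  w <- generate_weather(60, weather_truth(t_mean = 22), seed = 83)
  expect_lt(abs(mean(w$t_air) - 22), 0.5)
  expect_true(all(w$rh >= 20 & w$rh <= 100))
  expect_true(all(w$ppt >= 0) && all(w$rad >= 0))
})

test_that("tree series generation is deterministic and fault schedules apply", {
  met <- generate_weather(16, seed = 84)
  tr <- tree_truth("D1", status = "dead", sigma = 0.01)
  expect_equal(tr$growth_rate, 0)   # dead trees carry no growth/rain signal
  expect_equal(tr$rain_effect, 0)

  s1 <- generate_tree_series(tr, met, seed = 85)
  s2 <- generate_tree_series(tr, met, seed = 85)
  expect_identical(s1$band, s2$band)

  # scheduled jump days are masked by the jump screen, exactly
  jd <- fix_start + c(4, 8, 11)
  trj <- tree_truth("J1", faults = list(
    jumps = tibble::tibble(date = jd, size = c(0.8, -0.9, 1.1))))
  sj <- generate_tree_series(trj, met, seed = 86)
  b <- as_band_series(sj$band, make_grid(16))
  out <- screen_jump_days(b)
  expect_equal(sort(unique(as.Date(out$time[out$masked], tz = "UTC"))), jd)

  trbad <- tree_truth("J2", faults = list(
    jumps = tibble::tibble(date = fix_start + 100, size = 1)))
  expect_error(generate_tree_series(trbad, met, seed = 1), "outside the weather window")
})

test_that("dead trees decompose to near-zero daily increments", {
  met <- generate_weather(20, seed = 87)
  tr <- tree_truth("D2", status = "dead", sigma = 0.01)
  sim <- generate_tree_series(tr, met, seed = 88)
  d <- decompose_tree(as_band_series(sim$band, make_grid(20)))
  expect_lt(mean(abs(d$daily$I)), 0.01)
})

test_that("noise-free signal decomposes back into its components", {
  met <- generate_weather(20, weather_truth(p_wet_dry = 0.3), seed = 89)
  tr <- tree_truth("C1", sigma = 1e-9, growth_rate = 0.08, alpha0 = 0.25,
                   rain_effect = 0.12)
  sim <- generate_tree_series(tr, met, seed = 90, keep_components = TRUE)
  d <- decompose_tree(as_band_series(sim$band, make_grid(20)))
  with_comp <- sim$components
  target <- with_comp$G + with_comp$H + with_comp$R
  target <- target - target[1]
  recon <- d$samples$trend + d$samples$delta_c_r
  expect_lt(sqrt(mean((recon - target)^2, na.rm = TRUE)), 0.03)
})

test_that("cohorts are reproducible with the requested class mix", {
  c1 <- generate_cohort(n_trees = 6, n_days = 16, seed = 91,
                        mix = c(shrink = 1, swell = 0, no_pattern = 0, dead = 0),
                        faults = FALSE)
  expect_true(all(c1$truth$class == "shrink"))
  expect_true(all(c1$truth$status == "live"))

  c2 <- generate_cohort(n_trees = 6, n_days = 16, seed = 91,
                        mix = c(shrink = 1, swell = 0, no_pattern = 0, dead = 0),
                        faults = FALSE)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$band, c2$band)

  expect_error(generate_cohort(n_trees = 4, n_days = 16,
                               mix = c(shrink = 0.5, swell = 0.2)),
               "sum")

  # written cohort re-reads through the ingest layer
  dir <- tempfile()
  write_cohort(c1, dir)
  band <- read_band_log(file.path(dir, "band.csv"))
  expect_setequal(unique(band$tree_id), c1$truth$tree_id)
  met <- read_met(file.path(dir, "met.csv"))
  expect_true(attr(met, "sf_present"))
})

test_that("daily-table simulators are deterministic with exact dimensions", {
  a1 <- simulate_amplitude_table(n_trees = 5, n_days = 7, seed = 92)
  a2 <- simulate_amplitude_table(n_trees = 5, n_days = 7, seed = 92)
  expect_identical(a1, a2)
  expect_equal(nrow(a1), 35)
  r1 <- simulate_increment_table(n_trees = 4, n_days = 9, seed = 93)
  expect_equal(nrow(r1), 36)
  expect_true(all(c(TRUE, FALSE) %in% r1$rain))
})
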