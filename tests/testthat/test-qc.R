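test_that("manual-discrepancy screen masks only discrepant intervals", {
  b <- sine_band(n_days = 28, p2p = 0.1)
  t1 <- b$time[96 * 7 + 41]   # day 8, 10:00
  t2 <- b$time[96 * 21 + 41]  # day 22, 10:00
  # sensor drifts +5 mm between the checks; window width stays put
  drift <- approx(c(1, 96 * 7, 96 * 21, length(b$time)), c(0, 0, 5, 5),
                  xout = seq_along(b$time))$y
  b$position <- b$position + drift
  checks <- make_checks("X1", c(b$time[41], t1, t2, b$time[96 * 27 + 41]),
                        c(30, 30, 30.5, 30.5))
  out <- screen_manual_discrepancy(b, checks, tol = 4)
  iv <- b$time >= t1 & b$time <= t2
  expect_true(all(out$masked[iv]))
  expect_false(any(out$masked[!iv]))

  # matching changes -> untouched; skip flag -> identical object
  b2 <- sine_band(n_days = 28, p2p = 0.1)
  checks2 <- make_checks("X1", c(b2$time[41], t1), c(30, 30.02))
  expect_false(any(screen_manual_discrepancy(b2, checks2)$masked))
  expect_identical(screen_manual_discrepancy(b2, checks2, skip = TRUE), b2)
  expect_warning(screen_manual_discrepancy(b2, checks2[1, ]), "<2 manual checks")
})

test_that("jump-day screen masks whole days, with per-site thresholds", {
  b <- sine_band(n_days = 5, p2p = 0.3)
  j <- 96 * 2 + 48                       # midday of day 3
  b$position[j:length(b$position)] <- b$position[j:length(b$position)] + 0.6
  out <- screen_jump_days(b, threshold = 0.5)
  masked_days <- unique(as.Date(out$time[out$masked], tz = "UTC"))
  expect_equal(masked_days, fix_start + 2)   # exactly the jump day
  expect_equal(sum(out$masked), 96)

  # same 0.6 mm jump is kept under the 1.0 mm (tropical-site) threshold
  expect_false(any(screen_jump_days(b, threshold = 1.0)$masked))

  # smooth 0.3 mm p2p diurnal cycle never trips the rule
  expect_false(any(screen_jump_days(sine_band(n_days = 5, p2p = 0.3))$masked))
})

test_that("spike screen removes isolated excursions but not steps", {
  grid <- make_grid(3)
  flat <- band_series("X1", grid, rep(10, length(grid)))
  flat$position[100] <- 11               # isolated +1 mm
  out <- screen_spikes(flat)
  expect_true(out$masked[100])
  expect_equal(sum(out$masked), 1)

  step <- band_series("X1", grid, c(rep(10, 150), rep(10.8, length(grid) - 150)))
  expect_false(any(screen_spikes(step)$masked))  # persistent shift: jump rule's job

  # pure sinusoid: zero masks, cross-checked against a brute-force
  # rolling-median/MAD oracle
  b <- sine_band(n_days = 3, p2p = 0.3, noise = 0.01, seed = 3)
  out2 <- screen_spikes(b)
  v <- b$position
  oracle_flag <- vapply(seq_along(v), function(i) {
    w <- v[max(1, i - 2):min(length(v), i + 2)]
    med <- median(w)
    abs(v[i] - med) > 5 * max(median(abs(w - median(w))), 0.01)
  }, logical(1))
  expect_false(any(oracle_flag))
  expect_false(any(out2$masked))
})

test_that("screens are idempotent and masks only grow", {
  coh <- generate_cohort(n_trees = 4, n_days = 16, seed = 21, faults = TRUE)
  grid <- make_grid(16)
  for (id in unique(coh$band$tree_id)) {
    b <- as_band_series(coh$band[coh$band$tree_id == id, ], grid)
    b1 <- suppressWarnings(screen_manual_discrepancy(b, coh$checks))
    expect_true(all(b1$masked[b$masked]))
    b1b <- suppressWarnings(screen_manual_discrepancy(b1, coh$checks))
    expect_identical(b1b$masked, b1$masked)
    b2 <- screen_jump_days(b1)
    expect_true(all(b2$masked[b1$masked]))
    expect_identical(screen_jump_days(b2)$masked, b2$masked)
    b3 <- screen_spikes(b2)
    expect_true(all(b3$masked[b2$masked]))
    expect_identical(screen_spikes(b3)$masked, b3$masked)
  }
})

test_that("usable-tree selection applies the strict <50% exclusion", {
  rep_tbl <- tibble::tibble(tree_id = c("A", "B", "C"),
                            fraction_usable = c(0.49, 0.50, 1.0))
  expect_equal(select_usable_trees(rep_tbl), c("B", "C"))
})

test_that("a fault-free cohort is fully usable", {
  coh <- generate_cohort(n_trees = 5, n_days = 16, seed = 8, faults = FALSE)
  grid <- make_grid(16)
  fracs <- vapply(split(coh$band, coh$band$tree_id), function(x) {
    q <- suppressWarnings(qc_tree(as_band_series(x, grid), coh$checks))
    q$report$fraction_usable
  }, numeric(1))
  expect_true(all(fracs == 1))
})
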