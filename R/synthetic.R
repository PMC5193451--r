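# Synthetic study conditions: a stochastic weather generator (diurnal
# temperature, humidity coupling, Markov-chain rain, radiation, flux
# proxies) and a band-signal generator
#   position(t) = p0 + G(t) + H(t) + R(t) + B(t) + eps(t)
# (growth trend, diurnal hydraulic term, rain-pulse expansion, optional
# thermal term, i.i.d. sensor noise) with scheduled instrument faults
# (jumps, spikes, dropouts, manual-window drift). All randomness flows from
# one seed; per-tree substreams are derived by stable hashing of the id.

#' Weather-generator parameters
#'
#' @param t_mean mean air temperature (degC).
#' @param t_amp diurnal temperature semi-amplitude (degC), peak at 14:00.
#' @param t_ar1,t_anom_sd AR(1) coefficient and marginal SD of the
#'   day-to-day temperature anomaly.
#' @param rh_base baseline relative humidity (%).
#' @param rh_coupling RH decrease per degC of air-temperature excess.
#' @param rh_wet_boost RH addition on wet days (%).
#' @param rh_anom_sd SD of the daily RH anomaly.
#' @param p_wet_dry,p_wet_wet wet-day transition probabilities of the
#'   2-state Markov rain process.
#' @param rain_shape,rain_mean gamma shape and mean (mm) of daily rainfall.
#' @param rad_max clear-sky noon radiation (W m-2); half-sine 06:00-18:00.
#' @param rad_rain_factor radiation multiplier on wet days.
#' @param sf_genera,sf_probes genera with sap-flux probes and probes per
#'   genus.
#' @param et generate an evapotranspiration series.
#' @return list of class `weather_truth`.
#' @export
weather_truth <- function(t_mean = 22, t_amp = 4, t_ar1 = 0.6, t_anom_sd = 1.5,
                          rh_base = 75, rh_coupling = 2.5, rh_wet_boost = 8,
                          rh_anom_sd = 4, p_wet_dry = 0.25, p_wet_wet = 0.55,
                          rain_shape = 0.8, rain_mean = 8, rad_max = 850,
                          rad_rain_factor = 0.35,
                          sf_genera = c("Liriodendron", "Quercus"),
                          sf_probes = 3, et = TRUE) {
  stopifnot(p_wet_dry >= 0, p_wet_dry <= 1, p_wet_wet >= 0, p_wet_wet <= 1)
  structure(as.list(environment()), class = "weather_truth")
}

#' Generate a 15-minute weather series
#'
#' @param n_days number of days (>= 7).
#' @param truth a [weather_truth()].
#' @param seed integer seed (output is byte-identical under the same seed).
#' @param start_date first day of the series.
#' @return met tibble (`timestamp`, `t_air`, `rh`, `ppt`, `rad`, `et`,
#'   `sf_<genus>_<probe>` columns); attribute `rain_days` holds the wet
#'   `Date`s.
#' @export
generate_weather <- function(n_days, truth = weather_truth(), seed = 1,
                             start_date = as.Date("2015-06-19")) {
  stopifnot(n_days >= 7)
  withr::with_seed(seed, {
    grid <- band_grid(start_date, start_date + n_days - 1)
    n <- length(grid)
    lt <- as.POSIXlt(grid, tz = "UTC")
    h <- lt$hour + lt$min / 60
    day <- rep(seq_len(n_days), each = SAMPLES_PER_DAY)

    # 2-state Markov rain occurrence, started from the stationary law
    wet <- logical(n_days)
    p_stat <- truth$p_wet_dry / max(1e-12, 1 + truth$p_wet_dry - truth$p_wet_wet)
    wet[1] <- runif(1) < p_stat
    for (d in seq_len(n_days)[-1]) {
      wet[d] <- runif(1) < if (wet[d - 1]) truth$p_wet_wet else truth$p_wet_dry
    }

    ar1_series <- function(n, phi, sd_marg) {
      x <- numeric(n)
      x[1] <- rnorm(1, 0, sd_marg)
      sd_inn <- sd_marg * sqrt(max(0, 1 - phi^2))
      for (i in seq_len(n)[-1]) x[i] <- phi * x[i - 1] + rnorm(1, 0, sd_inn)
      x
    }
    t_anom <- ar1_series(n_days, truth$t_ar1, truth$t_anom_sd)
    rh_anom <- ar1_series(n_days, truth$t_ar1, truth$rh_anom_sd)

    # day-to-day variation in diurnal amplitude (cloud cover; damped on wet
    # days) so daily temperature range and radiation sums vary realistically
    amp_fac <- pmax(0.3, (1 + 0.15 * rnorm(n_days)) * ifelse(wet, 0.6, 1))
    cloud <- runif(n_days, 0.75, 1)
    t_air <- truth$t_mean + t_anom[day] +
      truth$t_amp * amp_fac[day] * cos(2 * pi * (h - 14) / 24)
    rh <- truth$rh_base - truth$rh_coupling * (t_air - truth$t_mean) +
      truth$rh_wet_boost * wet[day] + rh_anom[day]
    rh <- pmin(100, pmax(20, rh))

    rad <- truth$rad_max * cloud[day] * pmax(0, sin(pi * (h - 6) / 12)) *
      ifelse(wet[day], truth$rad_rain_factor, 1)

    ppt <- numeric(n)
    for (d in which(wet)) {
      amount <- rgamma(1, shape = truth$rain_shape,
                       scale = truth$rain_mean / truth$rain_shape)
      onset <- sample(24:72, 1)                 # 06:00-18:00
      len <- sample(6:24, 1)
      idx <- (d - 1) * SAMPLES_PER_DAY + onset + seq_len(len) - 1
      idx <- idx[idx <= d * SAMPLES_PER_DAY]
      w <- runif(length(idx))
      ppt[idx] <- ppt[idx] + amount * w / sum(w)
    }

    vpd <- vapor_pressure_deficit(t_air, rh)
    demand <- (rad / truth$rad_max) * vpd
    f <- demand / (0.3 + demand)                # saturating flux response
    met <- tibble::tibble(timestamp = grid, t_air = t_air, rh = rh,
                          ppt = ppt, rad = rad)
    if (truth$et) {
      met$et <- pmax(0, 5 * f * (1 + rnorm(n, 0, 0.05)))
    }
    for (g in truth$sf_genera) {
      for (p in seq_len(truth$sf_probes)) {
        pf <- exp(rnorm(1, 0, 0.25))
        met[[sprintf("sf_%s_p%d", g, p)]] <-
          pmax(0, 0.4 * f * pf * (1 + rnorm(n, 0, 0.05)))
      }
    }
    attr(met, "rain_days") <- (start_date + seq_len(n_days) - 1)[wet]
    met
  })
}

#' Ground-truth parameters for one synthetic tree
#'
#' @param tree_id identifier.
#' @param status `"live"` or `"dead"`; dead trees are forced to zero growth,
#'   zero driver sensitivity and zero rain effect.
#' @param bark_class `"thin"` or `"thick"`.
#' @param irrigated irrigation flag (metadata only).
#' @param growth_rate g (mm/day); suppressed to 0.25 g on the driest decile
#'   of days (highest daily VPD).
#' @param alpha0 baseline diurnal peak-to-peak amplitude (mm).
#' @param alpha1 amplitude sensitivity (mm per SD of daily VPD).
#' @param phase_offset phase of the diurnal term relative to band
#'   temperature: `pi` = hydraulic daytime shrinkage, `0` = in-phase
#'   swelling.
#' @param rain_effect d (mm): asymptotic circumference expansion added per
#'   rain day.
#' @param half_life rise half-life of the rain pulse (days).
#' @param beta optional thermal term (mm/degC of band-temperature anomaly).
#' @param sigma i.i.d. sensor noise SD (mm); must be > 0.
#' @param p0 sensor position offset (mm).
#' @param dbh,species metadata carried into the cohort tables.
#' @param faults list: `jumps` tibble(date, size), `spikes` tibble(time,
#'   size), `dropouts` tibble(start, end), `drift` NULL or list(t_start,
#'   t_end, size).
#' @param visit_dates manual-check visit `Date`s.
#' @return list of class `tree_truth`.
#' @export
tree_truth <- function(tree_id, status = "live", bark_class = "thin",
                       irrigated = FALSE, growth_rate = 0.08, alpha0 = 0.25,
                       alpha1 = 0.04, phase_offset = pi, rain_effect = 0.10,
                       half_life = 0.15, beta = 0, sigma = 0.01, p0 = 10,
                       dbh = 40, species = "Liriodendron tulipifera",
                       faults = list(), visit_dates = NULL) {
  stopifnot(sigma > 0)
  if (status == "dead") {
    growth_rate <- 0; alpha1 <- 0; rain_effect <- 0
  }
  out <- as.list(environment())
  defaults <- list(
    jumps = tibble::tibble(date = as.Date(character()), size = numeric()),
    spikes = tibble::tibble(time = as.POSIXct(character(), tz = "UTC"),
                            size = numeric()),
    dropouts = tibble::tibble(start = as.POSIXct(character(), tz = "UTC"),
                              end = as.POSIXct(character(), tz = "UTC")),
    drift = NULL)
  defaults[names(faults)] <- faults
  out$faults <- defaults
  structure(out, class = "tree_truth")
}

diurnal_shape <- function(h) {
  # raised cosine between 06:00 and 20:00, flat at night, in [-1, 1];
  # peaks (+1) at 13:00, roughly tracking the early-afternoon VPD maximum
  r <- ifelse(h >= 6 & h < 20, 0.5 * (1 - cos(2 * pi * (h - 6) / 14)), 0)
  2 * r - 1
}

#' Generate one tree's band series and manual checks
#'
#' @param truth a [tree_truth()].
#' @param met weather table from [generate_weather()].
#' @param seed substream seed for this tree.
#' @param keep_components also return the noise-free signal components
#'   (G, H, R, B, clean) for ground-truth assertions.
#' @return list `band` (tibble `tree_id`, `timestamp`, `position`,
#'   `band_temp`), `checks` (manual check tibble), and optionally
#'   `components`.
#' @export
generate_tree_series <- function(truth, met, seed = 1,
                                 keep_components = FALSE) {
  grid <- met$timestamp
  n <- length(grid)
  dates <- grid_dates(grid)
  udates <- unique(dates)
  n_days <- length(udates)
  day <- match(dates, udates)
  lt <- as.POSIXlt(grid, tz = "UTC")
  h <- lt$hour + lt$min / 60
  f <- truth$faults
  if (nrow(f$jumps) && !all(f$jumps$date %in% udates)) {
    stop("fault schedule outside the weather window")
  }
  withr::with_seed(seed, {
    vpd <- vapor_pressure_deficit(met$t_air, met$rh)
    vpd_day <- tapply(vpd, day, mean)
    z_vpd <- as.numeric(scale(vpd_day))
    if (all(is.na(z_vpd))) z_vpd <- rep(0, n_days)

    # growth, suppressed on the driest decile of days (highest daily VPD)
    driest <- rank(-vpd_day, ties.method = "first") <= ceiling(n_days / 10)
    g_day <- truth$growth_rate * ifelse(driest, 0.25, 1)
    G <- cumsum(g_day[day] / SAMPLES_PER_DAY)
    G <- G - G[1]

    amp_day <- pmax(0, truth$alpha0 + truth$alpha1 * z_vpd)
    H <- (amp_day[day] / 2) * cos(truth$phase_offset) * diurnal_shape(h)

    # rain pulse: saturating expansion from each rain event's onset
    R <- numeric(n)
    ppt_day <- tapply(met$ppt, day, sum)
    tnum <- as.numeric(grid) / 86400
    for (d in which(ppt_day > 0)) {
      onset_idx <- which(day == d & met$ppt > 0)[1]
      dt_days <- pmax(0, tnum - tnum[onset_idx])
      after <- tnum >= tnum[onset_idx]
      R[after] <- R[after] +
        truth$rain_effect * (1 - 2^(-dt_days[after] / truth$half_life))
    }

    t_band <- met$t_air + runif(1, -0.5, 0.5) + rnorm(n, 0, 0.15)
    B <- truth$beta * (met$t_air - mean(met$t_air))

    clean <- truth$p0 + G + H + R + B
    position <- clean + rnorm(n, 0, truth$sigma)

    # scheduled faults
    if (nrow(f$jumps)) {
      for (i in seq_len(nrow(f$jumps))) {
        drows <- which(dates == f$jumps$date[i])
        j <- drows[sample(9:88, 1)]          # interior of the day
        position[j:n] <- position[j:n] + f$jumps$size[i]
      }
    }
    if (nrow(f$spikes)) {
      idx <- snap_to_grid(f$spikes$time, grid)
      ok <- !is.na(idx)
      position[idx[ok]] <- position[idx[ok]] + f$spikes$size[ok]
    }
    if (nrow(f$dropouts)) {
      for (i in seq_len(nrow(f$dropouts))) {
        position[grid >= f$dropouts$start[i] & grid <= f$dropouts$end[i]] <- NA_real_
      }
    }
    if (!is.null(f$drift)) {
      frac <- as.numeric(grid - f$drift$t_start, units = "secs") /
        as.numeric(f$drift$t_end - f$drift$t_start, units = "secs")
      position <- position + f$drift$size * pmin(1, pmax(0, frac))
    }

    visit_dates <- truth$visit_dates %||%
      unique(c(udates[seq(1, n_days, by = 14)], udates[n_days]))
    visit_idx <- snap_to_grid(
      as.POSIXct(paste(visit_dates, "10:00:00"), tz = "UTC"), grid)
    visit_idx <- visit_idx[!is.na(visit_idx)]
    checks <- tibble::tibble(tree_id = truth$tree_id,
                             visit_time = grid[visit_idx],
                             window_width = 30 + clean[visit_idx] - clean[1])

    out <- list(band = tibble::tibble(tree_id = truth$tree_id,
                                      timestamp = grid, position = position,
                                      band_temp = t_band),
                checks = checks)
    if (keep_components) {
      out$components <- list(G = G, H = H, R = R, B = B, clean = clean)
    }
    out
  })
}

cohort_presets <- list(
  shrink = function() list(
    growth_rate = runif(1, 0.04, 0.12), alpha0 = runif(1, 0.15, 0.35),
    alpha1 = runif(1, 0.02, 0.08), phase_offset = pi,
    rain_effect = max(0.02, rnorm(1, 0.10, 0.02)), status = "live"),
  swell = function() list(
    growth_rate = runif(1, 0.02, 0.08), alpha0 = runif(1, 0.08, 0.20),
    alpha1 = runif(1, 0.01, 0.04), phase_offset = 0,
    rain_effect = max(0.01, rnorm(1, 0.06, 0.02)), status = "live"),
  no_pattern = function() list(
    growth_rate = runif(1, 0.02, 0.06), alpha0 = runif(1, 0, 0.012),
    alpha1 = 0, phase_offset = pi,
    rain_effect = max(0.01, rnorm(1, 0.06, 0.02)), status = "live"),
  dead = function() list(
    growth_rate = 0, alpha0 = 0, alpha1 = 0, phase_offset = pi,
    rain_effect = 0, status = "dead"))

#' Generate a full synthetic cohort (all input tables + ground truth)
#'
#' Builds weather, per-tree band series with class presets (hydraulic
#' shrinkers, in-phase swellers, signal-free live trees, dead trees),
#' metadata, manual checks and scheduled faults. Reproducible: all
#' randomness derives from `seed`, with per-tree substreams hashed from the
#' tree id.
#'
#' @param n_trees cohort size.
#' @param n_days analysis-window length (days).
#' @param mix named class fractions (`shrink`, `swell`, `no_pattern`,
#'   `dead`), summing to 1.
#' @param weather a [weather_truth()].
#' @param seed master seed.
#' @param start_date first day.
#' @param faults inject random jump/spike/dropout faults and one
#'   manual-window drift tree.
#' @param drift_size drift magnitude (mm) for the drift tree.
#' @param retention_targets optional numeric vector of usable-data fractions
#'   engineered (via one long dropout each) into the last trees of the
#'   cohort, replacing their other faults.
#' @param irrigated_fraction fraction of live trees flagged irrigated.
#' @return list: `band`, `checks`, `met`, `meta`, `truth` (one row per tree),
#'   `schedules` (jumps/spikes/dropouts/drift tibbles), `rain_days`,
#'   `start_date`, `end_date`, `n_days`, `seed`.
#' @export
generate_cohort <- function(n_trees = 30, n_days = 62,
                            mix = c(shrink = 0.55, swell = 0.15,
                                    no_pattern = 0.20, dead = 0.10),
                            weather = weather_truth(), seed = 1,
                            start_date = as.Date("2015-06-19"), faults = TRUE,
                            drift_size = 5, retention_targets = NULL,
                            irrigated_fraction = 0.3) {
  if (abs(sum(mix) - 1) > 1e-8) stop("class mix fractions must sum to 1")
  met <- generate_weather(n_days, weather, seed = derive_seed(seed, "weather"),
                          start_date = start_date)
  grid <- met$timestamp
  n_grid <- length(grid)
  dates_grid <- grid_dates(grid)
  udates <- seq(start_date, by = 1, length.out = n_days)
  counts <- diff(round(cumsum(c(0, mix)) * n_trees))
  classes <- rep(names(mix), counts)
  length(classes) <- n_trees
  classes[is.na(classes)] <- names(mix)[1]
  ids <- sprintf("T%02d", seq_len(n_trees))
  n_ret <- length(retention_targets)
  ret_ids <- if (n_ret) tail(ids, n_ret) else character()
  visit_dates <- unique(c(udates[seq(1, n_days, by = 14)], udates[n_days]))
  drift_id <- if (faults && n_trees >= 1) ids[1] else NULL

  bands <- list(); checks <- list(); truth_rows <- list()
  jumps <- list(); spikes <- list(); dropouts <- list(); drifts <- list()
  species_by_class <- c(shrink = "Liriodendron tulipifera",
                        swell = "Quercus alba", no_pattern = "Fagus grandifolia",
                        dead = "Quercus rubra")
  for (i in seq_len(n_trees)) {
    id <- ids[i]; cls <- classes[i]
    tseed <- derive_seed(seed, id)
    tr <- withr::with_seed(tseed, {
      pars <- cohort_presets[[cls]]()
      pars$tree_id <- id
      pars$sigma <- 0.01
      pars$half_life <- 0.15
      pars$p0 <- runif(1, 5, 15)
      pars$dbh <- runif(1, 20, 80)
      pars$species <- species_by_class[[cls]]
      pars$bark_class <- sample(c("thin", "thick"), 1)
      pars$irrigated <- pars$status == "live" && runif(1) < irrigated_fraction
      pars$visit_dates <- visit_dates

      flt <- list()
      if (id %in% ret_ids) {
        # one long dropout engineering the usable fraction; no other faults
        target <- retention_targets[match(id, ret_ids)]
        n_drop <- n_grid - round(target * n_grid)
        flt$dropouts <- tibble::tibble(start = grid[200],
                                       end = grid[200 + n_drop - 1])
      } else if (faults) {
        # fault types are scheduled disjointly so that each one is caught by
        # its intended screen: dropouts first, jumps on days untouched by
        # dropouts/drift/visits, spikes (below the hourly jump threshold)
        # away from jump days, dropouts and each other
        dropout_dates <- as.Date(character())
        if (runif(1) < 0.3) {
          # dropout blocks must not swallow a manual-visit sample (the
          # discrepancy screen needs sensor data near every visit)
          vis_idx <- snap_to_grid(
            as.POSIXct(paste(visit_dates, "10:00:00"), tz = "UTC"), grid)
          vis_idx <- vis_idx[!is.na(vis_idx)]
          len <- round(runif(1, 0.5, 2) * SAMPLES_PER_DAY)
          for (try in 1:25) {
            st <- sample(seq_len(n_grid - len), 1)
            if (!any(vis_idx >= st - 4 & vis_idx <= st + len + 4)) break
            st <- NA_integer_
          }
          if (!is.na(st)) {
            flt$dropouts <- tibble::tibble(start = grid[st],
                                           end = grid[st + len - 1])
            dropout_dates <- seq(grid_dates(grid[st]),
                                 grid_dates(grid[st + len - 1]), by = 1)
          }
        }
        interior <- udates[3:(n_days - 2)]
        interior <- interior[!interior %in% c(visit_dates, dropout_dates)]
        drift_dates <- as.Date(character())
        if (!is.null(drift_id) && id == drift_id) {
          flt$drift <- list(
            t_start = as.POSIXct(paste(visit_dates[2], "10:00:00"), tz = "UTC"),
            t_end = as.POSIXct(paste(visit_dates[3], "10:00:00"), tz = "UTC"),
            size = drift_size)
          drift_dates <- seq(visit_dates[2], visit_dates[3], by = 1)
          interior <- interior[!interior %in% drift_dates]
        }
        n_jump <- min(sample(0:2, 1), length(interior))
        jump_dates <- as.Date(character())
        if (n_jump > 0) {
          jump_dates <- sort(sample(interior, n_jump))
          flt$jumps <- tibble::tibble(
            date = jump_dates,
            size = sample(c(-1, 1), n_jump, TRUE) * runif(n_jump, 0.7, 1.2))
        }
        n_spk <- sample(0:4, 1)
        if (n_spk > 0) {
          cand <- which(!(dates_grid %in% c(jump_dates, dropout_dates, drift_dates)))
          cand <- cand[cand > 100 & cand < n_grid - 100]
          picked <- integer()
          for (k in sample(cand)) {
            if (length(picked) == n_spk) break
            if (!length(picked) || min(abs(picked - k)) > 8) picked <- c(picked, k)
          }
          if (length(picked)) {
            flt$spikes <- tibble::tibble(
              time = grid[sort(picked)],
              size = sample(c(-1, 1), length(picked), TRUE) * 0.35)
          }
        }
      }
      do.call(tree_truth, c(pars, list(faults = flt)))
    })
    sim <- generate_tree_series(tr, met, seed = derive_seed(tseed, "series"))
    bands[[id]] <- sim$band
    checks[[id]] <- sim$checks
    truth_rows[[id]] <- tibble::tibble(
      tree_id = id, class = cls, status = tr$status,
      bark_class = tr$bark_class, irrigated = tr$irrigated,
      growth_rate = tr$growth_rate, alpha0 = tr$alpha0, alpha1 = tr$alpha1,
      phase_offset = tr$phase_offset, rain_effect = tr$rain_effect,
      half_life = tr$half_life, beta = tr$beta, sigma = tr$sigma,
      p0 = tr$p0, dbh = tr$dbh, species = tr$species,
      n_jump_days = nrow(tr$faults$jumps), n_spikes = nrow(tr$faults$spikes),
      n_dropouts = nrow(tr$faults$dropouts),
      has_drift = !is.null(tr$faults$drift),
      retention_target = if (id %in% ret_ids)
        retention_targets[match(id, ret_ids)] else NA_real_)
    if (nrow(tr$faults$jumps)) jumps[[id]] <-
      tibble::tibble(tree_id = id, tr$faults$jumps)
    if (nrow(tr$faults$spikes)) spikes[[id]] <-
      tibble::tibble(tree_id = id, tr$faults$spikes)
    if (nrow(tr$faults$dropouts)) dropouts[[id]] <-
      tibble::tibble(tree_id = id, tr$faults$dropouts)
    if (!is.null(tr$faults$drift)) drifts[[id]] <-
      tibble::tibble(tree_id = id, t_start = tr$faults$drift$t_start,
                     t_end = tr$faults$drift$t_end, size = tr$faults$drift$size)
  }
  truth <- dplyr::bind_rows(truth_rows)
  meta <- tibble::tibble(tree_id = truth$tree_id, site = "SYN",
                         species = truth$species, dbh = truth$dbh,
                         status = truth$status, bark_class = truth$bark_class,
                         irrigated = truth$irrigated)
  list(band = dplyr::bind_rows(bands), checks = dplyr::bind_rows(checks),
       met = met, meta = meta, truth = truth,
       schedules = list(jumps = dplyr::bind_rows(jumps),
                        spikes = dplyr::bind_rows(spikes),
                        dropouts = dplyr::bind_rows(dropouts),
                        drift = dplyr::bind_rows(drifts)),
       rain_days = attr(met, "rain_days"),
       start_date = start_date, end_date = start_date + n_days - 1,
       n_days = n_days, seed = seed)
}

#' Write a synthetic cohort to CSV input files
#'
#' Emits the four pipeline input tables plus ground-truth and fault-schedule
#' CSVs (ISO-8601 timestamps, UTC-suffixed).
#'
#' @param cohort a [generate_cohort()] bundle.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(tbl) {
    for (cc in names(tbl)) {
      if (inherits(tbl[[cc]], "POSIXct")) {
        tbl[[cc]] <- format(tbl[[cc]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
      }
    }
    tbl
  }
  readr::write_csv(fmt(cohort$band), file.path(dir, "band.csv"))
  readr::write_csv(fmt(cohort$checks), file.path(dir, "manual_checks.csv"))
  readr::write_csv(fmt(cohort$met), file.path(dir, "met.csv"))
  readr::write_csv(cohort$meta, file.path(dir, "meta.csv"))
  readr::write_csv(fmt(cohort$truth), file.path(dir, "truth.csv"))
  for (nm in names(cohort$schedules)) {
    sch <- cohort$schedules[[nm]]
    if (nrow(sch)) readr::write_csv(fmt(sch),
                                    file.path(dir, sprintf("truth_%s.csv", nm)))
  }
  invisible(dir)
}

#' Simulate a daily amplitude table with a known driver slope
#'
#' Daily-level generator for the amplitude-model stage: one shared standard
#' driver x per day, per-tree random intercepts and slopes, i.i.d. noise.
#'
#' @param n_trees,n_days table dimensions.
#' @param slope fixed driver slope (mm per SD of driver).
#' @param slope_sd SD of tree-level slope deviations.
#' @param intercept,intercept_sd fixed intercept (mm) and tree-level SD.
#' @param sigma residual SD (mm).
#' @param seed integer seed.
#' @return tibble `tree_id`, `day`, `x`, `A`.
#' @export
simulate_amplitude_table <- function(n_trees = 20, n_days = 40, slope = 0.02,
                                     slope_sd = 0.005, intercept = 0.20,
                                     intercept_sd = 0.05, sigma = 0.03,
                                     seed = 1) {
  withr::with_seed(seed, {
    x <- rnorm(n_days)
    b0 <- rnorm(n_trees, 0, intercept_sd)
    b1 <- rnorm(n_trees, 0, slope_sd)
    out <- tidyr::expand_grid(tree = seq_len(n_trees), day = seq_len(n_days))
    out$x <- x[out$day]
    out$A <- intercept + b0[out$tree] + (slope + b1[out$tree]) * out$x +
      rnorm(nrow(out), 0, sigma)
    tibble::tibble(tree_id = sprintf("T%02d", out$tree), day = out$day,
                   x = out$x, A = out$A)
  })
}

#' Simulate a daily increment table with a known rain effect
#'
#' @param n_trees,n_days table dimensions.
#' @param rain_prob probability a day is rainy (shared across trees).
#' @param rain_effect fixed rainy-minus-rain-free difference d (mm).
#' @param rain_effect_sd SD of tree-level rain-slope deviations.
#' @param intercept,intercept_sd rain-free-day increment (mm) and tree SD.
#' @param sigma residual SD (mm).
#' @param seed integer seed.
#' @return tibble `tree_id`, `day`, `rain`, `I`, plus random `bark_class`
#'   and `irrigated` columns carrying no effect.
#' @export
simulate_increment_table <- function(n_trees = 30, n_days = 60,
                                     rain_prob = 0.3, rain_effect = 0.12,
                                     rain_effect_sd = 0.03, intercept = 0.05,
                                     intercept_sd = 0.02, sigma = 0.05,
                                     seed = 1) {
  withr::with_seed(seed, {
    rain <- runif(n_days) < rain_prob
    if (!any(rain)) rain[sample(n_days, 1)] <- TRUE
    if (all(rain)) rain[sample(n_days, 1)] <- FALSE
    b0 <- rnorm(n_trees, 0, intercept_sd)
    b1 <- rnorm(n_trees, 0, rain_effect_sd)
    bark <- sample(c("thin", "thick"), n_trees, TRUE)
    irr <- runif(n_trees) < 0.3
    out <- tidyr::expand_grid(tree = seq_len(n_trees), day = seq_len(n_days))
    out$rain <- rain[out$day]
    out$I <- intercept + b0[out$tree] + (rain_effect + b1[out$tree]) * out$rain +
      rnorm(nrow(out), 0, sigma)
    tibble::tibble(tree_id = sprintf("T%02d", out$tree), day = out$day,
                   rain = out$rain, I = out$I,
                   bark_class = bark[out$tree], irrigated = irr[out$tree])
  })
}
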