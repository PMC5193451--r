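# Pipeline orchestration: ingest -> qc -> decompose -> wavelet phase ->
# drivers & mixed models, with CSV outputs and a machine-readable manifest.

#' Default pipeline configuration
#'
#' All thresholds of the analysis with their canonical defaults: 4 mm
#' manual-check tolerance, 0.5 mm hourly jump threshold, 50% usable-data
#' cut, rain threshold 0 mm, Morlet omega0 = 6, coherence cut 0.7, 75%
#' dominance for tree classification.
#'
#' @param ... named overrides, merged recursively into the defaults.
#' @return nested configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    site = "SYN",
    start = NULL, end = NULL,
    paths = list(band = NULL, manual = NULL, met = NULL, meta = NULL,
                 out_dir = "dendrocycle_run"),
    qc = list(jump_threshold = 0.5, manual_tol = 4, min_usable = 0.5,
              skip_manual = FALSE, spike_window = 5L, spike_k = 5,
              mad_floor = 0.01),
    decompose = list(min_coverage = 0.75),
    rain_threshold = 0,
    wavelet = list(omega0 = 6, dj = 1 / 20, period_range = c(0.25, 4),
                   octaves = 0.6, coherence_cut = 0.7, dominance = 0.75,
                   max_gap_fraction = 0.25),
    seed = 1)
  utils::modifyList(cfg, list(...))
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_config(), config)
  cfg$start <- as.Date(cfg$start)
  cfg$end <- as.Date(cfg$end)
  if (is.na(cfg$start) || is.na(cfg$end)) stop("config: start/end dates required")
  n_days <- as.integer(cfg$end - cfg$start) + 1L
  if (n_days < 14) stop("window too short for wavelet stage (need >= 14 days)")
  cfg$n_days <- n_days
  cfg
}

tree_genus <- function(species) vapply(strsplit(species %na0% "", " "),
                                       `[`, character(1), 1)

#' Run the full analysis pipeline
#'
#' Deterministic given inputs and configuration. Reads the four input
#' tables, screens each tree, decomposes usable trees, builds the site
#' ensemble band temperature and daily driver table, classifies each tree's
#' diurnal phase pattern, fits the amplitude-driver and rain-response mixed
#' models, and writes all output tables plus a manifest to
#' `config$paths$out_dir`.
#'
#' @param config configuration list (see [default_config()]) or path to a
#'   YAML file with the same structure. Alternatively pass `cohort` to run
#'   directly on an in-memory [generate_cohort()] bundle.
#' @param cohort optional cohort bundle standing in for the input files.
#' @return (invisibly) list with every stage's tables and the output dir.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  cfg <- read_config(config)
  out_dir <- cfg$paths$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # ---- ingest ----
  if (is.null(cohort)) {
    band_raw <- read_band_log(cfg$paths$band)
    checks <- read_manual_checks(cfg$paths$manual)
    met_raw <- read_met(cfg$paths$met)
    meta <- read_meta(cfg$paths$meta)
  } else {
    band_raw <- cohort$band; checks <- cohort$checks
    met_raw <- cohort$met; meta <- cohort$meta
  }
  grid <- band_grid(cfg$start, cfg$end)
  met <- tibble::tibble(
    timestamp = grid,
    t_air = resample_to_grid(met_raw$timestamp, met_raw$t_air, grid, "interpolate"),
    rh = resample_to_grid(met_raw$timestamp, met_raw$rh, grid, "interpolate"),
    ppt = resample_to_grid(met_raw$timestamp, met_raw$ppt, grid, "aggregate_sum") %na0% 0,
    rad = resample_to_grid(met_raw$timestamp, met_raw$rad, grid, "interpolate"))
  if ("et" %in% names(met_raw)) {
    met$et <- resample_to_grid(met_raw$timestamp, met_raw$et, grid, "interpolate")
  }
  sf_ens <- genus_ensemble_sf(met_raw)
  if (!is.null(sf_ens)) {
    for (cc in setdiff(names(sf_ens), "timestamp")) {
      met[[cc]] <- resample_to_grid(sf_ens$timestamp, sf_ens[[cc]], grid,
                                    "interpolate")
    }
  }
  ids <- intersect(meta$tree_id, unique(band_raw$tree_id))
  bands <- lapply(setNames(ids, ids), function(id) {
    as_band_series(band_raw[band_raw$tree_id == id, , drop = FALSE], grid, id)
  })

  # ---- qc ----
  qc_out <- lapply(bands, qc_tree, checks = checks,
                   manual_tol = cfg$qc$manual_tol,
                   skip_manual = cfg$qc$skip_manual,
                   jump_threshold = cfg$qc$jump_threshold,
                   spike_window = cfg$qc$spike_window, spike_k = cfg$qc$spike_k,
                   mad_floor = cfg$qc$mad_floor, min_usable = cfg$qc$min_usable)
  qc_report <- dplyr::bind_rows(lapply(qc_out, `[[`, "report"))
  usable <- select_usable_trees(qc_report, cfg$qc$min_usable)
  screened <- lapply(qc_out[usable], `[[`, "band")

  # ---- decompose ----
  decomps <- lapply(screened, decompose_tree, n_days = cfg$n_days,
                    min_coverage = cfg$decompose$min_coverage)
  tband <- ensemble_band_temp(screened)
  samples_tbl <- dplyr::bind_rows(lapply(decomps, function(d) {
    tibble::tibble(tree_id = d$tree_id, d$samples)
  }))
  daily_tbl <- dplyr::bind_rows(lapply(decomps, function(d) {
    tibble::tibble(tree_id = d$tree_id, d$daily)
  }))

  # ---- drivers ----
  drivers <- daily_driver_table(met, tband, rain_threshold = cfg$rain_threshold)
  rain_dates <- drivers$date[drivers$rain_day]

  # ---- wavelet phase ----
  wv <- cfg$wavelet
  tband_filled <- gap_fill_linear(tband$t_band)
  tband_field <- morlet_cwt(tband_filled, dt = 1 / SAMPLES_PER_DAY, dj = wv$dj,
                            period_range = wv$period_range, omega0 = wv$omega0)
  phases <- lapply(decomps, phase_classify_tree, tband_field = tband_field,
                   rain_dates = rain_dates, coherence_cut = wv$coherence_cut,
                   dominance = wv$dominance,
                   max_gap_fraction = wv$max_gap_fraction, dj = wv$dj,
                   period_range = wv$period_range, omega0 = wv$omega0,
                   octaves = wv$octaves)
  phase_days <- dplyr::bind_rows(lapply(phases, function(p) {
    tibble::tibble(tree_id = p$tree_id, p$days)
  }))
  phase_summary <- dplyr::bind_rows(lapply(phases, function(p) {
    tibble::tibble(tree_id = p$tree_id, theta_mean = p$theta_mean, r = p$r,
                   n_qualifying = p$n_qualifying,
                   tree_class = p$tree_class %na0% "unclassified",
                   n_classified_days = p$n_classified_days,
                   frac_days_coherent = p$frac_days_coherent)
  }))
  phase_summary <- dplyr::left_join(
    phase_summary, meta[, c("tree_id", "site", "species", "dbh", "status",
                            "bark_class", "irrigated")], by = "tree_id")

  # ---- class/amplitude summary (Table-3 analogue) ----
  rainfree_A <- daily_tbl[!(daily_tbl$date %in% rain_dates), , drop = FALSE]
  tree_A <- dplyr::summarise(dplyr::group_by(rainfree_A, .data$tree_id),
                             mean_A = mean(.data$A, na.rm = TRUE),
                             .groups = "drop")
  cls_tbl <- dplyr::left_join(phase_summary, tree_A, by = "tree_id")
  table3 <- dplyr::summarise(
    dplyr::group_by(cls_tbl, .data$site, .data$status, .data$tree_class),
    n = dplyr::n(), A_mean = mean(.data$mean_A, na.rm = TRUE),
    A_sd = sd(.data$mean_A, na.rm = TRUE), .groups = "drop")

  # ---- amplitude ~ driver mixed models (Table-4 analogue) ----
  shrink_ids <- phase_summary$tree_id[phase_summary$tree_class == "shrinking" &
                                        phase_summary$status == "live"]
  amp_data <- dplyr::inner_join(
    rainfree_A[rainfree_A$tree_id %in% shrink_ids, , drop = FALSE],
    drivers, by = "date")
  driver_cols <- c(t_band_range = "t_band_range_z", vpd_mean = "vpd_mean_z",
                   rad_sum = "rad_sum_z", et_sum = "et_sum_z")
  table4 <- list()
  for (dn in names(driver_cols)) {
    dc <- driver_cols[[dn]]
    if (!dc %in% names(amp_data)) next
    dd <- amp_data[!is.na(amp_data$A) & !is.na(amp_data[[dc]]), , drop = FALSE]
    if (nrow(dd) < 30 || length(unique(dd$tree_id)) < 3 ||
        var(dd[[dc]]) == 0) next
    fit <- fit_amplitude_mixed_model(dd, driver = dc)
    table4[[dn]] <- amplitude_model_row(cfg$site, dn, fit)
  }
  # sap flux: each tree gets its genus ensemble
  sf_cols <- grep("^sf_[^_]+_sum_z$", names(drivers), value = TRUE)
  if (length(sf_cols)) {
    genus <- tree_genus(meta$species[match(amp_data$tree_id, meta$tree_id)])
    amp_sf <- amp_data
    amp_sf$sf_z <- NA_real_
    for (g in unique(genus)) {
      gc <- sprintf("sf_%s_sum_z", g)
      if (gc %in% names(drivers)) {
        rows <- genus == g
        amp_sf$sf_z[rows] <- drivers[[gc]][match(amp_sf$date[rows], drivers$date)]
      }
    }
    dd <- amp_sf[!is.na(amp_sf$A) & !is.na(amp_sf$sf_z), , drop = FALSE]
    if (nrow(dd) >= 30 && length(unique(dd$tree_id)) >= 3 && var(dd$sf_z) > 0) {
      fit <- fit_amplitude_mixed_model(dd, driver = "sf_z")
      table4[["sf_sum"]] <- amplitude_model_row(cfg$site, "sf_sum", fit)
    }
  }
  table4 <- dplyr::bind_rows(table4)

  # ---- rain-response mixed models (Table-5 analogue) ----
  rain_data <- dplyr::left_join(daily_tbl,
                                drivers[, c("date", "rain_day")], by = "date")
  rain_data <- dplyr::left_join(rain_data,
                                meta[, c("tree_id", "status", "bark_class",
                                         "irrigated")], by = "tree_id")
  rain_data$rain <- rain_data$rain_day
  rain_data$I <- rain_data$I
  table5 <- list()
  live <- rain_data[rain_data$status == "live" & !is.na(rain_data$I), ]
  if (nrow(live) && length(unique(live$rain)) == 2) {
    do_bark <- length(unique(live$bark_class[!is.na(live$bark_class)])) == 2
    do_irr <- length(unique(live$irrigated)) == 2
    fit <- fit_rain_mixed_model(live, bark = do_bark, irrigated = do_irr)
    table5[["live"]] <- rain_model_row("live", cfg$site, fit)
  }
  dead <- rain_data[rain_data$status == "dead" & !is.na(rain_data$I), ]
  if (nrow(dead) && length(unique(dead$tree_id)) >= 2 &&
      length(unique(dead$rain)) == 2) {
    fit_d <- fit_rain_mixed_model(dead)
    table5[["dead"]] <- rain_model_row("dead", cfg$site, fit_d)
  }
  table5 <- dplyr::bind_rows(table5)

  # ---- outputs ----
  wr <- function(tbl, name) {
    tbl <- as.data.frame(tbl)
    for (cc in names(tbl)) {
      if (inherits(tbl[[cc]], "POSIXct")) {
        tbl[[cc]] <- format(tbl[[cc]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
      }
    }
    readr::write_csv(tbl, file.path(out_dir, name))
  }
  wr(qc_report, "qc_report.csv")
  wr(samples_tbl, "decomposition_samples.csv")
  wr(daily_tbl, "daily_metrics.csv")
  wr(tband, "ensemble_tband.csv")
  wr(drivers, "drivers.csv")
  wr(phase_days, "phase_days.csv")
  wr(phase_summary, "phase_summary.csv")
  wr(table3, "table3_like.csv")
  if (nrow(table4)) wr(table4, "table4_like.csv")
  if (nrow(table5)) wr(table5, "table5_like.csv")
  cfg_yaml <- yaml::as.yaml(lapply(config_for_manifest(cfg), identity))
  cfg_file <- tempfile(fileext = ".yaml")
  writeLines(cfg_yaml, cfg_file)
  manifest <- list(
    package = "dendrocycle",
    version = as.character(utils::packageVersion("dendrocycle")),
    seed = cfg$seed, site = cfg$site,
    window = c(as.character(cfg$start), as.character(cfg$end)),
    config_md5 = unname(tools::md5sum(cfg_file)),
    n_trees_input = length(bands), n_trees_usable = length(usable))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  unlink(cfg_file)

  invisible(list(config = cfg, qc_report = qc_report, bands = screened,
                 decompositions = decomps, tband = tband, drivers = drivers,
                 phases = phases, phase_summary = phase_summary,
                 phase_days = phase_days, daily = daily_tbl,
                 table3 = table3, table4 = table4, table5 = table5,
                 out_dir = out_dir))
}

config_for_manifest <- function(cfg) {
  cfg$start <- as.character(cfg$start)
  cfg$end <- as.character(cfg$end)
  cfg$paths <- NULL   # volatile filesystem locations stay out of the digest
  cfg
}

amplitude_model_row <- function(site, driver, fit) {
  fe <- fit$full$fixed
  srow <- fe[fe$term != "(Intercept)", , drop = FALSE]
  irow <- fe[fe$term == "(Intercept)", , drop = FALSE]
  tibble::tibble(site = site, driver = driver,
                 n_obs = fit$full$n_obs, n_trees = fit$full$n_groups,
                 AIC = fit$aic, AIC_null = fit$aic_null,
                 delta_AIC = fit$delta_aic,
                 chisq = fit$lrt$chisq, df = fit$lrt$df, p = fit$lrt$p,
                 slope = srow$estimate, slope_sd = srow$sd, slope_t = srow$t,
                 intercept = irow$estimate, intercept_sd = irow$sd,
                 intercept_t = irow$t,
                 pct_var_fixed = fit$full$pct_var_fixed,
                 pct_var_both = fit$full$pct_var_fixed_random,
                 singular = fit$full$singular)
}

rain_model_row <- function(category, site, fit) {
  p_rain <- fit$lrt$p[fit$lrt$model == "rain" & fit$lrt$vs == "null"]
  extras <- fit$lrt[fit$lrt$vs == "rain", , drop = FALSE]
  tibble::tibble(category = category, site = site,
                 n_obs = fit$models$rain$n_obs,
                 n_trees = fit$models$rain$n_groups,
                 AIC = fit$aic, AIC_null = fit$aic_null,
                 delta_AIC = fit$delta_aic, p = p_rain,
                 rain_effect = fit$rain_effect$estimate,
                 rain_effect_sd = fit$rain_effect$sd,
                 rain_effect_t = fit$rain_effect$t,
                 rainfree_I = fit$intercept$estimate,
                 rainfree_I_sd = fit$intercept$sd,
                 rainfree_I_t = fit$intercept$t,
                 p_bark = if ("rain_bark" %in% extras$model)
                   extras$p[extras$model == "rain_bark"] else NA_real_,
                 p_irrigated = if ("rain_irrigated" %in% extras$model)
                   extras$p[extras$model == "rain_irrigated"] else NA_real_,
                 singular = fit$models$rain$singular)
}
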