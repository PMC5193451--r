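# Daily climatic / biomicrometeorological covariates.

#' Vapor pressure deficit (Magnus/Tetens over water)
#'
#' es = 0.6108 exp(17.27 T / (T + 237.3)) kPa; VPD = es (1 - RH/100).
#'
#' @param t_air air temperature (degC).
#' @param rh relative humidity (0-100 %).
#' @return VPD in kPa.
#' @export
vapor_pressure_deficit <- function(t_air, rh) {
  0.6108 * exp(17.27 * t_air / (t_air + 237.3)) * (1 - rh / 100)
}

#' Daily driver table for one site
#'
#' Per local calendar day: range of ensemble band temperature, mean VPD,
#' sums of radiation, sap flux (per genus ensemble), evapotranspiration and
#' precipitation, and the rain-day flag (`ppt_sum > rain_threshold`). Each
#' continuous predictor is additionally returned z-scored across the
#' analyzed days (`*_z` columns) for use as scaled covariates.
#'
#' @param met gridded met tibble (`timestamp`, `t_air`, `rh`, `ppt`, `rad`,
#'   optional `et`, optional `sf_<genus>` ensemble columns).
#' @param tband tibble from [ensemble_band_temp()] (`time`, `t_band`), or a
#'   vector on the same grid.
#' @param rain_threshold mm of daily precipitation above which a day is
#'   rainy (default 0: any measurable rain).
#' @return tibble, one row per day.
#' @export
daily_driver_table <- function(met, tband = NULL, rain_threshold = 0) {
  date <- grid_dates(met$timestamp)
  vpd <- vapor_pressure_deficit(met$t_air, met$rh)
  tb <- if (is.null(tband)) rep(NA_real_, nrow(met))
        else if (is.data.frame(tband)) tband$t_band else tband
  rng <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) NA_real_ else max(v) - min(v)
  }
  msum <- function(v) if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
  base <- tibble::tibble(date = date, tb = tb, vpd = vpd, rad = met$rad,
                         ppt = met$ppt,
                         et = if ("et" %in% names(met)) met$et else NA_real_,
                         t_air = met$t_air)
  sf_cols <- grep("^sf_[^_]+$", names(met), value = TRUE)
  for (cc in sf_cols) base[[cc]] <- met[[cc]]
  no_met <- tapply(is.na(base$t_air), date, all)
  drop_days <- as.Date(names(no_met))[no_met]
  if (length(drop_days)) {
    warning(sprintf("daily_driver_table: %d day(s) without met data dropped",
                    length(drop_days)))
    base <- base[!(base$date %in% drop_days), , drop = FALSE]
  }
  out <- dplyr::summarise(
    dplyr::group_by(base, .data$date),
    t_band_range = rng(.data$tb),
    vpd_mean = mean(.data$vpd, na.rm = TRUE),
    rad_sum = msum(.data$rad),
    et_sum = msum(.data$et),
    ppt_sum = msum(.data$ppt) %na0% 0,
    dplyr::across(dplyr::all_of(sf_cols), msum, .names = "{.col}_sum"),
    .groups = "drop")
  out$rain_day <- out$ppt_sum > rain_threshold
  zcols <- c("t_band_range", "vpd_mean", "rad_sum", "et_sum",
             paste0(sf_cols, "_sum"))
  for (cc in zcols) {
    v <- out[[cc]]
    if (all(is.na(v))) { out[[paste0(cc, "_z")]] <- NA_real_; next }
    s <- sd(v, na.rm = TRUE)
    out[[paste0(cc, "_z")]] <- if (is.na(s) || s == 0) 0 * v
                               else (v - mean(v, na.rm = TRUE)) / s
  }
  out
}
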