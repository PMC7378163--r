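#' A recorded kelp-loss event
#'
#' One historical loss record: a region, the affected coastline length, the
#' percent cover lost there, and (when the source reported it) the reef
#' area lost directly. At least the coastline + cover-loss pair or the
#' direct area must be present.
#'
#' @param region Region identifier.
#' @param period,driver Free-text period and driver of loss (optional).
#' @param coastline_km Affected coastline length (km), >= 0.
#' @param cover_loss_pct Percent cover lost over the period.
#' @param area_loss_ha Reef area lost (ha) if reported directly; overrides
#'   the coastline route.
#' @return An object of class `loss_event`.
#' @export
loss_event <- function(region, period = NA_character_, driver = NA_character_,
                       coastline_km = NA_real_, cover_loss_pct = NA_real_,
                       area_loss_ha = NA_real_) {
  has_area <- is_scalar_number(area_loss_ha) && area_loss_ha >= 0
  has_coast <- is_scalar_number(coastline_km) && coastline_km >= 0 &&
    is_scalar_number(cover_loss_pct)
  if (!has_area && !has_coast)
    stop_invalid_input(
      "a loss_event needs area_loss_ha, or both coastline_km and cover_loss_pct")
  structure(list(region = as.character(region), period = period, driver = driver,
                 coastline_km = coastline_km, cover_loss_pct = cover_loss_pct,
                 area_loss_ha = area_loss_ha),
            class = "loss_event")
}

#' Reef area from coastline length
#'
#' Converts a length of affected coast into reef area using an empirical
#' coastline-to-reef ratio, for loss records that report only the stretch
#' of coast affected.
#'
#' @param coastline_km Coastline length (km), > 0.
#' @param coast_reef_ratio_ha_per_km Reef area per km of coast (ha km^-1),
#'   > 0; default from [kelp_params()].
#' @return Reef area (ha).
#' @examples
#' reef_area_from_coastline(800, 283.25)
#' @export
reef_area_from_coastline <- function(coastline_km,
                                     coast_reef_ratio_ha_per_km =
                                       kelp_params()$coast_reef_ratio_ha_per_km) {
  if (!is_scalar_number(coastline_km) || coastline_km <= 0)
    stop_invalid_input("`coastline_km` must be > 0")
  if (!is_scalar_number(coast_reef_ratio_ha_per_km) ||
      coast_reef_ratio_ha_per_km <= 0)
    stop_invalid_input("`coast_reef_ratio_ha_per_km` must be > 0")
  coastline_km * coast_reef_ratio_ha_per_km
}

#' Carbon impact of a kelp-loss event
#'
#' Resolves the lost reef area (reported area if present, otherwise
#' coastline x coast-to-reef ratio x cover-loss fraction), then applies the
#' mean per-area density and sequestration rate: area x density -> standing
#' stock lost, area x rate -> annual sequestration lost, and stock x
#' remineralised fraction -> carbon returned to CO2 through food webs.
#'
#' @param event A [loss_event()].
#' @param density Per-area carbon density ([uq()], Mg C ha^-1), mean > 0.
#' @param rate Per-area sequestration rate ([uq()], Mg C ha^-1 yr^-1),
#'   mean > 0.
#' @param reminer_frac Fraction of lost stock remineralised, in \[0, 1\]
#'   (default 0.89).
#' @param coast_reef_ratio_ha_per_km Ratio for the coastline route.
#' @return A `loss_impact`: list with `region`, `area_loss_ha`,
#'   `stock_loss_mgc`, `seq_loss_mgc_yr`, `remineralised_mgc`.
#' @export
event_impact <- function(event, density, rate, reminer_frac = 0.89,
                         coast_reef_ratio_ha_per_km =
                           kelp_params()$coast_reef_ratio_ha_per_km) {
  if (!inherits(event, "loss_event"))
    stop_invalid_input("`event` must be a loss_event")
  if (!inherits(density, "uncertain_quantity") || density$mean <= 0)
    stop_invalid_input("`density` must be an uncertain_quantity with mean > 0")
  if (!inherits(rate, "uncertain_quantity") || rate$mean <= 0)
    stop_invalid_input("`rate` must be an uncertain_quantity with mean > 0")
  if (!is_scalar_number(reminer_frac) || reminer_frac < 0 || reminer_frac > 1)
    stop_invalid_config("`reminer_frac` must lie in [0, 1]")

  if (is_scalar_number(event$area_loss_ha)) {
    area <- event$area_loss_ha
  } else {
    area <- reef_area_from_coastline(event$coastline_km,
                                     coast_reef_ratio_ha_per_km) *
      event$cover_loss_pct / 100
  }
  if (!is_scalar_number(area) || area < 0)
    stop_invalid_input("could not resolve a non-negative lost area for event")
  stock <- area * density$mean
  structure(list(region = event$region,
                 area_loss_ha = area,
                 stock_loss_mgc = stock,
                 seq_loss_mgc_yr = area * rate$mean,
                 remineralised_mgc = stock * reminer_frac),
            class = "loss_impact")
}

#' Sum loss impacts across events
#'
#' Component-wise sums; permutation-invariant.
#'
#' @param impacts Non-empty list of `loss_impact` objects.
#' @return A `loss_impact` with `region = "total"`.
#' @export
aggregate_losses <- function(impacts) {
  if (!is.list(impacts) || length(impacts) == 0L)
    stop_invalid_input("`impacts` must be a non-empty list")
  if (!all(vapply(impacts, inherits, logical(1), "loss_impact")))
    stop_invalid_input("all elements must be loss_impact objects")
  pick <- function(f) sum(vapply(impacts, `[[`, numeric(1), f))
  structure(list(region = "total",
                 area_loss_ha = pick("area_loss_ha"),
                 stock_loss_mgc = pick("stock_loss_mgc"),
                 seq_loss_mgc_yr = pick("seq_loss_mgc_yr"),
                 remineralised_mgc = pick("remineralised_mgc")),
            class = "loss_impact")
}

#' @export
print.loss_impact <- function(x, digits = 3, ...) {
  cat(sprintf("%s: area %s ha, stock %s Mg C, sequestration %s Mg C yr-1, remineralised %s Mg C\n",
              x$region, format(signif(x$area_loss_ha, digits)),
              format(signif(x$stock_loss_mgc, digits)),
              format(signif(x$seq_loss_mgc_yr, digits)),
              format(signif(x$remineralised_mgc, digits))))
  invisible(x)
}

#' A range-contraction scenario
#'
#' @param label Scenario label, e.g. `"RCP2.6"`.
#' @param distribution_loss_frac Fraction of current distribution lost by
#'   the horizon year, in \[0, 1\].
#' @param horizon_year Horizon year (default 2100).
#' @return An object of class `scenario_projection`.
#' @export
scenario_projection <- function(label, distribution_loss_frac,
                                horizon_year = 2100L) {
  if (!is_scalar_number(distribution_loss_frac) ||
      distribution_loss_frac < 0 || distribution_loss_frac > 1)
    stop_invalid_input("`distribution_loss_frac` must lie in [0, 1]")
  structure(list(label = as.character(label),
                 distribution_loss_frac = distribution_loss_frac,
                 horizon_year = as.integer(horizon_year)),
            class = "scenario_projection")
}

#' Projected carbon losses under a range-contraction scenario
#'
#' Applies the scenario's distribution-loss fraction to a convention point
#' of the baseline stock and flux ranges (the midpoint by default; the low
#' or high endpoint for sensitivity).
#'
#' @param proj A [scenario_projection()].
#' @param baseline_stock A [stock_range()] (Tg C).
#' @param baseline_flux A [flux_range()] (Tg C yr^-1).
#' @param convention `"midpoint"`, `"lo"` or `"hi"`.
#' @return List with `label`, `stock_loss_tg`, `flux_loss_tg_yr`,
#'   `convention`.
#' @examples
#' project_scenario(scenario_projection("RCP2.6", 0.49),
#'                  stock_range(10.3, 22.7), flux_range(1.3, 2.8))
#' @export
project_scenario <- function(proj, baseline_stock, baseline_flux,
                             convention = c("midpoint", "lo", "hi")) {
  if (!inherits(proj, "scenario_projection"))
    stop_invalid_input("`proj` must be a scenario_projection")
  if (!inherits(baseline_stock, "stock_range"))
    stop_invalid_input("`baseline_stock` must be a stock_range")
  if (!inherits(baseline_flux, "flux_range"))
    stop_invalid_input("`baseline_flux` must be a flux_range")
  convention <- match.arg(convention)
  point <- function(r) switch(convention,
    midpoint = range_midpoint(r), lo = r$lo, hi = r$hi)
  list(label = proj$label,
       stock_loss_tg = proj$distribution_loss_frac * point(baseline_stock),
       flux_loss_tg_yr = proj$distribution_loss_frac * point(baseline_flux),
       convention = convention)
}
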