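#' Carbon content of a kelp plant
#'
#' Kelp tissue carbon is taken as a fixed fraction (default 30%) of dry
#' weight.
#'
#' @param biomass_dry_kg Dry weight per plant (kg), vectorised.
#' @param carbon_fraction Fraction of dry weight that is carbon, in (0, 1\].
#' @return Carbon mass (kg C).
#' @examples
#' plant_carbon(1.0, 0.30)
#' @export
plant_carbon <- function(biomass_dry_kg, carbon_fraction = 0.30) {
  if (!is_scalar_number(carbon_fraction) ||
      carbon_fraction <= 0 || carbon_fraction > 1)
    stop_invalid_config("`carbon_fraction` must lie in (0, 1]")
  if (!is.numeric(biomass_dry_kg) || any(!is.finite(biomass_dry_kg)) ||
      any(biomass_dry_kg < 0))
    stop_invalid_input("`biomass_dry_kg` must be finite and >= 0")
  biomass_dry_kg * carbon_fraction
}

## SD of a sample; a single observation carries no spread information, so
## returns 0 rather than NA.
sample_sd <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

check_plants <- function(plants, need_growth = FALSE) {
  if (!is.data.frame(plants) || nrow(plants) == 0L)
    stop_invalid_input("`plants` must be a non-empty data frame")
  col <- if (need_growth) "growth_rate_kg_yr" else "biomass_dry_kg"
  if (!col %in% names(plants))
    stop_invalid_input(sprintf("`plants` lacks column '%s'", col))
  v <- plants[[col]]
  if (any(!is.finite(v)))
    stop_invalid_input(sprintf("column '%s' contains missing or non-finite values", col))
  if (need_growth && any(v < 0))
    stop_invalid_input("growth rates must be >= 0")
  if (!need_growth && any(v <= 0))
    stop_invalid_input("plant biomass must be > 0")
  v
}

check_plots <- function(plots) {
  if (!is.data.frame(plots) || nrow(plots) == 0L)
    stop_invalid_input("`plots` must be a non-empty data frame")
  if (!"density_per_m2" %in% names(plots))
    stop_invalid_input("`plots` lacks column 'density_per_m2'")
  d <- plots$density_per_m2
  if (any(!is.finite(d)) || any(d < 0))
    stop_invalid_input("plot densities must be finite and >= 0")
  d
}

## Combine a per-plant quantity (kg per plant, or kg per plant per year)
## with plot densities (plants m-2) into a per-hectare carbon aggregate.
## kg C m-2 -> Mg C ha-1 is x 1e4 m2/ha / 1e3 kg/Mg = x 10.
## SD by first-order (delta-method) propagation assuming the plant and
## plot surveys are independent:
##   sd ~= mean * sqrt(cv_plant^2 + cv_density^2)
aggregate_per_area <- function(values, plots, carbon_fraction,
                               stratified, unit) {
  d <- check_plots(plots)
  if (stratified) {
    if (!"region" %in% names(plots))
      stop_invalid_input("stratified aggregation needs a 'region' column in `plots`")
    by_region <- tapply(d, plots$region, mean)
    mean_d <- mean(by_region)
    sd_d <- sample_sd(as.numeric(by_region))
  } else {
    mean_d <- mean(d)
    sd_d <- sample_sd(d)
  }
  mean_v <- mean(values)
  sd_v <- sample_sd(values)

  mean_agg <- mean_v * carbon_fraction * mean_d * 10
  if (mean_d == 0) {
    warn_kelpcarbon("mean plot density is 0; degenerate per-area estimate",
                    "kelpcarbon_degenerate_warning")
    return(uq(0, 0, unit))
  }
  cv_v <- if (mean_v > 0) sd_v / mean_v else 0
  cv_d <- sd_d / mean_d
  uq(mean_agg, mean_agg * sqrt(cv_v^2 + cv_d^2), unit)
}

#' Standing carbon density from plant and plot surveys
#'
#' Upscales individual plant dry-weight biomass and plot-level plant
#' densities to a per-hectare standing carbon stock:
#' `mean(biomass) * carbon_fraction * mean(density)`, converted from
#' kg C m^-2 to Mg C ha^-1. The SD combines the two sample SDs by the
#' delta method assuming the surveys are independent (they come from
#' different field programs).
#'
#' By default all records are pooled with equal weight. With
#' `stratified = TRUE` plot densities are first averaged within each
#' `region` and the regional means are averaged with equal weight, which
#' guards against regions with many more quadrats dominating the estimate.
#'
#' @param plants Data frame with column `biomass_dry_kg` (> 0), one row
#'   per plant.
#' @param plots Data frame with columns `density_per_m2` (>= 0) and,
#'   if `stratified`, `region`.
#' @param carbon_fraction Carbon fraction of dry weight, in (0, 1\].
#' @param stratified Average densities per region first (default FALSE).
#' @return An [uq()] in Mg C ha^-1.
#' @examples
#' plants <- data.frame(biomass_dry_kg = c(0.4, 0.5, 0.6))
#' plots <- data.frame(region = "A", density_per_m2 = c(2, 2.2))
#' standing_density(plants, plots)
#' @export
standing_density <- function(plants, plots, carbon_fraction = 0.30,
                             stratified = FALSE) {
  plant_carbon(1, carbon_fraction)  # validates the fraction
  b <- check_plants(plants, need_growth = FALSE)
  aggregate_per_area(b, plots, carbon_fraction, stratified, "Mg C ha-1")
}

#' Net primary production per area from growth and plot surveys
#'
#' As [standing_density()] but combining annual per-plant dry-weight
#' production (`growth_rate_kg_yr`) with plot densities, yielding NPP in
#' Mg C ha^-1 yr^-1.
#'
#' @param growth Data frame with column `growth_rate_kg_yr` (>= 0).
#' @inheritParams standing_density
#' @return An [uq()] in Mg C ha^-1 yr^-1.
#' @export
npp_per_area <- function(growth, plots, carbon_fraction = 0.30,
                         stratified = FALSE) {
  plant_carbon(1, carbon_fraction)
  g <- check_plants(growth, need_growth = TRUE)
  aggregate_per_area(g, plots, carbon_fraction, stratified, "Mg C ha-1 yr-1")
}

#' Percent cover loss from a monitoring time series
#'
#' Compares the mean of the first `k` records with the mean of the last
#' `k` records of a cover time series:
#' `100 * (first_mean - last_mean) / first_mean`. A gain comes back as a
#' negative loss. For short series (`n < 2k`) the two windows overlap,
#' which is allowed with a warning since historical monitoring records are
#' often sparse. The result is invariant to the cover unit (percent or
#' fraction).
#'
#' @param series Data frame with columns `year` (strictly increasing) and
#'   `cover` (>= 0), or a numeric cover vector already in time order.
#' @param k Window length (records averaged at each end), default 3.
#' @return Percent loss (scalar; negative for a gain).
#' @examples
#' cover_loss_from_timeseries(c(80, 80, 80, 40, 40, 40)) # 50
#' @export
cover_loss_from_timeseries <- function(series, k = 3) {
  if (is.data.frame(series)) {
    if (!all(c("year", "cover") %in% names(series)))
      stop_invalid_input("`series` needs columns 'year' and 'cover'")
    if (is.unsorted(series$year, strictly = TRUE))
      stop_invalid_input("years must be strictly increasing")
    cov <- series$cover
  } else if (is.numeric(series)) {
    cov <- series
  } else {
    stop_invalid_input("`series` must be a data frame or numeric vector")
  }
  n <- length(cov)
  if (n < 2L) stop_invalid_input("need at least 2 records")
  if (any(!is.finite(cov)) || any(cov < 0))
    stop_invalid_input("cover values must be finite and >= 0")
  if (!is_scalar_number(k) || k < 1) stop_invalid_input("`k` must be >= 1")
  w <- min(as.integer(k), n)
  if (n < 2L * w)
    warn_kelpcarbon(
      sprintf("series length %d < 2k = %d: first/last windows overlap", n, 2L * w),
      "kelpcarbon_window_overlap_warning")
  first_mean <- mean(cov[seq_len(w)])
  last_mean <- mean(cov[seq.int(n - w + 1L, n)])
  if (first_mean == 0)
    stop_undefined_baseline("baseline (first-window mean) cover is 0; loss undefined")
  100 * (first_mean - last_mean) / first_mean
}
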