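#' Default accounting parameters
#'
#' Central defaults for the kelp blue-carbon accounting chain. The habitat
#' extent (3.2--7.1 Mha of kelp forest on temperate Australian reef) is an
#' input taken from published habitat mapping; the carbon fraction of dry
#' tissue is 30%; the sequestration fraction is the 11% of seaweed NPP
#' estimated to reach long-term storage minus the 0.9% buried on the
#' continental shelf (excluded to avoid double counting with sediment-based
#' budgets of other coastal ecosystems), i.e. 10.1% of NPP exported below
#' the mixed layer; 89% of carbon in lost kelp stock is remineralised to
#' CO2 through marine food webs.
#'
#' @return Named list of parameters:
#' \describe{
#'   \item{area_lo_mha, area_hi_mha}{habitat extent range (Mha).}
#'   \item{carbon_fraction}{carbon content of kelp dry weight (0.30).}
#'   \item{total_npp_frac}{fraction of NPP sequestered overall (0.11).}
#'   \item{shelf_burial_frac}{fraction of NPP buried on the shelf (0.009).}
#'   \item{reminer_frac}{fraction of lost stock remineralised (0.89).}
#'   \item{coast_reef_ratio_ha_per_km}{reef area per km of coastline
#'     (283.25 ha km^-1, back-calculated from the Western Australia
#'     heatwave record).}
#'   \item{rounding_sigfigs}{significant figures for presentation (3).}
#' }
#' @export
kelp_params <- function() {
  list(
    area_lo_mha = 3.2,
    area_hi_mha = 7.1,
    carbon_fraction = 0.30,
    total_npp_frac = 0.11,
    shelf_burial_frac = 0.009,
    reminer_frac = 0.89,
    coast_reef_ratio_ha_per_km = 283.25,
    rounding_sigfigs = 3
  )
}

#' Habitat area range from reef area and percent cover
#'
#' Minimum and maximum kelp extents are suitable reef area multiplied by
#' mean cover minus and plus one SD. A lower endpoint that would fall below
#' zero (patchy reefs with SD near the mean) is clamped to zero with a
#' warning; an upper endpoint above full cover is clamped to the reef area.
#'
#' @param reef_area_mha Suitable reef area (Mha), > 0.
#' @param cover An [uq()] with `mean` in \[0, 1\] (cover as a fraction).
#' @return An [area_range()] in Mha.
#' @examples
#' kelp_area_range(10, uq(0.5, 0.1, "fraction"))
#' @export
kelp_area_range <- function(reef_area_mha, cover) {
  if (!is_scalar_number(reef_area_mha) || reef_area_mha <= 0)
    stop_invalid_input("`reef_area_mha` must be a single number > 0")
  if (!inherits(cover, "uncertain_quantity"))
    stop_invalid_input("`cover` must be an uncertain_quantity")
  if (cover$mean < 0 || cover$mean > 1)
    stop_invalid_input("`cover$mean` must lie in [0, 1] (fractional cover)")
  lo_frac <- cover$mean - cover$sd
  if (lo_frac < 0) {
    warn_kelpcarbon(
      sprintf("cover mean - SD = %.3f < 0; lower extent clamped to 0", lo_frac),
      "kelpcarbon_clamp_warning")
    lo_frac <- 0
  }
  hi_frac <- min(1, cover$mean + cover$sd)
  area_range(reef_area_mha * lo_frac, reef_area_mha * hi_frac)
}

#' Deep-ocean sequestration fraction of NPP
#'
#' Subtracts shelf burial from the total sequestered fraction of seaweed
#' NPP, leaving only export below the mixed layer / deep-sea deposition.
#' This conservatively removes any production that could already be counted
#' as allochthonous carbon in sediment budgets of marshes, mangroves or
#' seagrass.
#'
#' @param total_npp_frac Total fraction of NPP sequestered, in \[0, 1\].
#' @param shelf_burial_frac Fraction of NPP buried on the continental
#'   shelf, `0 <= shelf_burial_frac <= total_npp_frac`.
#' @return The deep fraction `total_npp_frac - shelf_burial_frac`.
#' @examples
#' derive_deep_fraction(0.11, 0.009) # 0.101
#' @export
derive_deep_fraction <- function(total_npp_frac, shelf_burial_frac) {
  if (!is_scalar_number(total_npp_frac) || total_npp_frac < 0 || total_npp_frac > 1)
    stop_invalid_config("`total_npp_frac` must lie in [0, 1]")
  if (!is_scalar_number(shelf_burial_frac) || shelf_burial_frac < 0)
    stop_invalid_config("`shelf_burial_frac` must be >= 0")
  if (shelf_burial_frac > total_npp_frac)
    stop_invalid_config("shelf burial fraction exceeds total sequestered fraction")
  total_npp_frac - shelf_burial_frac
}

#' Sequestration fractions as a validated set
#'
#' @param total_npp_frac,shelf_burial_frac See [derive_deep_fraction()].
#' @return List with `total_npp_frac`, `shelf_burial_frac`, and the derived
#'   `deep_frac`.
#' @export
sequestration_fractions <- function(total_npp_frac = 0.11,
                                    shelf_burial_frac = 0.009) {
  list(total_npp_frac = total_npp_frac,
       shelf_burial_frac = shelf_burial_frac,
       deep_frac = derive_deep_fraction(total_npp_frac, shelf_burial_frac))
}

#' Per-area sequestration rate from NPP
#'
#' Linear scaling of a per-area NPP (mean and SD together) by the deep
#' sequestration fraction.
#'
#' @param npp An [uq()], Mg C ha^-1 yr^-1.
#' @param deep_frac Fraction of NPP sequestered in the deep ocean, in (0, 1\].
#' @return An [uq()], Mg C ha^-1 yr^-1.
#' @examples
#' per_area_sequestration(uq(3.9, 0.9, "Mg C ha-1 yr-1"), 0.101)
#' @export
per_area_sequestration <- function(npp, deep_frac) {
  if (!inherits(npp, "uncertain_quantity"))
    stop_invalid_input("`npp` must be an uncertain_quantity")
  if (!is_scalar_number(deep_frac) || deep_frac <= 0 || deep_frac > 1)
    stop_invalid_config("`deep_frac` must lie in (0, 1]")
  scale_uq(npp, deep_frac)
}

## Shared range-scaling core: Mha x Mg ha-1 = Tg, so the unit conversion
## is the identity; the published ranges carry area uncertainty only, the
## per-area SD is deliberately NOT folded in here (see mc_propagate for
## full propagation).
scale_range <- function(area, per_area, ctor) {
  if (!inherits(area, "area_range"))
    stop_invalid_input("`area` must be an area_range (Mha)")
  if (!inherits(per_area, "uncertain_quantity"))
    stop_invalid_input("per-area value must be an uncertain_quantity")
  if (per_area$mean < 0)
    stop_invalid_input("per-area mean must be >= 0")
  ctor(area$lo * per_area$mean, area$hi * per_area$mean)
}

#' Scale a per-area carbon density over a habitat area range
#'
#' @param area An [area_range()] (Mha).
#' @param density An [uq()] carbon density (Mg C ha^-1); `mean > 0` for a
#'   meaningful stock.
#' @return A [stock_range()] in Tg C. The range reflects area uncertainty
#'   only; the density SD is reported alongside, not compounded (use
#'   [mc_propagate()] for full propagation).
#' @examples
#' scale_stock(area_range(3.2, 7.1), uq(3.2, 0.5, "Mg C ha-1"))
#' @export
scale_stock <- function(area, density) {
  scale_range(area, density, stock_range)
}

#' Scale a per-area rate over a habitat area range
#'
#' @param area An [area_range()] (Mha).
#' @param rate An [uq()] per-area rate (Mg C ha^-1 yr^-1).
#' @return A [flux_range()] in Tg C yr^-1.
#' @examples
#' scale_flux(area_range(3.2, 7.1), uq(0.3939, 0.0909, "Mg C ha-1 yr-1"))
#' @export
scale_flux <- function(area, rate) {
  scale_range(area, rate, flux_range)
}
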