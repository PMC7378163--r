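dens32 <- uq(3.2, 0.5, "Mg C ha-1")
rate394 <- uq(0.3939, 0.0909, "Mg C ha-1 yr-1")

test_that("coastline converts to reef area by the empirical ratio", {
  # ratio back-calculated from the heatwave record:
  # 97,438 ha / (800 km x 0.43) = 283.25 ha km-1 -- verify the oracle
  expect_equal(97438 / (800 * 0.43), 283.25, tolerance = 1e-6)
  expect_equal(kelp_params()$coast_reef_ratio_ha_per_km, 283.25)

  expect_equal(reef_area_from_coastline(100, 283.2), 28320)
  expect_equal(reef_area_from_coastline(1, 1), 1)
  expect_equal(reef_area_from_coastline(0.5, 200), 100)
  expect_error(reef_area_from_coastline(0, 283.25),
               class = "kelpcarbon_invalid_input")
  expect_error(reef_area_from_coastline(100, -1),
               class = "kelpcarbon_invalid_input")
})

test_that("event impact applies density, rate and remineralisation to lost area", {
  unit <- event_impact(loss_event("u", area_loss_ha = 1),
                       uq(1, 0, "Mg C ha-1"), uq(1, 0, "Mg C ha-1 yr-1"),
                       reminer_frac = 0)
  expect_equal(unit$area_loss_ha, 1)
  expect_equal(unit$stock_loss_mgc, 1)
  expect_equal(unit$seq_loss_mgc_yr, 1)
  expect_equal(unit$remineralised_mgc, 0)

  wa <- event_impact(loss_event("WA", area_loss_ha = 97438), dens32, rate394)
  expect_equal(wa$stock_loss_mgc, 311801.6, tolerance = 1e-6)
  # within 1% of the published 310,949 Mg C
  expect_lt(abs(wa$stock_loss_mgc - 310949) / 310949, 0.01)
  expect_equal(wa$remineralised_mgc, wa$stock_loss_mgc * 0.89)

  tas <- event_impact(loss_event("TAS", area_loss_ha = 4861), dens32, rate394)
  expect_lt(abs(tas$seq_loss_mgc_yr - 1908) / 1908, 0.01)

  # coastline route: 800 km x 283.25 ha/km x 43% reproduces the reported area
  coast <- event_impact(loss_event("WA", coastline_km = 800,
                                   cover_loss_pct = 43), dens32, rate394)
  expect_equal(coast$area_loss_ha, 97438, tolerance = 1e-9)

  # reported area overrides the coastline route
  both <- event_impact(loss_event("X", coastline_km = 800,
                                  cover_loss_pct = 43, area_loss_ha = 10),
                       dens32, rate394)
  expect_equal(both$area_loss_ha, 10)
})

test_that("event impact is linear in lost area", {
  e1 <- event_impact(loss_event("a", area_loss_ha = 5000), dens32, rate394)
  e2 <- event_impact(loss_event("a", area_loss_ha = 10000), dens32, rate394)
  expect_equal(e2$stock_loss_mgc, 2 * e1$stock_loss_mgc, tolerance = 1e-12)
  expect_equal(e2$seq_loss_mgc_yr, 2 * e1$seq_loss_mgc_yr, tolerance = 1e-12)
  expect_equal(e2$remineralised_mgc, 2 * e1$remineralised_mgc,
               tolerance = 1e-12)
  expect_lte(e1$remineralised_mgc, e1$stock_loss_mgc)
})

test_that("loss aggregation sums component-wise and ignores order", {
  mk <- function(a) event_impact(loss_event("r", area_loss_ha = a),
                                 uq(1, 0, "x"), uq(1, 0, "x"))
  imps <- lapply(c(1, 1), mk)
  tot <- aggregate_losses(imps)
  expect_equal(tot$area_loss_ha, 2)
  expect_equal(tot$stock_loss_mgc, 2)
  expect_equal(tot$remineralised_mgc, 2 * 0.89)

  shuffled <- lapply(c(3, 1, 2), mk)
  expect_equal(aggregate_losses(shuffled)$stock_loss_mgc,
               aggregate_losses(rev(shuffled))$stock_loss_mgc)
  expect_error(aggregate_losses(list()), class = "kelpcarbon_invalid_input")
})

test_that("bundled historical records reproduce published per-event losses", {
  tab <- loss_fixture
  events <- kelp_loss_events()
  expect_length(events, 5)
  imps <- lapply(events, event_impact, density = dens32, rate = rate394)
  for (i in seq_along(imps)) {
    expect_lt(abs(imps[[i]]$stock_loss_mgc - tab$published_stock_loss_mgc[i]) /
                tab$published_stock_loss_mgc[i], 0.01)
    expect_lt(abs(imps[[i]]$seq_loss_mgc_yr - tab$published_seq_loss_mgc_yr[i]) /
                tab$published_seq_loss_mgc_yr[i], 0.01)
  }
  # column sums of the five records
  expect_equal(sum(tab$area_loss_ha), 137557)
  expect_equal(sum(tab$published_stock_loss_mgc), 438982)
  expect_equal(sum(tab$published_seq_loss_mgc_yr), 53988)
})

test_that("scenario projection scales a convention point of the baseline", {
  stock <- stock_range(10.3, 22.7)
  flux <- flux_range(1.3, 2.8)
  p26 <- project_scenario(scenario_projection("RCP2.6", 0.49), stock, flux)
  expect_equal(p26$stock_loss_tg, 0.49 * 16.5, tolerance = 1e-12)

  none <- project_scenario(scenario_projection("none", 0), stock, flux)
  expect_equal(none$stock_loss_tg, 0)
  expect_equal(none$flux_loss_tg_yr, 0)

  all <- project_scenario(scenario_projection("all", 1), stock, flux)
  expect_equal(all$stock_loss_tg, range_midpoint(stock))
  expect_equal(all$flux_loss_tg_yr, range_midpoint(flux))

  lo <- project_scenario(scenario_projection("x", 0.5), stock, flux,
                         convention = "lo")
  expect_equal(lo$stock_loss_tg, 0.5 * 10.3)
  expect_error(scenario_projection("bad", 1.2),
               class = "kelpcarbon_invalid_input")
})
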