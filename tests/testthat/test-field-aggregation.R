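test_that("plant carbon is a fixed fraction of dry weight", {
  expect_equal(plant_carbon(1.0, 0.30), 0.30)
  expect_equal(plant_carbon(2.5, 0.30), 0.75)
  x <- c(0.2, 1.7, 3.3)
  expect_equal(plant_carbon(x, 1.0), x)
  expect_error(plant_carbon(1, 0), class = "kelpcarbon_invalid_config")
  expect_error(plant_carbon(1, 1.2), class = "kelpcarbon_invalid_config")
})

test_that("standing density upscales plant biomass x plot density correctly", {
  # hand oracle: 0.5 kg x 0.30 x 2.13 m-2 = 0.3195 kg C m-2 = 3.195 Mg C ha-1
  zero_var <- standing_density(const_plants(10, 0.5), const_plots(10, 2.13), 0.30)
  expect_equal(zero_var$mean, 3.195, tolerance = 1e-12)
  expect_equal(zero_var$sd, 0)

  # unit-conversion identity: 1 kg plant-1 x 1 plant m-2 x frac 1 = 10 Mg C ha-1
  one <- standing_density(const_plants(1, 1), const_plots(1, 1), 1.0)
  expect_equal(one$mean, 10)
  expect_equal(one$sd, 0)

  empty <- data.frame(site_id = character(0), biomass_dry_kg = numeric(0))
  expect_error(standing_density(empty, const_plots(3, 1)),
               class = "kelpcarbon_invalid_input")
  expect_warning(z <- standing_density(const_plants(3, 1), const_plots(3, 0)),
                 class = "kelpcarbon_degenerate_warning")
  expect_equal(c(z$mean, z$sd), c(0, 0))
})

test_that("NPP per area mirrors standing density with growth rates", {
  npp <- npp_per_area(const_growth(10, 0.609), const_plots(10, 2.133), 0.30)
  expect_equal(npp$mean, 0.609 * 0.30 * 2.133 * 10, tolerance = 1e-12)
  expect_equal(round(npp$mean, 1), 3.9)

  z <- npp_per_area(const_growth(5, 0), const_plots(5, 2), 0.30)
  expect_equal(c(z$mean, z$sd), c(0, 0))

  expect_error(npp_per_area(const_plants(5, 1), const_plots(5, 1)),
               class = "kelpcarbon_invalid_input")
})

test_that("aggregates are linear in carbon fraction and mean density", {
  plants <- data.frame(biomass_dry_kg = lnorm_sample(40, 0.5, 0.3, 11))
  plots <- const_plots(20, lnorm_sample(20, 2, 0.2, 12))
  base <- standing_density(plants, plots, 0.15)
  dbl <- standing_density(plants, plots, 0.30)
  expect_equal(dbl$mean, 2 * base$mean, tolerance = 1e-12)
  expect_equal(dbl$sd, 2 * base$sd, tolerance = 1e-12)

  plots2 <- plots
  plots2$density_per_m2 <- 3 * plots2$density_per_m2
  tri <- standing_density(plants, plots2, 0.15)
  expect_equal(tri$mean, 3 * base$mean, tolerance = 1e-12)
})

test_that("delta-method SD matches a Monte Carlo oracle within 5% at CV <= 0.5", {
  # grid keeps the combined CV of the product at or below 0.5, where the
  # first-order approximation is valid
  grid <- list(c(0.11, 0.11), c(0.20, 0.20), c(0.30, 0.30),
               c(0.35, 0.35), c(0.45, 0.15), c(0.40, 0.30))
  for (cvs in grid) {
    plants <- data.frame(biomass_dry_kg = lnorm_sample(200, 0.5, cvs[1], 21))
    plots <- const_plots(200, pmax(1e-6, lnorm_sample(200, 2.13, cvs[2], 22)))
    est <- standing_density(plants, plots, 0.30)

    mb <- mean(plants$biomass_dry_kg); sb <- sd(plants$biomass_dry_kg)
    md <- mean(plots$density_per_m2); sdd <- sd(plots$density_per_m2)
    mc_sd <- withr::with_seed(23, {
      x <- rnorm(1e5, mb, sb); y <- rnorm(1e5, md, sdd)
      sd(x * y * 0.30 * 10)
    })
    expect_lt(abs(est$sd - mc_sd) / mc_sd, 0.05)
  }
})

test_that("region-stratified aggregation equalises regional weight", {
  plants <- const_plants(4, 1)
  # region A has 8 plots at density 1, region B has 2 plots at density 3:
  # pooled mean 1.4, stratified mean 2
  plots <- rbind(const_plots(8, 1, region = "A"),
                 const_plots(2, 3, region = "B"))
  pooled <- standing_density(plants, plots, 1.0)
  strat <- standing_density(plants, plots, 1.0, stratified = TRUE)
  expect_equal(pooled$mean, 14)
  expect_equal(strat$mean, 20)
})

test_that("cover loss compares first and last window means", {
  expect_equal(cover_loss_from_timeseries(c(80, 80, 80, 40, 40, 40)), 50)
  expect_equal(cover_loss_from_timeseries(c(60, 60, 60, 60, 60, 60)), 0)
  # hand oracle: 100 * (90 - 10) / 90
  expect_equal(cover_loss_from_timeseries(c(90, 85, 95, 10, 12, 8)),
               100 * (90 - 10) / 90)
  # a gain comes back negative
  expect_lt(cover_loss_from_timeseries(c(20, 20, 20, 50, 50, 50)), 0)

  # invariant to the cover unit
  x <- c(82, 75, 91, 34, 28, 30)
  expect_equal(cover_loss_from_timeseries(x / 100),
               cover_loss_from_timeseries(x))

  # short series: overlapping windows allowed with a warning
  expect_warning(l <- cover_loss_from_timeseries(c(80, 60, 40)),
                 class = "kelpcarbon_window_overlap_warning")
  expect_equal(l, 100 * (60 - 60) / 60)

  expect_error(cover_loss_from_timeseries(c(0, 0, 0, 10, 10, 10)),
               class = "kelpcarbon_undefined_baseline")
  df <- data.frame(year = c(2000, 1999), cover = c(50, 60))
  expect_error(cover_loss_from_timeseries(df),
               class = "kelpcarbon_invalid_input")
})
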