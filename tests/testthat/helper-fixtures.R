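# Shared builders for the test suite. All randomness goes through fixed
# seeds so every run is identical.

const_plants <- function(n, biomass) {
  data.frame(site_id = paste0("s", seq_len(n)), biomass_dry_kg = biomass)
}

const_plots <- function(n, density, region = "A") {
  data.frame(plot_id = paste0("p", seq_len(n)), region = region,
             density_per_m2 = density)
}

const_growth <- function(n, growth) {
  data.frame(site_id = paste0("s", seq_len(n)), biomass_dry_kg = 1,
             growth_rate_kg_yr = growth)
}

# Lognormal sample with a given arithmetic mean and CV.
lnorm_sample <- function(n, mean, cv, seed) {
  withr::with_seed(seed, {
    s2 <- log(1 + cv^2)
    rlnorm(n, log(mean) - s2 / 2, sqrt(s2))
  })
}

# Published multi-ecosystem budget table and historical loss records used
# across tests (loaded once; these are literature values shipped with the
# package).
budget_fixture <- australian_blue_carbon()
loss_fixture <- kelp_loss_table()
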