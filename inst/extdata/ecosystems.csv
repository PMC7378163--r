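ecosystem,density_mean,density_sd,rate_mean,rate_sd,stock_area_lo_mha,stock_area_hi_mha,stock_lo_tg,stock_hi_tg,flux_area_lo_mha,flux_area_hi_mha,flux_lo_tg,flux_hi_tg,source
Tidal marshes,7.5,6.1,0.39,0.3,1.4,1.5,2.3,2.6,1.4,1.5,0.48,0.54,literature
Mangrove forests,125,90,12.6,0.9,0.3,1.1,50,158,0.3,1.1,0.4,1.4,literature
Seagrass beds,1.9,2.0,0.36,0.3,9.3,12.8,16,22,9.3,12.8,2.5,3.5,literature
Kelp forests,3.2,0.5,0.40,0.1,3.2,7.1,10.3,22.7,3.5,7.1,1.3,2.8,literature
Total,NA,NA,NA,NA,14.2,22.5,77,206,14.2,22.5,4.9,8.5,literature
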