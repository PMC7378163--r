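region,period,driver,coastline_km,cover_loss_pct,area_loss_ha,published_stock_loss_mgc,published_seq_loss_mgc_yr
Western Australia,2005-2015,Marine heatwave,800,43.0,97438,310949,38242
South Australia,1968-2007,Coastal pollution,20,60,6179,19720,2425
Victoria,1958-2014,Warming and drought,40,85.8,17665,56375,6933
Tasmania,2001-2017,Sea urchin grazing,80,11.8,4861,15513,1908
New South Wales,2002-2010,Tropical fish grazing,25,88.7,11414,36425,4480
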