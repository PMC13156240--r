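class,area_2008_km2,area_2019_km2,area_2024_km2
open_water,1785,1866,1850
developed_open,6330,6476,6720
developed_low,3084,3259,3365
developed_medium,641,730,781
developed_high,156,181,195
barren,347,366,480
deciduous_forest,254,239,236
evergreen_forest,38500,35759,35521
mixed_forest,846,648,590
shrub_scrub,4270,5065,5457
herbaceous,4830,6665,6409
hay_pasture,7140,7527,7826
cultivated_crops,17730,17426,16885
woody_wetlands,30831,30611,30025
emergent_wetlands,868,794,1271
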