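stratum,family,statistic,expected
ri_adult,richness,n_1,37
ri_adult,richness,n_2,18
nc_adult_a,richness,n_1,12
nc_adult_a,richness,n_2,34
nc_adult_a,richness,n_3,2
ri_juvenile,richness,n_1,31
nc_juv_a,richness,n_1,21
ri_adult,pairwise,c|AlotL1|Tgut,15
ri_adult,pairwise,c|AlotL1|Tspe,3
ri_adult,pairwise,c|Tgut|Tspe,0
ri_adult,solitary,s|Tspe,24
nc_adult_a,pairwise,c|AlotL1|Tsept,13
nc_adult_a,pairwise,c|AlotL2|Tsept,16
nc_adult_a,pairwise,c|AlotL1|AlotL2,1
nc_adult_a,pairwise,c|Tgut|Tsept,2
nc_adult_b,pairwise,c|AlotL1|Tsept,4
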