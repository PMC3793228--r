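hotspot,area_km2,species_total,species_endemic,mean_rate_printed,species_density_printed,speciation_density_printed
California Floristic Province,293804,8000,2124,0.39,0.027,1.32e-06
Cape Floristic Region,78555,9000,6210,0.40,0.196,5.05e-06
Cerrado,2031990,12669,4215,0.58,0.060,0.29e-06
Hawaiian Archipelago,28311,1004,900,0.73,0.035,25.68e-06
Mediterranean Floristic Province,2085292,22500,11700,1.07,0.010,0.52e-06
Paramos,35000,3431,,1.36,0.098,38.80e-06
Southwest Australia,356717,5500,2948,0.14,0.015,0.38e-06
Succulent Karoo,102691,6350,2439,0.76,0.062,7.38e-06
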