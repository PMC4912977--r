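# Physicochemical properties of the three bundled PBDE congeners.
# Partition coefficients (log10, 25 degC): case-study values (BDE-47 /
# BDE-99 / BDE-209 KAW -1.7/-2.9/-1.9, KOW 6.6/7.28/9.97, KOA 8.3/10.2/11.8).
# Half-lives are RECONSTRUCTED, not measured here: air half-lives follow the
# EQC half-life classes used in the Danish per-capita PBDE model this case
# study scales from; water and soil are 5500 h, identical across congeners
# and equal to each other; sediment is 4 x soil (22000 h), following the
# Wania & Dugani estimate for BDE-209 applied to all three since the
# water/soil/sediment half-lives are congener-independent. Activation
# energies: 10000 J/mol (air), 30000 J/mol (water, soil, sediment).
# Phase-change enthalpies default to 0 (no partition-coefficient
# temperature correction).
name,molar_mass,reference_temperature,log_kow,log_kaw,log_koa,vapor_pressure,solubility,half_life_air,half_life_water,half_life_soil,half_life_sediment,ea_air,ea_water,ea_soil,ea_sediment,dh_kaw,dh_koa,dh_kow
BDE-47,485.79,298.15,6.6,-1.7,8.3,NA,NA,170,5500,5500,22000,10000,30000,30000,30000,0,0,0
BDE-99,564.69,298.15,7.28,-2.9,10.2,NA,NA,550,5500,5500,22000,10000,30000,30000,30000,0,0,0
BDE-209,959.17,298.15,9.97,-1.9,11.8,NA,NA,1700,5500,5500,22000,10000,30000,30000,30000,0,0,0
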