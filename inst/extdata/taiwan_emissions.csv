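# Taiwan PBDE emission scenario: kg per hour into each compartment.
# Mode split 81 % air / 15 % soil / 4 % water for every congener; no direct
# emissions to sediment. Annual totals: 52.79 / 76.82 / 998.1 kg.
congener,compartment,kg_per_hour
BDE-47,air,4.90e-3
BDE-47,water,0.212e-3
BDE-47,soil,0.914e-3
BDE-99,air,7.12e-3
BDE-99,water,0.309e-3
BDE-99,soil,1.34e-3
BDE-209,air,92.5e-3
BDE-209,water,4.04e-3
BDE-209,soil,17.4e-3
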