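# Measured PBDE concentration ranges used for model benchmarking.
# Provenance is carried per row; compartments with no published data
# (coastal water around Taiwan) are deliberately absent.
# The BDE-209 air range is the span of reported station means
# (18 +/- 1.3 to 75 +/- 16.8 pg/m3, Tainan).
congener,compartment,low,high,units,source
BDE-47,air,0.41,12.7,pg/m3,Lin et al. - South/East China Sea atmospheric sampling
BDE-99,air,0.15,11.3,pg/m3,Lin et al. - South/East China Sea atmospheric sampling
BDE-209,air,18,75,pg/m3,Lin et al. - Tainan
BDE-47,soil,75,104,ng/g dw,WHO via Palm et al. - industrial area; all tetra-BDE congeners
BDE-99,soil,41,84,ng/g dw,WHO via Palm et al. - industrial area; all penta-BDE congeners
BDE-209,soil,260,330,ng/g dw,WHO via Palm et al. - industrial area
BDE-47,sediment,5e-05,2.7,ng/g dw,Li et al. - East China Sea sediment
BDE-99,sediment,5e-05,2.2,ng/g dw,Li et al. - East China Sea sediment
BDE-209,sediment,0.3,44.6,ng/g dw,Li et al. - East China Sea sediment
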