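# pbdefate

Multimedia fugacity fate modeling of polybrominated diphenyl ethers
(PBDEs) — a Level I–III Mackay-type mass-balance engine for a
four-compartment evaluative environment (air, water, soil, sediment),
bundled with a case study of BDE-47, BDE-99 and BDE-209 in a
100 km × 100 km western-Taiwan land/coastal domain.

It is written for environmental-fate modelers and exposure scientists who
want to ask: given a regional emission inventory and a chemical's
partitioning and persistence properties, where does the chemical
accumulate, how fast does it leave, and by which pathways?

## The model

Fugacity *f* (Pa) is a chemical's escaping tendency from a phase;
concentration is *C = Z f*, with the fugacity capacity *Z*
(mol m⁻³ Pa⁻¹) built from the partition coefficients:
*Z*<sub>air</sub> = 1/(RT), *Z*<sub>water</sub> = *Z*<sub>air</sub>/K<sub>AW</sub>,
solid phases via K<sub>OC</sub> = 0.41 K<sub>OW</sub> and the organic-carbon
fraction, aerosol via K<sub>OA</sub>. Transport and loss processes are
conductances *D* (mol Pa⁻¹ h⁻¹) — two-film diffusion, rain and aerosol
deposition, sediment deposition/resuspension/burial, soil runoff,
first-order degradation, bulk advection — and every flux is *D f*.

* **Level I**: closed-system equilibrium — mass shares Z·V/ΣZ·V.
* **Level II**: steady input at systemwide equilibrium — residence times,
  1/τ = 1/τ<sub>reaction</sub> + 1/τ<sub>advection</sub>.
* **Level III**: non-equilibrium steady state — a 4×4 linear balance per
  chemical with an itemized flux ledger and conservation checked to
  10⁻⁹.

Half-lives are temperature-corrected by an Arrhenius factor, partition
coefficients by a van't Hoff factor. A seeded synthetic-scenario
generator (log K<sub>OW</sub> 4–11, log K<sub>AW</sub> −6–0, half-lives
10–10⁶ h) backs the property-based test suite.

## Worked example

```r
library(pbdefate)

case <- run_pbde_case()   # bundled congeners, Taiwan domain, Taiwan emissions
subset(case$distribution, congener == "BDE-99")
#>  congener compartment fugacity_pa mass_kg share_pct
#>    BDE-99         air    1.92e-10    0.47      1.70
#>    BDE-99       water    2.02e-12    1.27      4.63
#>    BDE-99        soil    7.71e-13   15.99     58.10
#>    BDE-99    sediment    7.61e-12    9.81     35.60
```

Of the ~27.5 kg of BDE-99 standing in the domain at steady state, 58 %
sits in soil and 36 % in sediment — the two solid compartments dominate
because K<sub>OW</sub> is high and degradation there is slow. The flux
ledger (`case$ledgers[["BDE-99"]]`) itemizes every pathway in kg/h with
percentages on two labelled bases (share of total system input, share of
the source compartment's gross input), and the spin-up estimate
(standing mass / input rate) is reported per congener:

```r
signif(case$spin_up_hours, 4)
#>  BDE-47  BDE-99 BDE-209
#>    1833    3141    5934
```

Modeled concentrations can be benchmarked against the bundled measured
ranges:

```r
cmp <- compare_to_observations(case)
subset(cmp, compartment == "air" & congener == "BDE-47")
#>  congener compartment value  low high units_model ... status ratio_to_nearest_bound
#>    BDE-47         air  33.6 0.41 12.7       pg/m3 ...  above                   2.64
```

Modeled air concentrations sit a factor 2–4 above offshore measurements
(the domain straddles the emission source region), soil concentrations
sit below industrial-area readings — the same qualitative picture as the
study the case reproduces.

Every piece is swappable: `build_taiwan_environment()` /
`read_environment_config()` for the domain, `taiwan_emission_scenario()` /
`scale_reference()` for emissions (the per-capita scaling chain with
industrial and degradation factors), `pbde_congeners()` /
`read_chemical_table()` for the chemicals, and `level1()` / `level2()` /
`level3()` / `compute_z()` / `compute_d_values()` for engine-level work.
`inst/scripts/run_case_study.R` wraps the whole run for shell use.

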