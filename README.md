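# acetoclast

Simulation and calibration toolkit for anaerobic digestion with **two
competing acetoclastic methanogens**. Demand-driven biogas production
requires feeding digesters in pulses, which risks organic overloading and
acidification. Whether a digester survives an overload depends strongly on
which acetate-splitting methanogen dominates: *Methanosaeta* (high
affinity, washed in by steady feeding, but inhibited as soon as the pH
drops below 7) or *Methanosarcina* (fast, acid-tolerant, but needing high
acetate concentrations to compete). `acetoclast` is for process engineers
and microbial ecologists who want to simulate, calibrate and reason about
this competition and use the feeding regime as a microbial resources
management tool.

## The model

The package implements the Anaerobic Digestion Model No. 1 (ADM1, the IWA
standard ODE model of anaerobic digestion) for a CSTR, with the
acetoclastic guild split in two. Each population follows Monod uptake

    rho_j = k_m,j * S_ac/(K_j + S_ac) * X_j * I_j,

with inhibition `I_j = I_pH,j * I_IN * I_nh3`, where the pH factor uses the
lower-limit exponential form `exp(-3*((pH - pH_ul)/(pH_ul - pH_ll))^2)`
below `pH_ul`. The fitted kinetics are

| guild | Y | k_m (1/d) | K (gCOD/L) | k_dec (1/d) | pH_ll / pH_ul |
|---|---|---|---|---|---|
| X_ac1 *Methanosarcina* | 0.033 | 20 | 0.32 | 0.02 | 4 / 5.5 |
| X_ac2 *Methanosaeta* | 0.033 | 14.5 | 0.09 | 0.02 | 6.3 / 7 |

All other guilds and constants follow the mesophilic ADM1 benchmark set
(with re-fitted propionate/butyrate kinetics). The inorganic carbon and
nitrogen equations carry per-process balancing terms so every process
closes COD, C and N exactly; pH comes from an algebraic charge-balance
solve; the headspace vents by overpressure. Feed schedules are first-class
objects (continuous, daily/every-second-day pulses, overloading
disturbances), and the chemostat washout boundary
`HRT_crit = 1/(Y*k_m*S/(K+S) - k_dec)` is available in closed form.

## Worked example

Simulate the two 6-L laboratory reactors fed 37.2 gCOD/L of a
45/10/45 (COD) acetic/propionic/butyric medium at HRT 5.5 d for the
64-day training phase — one fed continuously, one receiving 88.5% of its
daily ration in a 20-minute pulse:

```r
library(acetoclast)
conti <- run_scenario(preset_scenario("exp1_conti"))
disco <- run_scenario(preset_scenario("exp1_disco"))
s_conti <- summarize_run(conti, training_end_day = 64)
s_disco <- summarize_run(disco, training_end_day = 64)
round(c(saeta_conti_pct   = 100 * (1 - s_conti$f_sarcina),
        sarcina_disco_pct = 100 * s_disco$f_sarcina,
        ph_max_conti      = s_conti$ph_max_training,
        ph_max_disco      = s_disco$ph_max_training,
        dic_conti_M       = s_conti$dic_end), 3)
#>   saeta_conti_pct sarcina_disco_pct      ph_max_conti      ph_max_disco
#>            99.621            54.238             7.255             7.631
#>       dic_conti_M
#>             0.105
```

Continuous feeding hands the reactor to *Methanosaeta* (99.6% of
acetoclastic biomass) and holds a large bicarbonate pool (0.105 M
dissolved inorganic carbon, pH peaking at 7.26). Daily pulses let
*Methanosarcina* rise to 54.2%, and the post-pulse CO2 stripping drains
the carbon pool, so the pulsed reactor cycles up to a *higher* pH maximum
(7.63) between feedings. A mass-balance audit is one call away:

```r
cod_balance(conti)$residual
#> [1] 3.72e-05
```

The community analytics mirror the study's fingerprinting conventions:

```r
vfa_unit_convert(c(ac = 0.45, pro = 0.10, bu = 0.45), total_cod = 1)$total_mass
#> [1] 0.7361788                     # g/L per gCOD/L of the VFA medium
hill_diversity(c(0.75, 0.25), q = 2) # inverse Simpson
#> [1] 1.6
mrta_correct(community_profile(c("tRF1", "tRF2"), c(0.4, 0.6),
             order = c("Methanobacteriales", "Methanosarcinales")))$abundance
#> [1] 0.25 0.75                     # mrtA carriers halved, renormalized
```

A thin command-line front end (`inst/cli/acetoclast.R`) exposes
`simulate`, `audit`, `presets` and `convert` over the same preset and
YAML-config machinery (`inst/extdata/*.yaml`).

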