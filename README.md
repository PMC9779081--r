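# nanoretain

Compartmental pharmacokinetic (PK) modelling of nanoparticle biodistribution
with explicit immune cell-mediated retention.

Conventional PK compartment models treat a tumor as a passive sink fed by
leaky vasculature. For nanoparticles this picture is incomplete: circulating
monocytes and tissue-resident macrophages actively internalize particles,
and that capture competes with — and in tumors can dominate — passive
accumulation. `nanoretain` is for modellers and nanomedicine researchers who
want to quantify this: it splits each classical compartment (blood `b`,
peripheral tissues `p`, tumor `t`) into a noninternalized pool `x_i` and a
macrophage-internalized pool `m_i`, and couples them with rates measured in
vitro.

The model family, in the field's standard notation:

* **Blood disposition** (two-compartment): biexponential blood decay with
  eigenvalues λ_b > λ_p and micro constants tied by
  λ_b + λ_p = K_el + K_bp + K_pb and λ_b·λ_p = K_el·K_pb.
* **Macrophage uptake** (two-state): internalized amount
  x_in(t) = K_in·X0/(K_in+K_out)·(1 − e^−(K_in+K_out)t), fitted per
  nanoparticle configuration, polarization state (M0/M1/M2) and dose, then
  dose-averaged.
* **Six-compartment retention model**: the linear ODE system
  ẋ_b = −(K_el+K_bp+K_bt+k_b·K_bm)x_b + K_pb·x_p + K_tb·x_t + k_b·K_mb·m_b,
  ẋ_p = K_bp·x_b − (K_pb+k_p·K_pm)x_p + k_p·K_mp·m_p,
  ẋ_t = K_bt·x_b − (K_tb+k_t·K_tm)x_t + k_t·K_mt·m_t,
  ṁ_i = k_i(K_im·x_i − K_mi·m_i), with tumor exchange scaled from the
  peripheral rates (K_bt = y·K_bp, K_tb = y·K_pb, y = 0.05% by default) and
  dimensionless factors k_i (default 40) scaling in vitro macrophage
  kinetics to in vivo avidity. Elimination from blood is the only sink.

The package bundles the fitted disposition rates for 20/30/100-nm core–shell
iron oxide (BNF) nanoparticles and the macrophage uptake rate tables for
their plain, trastuzumab- and IgG-conjugated variants, plus a synthetic-data
generator that emulates the blood-sampling and ferene-s uptake assay designs
so every estimator is testable offline.

## Worked example

```r
library(nanoretain)

# blood disposition of the 100-nm particles: derive K_el, K_bp from the
# fitted eigen-parameters
tc <- two_compartment_params(lambda_b = 20.273, lambda_p = 0.052, K_pb = 2.241)
tc
#> Two-compartment PK parameters (per hour):
#>   lambda_b = 20.27  lambda_p = 0.052
#>   K_pb = 2.241  K_el = 0.4704  K_bp = 17.61  X0 = 100 %ID

# assemble the six-compartment model: M0 kinetics in blood, M1 in peripheral
# tissue and tumor, tumor exchange at 0.05% of the peripheral rates, k = 40
p <- assemble_params(tc, load_bundled_rate_tables(), "BNF-Plain")
traj <- simulate_six_compartment(p, t_end = 48)
str(delivery_metrics(traj))
#> List of 5
#>  $ tumor_total_end     : num 1.08
#>  $ tumor_peak          : num 1.08
#>  $ tumor_peak_time_h   : num 48
#>  $ peripheral_total_end: num 40.1
#>  $ eliminated_end      : num 58.7
```

At 48 h the model retains ≈1 %ID in the tumor and ≈40 %ID in peripheral
tissues, with ≈59 %ID eliminated. `retention_decomposition(traj)` splits
each compartment into passive (`x_i`) and active (`m_i`) parts — in this
scenario macrophage-internalized particles overtake the passive pool at
≈13 h in peripheral tissue and ≈26 h in the tumor.
`sweep_parameter()` and `passive_only_scenario()` explore the sensitivity
scenarios (longer circulation, weaker peripheral uptake, no cell-mediated
uptake at all).

A command-line interface mirrors the main operations:

```sh
Rscript inst/cli/nanoretain.R simulate --config scenario.yaml --out run/
Rscript inst/cli/nanoretain.R fit-uptake --input assay.csv --out rates/
Rscript inst/cli/nanoretain.R synth --type uptake --seed 7 --out synth/
```

## Documentation

The methods vignette (`vignettes/immune-mediated-retention.Rmd`) describes
the model assumptions, the fitting and averaging conventions, the noise
model behind the synthetic assays, and the package's numerical choices.
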