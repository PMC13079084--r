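# peatmix

Isotopic source apportionment of dissolved inorganic carbon (DIC) in
humic lakes and rivers: how much of the CO2 a lake outgasses is ancient,
peat-derived carbon, how much is modern organic matter, and how much is
re-dissolved atmosphere?

The package is written for isotope biogeochemists working with paired
stable-carbon (delta 13C, permil VPDB) and radiocarbon (F14C, fraction
modern) measurements of aquatic carbon pools. It implements:

* **Radiocarbon conversions** — conventional age $-8033\,\ln F^{14}C$ with
  exact (asymmetric) error propagation, and its inverse.
* **End-member mixing** — exact linear un-mixing of $k$ sources from
  $k-1$ conservative tracers plus mass balance
  ($[S;\,\mathbf 1^\top]f = [m;\,1]$), wrapped in Monte Carlo rejection
  sampling: all tracers (sources and mixture) are drawn from normal
  distributions, the system is solved each iteration, and only solutions
  with every fraction in $[0,1]$ are retained.
* **Two gas-exchange scenarios** — a three-source "equilibration" model
  (peat + modern + atmosphere; both tracers) and a two-source
  "outgassing" model (peat + modern; F14C only, which is
  fractionation-corrected by construction), combined by inverse-variance
  weighting ($w = 1/\mathrm{s.d.}^2$) after a consistency check.
* **Miller-Tans regression** — OLS of $C\delta^{13}C$ on $C$; the slope
  estimates the delta 13C of the added carbon source.
* **Flux upscaling** — areal CO2 evasion (mmol m⁻² d⁻¹) × area ×
  source fraction → Gg C yr⁻¹, and hydraulic residence time.
* **A synthetic-data generator** with known ground truth, so the whole
  chain is verifiable by parameter recovery without any external data.

## Worked example

A complete run from a config file (the shipped file is a *synthetic*
demonstration, not measured data):

```r
library(peatmix)
cfg <- system.file("extdata", "run_synthetic.json", package = "peatmix")
report <- run_full_analysis(cfg)
print(report)
#> <peatmix_report> model = both; seed = 42; n_iter = 20000
#>   equilibration: f_peat = 0.399 +/- 0.098 (acceptance 98.1%)
#>   outgassing: f_peat = 0.408 +/- 0.110 (acceptance 99.6%)
#>   combined: f_peat = 0.403 +/- 0.073 (models consistent)
#>   flux: 115-238 Gg C yr^-1 over 29-60 mmol m^-2 d^-1
```

Reading: under the three-source equilibration scenario, 39.9 ± 9.8% of
the mixture's carbon is peat-derived; the two-source outgassing scenario
gives 40.8 ± 11.0%. The models agree within one combined standard
deviation, so they are pooled by inverse variance to 40.3 ± 7.3%.
Applying that fraction to an areal CO2 evasion of 29–60 mmol m⁻² d⁻¹
over 2,250 km² yields 115–238 Gg of source-attributed carbon per year.

Individual pieces:

```r
fm_to_age(fm(0.76, 0.02))
#> 2205 (+214/-209) 14C yr BP

residence_time(lake_geometry(2250, 4, 1295))
#> [1] 80.43758   # days

rec <- recovery_experiment(default_scenario(), n_datasets = 100,
                           n_iter = 20000, seed = 20)
rec$coverage   # fraction of datasets where mean +/- 2 s.d. covers truth
```

## Command line

A thin wrapper around `peatmix_cli()` is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "peatmix", package = "peatmix"))')
Rscript "$CLI" convert --f14c 0.76 --sigma 0.02
Rscript "$CLI" residence --area-km2 2250 --depth 4 --outflow 1295
Rscript "$CLI" run --config inst/extdata/run_synthetic.json --out report.json
```

Subcommands: `convert`, `mix`, `miller-tans`, `flux`, `residence`,
`simulate`, `recover`, `run` (see `?peatmix_cli`).

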