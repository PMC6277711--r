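# mppdyn

Deterministic system-dynamics simulation of a patented-drug market under
the Medicines Patent Pool (MPP), for health-policy analysts studying when
an originator enterprise and a government would both choose to join the
pool.

The MPP licenses patented medicines to generic manufacturers so that
affordable generics reach patients during the patent term. Whether that
happens hinges on economics: the originator joins only if a government
subsidy covers its profit shortfall, and the government joins only if its
medical expenditure falls net of that subsidy. `mppdyn` runs the same
market twice — in-pool and out-of-pool — and differences the cumulative
16-year ledgers to locate the policy thresholds.

## The model in brief

Three coupled subsystems advance on a two-month Euler step:

* **Patents and attraction.** Patent value decays as
  `dV/dt = -V/(τ + 1/d)`; relative intensity `r = V_in/(V_in + V_out)`
  and the class average price `p̄` drive adoption through the attraction
  index `A = r^γr · min(1, p_ref/p̄)^γp`.
* **Patients.** Diagnosed patients enter at
  `population × morbidity × σφϱε`, adopt at a potential-sales rate
  `pp = m(α·UP + β·CP)` per period (a fraction `A` starts therapy, the
  rest may retreat later), and leave therapy by death (`ln2/ω`) or
  suspension (`-ln(1-z)/ω`).
* **Economics.** Revenue = treated patients × price × step; the licensed
  generic launches at year 2 in-pool (year 14 out-of-pool), takes `0.7m`
  of the class share within six months, sells at `price_ratio × p_orig`,
  and pays `royalty_rate` of its revenue to the originator while the
  patent is alive. The government pays drug purchases plus a one-time
  pooling subsidy `subsidy_coef × V0` at pool entry.

The decision metrics compare the paired worlds: the *required subsidy*
(originator's pre-subsidy shortfall from joining) against the *affordable
subsidy* (government's pre-subsidy savings).

## Worked example

```r
library(mppdyn)
p <- mpp_params()   # published defaults + shipped calibration

cw <- compare_worlds(p, price_ratio = 0.30, royalty_rate = 0.05,
                     subsidy_coef = 0.065)
cw
#> Paired-world comparison (pooled vs unpooled)
#>   required subsidy   $2.4875e+06   affordable subsidy $4.02e+06
#>   d_profit_orig $762500 (joins)   d_gov $770000 (joins)   d_profit_gen $1.73599e+06
```

At a 30% generic price ratio and a 5% royalty, joining costs the
originator $2.49M over 16 years while saving the government $4.02M; a
subsidy coefficient of 0.065 (× the $50M market-level R&D investment =
$3.25M) leaves both parties better off, so both join flags are set. The
full feasible range of the coefficient:

```r
feasible_subsidy_interval(p, price_ratio = 0.30, royalty_rate = 0.05)
#> Feasible pooling-subsidy interval at price ratio 0.3, royalty 0.05
#>   [0.050, 0.080] (required $2.4875e+06, affordable $4.02e+06)
```

Sweeping the price ratio finds where the balance tips — above this
crossing no subsidy can satisfy both parties:

```r
sweep_price_ratio(p, grid = seq(0.30, 0.42, by = 0.002))
#> MPP sweep over price_ratio (61 points, 0.3 to 0.42)
#>   price_ratio_crossing: 0.358
```

Single worlds are plain classed data frames with `print`, `summary` and
`plot` methods:

```r
summary(simulate_market(default_scenario(pooled = TRUE), p))
#> ...
#> Horizon totals:
#>   profit_orig                  $4.50804e+06
#>   gov_expenditure              $3.9391e+07
#>   ...
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/mppdyn.R run --unpooled --out out/
Rscript inst/cli/mppdyn.R sweep --lever price_ratio --grid 0.10:0.60:0.002 --out out/
Rscript inst/cli/mppdyn.R reproduce --figure 4 --out out/
```

Configuration is flat YAML/JSON keyed by the `mpp_params()` fields
(unknown keys are errors); see `inst/extdata/example_config.yaml`.

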