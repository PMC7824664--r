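# rnavaxcap

Techno-economic capacity model for RNA vaccine drug-substance (DS)
manufacturing at pandemic scale.

## What it answers, and for whom

For process modellers and pandemic-supply planners: given an RNA vaccine
defined by its dose mass (0.1–100 µg RNA/dose), a batch production process
(bioreactor working volume, titre, recovery, failure rate) and a cost
parameter set, the package computes

* annual output of one production line (mass and doses),
* the batches, total bioreactor volume and facilities required to meet an
  annual demand (default 8 billion doses/year),
* annual operating cost (including annualised capital) and cost per dose,
  with a component breakdown,
* single-line production timelines,
* one-at-a-time tornado sensitivity of output and cost per dose,
* and whether drug substance or fill-to-finish is the supply bottleneck.

The core arithmetic: a line at volume $V$ completes $B(V)$ batches/year
(471 at 1 L → 444 at 30 L, linear in between; 30 L is the scale-up limit,
beyond which capacity scales out). Each batch yields $V t r$ grams of DS at
titre $t$ with effective recovery
$r = 0.56 \times (1-f) \times \rho = 0.49221$ at the defaults; doses are
grams over the per-dose mass, so required batches for demand $D$ doses at
$d$ µg/dose are $10^{-6} D d /(V t r)$ and facilities are the ceiling over
$B(V)$. OpEx per batch is materials + consumables + labour/QC, plus
annualised power-law CapEx per facility; cost per dose is OpEx over annual
doses. See `vignette("capacity-model")` for the model, the calibration and
its limits.

## Worked example

Resource requirements for the five built-in vaccines (low = 4 g/L and
medium = 5 g/L titre cases shown):

```r
library(rnavaxcap)
rep <- cmd_capacity()
subset(rep$table, case != "high", select = -capex_total)
#>     scenario   case titre volume opex_annual cost_per_dose total_scale_L batches facilities
#> 1   mRNA-100    low     4     30   2.129e+10      2.660903      915.1590   13544         31
#> 2   mRNA-100 medium     5     30   1.703e+10      2.128912      732.1272   10835         25
#> 4    mRNA-30    low     4     30   6.391e+09      0.798937      274.5477    4063         10
#> 5    mRNA-30 medium     5     30   5.113e+09      0.639149      219.6382    3251          8
#> 7    mRNA-12    low     4     30   2.041e+09      0.255120      109.8191    1625          4
#> 8    mRNA-12 medium     5     30   1.631e+09      0.203906       87.8553    1300          3
#> 10   saRNA-1    low     4      7   2.334e+08      0.029172        8.7305     580          2
#> 11   saRNA-1 medium     5      7   1.845e+08      0.023062        6.9844     464          1
#> 13 saRNA-0.1    low     4      1   4.521e+07      0.005651        0.8627     406          1
#> 14 saRNA-0.1 medium     5      1   3.644e+07      0.004555        0.6902     325          1
```

Reading the 100 µg row: meeting 8 billion doses/year at the low titre takes
13,544 thirty-litre batches — 915 L of total working volume across 31
single-line facilities — at 21.3 billion USD/year of OpEx, 2.66 USD per
dose. The 0.1 µg saRNA vaccine needs less than one litre of total capacity
and one facility, at 36–45 million USD/year.

Single-line timelines at the 30 L limit (medium titre, nominal-recovery
timeline convention):

```r
tl <- cmd_timeline()$table
subset(tl, volume == 30 & case == "medium")
#>     scenario volume   case titre   years  months    days
#> 2   mRNA-100     30 medium     5 21.4500 257.400 7829.26
#> 5    mRNA-30     30 medium     5  6.4350  77.220 2348.78
#> 8    mRNA-12     30 medium     5  2.5740  30.888  939.51
#> 14   saRNA-1     30 medium     5  0.2145   2.574   78.29
#> 20 saRNA-0.1     30 medium     5  0.0215   0.257    7.83
```

One 30 L line makes 8 billion doses of the 1 µg saRNA vaccine in 2.6
months, of the 0.1 µg vaccine in 8 days — and of the 100 µg mRNA vaccine in
21 years, which is why that vaccine needs 21–31 parallel facilities.

Tornado sensitivity (top rows; percent change versus the 30 µg / 30 L /
5 g/L baseline) and the fill-finish comparison:

```r
head(tornado()[, c(1, 4:7)], 4)
#>        parameter delta_doses_low delta_doses_high delta_cost_low delta_cost_high
#> 1   rna_per_dose         29900.0            -70.0          -99.7          233.33
#> 2          titre           -60.0             40.0          150.0          -28.57
#> 3         volume           -96.5             66.7          131.7           -5.66
#> 4 cleancap_price             0.0              0.0          -14.3           28.64

fillfinish_report()[, c("scenario", "ds_doses_per_month", "limiting_stage")]
#>    scenario ds_doses_per_month limiting_stage
#> 1  mRNA-100          3.108e+07 drug_substance
#> 2   mRNA-30          1.036e+08 drug_substance
#> 3   mRNA-12          2.590e+08 drug_substance
#> 4   saRNA-1          3.108e+09    fill_finish
#> 5 saRNA-0.1          3.108e+10    fill_finish
```

RNA amount per dose dominates both outputs; price parameters cannot move
output at all. At the 30 L limit the two saRNA vaccines out-produce a
1.26-billion-dose/month pouch-filling line, making fill-to-finish the
bottleneck.

## Command line

```sh
Rscript inst/cli/rnavaxcap.R capacity   --out results --format csv
Rscript inst/cli/rnavaxcap.R timeline   --config my_config.json
Rscript inst/cli/rnavaxcap.R tornado    --out results --format json
Rscript inst/cli/rnavaxcap.R fillfinish
Rscript inst/cli/rnavaxcap.R calibrate  --table batch_table.csv
```

(use `system.file("cli", "rnavaxcap.R", package = "rnavaxcap")` after
installation). Configs are JSON with sections `vaccine` / `process` /
`cost` / `demand`; examples for all five vaccines ship in
`inst/extdata/`. Omitted fields take the documented defaults; invalid
values exit nonzero naming the field.

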