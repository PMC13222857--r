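# multicause

Weighted multiple-cause-of-death (MCOD) mortality analysis in R.

Routine mortality surveillance counts each death once, under its underlying
cause of death (UCOD). That convention systematically understates conditions
— diabetes mellitus above all — that contribute to death without being
selected as its initiator, and the understatement worsened during the
COVID-19 pandemic, when certification rules made COVID-19 displace chronic
cardiovascular and metabolic disease from the UCOD position. `multicause`
is for epidemiologists and vital-statistics analysts who want to quantify
that gap from death-certificate microdata.

## The method

Each decedent carries total weight 1, split across the causes on the
certificate. With UCOD $u$ and $k$ Part II contributing causes:

* **UCOD**: weight 1 on $u$;
* **MCOD_HALF** (primary): $1/2$ on $u$, $1/2k$ on each contributing cause
  (1 on $u$ if $k = 0$);
* **MCOD_EQUAL** (sensitivity): $1/(k+1)$ on every mention.

Weighted counts are grouped through a configurable ICD-10 cause map
(neoplasms C00–D48, circulatory I00–I99, diabetes E10–E14, communicable
A00–B99 ∪ J00–J22 with COVID-19 U071/U072 carved out, ill-defined R00–R99
excluded from weighting), converted to rates per 100,000 person-years,
directly age-standardized with the WHO world standard
($\mathrm{ASMR} = \sum_a s_a r_a$, Fay–Feuer gamma 95% CIs), and the two
approaches are contrasted per year, sex and cause group as a standardized
rate difference ($\mathrm{ASMR}_{MCOD} - \mathrm{ASMR}_{UCOD}$, null 0) and
rate ratio (null 1). Missing sex/age are singly imputed (logistic /
multinomial or predictive-mean-matching). A synthetic death-certificate
generator with closed-form expected rates (`sim_config()`,
`simulate_deaths()`, `true_asmr()`) makes the whole pipeline testable
without registry access.

## Worked example

```r
library(multicause)
library(dplyr)

cfg    <- sim_config(years = 2019:2022, pop_total = 2e6, seed = 42)
deaths <- simulate_deaths(cfg)   # ~149k synthetic certificates
result <- run_pipeline(list(deaths = deaths, population = cfg$population, seed = 42))
result
#> <mc_pipeline>
#>   analyzed records: 147811 (excluded ill-defined: 930 , rejected: 0 )
#>   schemes: UCOD, MCOD_HALF, MCOD_EQUAL
#>   rate strata: 168
#>   contrast strata: 112

tidy(result) |>
  filter(group == "DM", scheme == "MCOD_HALF", sex == "M") |>
  select(period, asmr_mcod, asmr_ucod, rd, rr, rr_low, rr_high)
#> # A tibble: 4 × 7
#>   period asmr_mcod asmr_ucod    rd    rr rr_low rr_high
#>   <chr>      <dbl>     <dbl> <dbl> <dbl>  <dbl>   <dbl>
#> 1 2019        64.5      49.8  14.8  1.30   1.18    1.42
#> 2 2020        61.7      37.1  24.6  1.66   1.50    1.84
#> 3 2021        64.7      35.6  29.1  1.82   1.64    2.02
#> 4 2022        70.2      50.4  19.7  1.39   1.27    1.52
```

Read: men's diabetes ASMR per 100,000 is 30% higher under the half-weight
MCOD scheme than under the UCOD convention already in 2019 (64.5 vs 49.8,
rate ratio 1.30), and the gap peaks in the worst pandemic year, 2021, at
82% — the UCOD series *falls* as COVID-19 competes for the UCOD position
while the weighted series holds steady. `glance(result)` gives the record
accounting (input = analyzed + ill-defined-excluded + rejected),
`autoplot(result$rates)` and `autoplot(result$contrasts, measure = "rr")`
draw the standard surveillance displays, and `out_dir` in the config writes
all tables as tidy CSV plus a JSON run log. `contrast_bootstrap()` provides
correlation-respecting intervals for the contrasts (see the methods
vignette, `vignettes/weighted-mcod-methods.Rmd`).

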