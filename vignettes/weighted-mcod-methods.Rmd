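---
title: "Weighted multiple-cause mortality analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted multiple-cause mortality analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multicause)
library(dplyr)
```

## The problem

Routine mortality statistics attribute each death to a single underlying
cause of death (UCOD), selected by ICD-10 rules from Part I of the medical
death certificate. Part II of the certificate lists other significant
conditions that contributed to the death but were outside the Part I causal
chain. Counting only the UCOD understates the burden of conditions — diabetes
mellitus is the canonical example — that kill mostly as contributors rather
than initiators, and the distortion sharpens whenever certification rules
force one diagnosis to displace another from the UCOD position, as COVID-19
did for chronic cardiovascular and metabolic disease during the pandemic.

`multicause` implements a weighted multiple-cause-of-death (MCOD) analysis:
each decedent carries total weight 1, split across the causes mentioned on
the certificate, and cause-specific death "counts" become sums of fractional
weights. Because the weight per decedent is fixed, richer Part II reporting
redistributes weight across conditions instead of inflating totals, and
MCOD and UCOD tabulations remain directly comparable.

## Weighting schemes

For a certificate with UCOD $u$ and $k$ usable Part II mentions
$c_1,\dots,c_k$:

* **UCOD** — weight 1 on $u$. The classical tabulation.
* **MCOD_HALF** (primary) — weight $1/2$ on $u$ and $1/2k$ on each $c_i$;
  weight 1 on $u$ when $k=0$. The half share keeps the underlying condition
  privileged while giving contributors a fixed collective voice.
* **MCOD_EQUAL** (sensitivity) — weight $1/(k+1)$ on every mention, treating
  all reported causes as equally necessary for the death.

Weights are assigned per *mention*: duplicates, including a Part II repeat of
the UCOD code, each get their own weight and accumulate within a cause group
after mapping (`drop_ucod_duplicates` switches the alternative reading on).
Certificates whose UCOD is ill-defined (ICD-10 Chapter XVIII, R00–R99) carry
no usable underlying cause; they are excluded from every scheme's numerator
— they still appear in the tabulation output — and ill-defined Part II
mentions are dropped before $k$ is computed. No redistribution of ill-defined
deaths is attempted.

## Cause grouping

Codes are normalized (dots stripped, upper-cased, validated against the
letter–digit–digit(–alphanumeric) shape) and mapped through an ordered list
of inclusive code-prefix ranges; first match wins and unmatched codes fall to
a residual `OTHER`. The packaged default mirrors a condensed PAHO/WHO-style
list:

| group | ranges |
|---|---|
| COVID19 | U071–U072 |
| ILL_DEFINED | R00–R99 |
| DM | E10–E14 |
| NEOPLASMS | C00–D48 |
| CVD | I00–I99 |
| CD | A00–B99, J00–J22 |

COVID-19 is listed first so it is carved out of the communicable-diseases
chapter; condensed-list membership varies between published renderings (for
example whether selected G- or P-chapter codes belong to communicable
diseases), so the whole map is an ordinary CSV (`read_cause_map()`) and
alternative readings are drop-in. Matching is on 3-character prefixes with a
4th-character refinement only where a range itself carries four characters
(the COVID-19 codes), because national files mix 3- and 4-character coding
depth.

## Rates and intervals

Age- and sex-specific rates are weighted deaths per 100,000 person-years;
monthly analyses divide each year's population evenly across months. Direct
standardization uses the WHO world standard population on 5-year bands
(0–4 … 80–84, 85+), packaged and normalized to sum to 1:
$\mathrm{ASMR} = \sum_a s_a r_a$, with variance $\sum_a s_a^2 v_a$.

Two variance options exist for the age-specific cells because fractional
weights make the counts compound-Poisson rather than Poisson:

* `"poisson"` (default) treats the weighted count $D_w$ as a Poisson mean —
  exact under the UCOD scheme, slightly conservative under MCOD since
  $\sum w_i^2 \le \sum w_i$;
* `"weighted"` uses $\sum w_i^2$, the exact compound-Poisson variance, which
  the aggregation step carries alongside every count.

The default 95% interval for the ASMR is the Fay–Feuer gamma interval for a
weighted sum of Poisson-type counts, which behaves correctly at low event
counts; a symmetric normal interval is available for cross-checking (the two
agree within a couple of percent once cells hold hundreds of deaths).

## Contrasts and their correlation problem

Discrepancy between approaches is reported as the standardized rate
difference $\mathrm{RD} = \mathrm{ASMR}_{MCOD} - \mathrm{ASMR}_{UCOD}$ and
rate ratio $\mathrm{RR} = \mathrm{ASMR}_{MCOD} / \mathrm{ASMR}_{UCOD}$, with
nulls at 0 and 1. `rate_contrast()` builds intervals under an independence
approximation (summed variances; log-normal for the ratio). The two ASMRs
are computed from the *same* decedents, however, and are strongly positively
correlated, so the independence interval for the difference is materially
conservative — in simulation its empirical coverage exceeds 99%. For
calibrated inference `contrast_bootstrap()` resamples whole certificates
with replacement (seeded, `B` configurable) and takes percentile intervals;
these respect the within-record correlation and achieve close to nominal
95% coverage in the package's own simulation checks. The analytic contrast
remains the default arithmetic because it needs only the two rate tables;
the bootstrap needs record-level data.

When the UCOD ASMR is zero the ratio is reported as `NA` while the
difference is kept.

## Imputation

Missing sex and age are singly imputed, conditional on the other record
variables (year, month, UCOD cause group, number of clean Part II mentions,
and the other demographic where observed): logistic regression for sex;
for age either a multinomial model over age bands (a band is drawn from the
fitted probabilities, then a uniform age within it) or predictive mean
matching (default pool of 5 donors by predicted mean; when distances tie —
inevitable with nearly flat predictions — the pool expands to all tied
donors and one is drawn at random, which keeps the imputed distribution
honest instead of cloning five donors). Draws are seeded; observed values
are never modified. Because imputation is single, rate intervals ignore
imputation uncertainty; at the sub-0.3% missingness levels typical of the
registries this package targets, simulation shows the induced ASMR
perturbation stays well under 0.5% relative.

## The synthetic generator

`sim_config()` + `simulate_deaths()` produce delimited death-certificate and
population files with the statistical structure the analysis assumes:

* stratum death counts $\sim$ Poisson(hazard × population / 100,000), with
  Gompertz-style age schedules per cause group and a male/female hazard
  contrast of roughly 1.25 : 0.85;
* Part II counts from a zero-inflated Poisson truncated at 6 (certificate
  line limits), with the empty-Part-II probability declining across years
  (defaults 0.667 → 0.536 over 2019–2022) and the conditional mean rising —
  emulating the observed drift toward more complete certification;
* Part II group composition from a per-UCOD comorbidity profile (chronic
  UCODs mention CVD heavily; no profile mass on ill-defined codes, which
  keeps the closed-form expectations exact after cleaning);
* a COVID-19 hazard scaled by a per-year multiplier (0 in 2019, peaking in
  2021) — the one field added beyond a single per-group hazard table,
  since a pandemic cause cannot have a year-constant hazard;
* cause competition: in pandemic years, an eligible CVD/DM-UCOD decedent
  has COVID-19 recorded as UCOD with probability `competition_prob` and the
  chronic code demoted to Part II. Competition draws are consumed after all
  other randomness, so configurations differing only in `competition_prob`
  yield identical certificates with a nested set of swaps — which is what
  makes the monotonicity of the CVD rate gap testable at exactly fixed
  totals;
* MCAR missingness in sex (default 0.03%) and age (default 0.12%), spanning
  the registry-reported ranges.

`true_asmr()` returns the exact expected ASMR per year, sex, group and
scheme by integrating the weight rules over the Part II count distribution
and comorbidity profile — no simulation involved — and is the oracle for the
parameter-recovery checks. What the generator does *not* emulate: real
demography (migration, cohort effects), spatial heterogeneity, non-random
missingness, coding-practice changes other than the completeness drift, and
Part I causal-chain structure. Passing recovery tests therefore demonstrate
correctness of the estimator pipeline under the stated model, not fidelity
of any national registry.

## Problem sizes and numerical choices

The package's own verification suite runs at deliberately desk-scale sizes:
conservation and oracle checks on ~10⁴ certificates; parameter recovery on
three years at 10⁶ person-years per year–sex stratum (≈10⁵ deaths), asserting
agreement with the closed-form truth within 3 standard errors per cell using
the compound-Poisson variance; interval coverage on 500 replicates of a
three-band population with ≥200 deaths per sex–group stratum (bootstrap
B = 200); imputation robustness over 10 replicates at 0.04% / 0.24%
missingness. Ties in cause-map ranges are resolved by listed order;
degenerate standard populations (single non-zero band) are allowed;
unnormalized standards are normalized with a warning; a zero-population
stratum with non-zero deaths is a hard error rather than an infinite rate.

## Known limitations

* The independence-approximation contrast intervals over-cover; use the
  bootstrap when calibration matters.
* Single imputation understates variance by construction.
* The condensed cause list ships as a best-effort default; analyses sensitive
  to communicable-disease membership should supply their own map file.
* Monthly denominators assume equal-length months.
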