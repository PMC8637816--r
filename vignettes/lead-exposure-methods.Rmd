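---
title: "Models and methods for lead exposure assessment in lip cosmetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for lead exposure assessment in lip cosmetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liprisk)
```

## The problem

Lip cosmetics are the one cosmetic category that is routinely swallowed:
wearing lipstick, gloss or balm transfers a small mass of product into the
mouth every day. Trace lead, a contaminant of pigments and mineral raw
materials, therefore constitutes a chronic low-dose oral exposure with no
safe threshold for neurodevelopmental effects. `liprisk` assembles the
standard assessment chain for a measured concentration panel: descriptive
statistics, regulatory compliance, deterministic and probabilistic ingestion
risk, and blood-lead modelling for adults, the fetus, and young children.

## The concentration panel and its conventions

A panel is one record per purchased product: category (lipstick, lip gloss,
lip balm), retail metadata, and the ICP-MS-measured Pb concentration in
mg/kg. Two conventions matter:

* **Non-detects are stored as 0 with `detected = FALSE` and are included in
  means and standard deviations.** A survey with ~41% non-detects can only
  report the grand mean it does if zeros enter the average; summarising only
  the detected values would roughly double every mean. An optional
  half-detection-limit substitution (`summarize_panel(substitute_half_dl =)`)
  is provided for sensitivity analysis but is off by default.
* **The sample standard deviation uses the n − 1 denominator**, conventional
  for a market sample of a few dozen products.

Compliance is checked against the 10 mg/kg cosmetic Pb limit shared by
China, the US and Canada, with a *strict* inequality: a product exactly at
the limit complies.

Correlation between Pb content and category or price defaults to Spearman
rank correlation, because category is an ordinal code (lipstick = 1,
lip gloss = 2, lip balm = 3, following the panel presentation order and
overridable) and rank correlation is invariant to how the codes are spaced.
Pearson is available for sensitivity.

Instrument QC operates on tabulated values only: replicate ("parallel")
pairs pass when their relative deviation |a − b| / mean(a, b) is at most
10%, the calibration curve passes when its correlation coefficient is at
least 0.995 (inclusive), and every procedural blank must fall below the
detection limit.

## Deterministic ingestion risk

The oral pathway is the USEPA chain

$$\mathrm{ADD} = \frac{C \cdot IR \cdot EF \cdot ED \cdot CF}{BW \cdot AT},
\qquad \mathrm{HQ} = \frac{\mathrm{ADD}}{RfD}, \qquad
\mathrm{LCR} = \mathrm{ADD} \cdot SF.$$

Parameters, with units and defaults: intake rate $IR$ of 0.02578 g/d
(average user) or 0.14902 g/d (high user); exposure frequency $EF$ = 365
d/a; duration $ED$ = 70 a; conversion factor $CF$ = 0.001 bridging grams of
product to kilograms so ADD lands in mg Pb per kg body weight per day
(omitting it is the classic 1000× error); body weight $BW$ = 60 kg;
averaging time $AT$ = 25550 d; reference dose $RfD$ = 4 × 10⁻⁴ mg/(kg·d);
slope factor $SF$ = 0.0085 (kg·d)/mg. Because $EF \cdot ED = AT$ at these
defaults, the dose reduces to $C \cdot IR \cdot CF / BW$.

Classification thresholds (HQ vs 1, LCR vs 10⁻⁶) are strict
greater-than comparisons, so a metric exactly at its reference value is
"acceptable". Two algebraic identities follow from linearity and are used
throughout the tests: $\mathrm{LCR}/\mathrm{HQ} = RfD \cdot SF$
(3.4 × 10⁻⁶ at defaults) for any positive dose, and the high/average-user
ratio of any risk metric equals the intake-rate ratio 5.7804.

## The zero-inflated lognormal and Monte Carlo propagation

Detected concentrations in such panels are right-skewed and positive, and a
large fraction of records is censored at the detection limit. We model the
concentration as a mixture: mass $p_0$ at exactly 0 and a lognormal
$(\mu, \sigma)$ for the positives. $p_0$ is estimated as the zero fraction;
the lognormal is fitted to the positive values only (`zero_policy =
"inflate"`, the default; dropping zeros or substituting half a detection
limit are available for sensitivity, since how the original spreadsheet
analysis treated its zeros is not documented).

Two fitting methods:

* **Moment matching** (default): $\sigma^2 = \log(1 + (s/m)^2)$,
  $\mu = \log m - \sigma^2/2$ from the sample mean $m$ and sd $s$. This is
  also the *summary-driven* entry point (`fit_lognormal_moments()`): when
  only published summary statistics exist, the fit is exact in closed form.
  The fitted distribution's analytic mean and sd round-trip the inputs to
  1 × 10⁻⁹ relative, a property test in the suite.
* **Log-space MLE**: mean and 1/n-denominator sd of the log values.

`analytic_quantile()` is the exact quantile of the mixture (0 below $p_0$,
rescaled lognormal quantile above) and serves as the independent oracle for
the sampler: on 10⁵ seeded draws the empirical 5th/50th/95th percentiles
must agree within 2% relative.

Monte Carlo risk draws one concentration per iteration (default 10,000
iterations, mirroring common practice for this assessment) and pushes the
*same* draws through the dose chain for every exposure preset, which makes
between-preset percentile ratios exactly the intake-rate ratio rather than
ratios of independent noisy estimates. Percentiles use linear interpolation
between order statistics (`stats::quantile` type 7), stated explicitly
because spreadsheet add-ins differ here. Every output records its seed and
iteration count.

The published 95th-percentile risks for this kind of panel cannot be
reproduced absolutely without the raw per-product data and the original
software's fitting choices; the package therefore validates the Monte Carlo
stage through its exact ratio structure and the sampler-vs-quantile oracle,
not through absolute percentile values. One subtlety: with ~41% zero
inflation, low percentiles of HQ and LCR are exactly 0, so ratio identities
are asserted multiplicatively (LCR = 3.4 × 10⁻⁶ · HQ) rather than as 0/0
quotients.

## Adult blood lead and maternal transfer

The Adult Lead Methodology is additive and linear in μg/dl:

$$\mathrm{PbB} = \underbrace{Pb_s \cdot BKSF \cdot IR_{SD} \cdot AF_{SD}
\cdot EF_S / AT}_{\text{soil term}} +
\underbrace{Pb_L \cdot BKSF \cdot IR_L \cdot AF_L \cdot EF_L /
AT}_{\text{lip term}} + PbB_0.$$

Defaults: soil Pb 282 μg/g (Chinese reference value), lip-cosmetic Pb at
the panel mean 0.05791 μg/g, baseline $PbB_0$ = 1.62 μg/dl, biokinetic
slope factor 0.4 d/dl, soil intake 0.05 g/d at 12% absorption over 220
d/year, lip intake 0.0258 (average) / 0.1490 (high) g/d at absorption 1
(conservative) over 365 d/year. Fetal blood lead is the maternal total
times a transfer rate: 0.85 (ALM convention) or 0.9 (IEUBK convention).

Two design choices were genuinely open and are resolved as follows:

* **The low-background scenario excludes the soil term from the total.**
  The published scenario totals leave no room for a 0.41 μg/dl soil
  contribution on the low side (1.62 + 0.0006 = 1.6206 exactly); soil
  enters only the high-background scenario, where 1.62 + 0.4079 rounds to
  the quoted 2.03 μg/dl. The soil term is still computed and reported in
  every breakdown.
* **Rounding emulation.** Published tables of this kind are assembled in
  spreadsheets from intermediate *displayed* values. The only scheme that
  reproduces every published cell is: round the lip term half away from
  zero to 4 decimals and the background to 2 decimals *before* summing, and
  truncate the fetal product toward zero at 4 decimals (1.6235 × 0.85 =
  1.379975 → 1.3799, not 1.3800; 2.0335 × 0.85 = 1.728475 → 1.7284). This
  ships as the explicit `rounding = "paper_emulation"` mode;
  `"full_precision"` is the default for real use. Emulated cells sit within
  half a unit of the coarsest rounding step (0.005 μg/dl) of full
  precision — the high-background cells differ by ~0.002 μg/dl because
  rounding the background to 2 decimals dominates.

The maternal inputs to the child model are the arithmetic means of the four
fetal cells (2 users × 2 rates) per background: 1.41925 and 1.77800 μg/dl
under the defaults.

## Child multi-media uptake

For children aged 0.5–7, absorbed Pb per medium is concentration × intake
rate × absorption fraction, summed over air, drinking water, diet,
soil/dust, and lip balm (children are assumed to contact lip balm only
among lip cosmetics; other categories reach them via maternal transfer).
Study-fixed backgrounds: air 0.5 μg/m³ at 30% absorption, water 0.01 μg/L
with age-banded intakes 0.2–0.59 L/d, diet 8 μg/d (under age 3) or 20 μg/d
(ages 3–7), soil 282 μg/g at 45% child absorption. Water and diet
absorption are not fixed by the study configuration and default to 0.5 per
standard IEUBK guidance; daily ventilation (2–7 m³/d) and soil ingestion
(0.085–0.135 g/d) likewise ship as editable age-banded defaults.

The calculator deliberately stops at absorbed μg/d. Converting uptake into
a child blood-lead concentration requires the full biokinetic compartment
model of the external IEUBK program, which is out of scope; a user-supplied
`response` function can be attached for coupling to such a solver.

## The synthetic panel generator

Because no raw per-product concentrations are publicly deposited, the
generator emulates the survey's statistical structure: 34 products split
12/13/9 across categories, non-detects with probability 0.41, detected
values lognormal with (μ, σ) = (−3.5507, 1.1848) — the exact moment match
to the published mean 0.05791 and sd 0.10146 — prices uniform within the
survey's retail terciles (0–95, 96–266, >266 RMB, capped at 800 RMB as a
realistic market ceiling), and neutral placeholder brand/colour/country
vocabularies. QC replicate pairs carry multiplicative lognormal noise with
a default 2% coefficient of variation, typical of ICP-MS parallel
determinations.

What passing tests on synthetic panels do and do not show: they demonstrate
that the fitting stage inverts the generator (parameter recovery on 10⁴
records within 2%), that the pipeline is deterministic per seed, and that
every formula matches its closed-form oracle. They cannot validate the
lognormal assumption itself, brand- or price-dependence of contamination,
or between-batch variability in real products — those require real data.

## Numerical choices and problem sizes

* Percentiles: type-7 linear interpolation everywhere.
* Rounding helpers: `round_half_up()` and `trunc_to()` rescale, nudge by a
  7-decimal guard against binary floating point landing an exact decimal a
  hair below its integer image, then floor.
* Degenerate inputs fail loudly with classed conditions: constant values
  for a lognormal fit, replicate pairs with zero mean, constant variables
  in a correlation, empty panels.
* Test problem sizes: 10⁵ draws for sampler-vs-quantile checks, 10⁴
  records for parameter recovery, 10⁴ Monte Carlo iterations for the ratio
  structure — large enough that 2% Monte Carlo tolerances are comfortable,
  small enough that the whole suite runs in a few seconds.

## Known limitations

Oral ingestion only (no dermal or inhalation route); Pb only (no
multi-metal joint simulation); lognormal positives only (no Weibull/gamma
alternatives); the ALM is a steady-state linear model, not a
pharmacokinetic time course; and the child module ends at uptake, not blood
lead.
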