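---
title: "Modeling the attributable burden of excess dietary salt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the attributable burden of excess dietary salt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltcost)
```

## The model

`saltcost` implements a comparative risk assessment (CRA) of the cost of
illness attributable to salt intake above the WHO limit of 5 g/person/day,
parameterized like Costa Rica in 2018. The causal chain is:

salt intake → systolic blood pressure (SBP) → cardiovascular disease (CVD)
→ healthcare costs and premature-mortality productivity losses.

Four CVD outcome groups are modeled: coronary heart disease (CHD), stroke,
hypertensive disease, and rheumatic heart disease (RHD).

**Exposure.** Population salt intake is summarized as a mean and SD in
g/person/day (baseline default 10.0 ± 5.4; counterfactual 5.0 ± 2.65, the
WHO limit applied with proportional spread). Surveys report only these two
moments, so the distribution family is a design choice: we use a normal
truncated at zero and renormalized. Untruncated, a mean of 10 with SD 5.4
puts about 3% of the population at negative intake; truncation is the
smallest correction consistent with the reported moments. The distribution
is discretized into 1 g/day bins from 5 to 12 g with open tails ("less than
5" to "over 12"); each bin is represented by its midpoint, the open top bin
by the last edge plus half a bin width (12.5 g), and the sub-reference bin
is the unexposed category. With `sd = 0` the distribution degenerates to a
point mass, which flows through the whole pipeline (prevalence 0 or 1).

**Dose-response.** A linear salt→SBP slope: a 6 g/day salt difference moves
SBP by 5.8 mmHg (meta-analytic estimate; `dose_response_spec()` makes both
numbers tunable). `sbp_shift()` is linear and odd, so effects compose
additively.

**Risk.** Outcome-specific relative risks are supplied per 1 mmHg of SBP,
stratified by sex and 5-year age band. A bin's risk relative to the
reference intake is the per-mmHg RR raised to the bin's SBP shift
(`RR^ΔSBP`), the standard log-linear CRA rescaling. The combined RR over
the exposure distribution is the prevalence-weighted arithmetic mean of
per-bin RRs among exposed bins. With that definition the binary formula

PAR = 100 · P(RR − 1) / (P(RR − 1) + 1)

is algebraically identical to the multi-category attributable fraction
100·Σpᵢ(RRᵢ−1)/(Σpᵢ(RRᵢ−1)+1), because P(RR−1) = Σpᵢ(RRᵢ−1); the test
suite verifies the identity to 1e-12 on 3-bin toys. Protective exposures
(RR < 1) produce a negative PAR and a warning rather than an error.

**Counterfactual handling.** The attributable burden is
PAR(baseline) − PAR(counterfactual), both scored against the same 5 g
reference (`counterfactual_mode = "distribution"`, the default). With the
default counterfactual (mean exactly 5), about half its mass sits above the
reference, so its PAR is small but nonzero; `"threshold"` mode instead
defines the counterfactual burden as zero. When the counterfactual equals
the baseline the net PAR is identically zero.

**Pooling.** Cost tables are disease × service × sex with no age dimension,
so stratum PARs are pooled to outcome × sex as a population-weighted mean of
the age-specific PARs (the `strata` table carries a `population` column).
Averaging the PARs — rather than re-deriving a pooled (P, RR) pair — keeps
each age band's attributable share of an age-uniform cost pool exact under
the assumption that costs are proportional to population within sex; a
different split can be expressed by editing the population weights.

**Direct costs.** Each available cost cell is multiplied by its pooled PAR.
Cells flagged unavailable (medication costs for stroke and RHD in the
default parameterization) are excluded, never zero-filled, and reports
footnote the exclusion. Costs are held in raw currency units at full
floating precision; conversion from colones uses a fixed 600 CRC/USD, and
rounding to "thousand USD" and to integer-percent shares
(half-away-from-zero) happens only in the rendering layer. The published
tables this layout mirrors contain ±1-thousand inconsistencies that are pure
display-rounding artifacts; keeping the model at full precision prevents
them from propagating.

**Productivity.** Attributable deaths enter as an input table (they come
from an upstream macrosimulation that is out of scope here), so no PAR is
applied on the mortality side. Per record: YLL = deaths × residual life
expectancy at the age of death; YPLL = deaths × working years lost, where
working years span from age 15 (or the age at death, if later) to the
sex-specific pension age (60 women / 65 men); losses monetize YPLL at the
average monthly wage × 12 × labor-force participation (0.62, USD 765/month
by default). The wage is treated as monthly because national statistical
institutes report it monthly; the annualization factor is configurable. No
discounting or age-weighting is applied by default; a discount-rate option
(e.g. 3%) exists but is off. Deaths within an age band are assigned the
band midpoint as age of death unless exact ages are supplied.

## Uncertainty propagation

`run_monte_carlo()` resamples, per draw, the baseline mean intake, every
available cost cell, every per-mmHg RR, and (optionally) every death count;
reruns the full pipeline; and summarizes each output as the median of draws
with a 95% interval from the 2.5th/97.5th percentiles (type-7 interpolated
order statistics — the percentile-bootstrap reading of "interval for the
median"). 10,000 draws is the default. Choices worth knowing:

- **What "intake uncertainty" means.** The sampling distribution of the
  *mean* intake is resampled; the per-person SD stays fixed in the
  discretization. Sampling the full per-person distribution instead would
  conflate parameter uncertainty with population spread and change the
  meaning of the prevalence P.
- **Distribution families.** Log-normal (method-of-moments
  `lognormal_params()`: σ² = ln(1 + sd²/mean²), μ = ln mean − σ²/2) for
  intake mean, costs, and deaths; ln RR is sampled normally around its point
  value.
- **Input spreads.** Sources rarely publish standard errors for these
  inputs, so the defaults are explicit package choices, set once: cv 0.05
  for the intake mean, each cost cell, and each death count, and an SE of
  ln RR equal to 10% of ln RR. Setting all of them to 0 collapses every
  draw onto the deterministic pipeline (the tests assert equality and zero
  interval width).
- **Streams.** One global seed feeds a deterministic hashed substream per
  input cell (`rr/CHD/male/45-49`, `cost/stroke/hospitalization/female`, …),
  so adding an output — or perturbing an unrelated input — never shifts the
  draws of existing cells. Runs are bit-reproducible for a fixed seed.
- **Calibration.** Simulating "observed" inputs from a known truth under the
  same error model and running the engine, the 95% interval covers the truth
  in ≥ 90 of 100 replicates (asserted in the acceptance tests at 400 draws
  per replicate; the engine is vectorized across draws, so a 10,000-draw run
  on the full default fixture takes well under a minute on one CPU).

## The synthetic-data generator

`default_fixture()` is the deterministic reference bundle. Published key
inputs appear verbatim: intakes 10.0 ± 5.4 and 5.0 ± 2.65 g/day at 2171
kcal/day, participation 0.62, wage USD 765, pension ages 60/65, life
expectancy 82.6 (women) / 77.5 (men), 600 CRC/USD, and national annual cost
totals of USD 1,584,985,326.39 (hospitalizations), 853,309,618.14
(consultations) and 642,090.81 (medications, hypertension + CHD only). What
the sources do not publish is synthesized and labelled as such: the disease
× sex splits of the cost totals, the per-mmHg RR surface (log-linear,
attenuating 10% per decade of age so per-bin RRs stay in a plausible
1.0–1.6 range), the adult population pyramid (~3.8 M, smooth exponential
decline), and the attributable death counts (~350 CHD + stroke deaths with
a geometric age gradient, residual life expectancy approximated as life
expectancy at birth minus age at death, floored at 4 years).

Because the stratified cost appendices and the external RR tables behind
the published headline figures are not public, the fixture's pipeline
outputs are *not* expected to reproduce them; what the package reproduces
exactly is every printed aggregation and share when the published tables'
own component cells are fed through the reporting layer
(`reported_components()`). Passing tests therefore demonstrate the
correctness of the arithmetic, aggregation, uncertainty and reporting
machinery — not the field accuracy of the synthetic inputs.

`generate_random_bundle(seed)` produces randomized but invariant-respecting
bundles (RRs ≥ 1, weakly decreasing with age; positive costs; non-negative
deaths) for stress tests.

## Numerical choices and degenerate inputs

- Bins are left-open/right-closed; a point-mass intake on an edge falls in
  the lower bin.
- P = 0 (nobody exposed) gives combined RR = 1 by convention, hence PAR = 0.
- Percentiles use type-7 linear interpolation: for samples 1…1000 the 95%
  interval is (25.975, 975.025).
- `sd = 0` anywhere (intake, Monte Carlo cvs) is a supported degenerate
  case, never an error; `draws = 0` is an error.
- Duplicate cells (same disease × service × sex, or same outcome × stratum)
  are rejected rather than silently summed.

## Problem sizes in the test suite

The shipped tests use a three-age-band, two-outcome bundle for Monte Carlo
loops (400–2,000 draws), 100 replicates for the coverage check, one
10,000-draw run on the full 14-band fixture, and 10⁶ draws for the
log-normal moment round-trip — sizes chosen so the full suite runs in a few
seconds while keeping Monte Carlo assertions well clear of their tolerances.

## Limitations

- Time lags between exposure change and disease outcomes are not modeled;
  the estimate is an annual steady-state comparison.
- Only the salt→SBP→CVD pathway is represented; direct (non-SBP-mediated)
  effects of sodium are excluded.
- Direct costs cover hospitalizations, consultations and medications of a
  single public payer; primary care, out-of-pocket and insurance costs are
  out of scope, as are morbidity-side productivity losses (absenteeism,
  presenteeism) and the friction-cost method.
- The upstream estimation of attributable deaths and of the RR
  meta-analyses is out of scope; both enter as input tables.
- The kcal anchor on intake distributions is metadata; no calorie
  re-scaling is performed.

## A worked run

```{r, eval = FALSE}
b <- default_fixture()
res <- run_pipeline(b, mc = mc_config(draws = 10000, seed = 1))
res$direct_report
res$mc

# the published-table worked example
cost_report(reported_components("services"))
```
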