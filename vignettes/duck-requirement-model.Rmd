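---
title: "Dynamic energy and protein requirements for meat ducks: model and methods"
author: "ducknutr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic energy and protein requirements for meat ducks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ducknutr)
```

## The problem

Static phase-feeding tables give one ME and one CP value per growth phase.
Real flocks deviate from them systematically: maintenance demand rises
steeply in cold houses, fast-growing birds shift energy from maintenance to
tissue deposition, breeds differ in basal metabolism and temperature
sensitivity, and the amino-acid balance a season requires is not constant.
`ducknutr` implements a factorial requirement model with dynamic corrections
for all four effects, plus the machinery to calibrate its coefficients from
flock records and to test that calibration honestly on synthetic data.

## The model

For one animal-day with live weight $W$ (kg), daily gain $BGW$ (g/d),
ambient temperature $ET$ (°C):

$$ME = SF \cdot m \cdot \alpha_{\mathrm{eff}} W^{0.75}
     + \beta_{\mathrm{eff}} \, BGW + \Delta T + BC$$
$$CP = a_z W^{0.75} + b_z \, BGW + SF \cdot AAI$$

with season zones cold ($ET < T_{low}$), thermoneutral
($T_{low} \le ET \le T_{high}$) and heat ($ET > T_{high}$); boundaries are
assigned to the thermoneutral zone, matching the strict inequalities in the
source tables.

### Parameters, units and defaults

| symbol | meaning | unit | default |
|---|---|---|---|
| $\alpha$ | maintenance energy | kJ/(kg^0.75 d) | 541.7 |
| $\beta$ | growth energy | kJ/g gain | 19.86 |
| $k_3^{cold}$ | cold compensation | kJ/(kg^0.75 °C d) | 13.0 |
| $k_3^{heat}$ | heat reduction | kJ/(kg^0.75 °C d) | 6.5 |
| $BC$ | additive breed offset | kJ/d | 0 |
| $a$ | maintenance protein | g/(kg^0.75 d) | 6.013 |
| $b$ | growth protein | g/g gain | 0.18 |
| $SF$ | seasonal factor | — | 1.35 / 1.15 / 1.05 |
| $T_{low}, T_{high}$ | thermoneutral band | °C | 15, 28 |

$\alpha$, $\beta$, $a$, the SF values and the thermoneutral band are
tabulated constants of the underlying model. Two published maintenance
constants appear as 0.545/0.305 in MJ-scale units; the package uses the
kJ-scale values (545/305-class magnitudes, baseline 541.7) consistently —
energy is always kJ internally, with `kcal_to_kj()`/`kj_to_kcal()` for feed
densities quoted in kcal/kg.

$b$ = 0.18 g protein per g gain is an engineering default close to the
protein content of duck tissue gain, not a tabulated constant; it is
configurable and calibratable.

The magnitudes of $k_3$ are nowhere tabulated; they are meant to be
calibrated. The shipped starting values are derived from the published
cold-compensation magnitudes: a theoretical compensation of +12 % of
baseline maintenance for a cold spell 5 °C below the band gives
$k_3^{cold} = 0.12 \times 541.7 / 5 = 13.0$; the heat coefficient is set to
half that, reflecting the weaker per-degree intake response above the band.
Treat both as priors for `fit_lm()`, not as measurements.

### The temperature term

The literal reading of a $k_3 \cdot ET$ term with a sign-switching
coefficient would make cold-zone energy *increase* with rising temperature,
contradicting the compensation logic it is meant to express. The package
therefore uses the deviation-from-threshold form

$$\Delta T = \gamma(n)\, k_3^{cold} \max(0, T_{low} - ET)\, W^{0.75}
           - k_3^{heat} \max(0, ET - T_{high})\, W^{0.75},$$

which is positive below the band, negative above it, zero inside, and
continuous at both thresholds. $\gamma(n)$ is the temperature-lag damping: a
left-closed step function of the number of consecutive cold days
($1 \le n < 3 \to 0.85$, $3 \le n < 5 \to 0.51$, $n \ge 5 \to 0.32$, and
$n = 0 \to 1$). Only three breakpoints are published and the decay is
described as nonlinear, so a step function avoids inventing a curve between
them; the damping applies only to the cold branch, which is where the
under-response it models (birds not eating as much extra as theory predicts)
was observed. One published row (n = 1: 0.85 × 12 % printed as 8.5 %) is
inconsistent with the product rule that the n = 5 row verifies
(0.32 × 60 % = 19.2 %); the implementation computes the product.

### Seasonal factor placement

The energy equation as published has no SF, yet the published winter
maintenance example scales 541.7 by 1.35 to get 731.3 kJ. The package scales
the ME maintenance term by SF by default, with
`daily_requirement(sf_on_maintenance = FALSE)` to disable; in the protein
equation SF multiplies the amino-acid term as written. The protein
maintenance constants are printed per kg live weight while the equation uses
$W^{0.75}$; the implementation follows the equation and treats the printed
values as the 1-kg case, where the two coincide (6.013 × 1.35 = 8.118 vs
the printed winter value 8.138, a 0.3 % discrepancy retained as such).

### Growth-stage reallocation

Above the rapid-growth threshold (35 g/d) the maintenance coefficient drops
18 % and the growth coefficient rises 24 %, capturing the reallocation of
marginal energy toward deposition. The adjustment is a pure function of the
current gain, so it is idempotent and needs no state. The published
post-adjustment pair (0.44, 0.62) does not equal the stated percentages
applied to the published pre-adjustment pair (0.62, 0.38 → 0.508, 0.471);
the package applies the percentages and reports the published allocation
ratios (1.63:1 → ~1:1) as derived quantities.

### Breeds

Breed effects decompose into the interaction term $\lambda \times \delta$
(basal metabolism × temperature sensitivity, reported at two decimals:
Cherry Valley 1.00, Beijing 1.08 × 0.85 = 0.92, Muscovy 0.94 × 1.12 = 1.05)
which scales maintenance; a winter surcharge (Muscovy 8–10 %, CMD 6–8 %,
stored as midpoints with the interval kept as metadata) multiplying in the
cold zone; the additive offset BC (how the multiplier and the offset combine
is not specified upstream; the package's choice — multiplier on maintenance,
BC additive, both neutral for Cherry Valley — keeps the baseline exact); and
the season–amino-acid coefficient $\kappa$. Registries serialise to
YAML/JSON so breeds can be added without code changes.

### Amino-acid balance

No functional form for AAI is published beyond "a function of the
lysine/methionine ratio" equal to 1 in balance. The package uses the
simplest form with that property, `(lys/met) / 3.0` (3.0 being the midpoint
of the 2.8–3.2 span of practical ratios), normalised so a balanced
thermoneutral diet contributes exactly $SF$ to CP. The seasonal adjustment
is symmetric and multiplicative — cold: $\times(1-\kappa)$ (more methionine
lowers the index), heat: $\times(1+\kappa)$ — because only the directions
are stated. Both choices are isolated behind `compute_aai()` /
`seasonal_aai_adjustment()` so an alternative index can be substituted.

### A deliberate asymmetry: winter vs summer protein

Winter raises maintenance protein (and the ME surcharges); summer boosts
the protein growth coefficient by 23 % while cutting maintenance by 18 %.
Consequently CP(winter) > CP(summer) holds for maintenance-dominated states
(roughly $BGW < 26\,W^{0.75} - 3.5$ g/d — market-weight birds at moderate
gain) but inverts at peak growth, where the summer growth boost dominates.
That inversion is the model's substance (winter maintenance is higher while
growth requirement peaks in summer), so the package's tests assert the
winter ordering only on maintenance-dominated states rather than globally.

## Calibration

`requirement_residuals()` stacks (predicted − observed) for ME and CP, each
standardised by the standard deviation of its observations, so a joint fit
weights the two targets comparably regardless of units. Nothing upstream
specifies the multi-target objective; this is the simplest scale-free
choice.

`fit_lm()` is a damped least-squares (Levenberg–Marquardt) iteration on
that objective: damping starts at 1e-3, ×10 on a rejected step, ÷10 on an
accepted one; finite-difference Jacobians (central, relative step 1e-6,
falling back to one-sided at parameter-validity boundaries); convergence
when the relative cost change of an accepted step falls below 1e-8, with a
200-iteration cap. Singular normal equations escalate damping rather than
fail, and exhausting the damping range reports non-convergence instead of
raising. A QR rank check of the Jacobian at the start warns when the free
set is not identifiable from the data — for example, no cold exposure means
no information about $k_3^{cold}$.

`fit_gd()` is full-batch gradient descent with the learning-rate schedule
$lr_0 \cdot decay^e$ (defaults 0.001 and 0.95). Steps are taken on a
relative parameter scale (units of `max(|initial|, 1)`) so one learning rate
serves coefficients spanning 0.18 to 541.7; the cost is half the mean
squared standardised residual. Note the default schedule's total step mass
is $lr_0/(1-decay) = 0.02$ relative units, enough for refinement near a good
start but not for moving a coefficient by 20 % — for recovery from distant
starts pass a larger `lr0`/`decay` (the package's own recovery tests use
`lr0 = 0.05, decay = 0.999`). Ten consecutive cost increases abort with a
diagnostic. The damped least-squares fitter is the recommended tool; the
descent path exists for schedule-compatible comparisons.

## The synthetic generator

`generate_observations()` emulates the flock records the calibration
consumes, at desk scale:

* **Growth**: Gompertz curves $W(t) = A e^{-e^{-k(t - t_i)}}$ — the standard
  poultry growth backbone — with defaults $A = 3.2$ kg, $k = 0.08$/d,
  $t_i = 18$ d and 5 % lognormal between-bird variation on $A$. Peak gain
  (~94 g/d) exceeds the 35 g/d threshold, so the rapid-growth branch is
  exercised. Daily gain is the first difference of weight.
* **Temperature**: one house-level series; scenario mean (winter 8 °C,
  summer 31 °C, transition 21 °C, or an annual sinusoid spanning all three
  zones over 365 days) plus iid Gaussian noise, default SD 3 °C — a
  realistic day-to-day spread for naturally ventilated housing. Cold-day
  counts come from the same scan the CSV reader uses.
* **Observations**: `observed = true × (1 + ε)`, ε Gaussian with SD 5 % by
  default, independent per row and per target — multiplicative because
  requirements are positive and heteroscedastic.

Everything is a deterministic function of the config (one mandatory seed;
sub-draws use fixed offsets of it), which the byte-determinism tests pin
down. The default problem sizes used throughout the tests — 200 birds × 42
days for recovery studies, 2–15 birds for oracle comparisons — keep each
study in seconds while leaving estimator noise well below the tolerances
checked.

What the generator does **not** emulate: feed-intake behaviour (observations
are noisy model truths, not intake records), autocorrelated weather,
house-level management effects, mortality, or per-bird diet variation.
Passing recovery tests therefore show the fitters work when the model is
correctly specified; they say nothing about model adequacy on real flocks.

One identifiability note: under a steady winter scenario nearly every day
sits at $\gamma = 0.32$, so the cold term's leverage is damped and
$k_3^{cold}$ is the least-precise coefficient (across-seed spread near 9 %
relative at the default conditions, versus well under 1 % for $\alpha$ and
$\beta$). The recovery tests use the fixed default seed and also check the
20-seed bias against its Monte-Carlo standard error, which is the honest
summary of that precision.

## Degenerate inputs and numerical conventions

Zero gain, zero cold-days and boundary temperatures are all well-defined;
weight must be strictly positive. Component breakdowns are carried with
every result and sum to the totals to 1e-9 relative tolerance. Worked-value
comparisons round half away from zero to the printed decimals (base R
rounds half to even, which disagrees at printable ties). CSVs are written at
12 significant digits, making write→read→write byte-stable. Published
arithmetic that is internally inconsistent (the 8.138 vs 8.118 maintenance
value, the 18.3 vs 18.36 damped compensation, a 0.24 → 0.18 error drop
described as 23 % where the arithmetic gives 25 %) is reproduced by
computing the true arithmetic and documenting the printed value alongside;
`worked_examples()` carries each with its own tolerance.

## Known limitations

* Humidity is parsed and stored but unused; no parameterisation exists for
  it (the reserved column keeps southern-climate records loadable).
* Random-forest coefficient fitting is out of scope; the calibration surface
  is damped least squares and gradient descent.
* The breed registry covers the four calibration breeds; hybrid metabolic
  heterogeneity is not modelled.
* Economic optimisation (feed cost, nitrogen emission pricing) is out of
  scope; the model stops at requirements and diagnostics.
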