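# pigrowth

Growth-inflection analysis for pig production data: logistic growth-curve
fitting, closed-form growth landmarks (inflection point, maximum daily gain,
maximum-deceleration "optimal slaughter" age), post-inflection trait
trajectories with plateau detection, carcass/meat-quality trait screening,
and 2^−ΔΔCT relative gene expression — with a synthetic two-breed herd
generator so the whole pipeline can be exercised and validated without
animal records.

## Who it is for

Animal scientists and biostatisticians working with longitudinal
body-weight records from fattening pigs (or similar livestock) who want to
(a) locate the growth turning point of a population, (b) derive a
growth-rate-based slaughter-age recommendation, and (c) characterise how
carcass, meat-quality and composition traits change across 10-kg slaughter
weight groups beyond that point.

## The model

Body weight follows the logistic growth curve

    y(t) = A / (1 + B·e^(−K·t))

with `A` the mature (asymptotic) weight in kg, `B` a dimensionless shape
parameter and `K` the intrinsic growth rate per day. All landmark
quantities are closed forms:

| quantity | formula | meaning |
|---|---|---|
| inflection age | `ln(B)/K` | age of maximal daily gain |
| inflection weight | `A/2` | weight at the turning point |
| maximum daily gain | `A·K/4` (kg/d, reported in g/d) | peak growth rate |
| max-deceleration age | `[ln(B) + ln(2+√3)]/K` | where the growth rate falls fastest — the proposed optimal slaughter age |
| weight at that age | `A·(3+√3)/6` | |

Parameters are estimated by Levenberg–Marquardt nonlinear least squares on
log-transformed parameters, pooling all animals of a breed into one
population curve. Post-inflection trait trajectories (e.g. loin muscle area
LMA, intramuscular fat IMF) are fitted with quadratic or asymptotic
(`y = a − b·e^(−c·bw)`) families; a trajectory "plateaus" at the smallest
body weight where the fitted slope drops below 10% of its in-range maximum.
Trait screening uses one-way ANOVA (Tukey HSD post hoc) per 10-kg weight
group plus the sign of the trait–weight Pearson correlation to call each
trait up / down / unchanged, alongside correlation matrices, hierarchical
clustering and PCA. qPCR Ct tables are reduced to fold changes by the Livak
2^−ΔΔCT method.

## Worked example

```r
library(pigrowth)

# landmarks from published lean-type (Yorkshire) population parameters
yp <- logistic_params(A = 160.493, B = 16.901, K = 0.022)
growth_landmarks(yp)
#> Growth landmarks (logistic model)
#>   inflection:        80.25 kg at 128.52 days
#>   max daily gain:    882.71 g/day
#>   max deceleration:  126.58 kg at 188.38 days

# simulate a two-breed herd and refit the fat-type population curve
spec <- synthetic_herd_spec()
herd <- simulate_herd(spec, seed = 17)
fit  <- fit_logistic(herd[herd$breed == "QYP", ])
fit
#> Logistic growth fit: 2268 points (126 animals), PCC = 0.9924, residual SD = 5.199 kg
#> Logistic growth parameters: A = 138.996 kg, B = 20.0559, K = 0.0159795 /day

# post-inflection IMF trajectory of the fat-type breed: saturating response
sl <- simulate_slaughter(spec, seed = 17)
qy <- sl$traits[sl$traits$breed == "QYP", ]
imf <- fit_trait_curve(qy$body_weight, qy$IMF, "asymptotic",
                       trait_name = "IMF", breed = "QYP")
plateau_weight(imf)
#> IMF: plateau at 120.1 kg (slope 0.01709, 10% of max slope 0.1709)

# trend screen across 10-kg weight groups
trends <- screen_traits(sl$traits)
table(trends$breed, trends$direction)
#>       down unchanged up
#>   QYP    5         8 15
#>   YP     2        16 10
```

Reading the output: the lean-type curve turns over at 80.25 kg / 128.5 days
with a peak gain of 883 g/day, and its growth rate declines fastest at
188 days — the deceleration-based slaughter-age recommendation. The refit on
a simulated 126-animal herd recovers the generating fat-type parameters
(A within 1%, observed-vs-fitted correlation 0.992). The fat-type IMF
trajectory saturates near its programmed 110-kg plateau (here detected at
120 kg from one 73-animal herd; sampling error at this group size is about
±8 kg), and the trend screen recovers the programmed 15-up/5-down (fat) and
10-up/2-down (lean) trait structure.

A thin command-line wrapper with `simulate`, `fit`, `landmarks`,
`trajectory`, `screen`, `ddct` and `report` subcommands is installed at
`inst/cli/pigrowth.R`.

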