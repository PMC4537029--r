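---
title: "Scoring PDT combination synergy with the difference-in-logarithms statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring PDT combination synergy with the difference-in-logarithms statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlsynergy)
library(dplyr)
```

## The scientific problem

Photodynamic therapy (PDT) kills tumor cells through reactive oxygen
species generated when a photosensitizer (here chlorin e6, dosed in µM) is
irradiated with light of a matched wavelength (dosed in J/cm²). Because
surviving cells can repopulate through EGFR-driven pro-survival signalling,
PDT is often combined with an EGFR inhibitor such as nimotuzumab or
cetuximab (dosed in µg/ml). The scientific question for any such
combination is whether it merely adds two independent effects or genuinely
potentiates them. `dlsynergy` implements the full quantitative chain for
answering that question in a preclinical study: plate-reader signals →
survival fractions → a synergy statistic and call; xenograft calipers →
growth curves, an in-vivo synergy analog, and Kaplan–Meier survival; plus
the serum toxicity-panel calculators used to check treatment safety.

## The DL model

Independent action (Bliss independence) predicts that when two treatments
act through distinct mechanisms, the expected survival fraction of the
combination is the product of the monotherapy survival fractions,

$$SF_{add} = SF_{PDT} \times SF_{mono}.$$

The departure of the observed combination from this prediction is measured
on the log scale by the difference in logarithms,

$$DL = \log_{10} SF_{PDT} + \log_{10} SF_{mono} - \log_{10} SF_{comb}
     = \log_{10}\!\frac{SF_{add}}{SF_{comb}},$$

so $DL > 0$ means the combination killed more cells than predicted
(synergy), $DL < 0$ antagonism, and $DL = 0$ additivity. Significant
deviation from zero is established with a two-sided one-sample Student
t-test at $\alpha = 0.05$; the significance gate comes first, so a
non-significant DL is called *additive* regardless of sign, and a tie at
exactly $p = \alpha$ is conservatively additive (strict inequality).

Two conventions deserve explanation because the methodology is sometimes
written with a bare "log":

* **Logarithm base.** DL values are reported in log10 units. The t
  statistic and p-value are invariant to the base (a base change rescales
  the mean and SE identically — this is asserted to $10^{-12}$ in the test
  suite); only the magnitude of DL changes. Published DL tables in this
  assay family are on the log10 scale, and `dl_statistic(..., base =)`
  exposes the choice.
* **Unit of replication.** Survival fractions are formed *within* each
  independent experiment (treated mean signal ÷ untreated-control mean
  signal of the same experiment), one DL per experiment, and the SE of DL
  is the sample SD of those per-experiment DLs divided by $\sqrt{n}$ with
  $df = n - 1$. Pooling wells across experiments would understate the SE,
  since plate-to-plate variation dominates well-to-well variation.
  Published summary tables in this family are not always explicit about
  the replicate count behind each row (printed p-values can be consistent
  with $df = 5$ for some rows and $df = 4$ for others), so
  `dl_test(dl_mean =, dl_se =, df =)` accepts the summary triplet
  directly and `synergy_table(df_override =)` can force a convention.

## From plate to survival fraction

`background_correct()` subtracts the per-experiment mean of the medium-only
(blank) wells; a plate whose corrected control mean is nonpositive is
uninterpretable and raises an error rather than propagating nonsense.
`survival_fraction()` treats the corrected signal (ATP luminescence or
fluorescence) as proportional to viable cell number; no nonlinearity of the
detection chemistry is modelled. Survival fractions must be positive for
the log transform. A nonpositive corrected SF is a hard error by default;
`sf_floor` (suggested $10^{-4}$) can floor it instead, which is appropriate
when a very effective treatment drives the corrected signal below the
background noise — at the cost of biasing that DL downward.

Migration and invasion assays report fluorescence that is converted to cell
numbers through a calibration line: `fit_standard_curve()` is ordinary
least squares of signal on known quantity (a saturating four-parameter
logistic is deliberately not offered — the kit protocols describe a dose
curve in the linear regime), and `invert_standard_curve()` performs inverse
prediction, flagging — not rejecting — signals outside the calibrated
range.

## The in-vivo DL analog

Xenograft volumes come from three orthogonal caliper diameters via the
ellipsoid formula $V = \pi/6\, d_1 d_2 d_3$. For the synergy question the
survival-fraction analog of an animal is its **relative tumor burden**: its
volume at a fixed endpoint day divided by the mean control volume on that
day. `invivo_dl()` combines the group-mean analogs of the two monotherapy
arms with the per-animal analogs of the combination arm, giving one DL
replicate per combination animal and $df = n_{comb} - 1$ by default. This
is one of several defensible readings (growth rates or areas under the
growth curve are alternatives); the endpoint-volume reading is the most
direct, it reduces exactly to `dl_statistic()` when each group has one
animal, and both the endpoint day and the df are surfaced as parameters.
The default endpoint is the last day on which all four groups still have
measurements — late enough to see treatment separation, while every group
is still represented.

Survival analysis follows the study design in this field: an animal scores
an event on the first measurement day its volume reaches the ethical limit
(2 cm³ = 2000 mm³; no interpolation between measurement days), and animals
alive at the 90-day horizon are censored there. `km_estimate()` is the
product-limit estimator (via the `survival` package) with events processed
before censorings at tied times; the test suite checks it against a
brute-force product over explicit risk sets and against the empirical
survival function in the uncensored case.

## Toxicity-panel calculators

The kinetic AST/ALT activity is $B / ((T_2 - T_1)\,V)$ where $B$ is the
pyruvate amount (nmol) from the pyruvate standard curve, $T_1, T_2$ the
read times in minutes and $V$ the sample volume in ml — the only
arrangement of those symbols whose units come out as nmol/min/ml, i.e.
mU/ml. Creatinine uses the two-read kinetic protocol (ΔOD = OD at 30 min −
OD at 1 min, regressed on standard concentration and inverted); urea
nitrogen uses a single endpoint read against its standards. Normal-range
flags use inclusive endpoints (clinical convention) with murine defaults:
creatinine 0.1–2.1 mg/dL, urea nitrogen 2–71 mg/dL, AST 37–329 mU/ml, ALT
7–227 mU/ml — all overridable because they are reference values, not
assay constants.

## What the synthetic generator emulates

Real raw data for studies of this kind are rarely deposited, so every
stage is exercised against simulators with known ground truth.

**Viability plates.** The generator inverts the DL definition: given true
monotherapy SFs and a true DL, the combination's true SF is
$SF_a \, SF_b \, 10^{-DL}$. Noise is Gaussian on log10 SF — multiplicative
on SF, which matches the log-scale statistic and guarantees positive
survival — drawn once per condition *and experiment* (shared by the wells
of that condition), because the experiment is the biological replicate.
Optional additive per-well read noise mimics the plate reader. Default
conditions mirror a typical chlorin e6-PDT study: 3 independent
experiments, triplicate wells, mono PDT SF ≈ 0.25 (the 22–27% survival
range seen post-PDT), inhibitor-only SF ≈ 0.85, `noise_sd_log = 0.05`, and
a 4-dose factorial grid (50/100 µM × 50/100 µg/ml).

**Xenograft cohorts.** Volumes grow exponentially; treatment acts as a
multiplier on the log-growth rate, with per-animal lognormal rate jitter
and Gaussian caliper noise on the diameters (derived assuming a sphere —
the three orthogonal diameters of a real tumor are correlated but not
equal, which the jitter emulates without a shape model). Under this
parameterisation relative volumes multiply, so the Bliss-additive null is
$m_{comb} = m_{PDT} + m_{mono} - 1$; the default cohort (4 groups × 10
animals, 200 mm³ at enrolment, control rate 0.072/day so control tumors
reach the ceiling near day 32, mono multipliers 0.6, combination −0.3,
i.e. regression) is deliberately *super*-multiplicative, producing an
in-vivo DL on the scale published for this assay family and a high
combination-arm survival.

**What passing does not show.** The simulators share the analysis model's
own assumptions (log-normal SF noise, exponential growth). Passing
round-trip and calibration tests therefore demonstrates correctness of the
implementation and the statistical calibration of the t-test under its
assumptions — not robustness to plate spatial effects, detection
nonlinearity, non-exponential growth, or measurement-day irregularities,
none of which are modelled. Published group-level outcomes (percent
survival per arm, percent viability per dose) depend on the study's
specific animals and plates and are reproduced only qualitatively.

## Numerical choices and degenerate inputs

* `dl_test` with zero SE: p = 1 (additive) if the mean is also zero,
  otherwise p = 0 with a degeneracy warning — this happens with noiseless
  simulated data, where a t-test is meaningless.
* Experiments missing an arm of a triple are dropped with a warning;
  fewer than two complete experiments is an error (no SE exists).
* Mono-arm matching for triples is exact on doses — designs are
  categorical, so no tolerance is applied.
* Monte-Carlo problem sizes: the null-calibration study uses 10,000
  simulated datasets (binomial SE of the rejection rate ≈ 0.2 percentage
  points) and the recovery/coverage study 1,000 per true DL; both use the
  direct SF-level sampler `simulate_dl_replicates()`, which draws from
  exactly the per-experiment DL distribution implied by the plate
  generator.

## Worked example

```{r example}
spec <- viability_sim_spec(true_dl = 0.3, noise_sd_log = 0.02, seed = 101)
sim <- simulate_viability_experiment(spec)
sf <- survival_fraction(background_correct(sim$measurements, sim$design),
                        sim$design)
synergy_table(sf, sim$design) |>
  select(treatment, dl, se, df, p.value, call)
```

```{r invivo}
cohort <- simulate_tumor_cohort(tumor_sim_spec(seed = 17))
invivo_dl(cohort$tumors)
glance(km_estimate(cohort$survival))
```

## Known limitations

Only Bliss-style independence is scored — Loewe additivity, the
Chou–Talalay combination index and response-surface models are out of
scope, as are IC50 fitting, plate spatial-effect correction, log-rank
testing and mixed-effects growth models (standard routines exist elsewhere
for all of these). The in-vivo DL rests on the endpoint-volume reading
described above; studies wishing to score growth rates instead should
compute their own SF analogs and feed them to `dl_statistic()` /
`dl_test()` directly.
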