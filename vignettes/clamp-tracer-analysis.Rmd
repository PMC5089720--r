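---
title: "Tracer kinetics of the hyperinsulinemic-euglycemic clamp: models, estimators and validation"
author: "clampkin"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clampkin)
```

## The measurement problem

The hyperinsulinemic-euglycemic clamp is the reference method for
quantifying insulin sensitivity in vivo. Insulin is infused at a constant
rate (here 0.75-1.0 mU/kg/min) while exogenous glucose is infused at a
variable rate (GINF) to hold plasma glucose at its basal level; endogenous
insulin secretion is suppressed with somatostatin, so plasma insulin is
set entirely by the pump. Once glucose is clamped, the glucose infusion
requirement reflects insulin-stimulated disposal — but disposal (Rd) and
endogenous (hepatic) glucose production (EGP) can only be separated with a
tracer. The protocol modeled here uses a primed-continuous [3-3H]glucose
infusion (25 uCi prime, 0.25 uCi/min) with the exogenous glucose itself
labeled at 2.7 uCi/g ("hot GINF"), which keeps plasma specific activity
nearly constant during the clamp and thereby minimizes the model error of
the non-steady-state correction.

`clampkin` implements the full analysis chain — smoothing, Steele's
single-pool non-steady-state equations in the labeled-infusion form,
basal and steady-state summaries, sensitivity indices, and the group
statistics — together with a mechanistic simulator of the same protocol
that provides known ground truth for validating every step.

## Steele's equation, labeled-infusion form

All quantities are per kg body weight; G in mg/dl, tracer concentrations
in dpm/dl (plasma samples are recorded as dpm/ml and converted), V in
dl/kg. The plasma specific activity is

$$SA(t) = \frac{100 \cdot G^*(t)}{G(t)} \quad \text{(dpm/mg)},$$

and with both the tracer pump ($F^*$, dpm/kg/min) and the labeled
infusate (GINF times its specific activity $SA_{inf}$) delivering label,

$$Ra_{tot}(t) = \frac{F^*(t) + GINF(t)\,SA_{inf} - p\,V\,G(t)\,\dot{SA}(t)}{SA(t)},$$
$$EGP(t) = Ra_{tot}(t) - GINF(t), \qquad
  Rd(t) = Ra_{tot}(t) - p\,V\,\dot{G}(t).$$

$p$ is Steele's pool fraction (the rapidly mixing share of the glucose
space) and $V$ the glucose distribution volume. Neither is measurable
from a single clamp; the package defaults are the conventional
$p = 0.65$, $V = 2.2$ dl/kg, both configurable. Validation analyses
against the single-pool simulator use $p = 1$ with the simulator's $V$,
which makes the analysis model exactly match the data-generating model
and so isolates estimation error from model mismatch. Microcurie inputs
are converted at $2.22 \times 10^6$ dpm/uCi at the I/O boundary. Negative
EGP estimates are reported as computed and flagged, never clipped:
clipping would bias the hepatic insulin effect toward suppression.

## Optimal-segments smoothing

The non-steady-state terms require $\dot{G}$ and $\dot{SA}$, which must
come from a smooth fit, never from finite differences of noisy assay
values. `fit_optimal_segments()` fits a piecewise cubic with continuous
value and slope (C1), with segment boundaries chosen adaptively at sample
times by greedy forward insertion: the $k{+}1$-segment model adds the
interior sample point whose insertion most reduces the residual sum of
squares. Successive models are therefore nested, so RSS is non-increasing
in the segment count by construction, and knots concentrate where the
signal bends (the insulin-activation transient) rather than where samples
happen to be dense. An earlier design with knots at fixed data-count
quantiles was abandoned: non-nested knot sets can make RSS increase with
$k$, and a strictly greedy $k$-vs-$k{+}1$ F test can stall at $k = 1$
when the first refinement happens to fall on an uninformative boundary
(on clamped glucose the 1-to-2-segment step is locally non-significant
even though five segments fit dramatically better).

The segment count is the smallest $k$ that no finer admissible model
improves on significantly, by extra-sum-of-squares F tests at
`alpha = 0.05` (testing $k$ against *every* refinement, not only
$k{+}1$). `max_segments` defaults to 6, which for a ~30-point clamp
record caps the fit at 14 parameters and prevents interpolation of assay
noise; `alpha`, `max_segments` and the assay SD (`sigma`, storable or
estimated from the most flexible fit) are exposed. A single cubic segment
reproduces any cubic exactly (residuals below 1e-8 in the tests), and the
evaluator refuses extrapolation outside the fitted range.

### Infusion compensation for time-resolved fluxes

GINF is not a smooth signal: the operator resets the pump at each sample
draw, so the true glucose trajectory has slope kinks exactly at the
sample times, which a C1 smoother cannot represent. Because the pump
schedule is *known exactly*, `compute_fluxes()` can subtract the
cumulative infusion contribution before smoothing (the smoother then sees
the kink-free endogenous trajectories $G - \mathrm{cum}(GINF)/V$ and
$C^* - SA_{inf}\,\mathrm{cum}(GINF)/V$) and restore the step terms
analytically, pairing right-sided derivatives with the infusion rate in
force at each sample. This recovers the simulated flux time course within
2% through the post-transient period on noise-free data. It is **not**
the default: compensation widens the dynamic range the smoother must
track roughly seven-fold, which inflates variance under realistic assay
noise. Direct smoothing of G and SA (the default) is grid-stable and
more precise for the window-averaged summaries that the sensitivity
indices use; compensation (`compensate_infusion = TRUE`, with a larger
`max_segments`) is recommended when the goal is the flux *time course*
from low-noise records.

## Windows, indices, clearance

Steady state is the final 30 minutes of the clamp; the basal summary uses
the final 30 minutes before insulin starts. Both windows are half-open on
the left and include their right edge — in particular a sample drawn at
the moment insulin starts is still basal, since infused insulin has not
yet acted. With basal and steady-state averages,

$$SI_P = 10^4\,\frac{\Delta Rd}{\Delta Ins \cdot Gluc_{SS}}, \qquad
  SI_H = 10^4\,\frac{\Delta EGP}{\Delta Ins \cdot Gluc_{SS}},$$

where $\Delta Rd = Rd_{SS} - Rd_{basal}$,
$\Delta Ins = Ins_{SS} - Ins_{basal}$, and $\Delta EGP$ is defined
suppression-positive ($EGP_{basal} - EGP_{SS}$) so that a healthy liver
has $SI_H > 0$ and insulin-paradoxical stimulation of glucose production
appears as $SI_H < 0$. That sign convention is what lets a
conscious-to-anesthetized percent reduction exceed 100%: the reduction
formula $100\,(SI_{ref} - SI_{test})/SI_{ref}$ passes 100% exactly when
the test-condition index flips sign. The insulin metabolic clearance
proxy is $MCR = \text{insulin rate} / Ins_{SS}$, stored as the raw ratio
(mU/kg/min)/(uU/ml).

## The synthetic clamp

`simulate_clamp()` integrates a deliberately minimal physiology whose
steady states have closed forms:

* remote insulin action $\dot{X} = -p_2 (X - (I - I_b))$, glucose
  disposal $Rd = (k_b + s_P X)\,G$ with $k_b = EGP_b / G_b$, and
  production $EGP = \max(0,\, EGP_b (1 - s_H X))$, so basal is a fixed
  point by construction and the generator-implied true indices are
  $SI_P = 10^4 s_P$ and $SI_H = 10^4 EGP_b s_H / G_b$ away from the EGP
  floor;
* a glucose pool $V \dot{G} = EGP + GINF - Rd$ and a tracer pool
  $V \dot{C^*} = F^* + GINF \cdot SA_{inf} - Rd\,C^*/G$, initialized at
  the tracer prime;
* first-order insulin kinetics
  $\dot{I} = 1000 \cdot \text{rate}/V_I - n_I I$ with no endogenous
  secretion (somatostatin), giving
  $I_{SS} = 1000\cdot\text{rate}/(n_I V_I)$. Dimensional consistency
  requires $V_I$ in ml/kg; with $V_I = 150$ ml/kg and $n_I = 0.09$/min,
  a 1.0 mU/kg/min infusion yields $I_{SS} \approx 74$ uU/ml and an
  insulin clearance $n_I V_I \approx 13.5$ ml/kg/min, both in the
  physiological range for dogs.

Default physiology (invented, documented here): $G_b = 95$ mg/dl,
$EGP_b = 2.5$ mg/kg/min, $V = 2.2$ dl/kg, $p_2 = 0.05$/min, $I_b = 0$
under somatostatin. The four condition presets scale the insulin-action
parameters: anesthesia halves $s_P$ (8e-4 to 4e-4 per uU/ml in lean,
5e-4 to 2.5e-4 in fat-fed) and collapses $s_H$ toward or past zero
(0.012 to 0.002 in lean; 0.006 to -0.001 in fat-fed, the
insulin-paradoxical case). These mirror the directions and approximate
magnitudes of anesthesia and diet effects on clamp indices without
writing any published percentage into a test oracle. Body weights are
normal around 28.5 kg (SD 2 kg); between-animal dispersion draws
unit-mean log-normal factors (default CV 0.2) for $G_b$, $EGP_b$, $s_P$
and $s_H$. Volumes are held fixed so that matched-model analyses need no
per-animal constants.

### The glucose controller

The operator is modeled as a discrete controller acting at each sample
draw (default every 10 min):

$$GINF \leftarrow \max\!\big(0,\; GINF - K_d V \hat{\dot G} + K_p (G_b - G)
  + K_i {\textstyle\int}_{\text{last interval}} (G_b - G)\,dt\big),$$

with $\hat{\dot G}$ the slope of the last two glucose readings. The slope
term is how clamp operators actually reason — "glucose fell 5 mg/dl over
10 minutes at this GINF, so demand rose by about $V \times$ slope" — and
is what makes the clamp settle: a purely proportional-integral update
reacts only after an error has accumulated, and against the 20-min
time constant of insulin action it lets glucose dip ~15% mid-clamp. With
the demand-matching term (defaults $K_p = 0.25$, $K_i = 0.01$,
$K_d = 1$) the early dip is ~7% and the final 30 minutes hold within
0.1% of basal on every preset; a cumulative (rather than per-interval)
integral inside this incremental update would amount to double
integration and oscillate. The controller reads true glucose (bedside
duplicates are far more precise than the stored assay value); simulated
records carry multiplicative assay noise on glucose (CV 2%) and insulin
(CV 5%) and counting noise on the tracer (SD proportional to the square
root of the activity), applied only to the sampled values. Controller
failure (glucose off by more than 50%) aborts with a diagnostic rather
than returning an unusable record.

## What the tests do and do not show

The simulator is single-pool by design, so analyses with $p = 1$ and
matched $V$ are free of model mismatch; passing recovery tests
demonstrates the estimation chain is correct, not that Steele's
single-pool treatment is unbiased for a real two-compartment glucose
system. A mismatch mode (analyzing simulated data with the conventional
$p = 0.65$) is available to study that bias. Real clamp data also carry
slow assay drift, occasional missing draws, and inter-assay calibration
error, none of which the noise model emulates.

Problem sizes used by the validation suite: one noise-free record for the
flux-recovery check; 20 animals per condition for index recovery; 20
cohort replicates of the 16/16/16/8 design for the anesthesia headline
property; 2000-replicate null simulations for the type-I error
calibration of the pooled t test and the Type-II two-way ANOVA.

Two estimation limits are worth stating plainly. First, per-animal
$SI_H$ in anesthetized groups has large *relative* error no matter the
smoother settings: the true index is near zero there (that is the
biology being modeled), while assay noise propagates to roughly
0.1 mg/kg/min of irreducible error in a window-averaged EGP — about
0.15 in $SI_H$ units. Group means (n = 8-16) recover the effect
direction and magnitude reliably — across 20 simulated cohorts the
hepatic percent reduction exceeds the peripheral one in 20 of 20 — but
single-animal hepatic indices near zero should be interpreted as
sign-and-magnitude estimates, not precise values. Second, a time-resolved
flux curve through the activation transient needs the
infusion-compensated smoother and low noise; with default assay noise
only the window-averaged summaries are reliable.

## Numerical choices

ODE integration uses `deSolve::lsoda` at rtol = atol = 1e-10, piecewise
between controller updates so GINF is exactly a step function; tracer and
glucose mass-balance ledgers are integrated alongside the states and
close to ~1e-14 relative. The smoother's basis is evaluated on times
rescaled to [0, 1] for conditioning, and per-segment coefficients are
recovered as exact Taylor expansions at each left knot. Window membership
uses half-open intervals throughout, so boundary samples are counted
exactly once. The unbalanced ANOVA standardizes the response internally
(F and p are scale-invariant) because endpoints such as MCR (~0.013)
otherwise trip absolute zero-variance guards; sums of squares are
rescaled on output. Degenerate statistics are defined rather than NaN:
zero pooled variance with equal means gives t = 0, p = 1, with unequal
means p = 0; a single-animal group reports its SEM as undefined (NA),
not 0.
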