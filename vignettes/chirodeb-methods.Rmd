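---
title: "The chirodeb model: bioenergetics of the C. riparius life cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The chirodeb model: bioenergetics of the C. riparius life cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`chirodeb` implements a Dynamic Energy Budget (DEB) model of the
holometabolous midge *Chironomus riparius* of the "hax" family: metabolic
acceleration between birth and puberty, reproduction-buffer filling
restricted to the last larval instar, a non-feeding pupa whose structure is
reset, and a non-feeding, non-growing imago. An individual is described by
four state variables: reserve $E$ (J), structure $V$ (cm^3), maturity
$E_H$ (J) and the reproduction buffer $E_R$ (J). Mobilised reserve is split
by the $\kappa$-rule: a fraction $\kappa$ funds somatic maintenance
$\dot p_S = [\dot p_M] V$ and growth, the rest funds maturity maintenance
$\dot p_J = \dot k_J E_H$ and maturation or reproduction. The fluxes are

$$\dot p_A = \{\dot p_{Am}\}\, s_M f V^{2/3}, \qquad
\dot p_C = E\,\frac{[E_G]\,\dot v\, s_M V^{2/3} + [\dot p_M] V}
                  {\kappa E + [E_G] V},$$

with $\dot p_G = \kappa \dot p_C - \dot p_S$ and
$\dot p_R = (1-\kappa)\dot p_C - \dot p_J$, and the dynamics
$dE/dt = \dot p_A - \dot p_C$, $dV/dt = \dot p_G/[E_G]$,
$dE_H/dt$ or $dE_R/dt = \dot p_R$ depending on the stage.

The life cycle proceeds through events located exactly by root-finding on
the continuous solution:

1. **Embryo.** No assimilation, isomorphic, $s_M = 1$. The initial egg
   energy $E_0$ is solved by bisection shooting so that the scaled reserve
   density $e = E\dot v/(\{\dot p_{Am}\} V)$ equals 1 at birth
   ($E_H = E_H^b$) — the abundant-food maternal condition, used for all
   scenarios because egg size is taken to be independent of the mother's
   ration.
2. **Immature larva (L1–L3).** The larva feeds and grows as a V1-morph:
   surface area scales with volume, which is expressed by the acceleration
   factor $s_M = \max(1, \min(L, L_p)/L_b)$ multiplying
   $\{\dot p_{Am}\}$ and $\dot v$. Structure therefore grows exponentially
   at constant food. Puberty is the maturity event $E_H = E_H^p$, tied to
   the L3→L4 molt; $s_M$ freezes at $L_p/L_b$ thereafter (deliberately so
   for the pupa as well, whose own structural length restarts near zero and
   would otherwise spuriously de-accelerate).
3. **Fourth instar, Phase I.** Maturation stops ($E_H$ frozen at $E_H^p$)
   and $\dot p_R$ fills the reproduction buffer. The phase ends when the
   buffer *density* reaches the threshold $[E_R^j]$.
4. **Fourth instar, Phase II.** Growth and buffer filling stop; assimilated
   energy tops up the general reserve at fixed structure
   ($\dot p_C = \dot p_S + \dot p_J$). Pupation is triggered when the
   reserve density reaches its maximum capacity
   $[E_m] = \{\dot p_{Am}\}/\dot v$. At abundant food the reserve density
   is already at capacity when Phase II starts, so its duration collapses
   to zero; under food limitation this second trigger is what prolongs the
   fourth instar without inflating fecundity — the behavioural signature
   this dual-trigger design exists to capture.
5. **Pupa.** Larval structure is instantaneously converted to reserve with
   the (tiny) efficiency $\kappa_V$, structure restarts from a small seed,
   maturity restarts from zero and is rebuilt to $E_H^e$; the reproduction
   buffer is retained untouched.
6. **Imago.** Neither feeds nor grows; mobilisation is
   $E \dot v s_M V^{-1/3}$ and pays maintenance until the reserve can no
   longer cover it or the horizon ends. Eggs per female are
   $N_i = \kappa_R [E_R^j] V_j / E_0$ with $V_j$ the structure at pupation.

## Forcing

Food enters as the scaled functional response $f = X/(X_K + X)$ (Holling
type II); scenarios may also set $f$ directly, including values above 1
for richer diets. A piecewise-linear profile reproduces the rearing
protocol of the growth experiments: $f = 1$ until puberty, then a linear
decline over 7.5 d to a per-ration minimum (`scenario_variable_f()`).
Integration is restarted at profile breakpoints so event roots are never
bracketed across a derivative discontinuity.

Temperature acts through one correction factor applied to every rate
($\{\dot p_{Am}\}, \dot v, [\dot p_M], \dot k_J, \dot h_b,
\dot k_{starv}$):

$$c_T(T) = \exp\!\left(\frac{T_A}{T_{ref}} - \frac{T_A}{T}\right)
\frac{1 + \exp(T_{AH}/T_H - T_{AH}/T_{ref})}
     {1 + \exp(T_{AH}/T_H - T_{AH}/T)},$$

the upper-bounded Arrhenius form of DEB theory, normalised at
$T_{ref} = 293.15$ K. No lower thermal boundary is applied: the
parameterisation did not support one, and predictions below about 15 °C
should be read with corresponding caution. Because every rate carries the
same factor, event *times* at constant $f$ scale exactly as $1/c_T$ while
lengths, weights and egg numbers are temperature-invariant.

## Parameters

The packaged defaults (`deb_params()`, mirrored verbatim in
`inst/extdata/chironomus_riparius.yaml`) are the published reference values
at 20 °C. Three groups deserve comment:

* **Maintenance ratio.** $k = \dot k_J [E_G]/[\dot p_M] = 0.9967$, i.e. the
  estimation's $k = 1$ pseudo-datum is honoured to a fraction of a percent.
  This near-identity makes maturity proportional to structure along
  abundant-food trajectories, so lengths at events are nearly independent
  of food level — a property the package's tests assert.
* **$\kappa_R$ (reproduction efficiency)** appears only in the egg-number
  formula and is not part of the published table; the conventional DEB
  value 0.95 is the default and is configurable.
* **Composition coefficients** (`comp_params()`) linking state to weight
  are likewise not published; defaults follow common DEB practice
  (structural dry density 0.17 g/cm^3, reserve mass per energy
  $w_E/\bar\mu_E = 23.9/550000$ g/J, water fraction 0.83). All
  weight-valued outputs are therefore order-of-magnitude quantities unless
  these coefficients are calibrated. The reproduction buffer is counted as
  dry mass in both wet and dry weight (aquatic insect eggs hydrate after
  laying), which is what makes the dry-weight fraction rise through the
  fourth instar.

## Instar partition

The molt constants $s_1 = s_2 = 2.48$ partition the immature phase into
L1–L3 by Dyar-type length thresholds pinned at the puberty length. The
package applies them as ratios of *squared* structural length (surface
area) between consecutive molts — thresholds $L_b\sqrt{s_1}$ and
$L_b\sqrt{s_1 s_2}$ — because this is the only simple reading consistent
with the reported instar durations (under exponential V1-morphic growth it
yields durations in proportion 1.87 : 1.87 : 2.65 d at 21 °C, against the
reported 1.9/1.9/2.6), and because a plain length-ratio reading would put
the second threshold beyond the puberty length. The mapping is exposed as
a strategy argument (`surface`, `length`, `volume`) on
`instar_boundaries()` and `deb_lifecycle()`.

## Survival

$S(t) = \exp(-\int h\,dt)$ accrues from hatching with
$h = c_T\,(\dot h_b + \dot k_{starv}\,
\max(0, 1 - \kappa \dot p_C/\dot p_S))$ in $\kappa$-rule stages; in
Phase II and the imago, where the $\kappa$-rule is suspended, the deficit
is measured against total maintenance
($1 - \dot p_C/(\dot p_S + \dot p_J)$). At abundant food the deficit is
identically zero and survival reduces to the background exponential. The
exact starvation form used in the original estimation is not published;
this form uses exactly the two published hazard parameters, reduces to
background hazard ad libitum, and makes survival decay strictly faster
once mobilisation cannot cover maintenance.

## Numerical choices

* Integration uses `deSolve::lsodar` with relative tolerance $10^{-10}$
  (default simulations; $10^{-8}$ during estimation) and state-scaled
  absolute tolerances; every stage transition is an lsodar root, so the
  recorded event states satisfy their defining equalities to ~$10^{-9}$
  relative. Molt thresholds are additional non-terminal roots.
* The egg shooting solve brackets $E_0$ starting from
  $[2 E_H^b, 50 E_H^b]$, widening by factors of 4 up to a hard cap, then
  applies Brent's method to tolerance $10^{-12}$ J.
* The embryo starts from $V_0 = 10^{-12}$ cm^3 (the growth equation is
  non-Lipschitz at $V = 0$); the pupa restarts from
  $V_{seed} = 10^{-8}$ cm^3. Both are configurable; halving $V_{seed}$
  moves the emergence age by well under 0.5% because mobilisation vanishes
  with surface area.
* Phase II is entered with an explicit capacity check: if
  $E/V \ge [E_m]$ at the switch (the abundant-food case) pupation is
  immediate, avoiding a root that would otherwise sit on a zero of the
  trigger function for the entire phase.
* The default horizon is 200 d since oviposition; unreachable triggers
  terminate with an explicit status (`pupation_not_reached`, ...) rather
  than an error.
* A fixed-step classical RK4 integration at $h = 10^{-4}$ d, written
  independently in the test helpers, reproduces the adaptive solver's
  event ages to better than 0.1%.

## Conventions settled during development

* **Emergence clock.** "Time at emergence" is reported since hatch: the
  full simulation gives 20.6 d since hatch at 20 °C against the published
  20.0 d (and 24.4 d since oviposition), which settles the ambiguity in
  favour of the since-hatch convention. The report carries both clocks.
* **Length at pupation** is converted with the dead-specimen shape
  coefficient $\delta_{M2}$: the underlying datum was measured on
  preserved animals, and only this choice makes the published pupation
  length and wet weight mutually consistent.
* **Food-sweep range.** Within the 200 d horizon pupation remains
  reachable down to $f \approx 0.03$, where stage durations stretch to
  tens of days. The published sweep statements (immature duration up by
  ≈5 d, Phase II by ≈7 d, total larval time "almost doubling") are
  mutually consistent only if the scarcity end of the swept range is the
  point where larval duration has doubled, $f \approx 0.26$ here; the
  acceptance checks anchor the sweep there, locating the doubling point by
  interpolation rather than by grid choice.

## What the synthetic-data generator does and does not emulate

`synthetic_datasets()` reproduces the observation *structure* of the
calibration data: zero-variate event ages and fecundity plus uni-variate
length-at-age and wet-weight-at-age series, under any forcing scenario,
with multiplicative lognormal noise (mean-preserving, configurable CV; the
paper states no error model, and positive observables make a
multiplicative model the natural choice). It does not emulate
between-individual parameter variability, measurement rounding, censoring
of late emergers, or the food-accumulation dynamics of the rearing medium
(scenarios act directly on $f$). Passing recovery tests therefore
demonstrate identifiability under the model's own error structure, not
robustness to real-data pathologies.

The packaged recovery study (also the calibration acceptance check)
generates data at the reference truth with CV = 0.05 under $f = 1$ at
21 °C (four event ages, fecundity, and 12-point length and weight series
to day 13), displaces {$\{\dot p_{Am}\}, \dot v, [\dot p_M], E_H^p,
[E_R^j]$} by ±20%, and recovers each within 10% (observed: within ~2%)
in about 400 Nelder–Mead iterations.

## Estimation machinery

The loss is the symmetric bounded form: per point
$w\,(d - p)^2/(d^2 + p^2)$ (0/0 defined as 0), summed with per-dataset
weights normalised by dataset size; it is symmetric in data and
prediction, scale-invariant, and bounded per point by its weight.
Goodness of fit is summarised by the mean relative error (MRE, weighted
mean over datasets of mean $|p - d|/|d|$; zero-valued data excluded with
a warning) and the symmetric mean squared error (SMSE, the analogous mean
of the bounded symmetric ratios, in $[0, 1]$). Optimisation is
Nelder–Mead in log-parameter space (positivity by construction), with the
maintenance-ratio pseudo-datum $k = 1$ at weight 0.1 by default and
optional jittered restarts that are deterministic under the seed.
Non-convergence within the iteration budget returns the best-so-far
parameters with an explicit flag.

The packaged zero-variate table (`zero_variate_data()`) and per-ration
functional-response estimates allow prediction-only fits out of the box.
The published all-data fit quality (MRE ≈ 0.13) is *not* reproducible
here: most of the source uni-variate datasets are not published in
tabular form, and no attempt is made to assert it.

## Known limitations

* Predictions below ~15 °C inherit the missing lower thermal boundary.
* Weight observables depend on unpublished composition coefficients
  (order-of-magnitude only by default).
* Oxygen consumption is a flagged dissipation proxy, not a mineral-flux
  computation.
* No ageing: imago lifespan is reserve-limited or horizon-limited by
  design, and no egg-laying schedule is modelled.
* Sex differences are represented solely by the male assimilation
  ceiling $\{\dot p_{Amm}\}$.

## Problem sizes used by the test-suite

The suite simulates full life cycles (≈500–1700 recorded samples each) at
five temperatures and eight food levels, runs one five-parameter recovery
study (~400 objective evaluations, each a complete life-cycle simulation),
and two single-parameter fits; the whole suite completes in a few minutes
on one core.
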