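# chirodeb

A Dynamic Energy Budget (DEB) life-cycle model for the harlequin fly
*Chironomus riparius*, the chironomid most widely used in aquatic toxicity
testing. The package simulates the full cycle — egg, four larval instars,
pupa, imago — under arbitrary food and temperature forcing, and predicts
the endpoints that sediment-toxicity and risk-assessment studies care
about: event ages (hatch, molts, puberty, pupation, emergence), body
length and weight, fecundity and survival. It is aimed at ecotoxicologists
and modellers who need a mechanistic control (non-toxicant) model of
*C. riparius* development, e.g. as the bioenergetic backbone of TKTD
analyses.

## The model in brief

An individual carries four state variables: reserve $E$ (J), structure
$V$ (cm³), maturity $E_H$ (J) and a reproduction buffer $E_R$ (J).
Assimilation is $\{\dot p_{Am}\} s_M f V^{2/3}$ with $f$ the scaled
(Holling type II) functional response; mobilised reserve
$\dot p_C = E([E_G]\dot v s_M V^{2/3} + [\dot p_M]V)/(\kappa E + [E_G]V)$
is split by the κ-rule between soma and maturation/reproduction. The
immature larva (L1–L3) grows as a V1-morph — the acceleration factor
$s_M = \max(1, \min(L, L_p)/L_b)$ rises with structural length and then
freezes at puberty. The fourth instar is biphasic: in Phase I the κ-rule
fills the reproduction buffer until its density reaches $[E_R^j]$; in
Phase II growth stops and assimilation tops up the reserve until the
reserve density reaches its maximum capacity
$[E_m] = \{\dot p_{Am}\}/\dot v$, which triggers pupation. This **dual
trigger** is the point of the model: under food limitation the fourth
instar stretches by days-to-weeks while egg number
($N_i = \kappa_R [E_R^j] V_j / E_0$) falls only moderately — the pattern
observed in rearing experiments, and one that single-trigger DEB insect
models fail to produce. All rates share one Arrhenius temperature
correction with an upper tolerance boundary.

## Worked example

```r
library(chirodeb)

p  <- deb_params()                        # published reference values, 20 degC
lc <- deb_lifecycle(p, deb_scenario(T_c = 21, f = 1))
lc
#> Simulated C. riparius life cycle (hax DEB model)
#> Forcing scenario: T = 21 degC; constant f = 1 ; female ; horizon 200 d
#>   status: completed
#>   E_0 = 0.02257 J; age at birth 3.56 d; L_b = 0.008371 cm
#>   molt L1->L2                     2.03 d since birth
#>   molt L2->L3                     4.06 d since birth
#>   puberty (L3->L4)                6.75 d since birth
#>   phase switch (ER/V = [ERj])    14.07 d since birth
#>   pupation (E/V = [Em])          14.07 d since birth
#>   emergence                      19.25 d since birth
#>   s_M = 4.520; L_j = 0.09904 cm; eggs/female N_i = 217.7
```

Reading this: the egg needs 0.0226 J to hatch with a full reserve after
3.56 d at 21 °C; the larva accelerates its metabolism 4.5-fold while
growing through L1–L3 (about 2 d per early instar); at abundant food the
reserve density is already at capacity when the buffer threshold is met,
so Phase II has zero length and pupation follows the phase switch
immediately at 14.1 d after hatch; the imago emerges 19.2 d after hatch
carrying a buffer worth ~218 eggs.

Food limitation stretches the larval stages and trims fecundity:

```r
cmd_sweep("f", c(0.3, 0.5, 1), T_c = 21)[,
  c("f", "immature_duration", "phase2_duration", "t_pupation", "N_i")]
#>     f immature_duration phase2_duration t_pupation    N_i
#> 1 0.3              9.89            6.23      25.53 141.12
#> 2 0.5              8.12            2.81      19.17 175.33
#> 3 1.0              6.75            0.00      14.07 217.66
```

Other entry points: `scenario_variable_f()` (the declining-ration profile
of the growth experiments), `deb_observables()` / `plot()` (lengths,
weights, survival along the trajectory), `synthetic_datasets()` (noisy
calibration data from a known truth) and `deb_calibrate()` (Nelder–Mead
estimation with the symmetric bounded loss, pseudo-data and MRE/SMSE
reporting). A thin command-line wrapper lives at `inst/cli/debchiro.R`
(`simulate`, `sweep`, `fit`, `make-synthetic`).

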