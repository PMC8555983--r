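---
title: "Division control from single-cell lineages: models, observables, and the limiting probability pH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Division control from single-cell lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concycle)
```

## The problem

Slow-growing *E. coli* coordinates two cell-cycle processes whose relative
timing is disputed: chromosome replication/segregation (initiation, the C
period from initiation to termination, and the D period from termination to
division) and a replication-independent inter-division process anchored at
birth (an accumulator such as FtsZ reaching a threshold). Three model
families make distinct predictions for how size fluctuations propagate
through the cycle:

* **ICD models** — replication limits division: an inter-initiation process
  sets initiation size, and a coupling over the C+D period sets division.
* **Double-adder models** — the ICD special case in which both the
  inter-initiation and C+D processes are perfect adders.
* **Concurrent cycles** — division waits for *both* an inter-division (H)
  process and a replication/segregation (C+D') process; the probability
  `pH` that H finishes last measures how often division is
  replication-independent.

This package implements the linear-response formalism that turns those
models into testable slope predictions, stochastic simulators of all three
families, the observables pipeline (robust adder slopes over the G, I and
C+D subperiods), replication-round detection on per-frame replisome-signal
traces, the `pH` fit, and a synthetic mother-machine data generator that
stands in for the original microscopy data.

## Coupling constants

Size control over any subperiod can be quantified on the adder plot: added
size against initial size, conventionally both normalized by their means.
Its slope is the coupling constant `zeta`: 0 for an adder, -1 for a sizer
(final size independent of initial size), and `Q - 1` for a timer, where
`Q = exp(<log(final/initial)>)` is the subperiod's mean multiplicative
growth factor (about 2 for the full cycle of symmetrically dividing cells,
with origin-number corrections for subperiods that span divisions or
initiations). The equivalent size-growth-plot slope `lambda` satisfies
`zeta = (1 - lambda) Q - 1` in the small-fluctuation limit;
`zeta_from_lambda()` and `lambda_from_zeta()` convert between them.

Two slope conventions coexist and are easy to conflate. The covariance
relations below predict the *raw-unit* regression slope of added on initial
size. The plotted convention divides both axes by their means, which leaves
the slope unchanged exactly when mean added size equals mean initial size —
true for the inter-division (G) and inter-initiation (I) periods, not for B
or C+D (they differ by the factor `mean(initial)/mean(added)`, about 1.3
for C+D here). Following the original analysis procedure, the pipeline
reports normalized slopes and feeds them to the `pH` fit; the
theory-versus-simulation checks in the test suite use raw slopes
(`adder_slope(..., normalize = FALSE)`, or plain least squares, since the
predictions are covariance statements).

## Model predictions

With `vr = var(VB)/var(V0)` (initiation-size to birth-size variance ratio)
and `n` the number of generations spanned by C+D
(`n = floor(tau_CD/tau) + 1`):

* ICD (`predict_icd()`):
  `zeta_G + 1 = (zeta_CD + 1)^2 (zeta_I + 1) vr / 4^n` and
  `zeta_B + 1 = (zeta_CD + 1) (zeta_I + 1)^n vr / 4^n`.
* Double-adder (`predict_witz()`): the same with
  `zeta_I = zeta_CD = 0`.
* Concurrent cycles (`predict_concurrent()`), with the
  replication/segregation process a pure timer and `QCD'` its growth
  factor:
  `zeta_CD + 1 = (1 - pH) QCD' / (1 - pH (zeta_H+1)(zeta_I+1)/4)`,
  `zeta_B + 1 = (zeta_CD + 1)(zeta_I + 1) vr / 4`, and
  `zeta_G + 1 = pH (zeta_H + 1) + (1 - pH) QCD' (zeta_B + 1)`.

`QCD'` is not measurable; it is approximated by the measured unperturbed
`Q_CD = 1.8` and held constant across perturbations (the C period is
unaffected by them). As `pH` runs from 0 to 1, `zeta_CD` interpolates
monotonically from `QCD' - 1` down to -1 — the model's signature.

The general-`n` ICD prefactors were re-derived from the single-generation
covariance recursions; predictions with `n > 1` are flagged approximate and
are validated by simulation, as the concurrent-cycles theory itself is
restricted to non-overlapping rounds (`C+D < tau`).

`fit_ph()` inverts these relations. In fixed mode (`zeta_H = 0`):
`pH = (QCD' - (zeta_CD+1)) / (QCD' - (zeta_CD+1)/4)`, clipped to [0, 1]
with a warning since sampling noise can push the inversion slightly
outside. In free mode, `(pH, zeta_H)` minimize the squared residuals of
the G and C+D relations weighted by the inverse squared standard errors of
the observed slopes — slopes from different conditions carry very
different uncertainty, so unweighted fitting would let the noisiest
condition dominate.

## Simulators

Both simulators follow mother-machine lineages (one daughter per division,
independent channels, vectorized across channels), with exponential
single-cell growth at a per-cell log-normal rate and log-normal added
sizes. Division asymmetry draws the inherited fraction from a Gaussian
with mean 1/2 and standard deviation `alpha/2`, so the measured asymmetry
`(L0_sib - L0)/(L0_sib + L0)` has standard deviation `alpha` (5% in the
experiments emulated here).

Initiation follows the per-origin adder: in the frame of the cell in which
a round fires, the next threshold is the firing size plus `2 dI` (two
origins each adding `dI`), or `4 dI` when the round fires on two origins
(initiation in the mother of the cell whose division it gates, the
`n = 2` regime); thresholds and pending initiation events transform across
divisions with the additive asymmetry bookkeeping
`VB' = VB/2 + dI - (Vd/2 - V0')`. This keeps the *measured* ori-normalized
added size between initiations equal to the drawn `dI`, and the measured
mean per-origin initiation size equal to `2 <dI>`, in both the `n = 1` and
`n = 2` regimes. Rounds gating a division more than two generations ahead
(overlapping rounds) are outside the supported regime.

The ICD simulator divides at `VB + dCD`. The concurrent simulator computes
two completion times — the H candidate at size `V0 + dH` and the C+D'
candidate at `t_init + tau'` — and divides at the later one (`gate =
"and"`), recording which process was limiting; `emergent_ph()` is the
post-burn-in fraction of H-limited divisions. Because the two candidate
times grow monotonically with size along one cell's trajectory, taking the
later time is equivalent to taking the larger candidate size.

The closed-form relations treat `pH` as a mixing weight independent of the
fluctuations. In the AND gate the limiting indicator co-fluctuates with
initiation size (a larger initiation size delays the C+D' candidate), which
biases the measured `zeta_CD` slightly above the prediction; the bias
scales with the noise variance (about +0.01 in raw slope at 3% CVs, +0.03
at 5%, +0.10 at the realistic unperturbed noise mix). The simulator
therefore also offers `gate = "lottery"`, which draws the limiting process
as an independent Bernoulli(`p_H`) — the coupling scheme for which the
closed forms are exact — and the test suite validates the algebra against
the lottery scheme and the mechanistic behavior against the AND gate.

Other numerical choices: burn-in of 10 generations discarded everywhere;
steady-state-informed initial conditions; an explicit divergence error if
sizes leave `(1e-4, 1e4)` times the natural scale or a threshold becomes
non-positive; simulation time is continuous, with frame discretization
applied only when traces are exported.

## Observables

Lengths (not volumes) are the size proxy throughout: in mother-machine
data, width measurement noise inflates volume uncertainty severalfold,
while length fluctuations track size fluctuations directly.

Statistics are computed on grandmother–mother–cell triplets so that rounds
initiated up to two generations before the division they control live on
one trajectory: the ori-normalized length `L*(t)` is the cell's length, the
mother's length over 2, or the grandmother's length over 4 (exponential
interpolation between recorded birth and division lengths). Added sizes
are `Delta_I = L*(tB_cell) - L*(tB_mother)` between consecutive
initiations, `Delta_CD = L*(td) - L*(tB)` from initiation to division, and
`Ld - L0` over the full cycle. Only cells with at least four recorded
ancestors enter (configurable), and burn-in rows of simulated tables are
excluded.

The optional division-asymmetry correction adds the offset
`L0(child) - Ld(parent)/2 = alpha Ld(parent)/2` to the trajectory at every
crossed division. This additive form makes `L*` exactly continuous across
asymmetric divisions and recovers the generative added sizes of the
asymmetric-division adder recursion; a multiplicative correction (scaling
by the inherited fraction) was rejected during development because it
feeds the measured asymmetry into the regression anchor and biases
`zeta_I` by an errors-in-variables term of order -0.25 at 5% asymmetry.
With symmetric data the correction vanishes identically, and at 5%
asymmetry corrected and uncorrected slopes agree within error — the
justification for keeping the symmetric rule as the default.

Slopes are estimated by iteratively re-weighted least squares with Tukey
bisquare weights (tuning constant 4.685, tolerance 1e-8, at most 50
iterations) via `MASS::rlm`, guarding against occasional gross outliers;
the contamination test in the suite shows 1% gross outliers move the slope
by less than 0.02 (the residual shift comes from the non-robust mean
normalization, not the fit). Single-cell growth rates come from a
log-linear least-squares fit, rejecting cells with fewer than 4 frames,
non-positive rate, or R-squared at or below 0.8.

`literature_adapter()` reconstructs subperiod samples from published
per-cell tables that report newborn/division lengths and a raw per-origin
initiation size whose origin multiplicity is unspecified: a reported value
below the newborn length marks a round spanning the next division (the
full-frame initiation length is twice the report), and the added sizes are
rebuilt with asymmetry-aware `/2` terms. The expected schema is a
documented synthetic stand-in (the original supplementary formats are not
available here); a round-trip test checks that a simulated lineage exported
to this schema reproduces the native added sizes exactly.

## Replication-round detection

The detector consumes per-frame scalar traces: `Itot`, the
median-subtracted summed excess replisome-signal intensity (positive while
a replication round is ongoing), and focus positions `z/L`. Pixel-level
processing is upstream and out of scope.

For each mother–daughter pair, maximal runs with `Itot > 0` lasting at
least 25 min are candidate rounds. Run endpoints are corrected for frame
censoring by half a frame interval at each end: a continuous interval
observed on a grid loses half a frame at each end in expectation, so the
uncorrected duration underestimates C by one full frame interval on
average — with the correction the recovered C and D means are unbiased.
Candidates must start and end within 11 frames of the population-average
initiation and termination times; those averages come from a first pass
over the division-aligned occupancy profile (mother and daughter frames
both aligned to the daughter's division, so rounds initiated in the mother
appear at their true time before division), smoothed with a 3-bin moving
average, taking the latest comparably steep fall and the latest comparably
steep rise preceding it (the profile also contains the mother's own round
one generation earlier; boundary bins are data edges, not inflections).
Among admissible candidates the largest is selected, ties broken toward
the later run; runs truncated at the start of the pair trace have no
observable initiation and are excluded; pairs are processed in division
order and a round already assigned to the mother is not re-assigned to the
daughter (each division consumes one round). A round whose signal reaches
the last observed frame terminates at division (`D = 0`). C is the
corrected run duration and D the lag from corrected termination to
division.

On the unperturbed synthetic condition this recovers the generating mean C
and D within a fraction of a frame interval with a detection rate above
99%; along the in-silico perturbation series the detected D rises while C
stays constant. The real-data caveat that the replisome reporter stays
bound ~5 min after termination (overestimating C, underestimating D by
that amount) applies to the microscopy, not to the synthetic traces, and
is not modeled.

## Synthetic data and the unperturbed preset

`generate_condition()` turns a simulated lineage table into per-frame
traces on the global imaging grid (6- or 8-min intervals): exponential
lengths, `Itot` drawn Gaussian around +A during replication and -A/2
outside (SD 10% of A, so sign flips are vanishingly rare), and two foci
migrating from mid-cell toward the quarter positions as replication
progresses. Replication termination is placed at `t_init + C` with
per-cell log-normal C periods truncated at division.

The unperturbed preset is the package's stand-in for slow growth in
glycerol minimal medium: 6-min frames, 90-min doubling time (growth-rate
CV 0.07), per-origin initiation adder of 1 um (CV 0.15), division
asymmetry 5%, C period 51 min (CV 0.08), and balanced concurrent cycles.
Because the emergent D period exceeds the timer margin `tau' - C` by the
expected positive part of the candidate-time difference, `tau' = 67.0 min`
and `dH = 1.59 um` were calibrated once (and frozen) so that the emergent
mean C and D equal the measured 51 and 22 min with `pH` near 0.5. The
noise split between the initiation adder and the two division processes
(0.15 vs 0.10) was likewise fixed so that the initiation/birth variance
ratio and the near-adder inter-division slope resemble the measured
inputs; the noise CVs are not printed in the source experiments and are
calibration choices exposed in the preset.

The width-perturbation series (`generate_a22_series()`) holds the C
period, the replication/segregation timer and the initiation adder fixed —
the experimental observation is that these are unperturbed — and raises
only the mean inter-division added size `dH` (1.59 to 2.07 um by default),
which makes the H process increasingly limiting. The longer D period is
then an *emergent consequence*, exactly the causal pathway the concurrent
model assigns to the width perturbation; varying the timer duration
instead would lengthen D while making replication *more* limiting,
contradicting every observed correlation trend. Width itself is not
modeled. The default series spans detected D of roughly 22 to 45 min, a
scaled-down version of the experimental 22-60 min range: beyond it the
condition leaves the non-overlapping regime (`C+D > tau`) that both the
analytic theory and the detector's supported regime assume.

What the generator does *not* emulate: cell width and volume (lengths
only), pixel images and spot calling, measurement noise on lengths,
reporter-unbinding delays, filamentation, and overlapping replication
rounds (`n > 2`). Passing tests therefore show the pipeline is correct and
well-calibrated on data with the assumed statistical structure, not that
the biological conclusions hold on real images.

## Problem sizes and reproducibility

All randomness flows from explicit integer seeds in parameter objects and
presets; identical seeds give byte-identical outputs. The test suite and
the acceptance script use 10^4-cell simulations for theory-vs-simulation
checks, a 1200-cell unperturbed condition for the detection recovery
checks, and five 5000-cell conditions for the perturbation series; these
sizes put Monte-Carlo errors on slopes near 0.01-0.03, well below the
effects being tested, while keeping a full run in minutes on one CPU.
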