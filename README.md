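# concycle

Tools for analysing bacterial cell-division control from single-cell
mother-machine lineages, built around the question of what limits cell
division in slow-growing *E. coli*: chromosome replication/segregation, a
replication-independent inter-division process, or — as the
concurrent-cycles model proposes — whichever of the two finishes last in
each cell.

The package is aimed at quantitative microbiologists and modellers working
with single-cell lineage data (birth/division times and lengths, parent
links, per-frame replisome-reporter traces). It provides:

* the **adder coupling-constant formalism**: conversions between adder-plot
  slopes ζ and size-growth slopes λ, `ζ = (1 − λ)Q − 1`, with subperiod
  growth factors `Q = exp⟨log(final/initial)⟩`;
* **closed-form correlation predictions** for replication-limited (ICD)
  models, the double-adder special case, and the concurrent-cycles model,
  e.g. the adder-adder scheme

      ζ_CD + 1 = (1 − pH) Q_CD′ / (1 − pH/4)

  which interpolates ζ_CD from `Q_CD′ − 1` (replication always limiting)
  to −1 (never limiting) as the limiting probability pH rises;
* **stochastic lineage simulators** for all model families (per-origin
  inter-initiation adder, log-normal added sizes, Gaussian division
  asymmetry, AND-gate or effective "lottery" coupling of the two division
  processes);
* the **observables pipeline**: ori-normalized lengths on
  grandmother–mother–cell triplets, added sizes over the G, I and C+D
  subperiods (with optional division-asymmetry correction), growth rates,
  and robust (IRLS/bisquare) adder-plot slopes;
* **replication-round detection** on per-frame scalar traces (median-
  subtracted summed replisome intensity), recovering per-cell C and D
  periods, plus division-aligned replisome-position density maps;
* **pH fitting** from measured slopes (closed-form inversion, or a joint
  weighted fit of pH and ζ_H);
* a **synthetic data generator** with a calibrated unperturbed preset
  (6-min frames, C = 51 min, D = 22 min, 5% division asymmetry, balanced
  concurrent cycles) and an in-silico analogue of the A22
  width-perturbation series.

## Worked example

Generate the unperturbed synthetic condition, detect replication rounds
from the traces, and estimate slopes and pH:

```r
library(concycle)

preset <- unperturbed_preset(seed = 1, n_lineages = 40, n_generations = 30)
cond   <- generate_condition(preset)      # 1200 cells + per-frame traces
report <- analyse_condition(cond)
```

Running this (it is `analysis/03_unperturbed_pipeline.R`) prints:

```
cells analysed: 1200  (detection rate 0.999)
detected C period: 51.0 min   detected D period: 21.7 min
zeta_G = +0.026 +/- 0.036   zeta_I = +0.068 +/- 0.051   zeta_CD = +0.128 +/- 0.038
fitted pH (fixed zeta_H = 0): 0.443 +/- 0.022
```

The detector recovers the generating C and D periods (51 and 22 min) to
within a fraction of a frame interval; the inter-division and
inter-initiation processes behave as adders (slopes near 0); and the
fitted limiting probability is close to one half — the balanced regime in
which replication and the inter-division process are about equally likely
to set the timing of division.

The numbered scripts under `analysis/` walk through the full study:
analytic model predictions (`01`), simulator-versus-theory checks (`02`),
the unperturbed pipeline above (`03`), the width-perturbation series in
which only the inter-division increment grows — the D period lengthens at
constant C, ζ_CD falls monotonically from +0.10 toward −1, and pH rises
from 0.46 to 0.84 (`04`) — and the pH fits under both fitting strategies
(`05`). Each writes its table under `results/`.

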