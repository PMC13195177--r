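# ofvplan

Objective-function-value (OFV) feedback control of automated VMAT
inverse planning, reimplemented end-to-end on synthetic 2-D thoracic
phantoms.

In clinical automated breast planning, a script can steer the optimizer
by reading, after each optimization pass, the *objective function value*
of every organ-at-risk (OAR) term and tightening or relaxing that
organ's MaxEUD constraint (an upper limit on its generalized equivalent
uniform dose) accordingly. `ofvplan` reproduces this closed-loop
mechanism at desk scale:

1. **Phase 1** — optimize with every OAR MaxEUD limit set to the
   prescription (50 Gy): all OAR terms are inactive and the plan shows
   what coverage alone can achieve.
2. **Phase 2** — set each OAR's MaxEUD limit to a fixed fraction of its
   Phase-1 mean dose: 50 % for *class-1* organs (contralateral lung,
   contralateral breast), 20 % for *class-2* organs (ipsilateral lung,
   heart).
3. **Phase 3** — iterate: optimize, read each OAR's OFV, form the
   multiplier `s = m·OFV + n`, and update `MaxEUD ← s·MaxEUD` (clamped).
   Class 1 uses `s = 0.44·OFV + 0.8`, class 2 uses `s = 0.089·OFV + 0.8`,
   so the limits stop moving exactly at the *target OFVs* 0.45 and 2.25
   — the laws' fixed points `(1 − n)/m`. The loop ends when every
   class-2 organ holds `|s − 1| ≤ 0.005` on two consecutive loops
   (*saturation*) or after 12 loops, and a PTV-coverage repair pass runs
   if the target's V95 % dropped below 95 %.

The target OFVs themselves are calibrated by a *sensitivity analysis*:
one organ's limit is driven down a fixed schedule, six plan metrics are
tracked, smoothed, and differenced, and an aggregate score `S(j)` over
clinically critical steps marks the OFV beyond which further sparing
costs more than it helps.

Everything runs on seeded synthetic phantoms (a 128×128 axial slice with
breast PTV, heart, lungs, contralateral breast), a coplanar-arc
pencil-beam influence matrix with a two-Gaussian lateral kernel, and a
projected-gradient inner optimizer with Barzilai–Borwein steps — no
external planning system required, fully deterministic per seed.

## Quick start

```r
library(ofvplan)

phantom  <- generate_phantom(phantom_config(laterality = "left"), seed = 1)
phantom
#> Synthetic thoracic phantom (left-sided, seed 1)
#>   grid: 128 x 128 voxels @ 3 mm, slice 3 mm
#>   PTV                23.2 cm^3 (859 voxels)
#>   heart              11.9 cm^3 (442 voxels)
#>   lung_ipsi          26.7 cm^3 (988 voxels)
#>   lung_contra        33.3 cm^3 (1234 voxels)
#>   breast_contra      22.1 cm^3 (819 voxels)
#>   external          172.3 cm^3 (6380 voxels)

beamset   <- build_beamset(phantom)           # left arc, 180 -> 288 deg
influence <- compute_influence(phantom, beamset)
influence
#> Influence matrix: 16384 voxels x 672 beamlets, 2331002 nonzeros

run <- run_controller(phantom, beamset, controller_config(),
                      influence = influence, verbose = TRUE)
#> loop  1 [phase1]  total=0.1333  V95=100.0%  OFV: lung_ipsi=0 heart=0 lung_contra=0 breast_contra=0
#> loop  2 [phase2]  total=4.42  V95=93.6%  OFV: lung_ipsi=1.01 heart=0 lung_contra=0 breast_contra=1.09
#> loop  3 [phase3]  total=2.575  V95=96.4%  OFV: lung_ipsi=0.754 heart=0 lung_contra=0.0313 breast_contra=0.253
#> ...
#> loop 12 [phase3]  total=11.64  V95=93.1%  OFV: lung_ipsi=1.58 heart=1.83 lung_contra=0.548 breast_contra=0.507
#> coverage repair: V95 93.13% -> 93.13%

run
#> OFV-feedback run: 12 outer loops, stopped at max loops
#>   final PTV V95 = 93.13%, total objective = 11.64

evaluate_goals(run$plan)
#>      structure metric comparator limit value  pass
#>      lung_ipsi   mean          <  10.0  3.88  TRUE
#>      lung_ipsi  V10Gy          <  35.0 13.66  TRUE
#>      lung_ipsi  V20Gy          <  20.0  6.88  TRUE
#>    lung_contra   mean          <   2.0  1.15  TRUE
#>          heart   mean         <=   2.5  1.24  TRUE
#>  breast_contra   mean         <=   2.0 10.39 FALSE
```

The run takes ~10 s. Note the controller's effect: the ipsilateral lung
mean falls from 29.8 Gy (Phase 1, no sparing) to 3.9 Gy, the heart from
24.5 Gy to 1.2 Gy, while both class-2 OFVs climb toward the 2.25 target.

One call does phantom → plan → artifacts:

```r
run_pipeline(list(seed = 7, laterality = "left"), output_dir = "run7")
# writes phantom.ctr.json, trajectory.csv, dvh.csv, report.json, summary.txt
```

Sensitivity-based tuning-point calibration:

```r
trace <- run_schedule(phantom, beamset, sensitivity_config(),
                      influence = influence)
sm <- smooth_trace(trace, 3)
sc <- sensitivity_score(change_rates(sm),
                        criticality_masks(sm, change_rates(sm)), trace = sm)
sc
#> Sensitivity score: j* = 8, OFV at j* = 4.663
```

## Command line

A thin CLI wraps the exported functions (installed under
`inst/cli/ofvplan.R`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/ofvplan.R", package="ofvplan"))')" \
    phantom generate --laterality left --seed 7 --out phantom.ctr
# plan run --phantom phantom.ctr --config run.yaml --out plan_dir/
# tune sensitivity --phantoms 3 --seed 1 --config tune.yaml --out tune_dir/
# report metrics --plan plan_dir/ --out report.json
```

## Package layout

| Module | File | Contents |
|---|---|---|
| phantom | `R/phantom.R` | seeded 2-D thoracic phantom generator |
| beams | `R/beams.R` | arc geometry, pencil-beam influence matrix |
| dose objectives | `R/objectives.R` | gEUD, uniform/MaxEUD/min/max-dose terms, gradients |
| optimizer | `R/optimizer.R` | projected gradient descent with BB steps |
| controller | `R/controller.R` | phased OFV-feedback loop, repair, threshold sweep |
| sensitivity | `R/sensitivity.R` | schedule, smoothing, criticality masks, S(j) |
| metrics | `R/metrics.R` | DVH, V/D queries, Paddick CI, HI, clinical goals |
| cli/io | `R/io.R`, `inst/cli/ofvplan.R` | YAML config, serialization, pipeline, CLI |
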