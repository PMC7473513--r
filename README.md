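# escrtkinetics

Quantitative kinetics of ESCRT recruitment at HIV Gag VLP budding
sites, from high-speed TIRF movies.

During HIV budding, the ESCRT machinery — the adaptor ALIX, the
ESCRT-III subunit CHMP4b, and the AAA-ATPase VPS4 — is recruited to the
budding site for about a minute and then disassembles in a
characteristic order: the early factors (ALIX/CHMP4b) leave first while
the VPS4 platform persists for ~15 s before departing. ATP depletion
blocks the disassembly, locking roughly twice the usual amount of ESCRT
on each site. This package is for microscopists and image analysts who
want to quantify that behaviour from multi-channel TIRF time series
(or to validate such an analysis end to end on synthetic data):

* **Spot detection** on the Gag reference frames (difference of
  Gaussians, subpixel centroids) and stationary-site matching between
  the start and end of the record.
* **Aperture photometry** with local-annulus background correction and
  cohort **normalization** of mean per-event maxima to 10000 a.u.
* **Kinetic fitting** of the Boltzmann growth equation
  `I(t) = A1 + (A2 - A1) / (1 + exp(-(t - t0)/dx))` to the assembly and
  disassembly phases, after three-phase segmentation. Rates are the
  maximum slope `(A2 - A1)/(4 dx)` (a.u./s), the total assembly time is
  the 10–90% rise time `ln(81) dx`, and the retention time is the gap
  between the fitted 90% crossings of the two sigmoids.
* **Phenotyping**: major (delayed late channel) vs minor
  (co-disassembly) vs locked, plus WT vs ATP-depleted fold-change
  comparison with a bootstrap interval.
* A **synthetic TIRF movie generator** (seeded, deterministic) that
  renders Gaussian spots with three-phase kinetics, Poisson + read
  noise, and writes multi-page 16-bit TIFFs — the ground-truth oracle
  for every stage.

## Worked example

Simulate a 10-event wild-type cohort, render it as a three-channel
movie, and run the full pipeline:

```r
library(escrtkinetics)
cfg <- sim_config(n_events = 10)              # 300 frames @ 0.2 s, 80/20 mixture
co  <- simulate_cohort(cfg, seed = 7)         # ground-truth kinetics
mv  <- render_movie(co, cfg, seed = 8)        # noisy TIRF stacks + truth table
res <- run_pipeline(pipeline_config(channels = mv$channels, dt = cfg$dt))
res$summary
```

```
<CohortSummary> 10 events (10 classified, 0 unclassifiable)
  phenotypes: delayed_late_channel 80%, co_disassembly 20%, locked 0%
  early: r_a 1.12e+03 +/- 393, r_d 1.99e+03 +/- 556 a.u./s; tau 9.83 +/- 3.33 s; T_a 11.1 +/- 3.62 s (n=8)
  late: r_a 624 +/- 230, r_d 1.72e+03 +/- 580 a.u./s; tau 14 +/- 2.96 s; T_a 18.9 +/- 6.93 s (n=8)
```

Reading this: all 10 simulated VLP sites were detected, extracted and
classified; 80% show the major phenotype (late channel persists). The
late (VPS4) channel retains its plateau for ~14 s on average (generator
mean: 15 s) and assembles more slowly than the early channel (larger
T_a, smaller rate), as constructed. Rates are in normalized a.u./s
(the cohort scale factor is `res$scale`).

Condition comparison with a shared normalization scale:

```r
dp_cfg <- sim_config(n_events = 10, condition = "ATP_depleted")
dp_mv  <- render_movie(simulate_cohort(dp_cfg, seed = 9), dp_cfg, seed = 10)
dp     <- run_pipeline(pipeline_config(channels = dp_mv$channels,
                                       dt = dp_cfg$dt, scale = res$scale,
                                       condition = "ATP_depleted"))
compare_conditions(res$phenotypes, dp$phenotypes)$fold_change  # ~2
```

## Command line

```sh
escrt-kinetics simulate --n-events 40 --seed 1 --out simdir
escrt-kinetics run --gag simdir/gag.tif --early simdir/early.tif \
    --late simdir/late.tif --out results
```

(the launcher script lives in `inst/cli/`; exit codes: 0 success,
2 validation error, 3 stage failure).

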