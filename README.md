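# chromkin

Quantitative analysis of **sister-chromatid resolution and chromosome
compaction kinetics** from live-cell tracking of two fluorescently marked
chromosome loci (tetO/lacO operator arrays visualised as red/green dots).

Audience: groups doing locus-tracking microscopy of mitotic entry who need
to (i) turn per-minute 3D dot centroids into chromosome-configuration
states, (ii) estimate *when* resolution and compaction start and *how
fast* they proceed, and (iii) validate the whole analysis on synthetic
data with known ground truth.

## The model

A marked region progresses through three states,

```
nonresolved  --(after licensing 1, rate r1)-->  resolved
resolved     --(after licensing 2, rate r2)-->  compacted
```

on a 1-min grid from −140 to +90 min around nuclear envelope breakdown
(NEBD, t = 0). Licensing 1 occurs at `t1 = −Exp(τ1)` (at or before NEBD);
licensing 2 at `t2 = t1 + Exp(τ2)`. Once licensed, each transition fires
per step with probability `p = 1 − exp(−r·Δt)`; compaction additionally
requires resolution to have happened. Four parameters — τ1, τ2 (min) and
r1, r2 (min⁻¹) — are reported as **ST = τ1·ln2** (median start of
resolution licensing before NEBD), **TD = τ2·ln2** (median delay of
compaction licensing), rate half-lives ln2/r and per-step probabilities.

Fitting minimises the sum of squared differences between simulated
(m = 10,000 cells, common random numbers) and observed state proportions
over −50..+30 min (BFGS on log parameters); uncertainty comes from
bootstrapping time points (default B = 300) with medians and 1.5·IQR box
summaries.

The classifier applies the assay's rules to z-corrected 3D centroids
(0.75 µm z-step × 0.85 refractive scaling): sister doublets separated
beyond 0.85 µm, tetO–lacO colocalization within a 0.4 µm radius, the
five-state blue/brown/pink/red/black vocabulary, NEBD alignment, 9-min
rolling-mean display smoothing, phase windows, chi-square comparisons and
the tetO/lacO separation-asymmetry statistic.

## Worked example

```r
library(chromkin)

## derived quantities at the wild-type fit values
derived_quantities(model_params(tau1 = 18.0, tau2 = 9.3,
                                r1 = 0.065, r2 = 0.12))
#> $ST            12.47655   # min before NEBD (prints as 12.5)
#> $TD            6.446302   # min
#> $r1_half_life  10.66380   # min (prints as 10.7)
#> $r2_half_life  5.776227
#> $p1_step       0.0629319  # per 1-min step (prints as 0.063)
#> $p2_step       0.1130796

## synthetic cohort -> classification -> proportions -> fit -> bootstrap
cfg <- synth_config()                    # 40 cells, WT-like parameters
tr <- generate_truth(cfg, seed = 1)
coords <- render_coordinates(tr, seed = 2)
states <- classify_cells(coords, tr$meta, cfg$classifier)
obs <- to_model_proportions(proportions_over_time(states))

fc <- fit_config()
boot <- bootstrap_fit(obs, fc, B = 50, seed = 1)
boot
#> bootstrap over 50 repetitions (0 skipped)
#> medians:
#>    tau1    tau2      r1      r2
#> 19.8910 10.1286  0.0615  0.1160
```

The bootstrap medians recover the generating values (τ1 = 18, r1 = 0.065)
to within ~10% and ~5% here; ST follows as `19.89 × ln2 ≈ 13.8` min before
NEBD. A cohort of 40 cells carries real sampling noise — independent
cohorts scatter the recovered τ1 by roughly ±15%.

A thin CLI over the same functions ships in `inst/cli/chromkin.R`
(`synth`, `classify`, `simulate`, `fit`, `bootstrap`, `report`
subcommands).

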