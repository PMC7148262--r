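# trialkit

A headless, engine-agnostic R implementation of the experiment-management
core behind computer-based human-behavior studies: the
**session–block–trial** model with automatic numbering and lifecycle
events, **cascading settings** (trial → block → session → JSON profile),
**behavioral** (one CSV row per trial) and **continuous** (per-trial
time-series CSV) data output in an `experiment > participant > session`
directory layout, a **deferred write queue** that guarantees durability at
session end, and a **participant demographics registry**. It is aimed at
behavioral and movement scientists who want the bookkeeping of an
experiment — numbering, timestamps, independent variables, data files — as
tested library code, with stimulus presentation left entirely to the host
application or simulation.

The package demonstrates itself end to end with a synthetic replication of
the classic *swinging-room* posture paradigm: a virtual room pitches
sinusoidally about the floor axis (default amplitude 5°, frequency
0.25 Hz) while the head of a simulated participant is tracked at 90 Hz for
two 10-s trials (static vs. oscillating room). Postural stability is
indexed by the **path length** of the head,

    L = Σᵢ ‖p(i+1) − p(i)‖₂   (meters; larger = more sway),

computed per trial from the tracked positions. Cohorts of synthetic adults
and children are generated by an explicitly invented mean-reverting
random-walk sway model with a visual-coupling term (see the methods
vignette in `vignettes/experiment-engine.Rmd`).

## Worked example

The bundled two-block doubling task (see a number *x*, answer *2x*) runs
the whole stack — session, blocks, cascade-resolved manipulation flag,
per-trial stimulus settings, results, behavioral CSV:

```r
library(trialkit)
demo <- doubling_demo(base_dir = tempfile())
demo$table
#>    experiment ppid session_num trial_num block_num start_time end_time manipulation  x response
#> 1    doubling  P01           1         1         1          0        1        false  8       16
#> 2    doubling  P01           1         2         1          1        2        false  3        6
#> ...
#> 6    doubling  P01           1         6         2          5        6         true  9       18
#> ...
#> 10   doubling  P01           1        10         2          9       10         true  3        6
```

Trial numbers run globally across both blocks; `manipulation` flips to
`true` on block 2 through a single block-level setting (no per-trial
storage); `response` is the scripted participant's `2x`.

The synthetic cohort study:

```r
res <- run_study(n_adults = 50, n_children = 50, base_dir = "data", master_seed = 1)
aggregate(path_length_m ~ group, res, mean)
#>   group path_length_m
#> 1 adult      1.153680
#> 2 child      2.310272
aggregate(path_length_m ~ condition, res, mean)
#>     condition path_length_m
#> 1      normal      1.731200
#> 2 oscillating      1.732752
```

Children (double sway noise) show roughly twice the adult path length, and
the oscillating room adds about 2 mm per 10-s trial — both directions are
built into the generator; the magnitudes are simulation outputs, not
human data. Each participant leaves a complete session directory
(`trial_results.csv`, `head_T001.csv`/`head_T002.csv`, `log.txt`) plus a
row in `participant_list.csv`, and the whole study is a pure function of
`master_seed`.

A small CLI wraps the same functions (`inst/cli/trialkit`):

```sh
trialkit demo-doubling --ppid P01 --out data --demo age=27
trialkit swingroom --n-adults 50 --n-children 50 --seed 7 --out data
trialkit validate --dir data/doubling/P01/S001
```

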