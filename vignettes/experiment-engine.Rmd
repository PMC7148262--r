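---
title: "The trialkit experiment engine: model, data contracts, and the swinging-room simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The trialkit experiment engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialkit)
```

## The session--block--trial model

Most computer-based behavioral experiments share one structure: a *trial* is
a single stimulus--response unit; a *block* groups consecutive trials that
share a manipulation; a *session* is one complete run of the task by one
participant. trialkit represents these as mutable objects with reference
semantics (environments), because an experiment in progress *is* mutable
state: trials begin, accumulate observations, and end.

Numbering is never assigned by the user. Blocks are numbered 1, 2, ... in
creation order and trial numbers are **session-global**: block 2's first
trial continues the count where block 1 stopped. A session-global
`trial_num` is what lets every output artifact -- behavioral rows,
per-trial continuous files -- join on a single integer key. Blocks and
trials can be created in batches (`create_block(session, n_trials = 10)`)
or one at a time (`create_trial(block)`), so adaptive and staircase designs
that decide the next trial from the last response are expressible without
special support.

### Lifecycle and timestamps

A trial moves `not_started` → `in_progress` → `done`, each transition at
most once; a session moves `created` → `in_progress` (when its first trial
begins) → `ended`. Begin and end record timestamps in **seconds since the
session began**, read from an injectable monotonic clock and serialized
with 3 decimal places (millisecond resolution, ample for trial-level
timing; continuous data carry their own higher-resolution time column).
The default clock reads process elapsed time; simulations inject
`sim_clock()` and advance it explicitly, which is how the worked examples
get exactly contiguous trials (trial *k* starts where *k − 1* ended --- a
pattern we reproduce but deliberately do not enforce, since real tasks have
inter-trial gaps).

Results (`add_result()`) are accepted while a trial is in progress *and*
after it is done --- post-hoc scoring of a finished trial is routine --- and
rejected only before it begins. Re-adding a name overwrites; the column set
of the behavioral table is the union of names over trials, in first-seen
order, with blank cells where a trial never set a name.

Four *events* --- `session_begin`, `trial_begin`, `trial_end`,
`session_end` --- accept ordered lists of hooks, the mechanism by which
task code attaches stimulus presentation or response collection to the
lifecycle. A hook exception is caught and written to the session log rather
than propagated: a bug in a cosmetic hook must not destroy a participant's
session.

## The settings cascade

Settings are the independent variables. A key can be stored at trial,
block, or session level (and in an optional profile above the session);
resolution searches upward from the requesting level and returns the first
hit. The idiom this buys is "gross" storage with "fine" overrides: store
`stimulus = "standard"` once on the session, then override ten of a
hundred trials with `stimulus = "deviant"`, and every trial resolves the
right value with no per-trial bookkeeping for the other ninety.

Three policies worth stating:

* **A missing key raises** (with the key name and the levels searched)
  rather than returning `NULL`. A typo in a setting name should stop the
  experiment at the first lookup, not silently run 200 trials with a
  default.
* **Profiles populate the session level only.** A profile is a JSON object
  of session parameters selected by name at launch; values set
  programmatically on the session shadow it. Per-block or per-trial
  profile targeting was considered and rejected: it would couple the
  profile format to a particular block structure, and the programmatic API
  already covers it.
* Keys are case-sensitive exact strings; values must be JSON-compatible
  (atomic vectors, `NULL`, nested lists), so any session can be described
  by a plain-text document.

The profile `source` is injectable --- a function returning JSON text is
accepted wherever a file path is --- which is the seam for fetching
settings from a remote URL without any network code in the core.

## Data output and the deferred write queue

All files of a session live under `base_dir/experiment/ppid/S<nnn>`:

* `trial_results.csv` --- one row per **begun** trial: identity columns,
  numbering, timestamps, then registered settings-of-record and results.
* `<tracker>_T<nnn>.csv` --- one continuous file per tracker per trial.
* `log.txt` --- timestamped lifecycle events and hook failures.
* `participant_list.csv` (at the top of `base_dir`) --- the demographics
  registry, one row per ppid, columns the union of all fields ever
  recorded, updatable as measurements arrive mid-task.

The CSV dialect is fixed: comma delimiter, `.` decimal point, LF line
endings, header always present, minimal quoting, logicals as lower-case
`true`/`false`, times with 3 decimals. A ppid/session-number collision is
refused unless `overwrite = TRUE` --- collected data are the one thing the
engine must never silently destroy.

Writes are *deferred*: producing data enqueues a task (destination +
lines + optional post-write hooks) in FIFO order and performs no I/O;
`drain()` --- called automatically by `end_session()` --- writes everything
and returns only when the queue is empty. In the original VR setting the
motivation is keeping file I/O off a 90 Hz frame loop; here the queue is a
single-threaded deferral with the same observable contract: enqueue never
blocks on disk, per-destination order equals enqueue order, and after
`end_session()` returns every file is durably present. A failed write is
recorded per task and reported at drain; it never raises into task code
mid-session. Post-write hooks (fired once, only after a successful write,
with the written path) are the extension point for shipping files to
remote storage.

## Continuous tracking

A tracker logs time-varying quantities within each trial: a header
(`time` first), a per-trial buffer, and a flush to
`<name>_T<nnn>.csv` when the trial ends. The canonical tracker is the
six-channel pose tracker (`pos_x, pos_y, pos_z` in meters --- x lateral,
y up, z anterior--posterior --- and `rot_x, rot_y, rot_z` Euler degrees),
but any field set works (a one-channel pressure pad, say). Times are
trial-relative and must strictly increase; a non-increasing sample is
rejected as a row error, not silently reordered. The library never owns a
frame loop: an external clock --- real or simulated --- drives `record()`.
No interpolation, resampling, or filtering is applied; files contain
exactly what was recorded.

## The swinging-room case study

The classic moving-room paradigm isolates vision's contribution to posture:
the visual surround (walls and ceiling) oscillates while the floor --- and
with it the kinesthetic information --- stays fixed. Sway is quantified by
the **path length** of the head,

$$ L = \sum_{i=1}^{n-1} \lVert p_{i+1} - p_i \rVert_2 , $$

the sum of point-to-point distances over a trial's position samples (larger
= more sway = worse postural stability). The room pitches about the x-axis
through the floor-center point as $\theta(t) = A \sin(2\pi f t)$ with
amplitude $A = 5°$ and frequency $f = 0.25$ Hz by default, in a 3 m × 6 m ×
6 m room; trials last 10 s, logged at 90 Hz (an HMD refresh rate), so a
trial is exactly 900 samples.

### The synthetic sway model

Human participants are replaced by an *explicitly invented* head-sway
model --- the package simulates the study design, not the physiology.
Per axis, the head position follows a mean-reverting random walk with a
visual-coupling drive on the anterior--posterior axis:

$$ p_{i+1} = p_i + \lambda\,(r - p_i) + \eta_i + c\,\bigl(\theta_{i+1} - \theta_i\bigr)\,\hat z $$

| parameter | meaning | default |
|---|---|---|
| `noise_sd_m` | per-tick Gaussian sway noise, per axis | 0.8 mm (adult), 1.6 mm (child) |
| `mean_reversion` ($\lambda$) | per-tick pull toward rest posture | 0.02 |
| `coupling_m_per_deg` ($c$) | head displacement per degree of room-pitch change | 2 mm/deg |
| `rest_height_m` ($r_y$) | rest head height | 1.6 m (typical adult eye height; irrelevant to path length) |

The defaults are frankly arbitrary: they encode the two qualitative facts
the paradigm is known for --- children sway more than adults, and an
oscillating room adds sway --- at magnitudes where both directions are
decisively detectable in a 50-per-group cohort. Doubling the child noise
roughly doubles the child path length (~2.3 m vs ~1.15 m per 10-s trial),
a far larger separation than the coupling effect (~+2 mm per trial).

The recurrence is computed per axis with a first-order recursive filter
(`stats::filter(..., method = "recursive")`), which is the same AR(1)
update evaluated in compiled code; a test verifies bitwise-level agreement
(1e−12) with the naive step-by-step loop.

### Study design and randomness

`run_study()` gives each synthetic participant one full session --- two
trials, *normal* (static room) and *oscillating*, in randomized order, the
condition stored as a trial setting, the head pose recorded through a real
tracker at 90 Hz, the path length added as a behavioral result --- and
writes ordinary session directories plus a tidy `study_results.csv`.

Randomness derives entirely from one `master_seed` through per-participant
substreams, so the study is bit-reproducible and participant *i*'s data are
stable when the cohort grows. Within a participant, **both conditions reuse
the same noise substream** (common random numbers). This models a stable
individual sway trait and makes the condition contrast paired, exactly as
the within-participant design intends: with independent noise per trial the
~2 mm coupling effect would drown in between-trial noise at n = 50/group
(standard error ≈ 2.2 mm), whereas the paired contrast has a standard error
of ≈ 0.15 mm. It also yields a clean falsifiable invariant: with coupling
zero, the two conditions produce *identical* traces at matched seeds.

What the generator emulates: the design (groups, conditions, order
randomization, durations, sampling rate), the logging pipeline, and the
direction of both effects. What it does not: postural biomechanics, the
frequency structure of human sway, HMD tracking noise, or the original
effect sizes --- passing tests on synthetic cohorts demonstrates the
*engine and analysis pipeline*, and says nothing quantitative about real
posture. Group-level inferential statistics on synthetic data are
deliberately limited to descriptive means.

### The doubling demonstration

`doubling_demo()` is the minimal end-to-end exercise: ten trials in two
blocks, a session-level `manipulation = FALSE` overridden to `TRUE` at
block 2 (cascade, not per-trial storage), the stimulus `x` as a per-trial
setting, and a scripted responder answering `2x`. Its behavioral file shows
every output contract at a glance --- global trial numbering across blocks,
contiguous simulated timestamps, the cascade-resolved flag, and the
stimulus/response columns.

## Numerical and degenerate-input choices

* Empty blocks are legal and consume a block number without touching trial
  numbering; empty tracker buffers flush a header-only file; a session with
  no begun trials writes a header-only behavioral table.
* `path_length` of a single sample is 0; of an empty input, an error.
* Seeds derived from a master seed use fixed affine strides modulo
  2^31 − 1, keeping every derived seed a valid 32-bit value.
* Simulated trajectories start exactly at rest; sample *i* sits at time
  $(i-1)/\text{rate}$, so a duration × rate product must be integral.
* The spectral check uses the raw FFT magnitude with the DC bin excluded;
  on a 40-s, 90 Hz trace the 0.25 Hz drive falls exactly on bin 10, so the
  peak location is exact, not approximate.

## Problem sizes

The shipped tests run the full cohort (50 + 50 participants, two 10-s
trials at 90 Hz each, ~10 s of compute), a 1,000-task write-queue stress,
200-seed Monte-Carlo checks of the noise-monotonicity property (on 2-s
trials), and property sweeps over random chains and operation sequences;
these sizes were chosen to exercise every contract at the study's native
scale while keeping a full run comfortably interactive.

## Known limitations

* The queue defers writes but runs on the caller's thread; a crash between
  enqueue and drain loses buffered (not yet drained) data, which is why
  `end_session()` drains before returning.
* The participant registry is a single CSV rewritten on each upsert ---
  right for hundreds of participants, wrong for millions.
* `validate_session()` checks schema invariants, not scientific
  plausibility.
* The sway model is a design stand-in; do not fit it to real data.
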