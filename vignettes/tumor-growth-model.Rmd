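---
title: "A stochastic cell-based model of tumor growth and intravasation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic cell-based model of tumor growth and intravasation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intravasim)
```

## The model

`intravasim` simulates a two-dimensional section of vascularized tissue in
which breast-cancer-like cells migrate, divide, fall quiescent, die, or
enter the bloodstream. Cells are circular agents of diameter `d_cell` in
continuous space with discrete time steps `dt`; the domain is a square of
side `L` with periodic boundaries. A lattice of squares of side `d_cell`
overlays the field and carries three kinds of information: *lumen* squares
(cross-sections of blood vessels running perpendicular to the section,
impenetrable to cells), *nourished* squares (every square whose center
lies within `nourished_radius` of a lumen square under the periodic
metric), and the occupancy index used for neighborhood queries.

**Migration** is a discretized persistent random walk. A cell's step
length is a speed sampled from its phenotype's profile times `dt`. Eight
discrete headings at 45° spacing are available; with probability equal to
the cell's persistence ratio the candidate headings are the *forward* set
of the previous heading (angular difference at most 90° inclusive — five
headings), otherwise the *backward* set (the remaining three). Candidates
whose destination would overlap another cell (center distance below
`d_cell`, destination checked only — cells may cross occupied ground
mid-step), or would land in a lumen square, are discarded. If the cell
currently sits in a nourished zone, one *zone-exit* draw per step decides
(with acceptance probability `p_exit_nourished`) whether candidates that
leave the zone remain admissible; this is what holds cells near vessels.
One surviving candidate is chosen uniformly; if none survive the cell
stays and keeps its heading.

**Division** is driven by the proliferation score
$$PS = T + D + V,$$
where $T$ is the time since the cell's last division (hours),
$D = \Delta_D\,(8 - n)/8$ is a crowding bonus that vanishes as the Moore
neighborhood fills ($n$ = number of the 8 surrounding lattice squares
holding a cell center), and $V = \tau\,(1 - 1/(1+a))$ is the vessel bonus
for cells inside a nourished zone, chosen so that the effective cycle
length there is $\tau/(1+a)$ with $a$ = `nourished_advantage` = 0.30 (a
30% higher proliferation *rate*, not a 30% shorter cycle). The per-step
division probability is `p_div_high` when $PS \ge \tau$ — or when the
cell has accumulated the G1-phase length `t_G1` of nourished residence
since its last division (the G1 fast track; the clock tolerates brief
exits and resets on division) — and `p_div_low` otherwise. A fully
enclosed cell ($n = 8$) cannot divide at all. On success the second
daughter occupies a free Moore spot of the mother (axial offsets at
distance `d_cell`, diagonal at $\sqrt2\,d_\text{cell}$), selected by the
same forward/backward rule applied to the mother's heading; if the
selected half has no free spot any free spot is used, and with no free
spot the division *fails without resetting* $T$ — the mechanism that
turns persistent crowding into necrosis. Each newborn cell draws its
phenotype from the population mixture fractions (every cell in the tumor
has its own chance of developing the low-Giantin phenotype) and, within
the phenotype, a migratory group from the group abundances.

**Fate.** A cell that has not divided for `n_s` cell cycles is
*quiescent* (it stays in the field and can re-enter the cycle); at `n_n`
cycles ($n_s < n_n$, default 2 and 3) it is *necrotic* and removed.

**Intravasation.** A cell is *in contact* with a vessel when its square
is Moore-adjacent to a lumen square. In the default `contact_mode =
"resident"`, every step spent in contact draws once against
$p_\text{intr} \times \text{fold}$, where `p_intr` = 1e-4 is the baseline
per-contact probability (the 1:10,000 chance estimated from circulating
tumor cell abundance) and `fold` is the phenotype's intravasation
multiplier. The alternative `contact_mode = "move"` draws only when a
move lands in a contact square; it is retained because the two readings
of "intravasate when they get in contact" differ, but residence-based
contact is the default — a cell pressed against a vessel wall remains in
contact — and it is the only reading that produces intravasated counts
of the observed order (tens per thousand cells) at the anchored `p_intr`.

**Stochastic events** all follow one contract: a uniform number on
(0, 1] is drawn and the event fires iff it is at most the parameter value,
so probability 0 never fires and 1 always does. Seven named
xoshiro256++ streams (movement, division, intravasation, zone exit,
phenotype assignment, vessel placement, update-order scheduling) derive
from one master seed via splitmix64, so adding draws to one process never
perturbs another and every result is bit-reproducible from `(params,
seed)`. Cells update in a freshly shuffled order each step: clocks and
necrosis first (a cell dead at step start cannot act), then movement and
the contact draw, then division — daughters first move in the following
step.

## Parameters

| key | default | unit | meaning |
|---|---|---|---|
| `L` | 2000 | µm | domain side (periodic) |
| `dt` | 1 | h | time step |
| `duration` | 2160 | h | horizon (90 days) |
| `d_cell` | 20 | µm | cell diameter = lattice square side |
| `tau` | 336 | h | cell-cycle length (14 d, tissue scale) |
| `t_G1` | 144 | h | G1 length (~43% of the cycle) |
| `n_s`, `n_n` | 2, 3 | cycles | quiescence / necrosis thresholds |
| `delta_D` | 4 | h | maximum crowding bonus |
| `nourished_advantage` | 0.30 | — | proliferation-rate gain near vessels |
| `p_div_high`, `p_div_low` | 0.25, 1e-4 | /step | division probabilities |
| `p_intr` | 1e-4 | /contact-step | baseline intravasation probability |
| `p_exit_nourished` | 0.5 | — | zone-exit acceptance |
| `vessel_count` | 240 | — | lumen squares (60 vessels/mm²) |
| `nourished_radius` | 100 | µm | nourished-zone radius |
| `n_init` | 1 | — | founding cells (compact central cluster) |

`n_n = 3` (death after three doubling times without division), `p_intr` =
1e-4, and the 30% nourished advantage are anchored values of the model;
the rest are this package's defaults. Three of them deserve comment
because they were set by calibrating the model's headline output — the
number of intravasated cells by the time a pure low-Giantin tumor reaches
one thousand living cells, which should be of order 30:

* `tau = 336` h. In tissue, effective tumor doubling times are weeks, not
  the ~24 h of the same lines on 2D plastic. A 14-day cycle lets a tumor
  founded by one cell reach a few thousand cells inside the 90-day
  horizon without saturating the field.
* `vessel_count = 240` on the 2 × 2 mm field is a microvessel density of
  60/mm², inside the range reported for invasive breast carcinoma.
* the default migratory-group speeds are 2.4 and 7.2 µm/h. These are
  tissue-scale speeds; the 10–50 µm/h measured for freely migrating cells
  on 2D substrates would let cells traverse many diameters per division
  interval, producing uniformly diffuse tumors in which neither crowding
  necrosis nor the speed–size coupling can arise.

With these defaults the assay gives a mean of ≈30 intravasated cells per
1000 (sd ≈ 4–8 over 25 replicates), and the two-phenotype mixture
experiments reproduce the expected orderings: at the baseline rate a 65%
low-Giantin tumor is smaller and seeds *fewer* cells than a 14% tumor; at
a 2-fold rate the two are comparable; at 4-fold the smaller tumor seeds
*more*.

## Phenotypes and the four migratory groups

Trajectory analysis (`rms_speed()`, `persistence_ratio()`,
`assign_groups()`) scales each track's root-mean-square speed and
persistence ratio by the population means and classifies tracks into four
groups: 1 low speed/low persistence, 2 low/high, 3 high/low, 4 high/high
(boundary values count as high). `default_phenotypes()` mirrors this in
the simulator: the intact-Golgi phenotype draws groups uniformly, the
fragmented-Golgi (low-Giantin) phenotype is shifted toward the low-speed
groups (abundances 0.40/0.35/0.15/0.10) and carries the intravasation
fold. These abundances and the group speed/persistence values are
*synthetic* fixtures shaped like the experimental pattern (knockdown
cells enriched in the slow groups, persistence unchanged), not measured
numbers.

## The synthetic-track generator

`generate_tracks()` runs the motility rule itself — same heading sets,
same persistence gating, same RNG discipline — for single unobstructed
cells in unwrapped coordinates, emitting tables shaped like centroid
tracking output (`track_id`, `frame`, `t`, `x`, `y`). It recovers its
nominal speed to within 5% over 200 tracks, and the input persistence
maps monotonically onto the measured persistence ratio. What it does not
emulate: localization noise, track fragmentation and mis-linking, cell
collisions in dense assays, and speed–persistence correlation within a
track. Passing the parameter-recovery tests therefore says the estimators
and the walk are mutually consistent, not that real imaging data would be
this clean.

## The reduced sweep

The speed–persistence sweep (`run_sweep()`) is the model's
characterization experiment: a grid of constant-speed phenotypes crossed
with persistence ratios, replicated, each run summarized by final counts
and the uniformity index. The default conditions (`sweep_params()`) are a
scaled-down 30-day setting chosen so that the full fate repertoire is
expressed inside the horizon: a 1.2 mm field with 81 vessels (a
comparable 56/mm² density), a 7-day cycle with G1 at 40%, and a compact 9-cell
founding cluster whose interior is crowding-blocked from the start —
without it, necrosis (three cycles without division) cannot appear within
30 days. Speeds 0.5–8 µm/h span frozen-compact to diffuse tumors;
persistence 0.2–0.8. Under these conditions the final necrotic count is
strongly anti-correlated with the uniformity index (r ≈ −0.8: compact,
low-UI tumors starve their cores) while the quiescent count is only
weakly anti-correlated (r ≈ −0.35): quiescence is transient — in compact
tumors blocked cells pass through it into necrosis, while large diffuse
tumors contribute a size-proportional number of locally crowded,
vessel-adjacent cells.

## Uniformity index

The authors of the index cite it without printing a formula, so this
package uses the normalized total-variation form
$$UI = 1 - \frac{\sum_i |c_i - N/k|}{2N(1 - 1/k)}$$
over `k` equal quadrats tiling the *fixed* domain (default k = 25),
which is 1 for perfectly even quadrat counts and 0 when all cells share
one quadrat. Absolute UI values are comparable only at fixed `k`, and may
differ from other formulations by a monotone transform; ordinal
statements (correlations, orderings) are the reliable surface.

## Numerical choices and degenerate inputs

* Uniform draws live on (0, 1]; probability-0 events are impossible by
  construction, not by rounding.
* Overlap is strict (`distance < d_cell` blocks; exactly `d_cell`, the
  packing distance of daughters, is legal) with a 1e-9 µm² slack against
  floating-point jitter in the squared comparison.
* Boundary thresholds are inclusive: division at $PS \ge \tau$, fast
  track at clock $\ge t_{G1}$, quiescence at $T \ge n_s\tau$, necrosis at
  $T \ge n_n\tau$, each with a 1e-9 h tolerance.
* Tie-breaking among surviving move candidates and free daughter spots is
  uniform with a single draw over the set, candidates enumerated in fixed
  heading order for determinism.
* Blocked movement and failed division are legal outcomes, not errors; a
  cell with no admissible move keeps its heading.
* Zero-cell fields are legal states (the population can go extinct; the
  run then stops); the uniformity index of an empty field is undefined
  and recorded as `NA`.
* Periodic wrapping uses floor-based modular arithmetic mapping onto
  [0, L).

## Problem sizes

The test suite runs on 400–800 µm fields with 24 h cycles (seconds per
scenario) and checks the invariants — conservation, non-overlap against a
brute-force all-pairs oracle, occupancy-index rebuilds, binomial
calibration, estimator closed forms — at populations up to 200 cells
where exhaustive oracles are cheap. The acceptance computations are the
default reduced sweep (100 runs, ~10 s) and the 25-replicate
thousand-cell assay (~10 s). The full-scale defaults (2 mm field, 90
days) run in about a second per simulation.

## Limitations

* Two spatial dimensions; vessels are static point cross-sections with no
  angiogenesis, collapse, or oxygen transport — nourishment is a binary
  zone membership.
* No cell mechanics: no pushing, adhesion, or contact inhibition of
  locomotion; overlap exclusion and discrete Moore spots stand in for all
  of it.
* Heading space is discrete (8 directions); persistence is a set-choice
  probability, so the measured persistence *ratio* of an unobstructed
  walk is a monotone but nonlinear image of the input parameter.
* The quiescence–necrosis clock depends only on time since division;
  there is no distinct apoptosis, and "quiescent" lumps dormant and
  senescent states.
* Phenotype fractions act at birth; there is no phenotype switching of
  living cells and no heritability of the migratory group.
* Calibrated defaults reproduce the order of magnitude of intravasation
  per 1000 cells under one vascular geometry; they are not fitted to any
  patient data.
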