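---
title: "Spatial competition and adaptive cancer therapy on a lattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial competition and adaptive cancer therapy on a lattice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latticeAT)
```

## The model

`latticeAT` simulates a tumour as agents on a closed square lattice of
`L x L` sites, each holding at most `K` cells (`K` = 1 or 2). Two cell types
compete for space: drug-sensitive cells (S) and drug-resistant cells (R).
Time advances in daily steps. Each day, every cell alive at the day's start
is visited exactly once in a freshly shuffled order and runs through one
decision tree:

1. **Migration.** With probability `m` the cell attempts to move. If any of
   the four von Neumann neighbours (east, west, south, north; truncated at
   the closed boundary) has a free slot, the cell moves to one chosen
   uniformly at random; either way the attempt ends its turn. Migration and
   division are therefore mutually exclusive within a day.
2. **Event.** Otherwise, with probability `r_j + d_T` something happens,
   where `r_j` is the type's division probability and `d_T` the natural
   death probability.
3. **Divide or die.** Given an event, it is a division attempt with
   probability `r_j / (r_j + d_T)`; otherwise the cell dies and immediately
   vacates its slot.
4. **Drug.** A sensitive cell attempting division while the drug is on is
   killed with probability `delta_D`. Resistant cells never die of the
   drug — resistance is complete, and its cost is a 30% lower division
   probability.
5. **Placement.** A surviving attempt places one daughter uniformly at
   random among the free capacity slots of the neighbourhood (plus the
   mother's own spare slot when `K = 2`). With no free slot the division is
   simply not executed: crowding, not an explicit death term, is what slows
   dense populations.

Cells sitting on fibroblast (CAF) sites divide with probability
`alpha * r_j` instead of `r_j`: the microenvironment promotes growth of
both types, which also exposes sensitive cells to more drug kills because
only dividing S-cells can be hit.

Daughters born today are excluded from today's shuffled list, and dead
cells are removed at once; this matches the standard asynchronous-sequential
update of shuffled-list lattice ABMs and makes one "day" exactly one sweep
over the population present at dawn.

## Parameters

| name | meaning | default | notes |
|------|---------|---------|-------|
| `r_S` | S division probability/day | 0.027 | sets the time scale (doubling ~26 d) |
| `r_R` | R division probability/day | `0.7 * r_S` | 30% fitness cost of resistance |
| `d_T` | natural death probability/day | `0.3 * r_S` | shared by both types |
| `delta_D` | drug kill probability per division attempt | 0.75 | S-cells only |
| `m` | migration probability/day | 0 | sweeps use multiples of `r_S` up to `4 r_S` |
| `alpha` | CAF growth promotion | 2 | 2 or 4 are the studied strengths |
| `K` | cells per site | 1 | 2 models a laxer packing constraint |
| `rho` | adaptive pause threshold | 0.5 | see below |
| `N0`, `f0` | initial burden and resistant % | 5000, 10% | 7000 and 1% are studied variants |
| `L`, `T_end` | domain side, horizon | 100, 2000 d | virtual patient uses 200, 3500 d |
| `progression_factor` | progression threshold | 1.2 | 120% of `N0` |

All rates are per-day Bernoulli probabilities; there are no waiting times or
sub-daily events.

## Treatment strategies and outcome measures

Two dose schedules emit `D(t)` in {0, 1} once per day, evaluated before the
day's update from the previous day's closing count:

* **CT-MTD** — continuous maximum tolerated dose, `D(t) = 1` always.
* **AT** — adaptive therapy: full dose until the total population drops
  strictly below `rho * N(0)`, then a treatment holiday until it regrows to
  `N(0)` (ties resume treatment). The controller starts "on".

Outcomes: **TTP**, the first day `N(t)` reaches
`progression_factor * N(0)`; **TG**, the time gained by AT over CT-MTD on
seed-paired runs (same initial lattice and same dynamics stream, which agree
bit-for-bit until the doses first diverge); **TR50**, the first day the
resistant population alone reaches half the initial burden; and the count of
on-blocks of the dose series ("treatment cycles"). Runs that never progress
within the horizon are censored and excluded from paired statistics.

Local competition is quantified by `neighborhood_counts()`: for each focal
cell, the numbers of S-cells, R-cells and empty capacity slots in its
neighbourhood, whose interior total is 4 for `K = 1` and 9 for `K = 2`
(eight neighbour slots plus the own spare). `area_of_impact()` counts the
CAF sites lying more than `margin` (default 10) sites from the boundary —
fibroblasts further out cannot influence TTP because progression occurs
before the expanding front reaches them. The margin is exposed as a
parameter rather than derived: the heuristic that motivates 10 sites does
not pin it down sharply.

## Initial configurations

Sensitive cells are always scattered uniformly. The resistant cells follow
one of three dispersion patterns that set the intensity of R-R
self-crowding, the lever behind all strategy contrasts:

* **clumped** — uniform within a centred `clump_side x clump_side` square
  (40 by default): maximal self-crowding, slowest regrowth;
* **random** — uniform over the whole domain;
* **uniform** — a deterministic, evenly spaced near-square grid chosen to
  approximate maximal pairwise distance. True max-min placement has no
  closed form and would depend on the optimizer; a grid with
  `rows * cols >= R(0)` and `|rows - cols|` minimal, surplus dropped from
  the last row, is reproducible and spacing-equivalent. Sensitive cells
  displaced by the grid are relocated to random free slots (the grid takes
  priority).

Fibroblast layouts (`caf_mask()`) each cover about 10% of the default
domain: a centred square overlapping the resistant clump (`FC`), an offset
rectangle partially overlapping it (`FCp`), a hollow square surrounding it
(`FSq`), an L-shaped band partially surrounding it (`FSp`), ten random
non-overlapping 10 x 10 clumps (`FR`), or none (`NoF`). The `FR` layout is
re-drawn for every realization by default; `caf_fixed_seed` freezes one
draw across a cohort, which `run_cohort()` uses when a single geometry must
be related to cohort-level outcomes (e.g. the area-of-impact regression).

## Cohorts and the virtual patient

`run_cohort()` runs 30 realizations per strategy by default (realization
`i` uses seed `base_seed + i - 1`), reports per-realization outcomes, the
across-realization mean trajectories and their progression day, and paired
time gains. Because the strategies share seeds, paired comparisons remove
most between-realization variance. `two_sample_ttest()` is Welch's test by
default — the variance-equality assumption buys nothing here — with a
pooled-variance switch, annotated with the conventional significance stars.

`simulate_patient()` couples several independent lesion domains through one
systemic controller: the dose decided from the summed burden (including any
undetected lesion) is applied to every lesion. The four predefined cases
vary fibroblasts and migration in an initially invisible fourth lesion
holding 10% of a visible lesion's cells; its **emergence time** is the day
it reaches half its domain's carrying capacity. Per-lesion RNG streams are
derived from the run seed, so a lesion simulated under a constant dose
reproduces the single-lesion engine exactly — the regression test of the
multi-lesion plumbing.

The per-lesion burden of the visible lesions and the exact per-lesion
parameter mix are genuinely open choices; the defaults (5000 cells per
visible lesion; scattered-CAF/no-migration, migration-only and bare lesions)
are one reading of the intended contrast and every piece is overridable via
`lesion_spec()`. Conclusions that depend on the absolute systemic
progression day should be drawn only after fixing these to the scenario at
hand; the ordering of emergence versus progression is robust across seeds,
the ranking of the two strategies' progression days in a single realization
is not.

## Numerical choices

* **RNG.** Each realization (and each lesion within a patient) owns a
  64-bit Mersenne Twister stream seeded deterministically from the
  user-facing integer seed; draws occur in decision-tree order, so runs are
  bit-reproducible and order-independent across lesions. Lattice
  construction uses R's own RNG under a locally set seed that is restored
  afterwards.
* **Drug-check order.** By default a sensitive cell attempting division is
  exposed to the drug before free space is checked, so it can die even when
  fully enclosed. The alternative reading — check space first, so a blocked
  attempt cannot be punished — is available as
  `drug_check_after_space = TRUE`; the two differ only through the small
  population of fully enclosed S-cells under dose, and cohort-level results
  are insensitive to the choice (both orders are exercised by an exact
  enumeration test).
* **Placement ties.** Daughters choose uniformly among free *slots*, so for
  `K = 2` a twice-empty site is twice as likely; migration chooses uniformly
  among free *sites* (a cell does not migrate into its own site).
* **Degenerate inputs.** `f0 = 0` yields a sensitive-only tumour (useful for
  extinction checks); a population hitting zero stays zero; neighbourhood
  means over an empty focal set are `NaN` by design.
* **Problem sizes.** The test suite validates kernels by exact enumeration
  on 3 x 3 lattices and binomial Monte Carlo on lattices of isolated cells
  (1e5 cell-days), and reproduces cohort-level results at the full study
  scale (30 realizations, `L = 100`, horizons 800-2000 days chosen to sit
  well past the latest observed progression of each configuration; the
  four-lesion patient runs a single realization at `L = 200` to 3500 days).

## What the simulations do and do not show

The generator *is* the model: synthetic tumours share its assumptions, so
agreement between simulated cohorts and published summary statistics
validates the implementation, not the biology. Real tumours have continuous
space, heterogeneous drug penetration, phenotype switching, vasculature and
immune interactions, none of which are modelled; fibroblasts here are a
static growth-promoting mask with no dynamics of their own, and the drug is
spatially homogeneous with binary dosing. Within those assumptions the
package reproduces the characteristic findings — clumped resistant cells
progress far later than dispersed ones, adaptive therapy buys the most time
exactly when resistance is spatially concentrated, migration and extra
per-site capacity erode that advantage, and fibroblast regions outside the
resistant clump accelerate progression in proportion to their area of
impact. One published summary the implementation does not recover is the
absolute minimum of the mean trajectory in the fibroblast comparison: its
reported values sit below the floor that the initial resistant burden and
monotone resistant growth impose under every parameterization consistent
with the other reported quantities (the decline and regrowth rates, which
are recovered), so the corresponding acceptance check documents the
discrepancy rather than hiding it.

## Reproducing the study-level numbers

`scripts/acceptance.R` (see the README) re-runs the cohort experiments from
scratch at the full study scale and writes the headline quantities — the
mean-trajectory progression days for the three dispersion patterns under
both strategies, the adaptive extension percentage, the migration and
fibroblast variants, and the clumped/random time-gain ratio — as JSON, so
the whole chain from seeds to summary statistics is a single command.
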