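# latticeAT

Stochastic on-lattice simulation of competition between drug-sensitive and
drug-resistant tumour cells under continuous versus adaptive cancer therapy.

## The problem

Continuous dosing at the maximum tolerated dose (CT-MTD) clears
drug-sensitive cells quickly — and thereby hands the surviving resistant
clone free space to grow into. Adaptive therapy (AT) instead pauses
treatment whenever the tumour burden falls below a fraction `ρ` of its
initial size and resumes once it regrows, deliberately keeping sensitive
cells around to crowd the resistant ones. How much time this buys depends on
*where* the resistant cells sit: a clumped resistant population competes
mostly with itself, a dispersed one hardly at all. Stromal geometry matters
too, because cancer-associated fibroblasts (CAFs) locally boost
proliferation of whatever sits on them.

`latticeAT` is a simulator for exactly these questions, aimed at
computational-oncology researchers. Cells live on a closed `L × L` lattice
(capacity `K` ∈ {1, 2} per site). Each day every cell, in shuffled order,
either attempts migration (probability `m`), dies naturally (`d_T`), or
attempts division (`r_S` or `r_R = 0.7 r_S`); a sensitive cell dividing
under dose `D(t) ∈ {0, 1}` is killed with probability `δ_D D(t)`, and a
daughter needs a free neighbourhood slot — no space, no division. CAF sites
multiply the occupant's division probability by `α`. Dose control is either
`D(t) ≡ 1` (CT-MTD) or the adaptive on–off rule (off below `ρ N(0)`, on
again at `N(0)`). Progression (TTP) is the first day `N(t) ≥ 1.2 N(0)`.

On top of the single-lesion engine the package provides the three initial
resistant-cell dispersions (clumped / random / uniform), six CAF layouts,
neighbourhood-competition metrics, 30-realization seed-paired cohorts with
Welch t-tests, and a four-lesion "virtual patient" in which one systemic
dose controller — driven by the summed burden, including an initially
undetectable lesion — treats all lesions at once.

## Worked example

```r
library(latticeAT)

p <- model_params()   # 100x100, K = 1, N0 = 5000, f0 = 10%, T = 2000 days
sim <- simulate_tumor(p, strategy = "ctmtd", seed = 1, r_pattern = "clumped")
sim
#> tumor_sim: CTMTD, seed 1, 2000 days on 100 x 100 (K = 1)
#>   N: 5000 -> 6895 (S 0 / R 6895 at end)
#>   progression: day 1747 (>= 120% of N0), 1 treatment cycle(s)
#>   TR50: day 650
```

Under continuous dosing the sensitive population is eradicated and the
clumped resistant clone needs 1747 days to push the burden past 120% of its
initial value; the resistant cells alone reach half the initial burden on
day 650. A seed-paired cohort comparison of the two strategies:

```r
coh <- run_cohort(p, "clumped", strategies = c("ctmtd", "at"),
                  n_realizations = 30, base_seed = 100)
coh
#> tumor_cohort: 30 realization(s), clumped R-cells, CAF NoF, 2000 days
#>   CTMTD  mean-trajectory TTP = 1713; per-run TTP mean 1712 (sd 50), 0 censored
#>   AT     mean-trajectory TTP = 1868; per-run TTP mean 1868 (sd 58), 1 censored
#>   time gain (AT - CT): mean 153, median 152 over 29 uncensored pair(s)
```

Adaptive therapy delays mean progression by about 150 days (~9%) for
clumped resistance; re-running with `"random"` shrinks the gain by roughly
an order of magnitude — dispersion, not dose, is what the benefit hinges on.
`simulate_patient(patient_case("I", "clumped"), "at", model_params(L = 200,
T_end = 3500))` runs the four-lesion virtual patient; `plot()` methods show
trajectories, and `inst/cli/latticeAT.R` exposes `simulate` / `cohort` /
`patient` subcommands for shell use.

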