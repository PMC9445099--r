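---
title: "A minimal model of branching organoid morphogenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A minimal model of branching organoid morphogenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(orgbranch)
library(dplyr)
```

## The model

Branched pancreatic-duct organoids grown from single cells in collagen
pass through an extension phase in which elongated branches invade the
matrix, multiply by tip branching, and thicken by proliferation.
`orgbranch` implements the minimal biophysical description of that
phase, built from three ingredients:

1. **Tip invasion.** Every elongating tip advances at a constant speed
   $v_0$ (calibrated value 80 µm/day), independent of the rest of the
   organoid.
2. **Stochastic tip branching.** Every tip branches at a constant rate
   $k_b$ (calibrated value 0.55/day), so the number of tips is a Yule
   (pure-birth) process with mean $e^{k_b t}$ and variance
   $m(m-1)$, $m = e^{k_b t}$ — the standard deviation of branch counts
   grows to the same order as the mean, which is the observable
   signature of stochastic branching.
3. **Proliferation feedback.** The per-cell division rate decreases
   linearly with local branch width,
   $k_d(w) = k_d^0\,\max(0,\,1 - w/w_0)$, reflecting contact inhibition
   and the larger matrix stress borne by thick branches. $k_d^0$ (the
   maximal division rate) and $w_0$ (the width at which proliferation is
   abrogated) are free parameters recovered by regression; the package
   default $k_d^0 = 1.5$/day, $w_0 = 60$ µm is a representative
   calibration.

Cell number and geometry are tied by a cylindrical closure
$N_c\,v_\mathrm{cell} = \tfrac{\pi}{4}\,w^2\,L_\mathrm{tot}$: branches
are cylinders of mean width $w$, and each cell occupies
$v_\mathrm{cell}$ (default 1000 µm³, a cell of ≈12.4 µm diameter). The
closure is a modelling choice — the governing equations never state how
width follows from cell number — but the plateau prediction below does
not depend on it: `integrate_meanfield()` accepts any closure function,
and a sheet closure (linear in $w$) reaches the same plateau, because
the fixed point is set by $k_d(w^*) = k_b$ alone.

### Mean-field equations

The deterministic, ensemble-averaged description integrates

$$\frac{dL_\mathrm{tot}}{dt} = v_0\,e^{k_b t}, \qquad
  \frac{dN_c}{dt} = k_d^0\left(1 - \frac{w}{w_0}\right) N_c,$$

with $w$ given by the closure at all times. Two growth phases follow:
while branches are thin ($w \ll w_0$) cell number grows at the maximal
rate $k_d^0$; once proliferation has caught up with elongation the
width settles at

$$w^* = w_0\left(1 - \frac{k_b}{k_d^0}\right)$$

and growth continues exponentially at the slower branching rate $k_b$.
Demonstrating the early phase numerically requires $w(0) \ll w_0$; at
the standard geometry the initial closure width is ≈7 µm, so the
two-phase check in the test suite uses $w_0 = 600$ µm to give the early
window four clean days at $k_d \approx k_d^0$ before the feedback
engages. This is a model-structure check, not a calibration.

```{r meanfield}
p <- growth_params()
p
traj <- integrate_meanfield(p, t_end = 20)
plateau_width(p)
tail(traj, 1)
```

Integration uses `deSolve::lsoda` with tight tolerances (`1e-10`) and
dense output on a fixed reporting grid (default 0.01 day); the system is
smooth and non-stiff at calibrated rates, and halving the grid changes
reported states by less than $10^{-6}$ relative.

## The spatial stochastic simulator

`simulate_organoid()` runs the same ingredients in space. Per fixed
time step `dt` (default 0.01 day, tau-leaping with per-event
probability $1 - e^{-r\,dt}$):

* every terminal, unbroken branch's tip advances $v_0\,dt$ along its
  heading, which diffuses by a Gaussian angle of variance
  $d_\theta\,dt$ ($d_\theta$ default 0.2 rad²/day — mild wandering, so
  branches stay locally straight as in the imaging data);
* every branch's volume grows by $e^{k_d(w)\,dt}$ and its width is
  recomputed from the volume–length closure, so elongation thins a
  branch while proliferation thickens it — the conservation law behind
  both drug predictions below;
* terminal branches branch; the mother becomes non-terminal and two
  daughters leave at $\pm\theta_b$ (default 0.6 rad, in a random plane
  containing the mother direction in 3D) with length `l_init` and the
  mother's current width;
* a branch thinner than `w_min` ruptures: it keeps its geometry but
  stops elongating and growing.

Runs are bit-reproducible from the integer seed; the stepping core is
compiled (Rcpp) and uses R's RNG, so `set.seed` semantics carry over.

### Division-coupled branching

Branching events follow tip-cell divisions in the data (in over 90% of
scored events). The simulator reproduces this causally: divisions fire
in the tip compartment (the leading 6 cells) at rate $6\,k_d(w)$, and
each division triggers a branching event with conditional probability
chosen so that the per-step branching probability is exactly
$1 - e^{-k_b dt}$. A thinned Poisson process is again Poisson, so the
long-run branching rate per tip is exactly $k_b$, Yule statistics are
preserved, and every branching event coincides with a triggering
division. The alternative of *deferring* independently drawn branching
times to the next division was rejected: the extra waiting time lowers
the ensemble growth exponent of the branching process (a
Bellman–Harris effect), contradicting the requirement that coupling
leave the rate $k_b$ unchanged. Uncoupled Poisson branching remains
available (`couple_branching_to_division = FALSE`).

### Numerical and design choices

* **Branch angle and angular noise** ($\theta_b$, $d_\theta$) have no
  measured values; defaults are configurable and no quantitative check
  depends on them (path-length tip speed is exactly $v_0$ regardless of
  heading noise).
* **Daughter seeding.** Daughters start at the mother's tip width with
  newly created seed volume (interpreted as tip proliferation feeding
  the bud); `split_mother_volume = TRUE` instead takes the seed volume
  out of the mother. `l_init` defaults to 25 µm: at much smaller seed
  lengths the elongation-dilution rate $v_0/l$ at birth (≈5/day at
  15 µm) overwhelms $k_d^0$, so every generation of daughters inherits
  a dipped width and dips further — a thinning ratchet that spuriously
  ruptures lineages and suppresses branch counts, which the real system
  does not show.
* **Rupture threshold.** `w_min` defaults to 0.5 µm, deliberately below
  any width reached during unperturbed growth (no spontaneous rupture
  is observed experimentally). The aphidicolin demonstration raises it
  to 5 µm — a single-cell scale at which a thinning tube plausibly
  loses integrity — so that rupture becomes observable within a
  one-week treatment window; the prediction under test (youngest
  branches break first) is an ordering and does not depend on the
  threshold value.
* **Breakage bookkeeping.** Broken branches keep their geometry and are
  still counted (rupture, not removal).
* **Self-avoidance** is off by default; an optional arrest distance
  terminates tips that approach existing centerlines.

### What the spatial model does and does not reproduce

Ensemble tip counts match the mean-field $e^{k_b t}$ within 1% and
total length matches once the documented seeding term ($2\,l_\mathrm{init}$
per branching event) is added to the bare elongation equation. Cell
number is only loosely captured by the single-width mean-field closure:
the ensemble-to-mean-field ratio runs from ≈1.7 early (newly seeded
volume) to ≈0.7 by day 8, because saturated non-terminal ducts
($w \to w_0$, $k_d \to 0$) hold a growing share of the volume while the
mean-field keeps proliferating at $k_d(\bar w)$. Likewise, terminal
branches in the spatial model plateau well below the mean-field
$w^*$ — the terminal pool is dominated by young, recently thinned
branches — while non-terminal branches, no longer thinned by
elongation, climb towards $w_0$. The *ordering* (terminal thinner than
non-terminal) is the prediction confirmed by the data and asserted in
the tests; absolute spatial width values are not calibration targets.

## In-silico perturbations

`perturbation_preset()` encodes the two treatments used to test the
model:

* **batimastat** (MMP inhibitor): abolishes invasion ($v_0 \to 0$) and
  scales volumetric growth to its measured residual
  ($k_d^0 \to 0.23\,k_d^0$, the −77% condition). Without elongation to
  thin them, branches thicken monotonically towards $w_0$.
* **aphidicolin** (DNA-polymerase inhibitor): $k_d^0 \to 0$. Continued
  elongation with no volume growth thins every elongating branch as
  $w \propto \sqrt{l/(l + v_0 \Delta t)}$; nascent branches (small $l$)
  thin fastest and reach the rupture threshold first.

```{r perturb, eval = FALSE}
p <- growth_params()
cfg <- sim_config(params = p, duration = 12, seed = 1)
sim <- simulate_organoid(cfg,
  schedule = perturbation_preset("batimastat", at = 8, params = p),
  record_nodes = FALSE)
plot_width_classes(width_by_class(sim$branch_samples), p)
```

## Morphometrics

`measure_tree()` applies the measurement conventions of the study:
terminal width 30 µm behind the tip (base fallback for branches shorter
than the offset), body width at 100 µm, non-terminal width 100 µm after
the base of the "Y", branch counting by terminal/non-terminal class,
and the maximal pairwise node distance as a skeleton proxy for the
fitted-ellipse major axis (an upper-bound proxy — no image mask exists
for a simulated tree, and no quantitative check compares it to imaging
values). Simulated branches carry one width scalar, so the offset
conventions return that scalar exactly; tapered per-node widths are
supported for fixtures so that real skeleton data could be measured
identically. The normalized volumetric growth rate of a branch over an
interval is $(V(t+\Delta)-V(t))/(V(t)\Delta)$.

## Parameter recovery

`fit_growth_parameters()` mirrors the study's regressions:

* `fit_proliferation_feedback()` — OLS of growth rate on width over
  unbinned pairs; $k_d^0$ is the intercept and $w_0 = -b_0/b_1$ the
  width-axis crossing. A fit with non-negative slope refuses to report
  $w_0$. Bootstrap intervals (1000 resamples, seeded) are available.
* `fit_branching_rate()` — OLS of log count on time; the intercept is
  free by default (day-1 structures may already have several branches)
  and the fixed-intercept variant is reported alongside.
* `fit_tip_speed()` — per-track slope of cumulative path length,
  averaged across tracks.
* `compare_cellcount_prediction()` — log-scale RMSE plus coverage of
  the observed mean ± sd band (boundary counted in).

## The synthetic-data generator

`generate_morphometric_dataset()` is the stand-in for the measured
tables: it simulates `n_organoids` with distinct sub-seeds
(`seed + i`, so any organoid regenerates alone), measures them, and
applies observation noise. The emulated design follows the study:
growth-rate pairs from a live-imaging window (day 7–10) with short
measurement intervals (0.05 day — the finite-difference rate exceeds
the instantaneous $k_d$ by $\sim k_d^2\Delta/2$, about 3% at the
maximal rate, so short intervals matter) at anchors every 0.5 day;
daily branch and cell counts (day 0–9); tip tracks for the first three
organoids (live imaging covers a few organoids, not the whole
collection). Noise is multiplicative lognormal with mean one (widths,
rates, counts; default CV 10%) plus additive Gaussian track jitter
(2 µm); magnitudes are declared assumptions, not measured values. With
60 organoids at these defaults the full loop recovers $v_0$, $k_b$,
$k_d^0$ and $w_0$ within 10% in well over 90% of seeded repeats; the
dominant residual is the +3% finite-interval bias on $k_d^0$.

What the generator does **not** emulate: image segmentation noise
structure, projection effects, tip misidentification, or any
correlation between measurement errors — passing the recovery tests
shows the estimators are consistent for the model's own data-generating
process, not that they are robust to every failure mode of real
imaging.

```{r worked}
ds <- generate_worked_fixture()
fit <- suppressWarnings(fit_growth_parameters(ds))
tidy(fit)
```

## Problem sizes

The shipped tests use the ensemble sizes of the corresponding claims:
500 runs for the branching-rate recovery, 1000 for the Yule
statistics, 200 for division precedence, 100 repeats × 60 organoids
for the full recovery loop, and 20-run ensembles for the perturbation
orderings. A 9-day organoid takes a few hundredths of a second to
simulate without geometry recording.

## Known limitations

* The mean-field cell-number curve is quantitatively reliable only
  while width heterogeneity is mild (roughly the first week at
  calibrated rates); see above.
* Lumen formation, matrix mechanics, gel contraction and osmotic
  swelling — later morphogenesis phases — are outside the model.
* Rupture is a threshold event on mean width; the local pinching
  instability seen in time-lapse has no counterpart at this
  resolution.
* The spatial rules not fixed by the main-text description (branch
  angle, angular noise, daughter seeding, self-avoidance) are declared
  package choices; quantitative checks use only quantities that do not
  depend on them.
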