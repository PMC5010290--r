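---
title: "Selecting leukocyte motility models by multi-objective calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting leukocyte motility models by multi-objective calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leukowalk)
```

## The problem

Two-photon imaging of immune cells yields time series of 3D cell positions:
tracks. Deciding which random-walk model best describes a tracked population
-- Brownian motion, a Lévy walk, or a correlated random walk (CRW) -- is
harder than it looks, for two reasons.

First, 3D motility cannot be summarised by one number. Two models can match
a dataset's mean squared displacement while differing completely in how
cells translate and turn. Any serious comparison has to consider several
motility metrics *simultaneously*, and accept that models trade off
performance between them.

Second, the data are biased by the observation process. Cells are only
tracked while inside a finite imaging volume, so fast cells moving in a
persistent direction leave quickly and are observed few times, while slow
meandering cells rack up long tracks. In a raw export, a track's observation
count correlates negatively with its median translational speed and
positively with its median turn speed. Track-to-track differences in median
speed might therefore be a sampling artifact rather than genuine cell
heterogeneity -- unless the analysis reproduces the bias.

`leukowalk` implements a complete pipeline for this problem:

1. **Motility profiling** of track data (`build_motility_profile()`,
   `msd_curve()`, `displacement_autocorrelation()`, `motility_report()`).
2. **Bias-aware distribution fitting** that asks which statistical family
   explains pooled speed data *and* the per-track median structure, under
   the same observation bias (`synthesize_grouped_dataset()`,
   `fit_pooled()`, `evaluate_median_capture()`, `fit_report()`).
3. **Six random-walk models** simulated in a 3D arena with the imaging
   volume built into the observation process (`walker_params()`,
   `run_ensemble()`).
4. **Multi-objective calibration** of each model against a target motility
   profile with NSGA-II, and **Pareto-front model comparison**
   (`nsga2_calibrate()`, `compare_models()`).

## Motility metrics and their conventions

Units are fixed package-wide: positions in µm, time in s, translational
speed in µm/min, turn speed in °/min. For a track sampled every $\Delta t$
seconds with displacement vectors $d_i$:

* **translational speed** over step $i$ is $|d_i| / (\Delta t/60)$;
* **turn speed** at interior point $i$ is the angle between $d_i$ and
  $d_{i+1}$ (degrees) divided by $\Delta t/60$. The largest measurable
  angle is 180°, so turn speed is capped at $180/(\Delta t/60)$: 360 °/min
  at 30 s sampling, 240 °/min at 45 s. A zero-length displacement leaves
  the angle undefined; that observation is skipped and counted, never
  imputed as zero;
* **meandering index** is net (first-to-last) displacement over total path
  length: 1 for a straight monotone track, 0 for a closed loop.

Tracks whose net displacement is below 27 µm are excluded before profiling.
This mirrors the preprocessing used on imaging data to drop sessile
contaminating cells and dead/dying cells, and the same threshold is applied
to simulated data so comparisons are fair. The filter reads "net"
displacement (the standard track-displacement statistic of tracking
software), with ties at exactly 27 µm retained.

A **motility profile** pools per-step translational speeds, per-step turn
speeds and per-track meandering indices across all surviving tracks. These
three distributions are the calibration objectives. Per-track medians of
each speed type are kept alongside as diagnostics -- they are deliberately
*not* calibration objectives, which later makes them a useful independent
check on calibrated models.

MSD curves use overlapping windows (all start points, lags from anywhere in
the temporal domain) up to 25% of the longest track duration, and report
the log--log regression slope: 1 is diffusive, 2 ballistic. Displacement
autocorrelation uses the per-pair cosine
$d_i \cdot d_{i+k} / (|d_i||d_{i+k}|)$, reported as median and IQR per lag.
The cosine form is chosen for scale-invariance and a guaranteed $[-1, 1]$
range; it is a diagnostic only and never enters calibration.

## Statistical families and the bias-matched fitting framework

Four families model a population's pooled translational (or turn) speeds:
uniform on $(0, \lambda]$; Lévy with stability $\alpha \in (0,2]$ and scale
$\beta$ (sampled through the classic uniform/exponential transient
construction, reducing to a half-Cauchy at $\alpha = 1$ and to the Gaussian
limit at $\alpha = 2$); a homogeneous Gaussian $G(\mu, \sigma)$; and a
*heterogeneous* Gaussian in which each cell $i$ owns a bespoke
$G_i(\mu_i, \sigma_i)$ whose parameters are themselves drawn once from
Gaussians, $\mu_i \sim G(\mu_M, \sigma_M)$ and
$\sigma_i \sim G(\mu_S, \sigma_S)$.

Two conventions are worth stating explicitly. The spread parameters are
standard deviations (the arguments passed to the normal sampler). Since the
per-cell spread is itself Gaussian-distributed it can be drawn negative; it
is clamped at 0, a degenerate point mass, which keeps the sampler total --
poorly fitting regions are simply avoided by the optimiser. And Gaussian
speed draws are used as magnitudes, $|x|$: cells do not move backwards, and
turn magnitudes are treated the same way.

To score a family against a tracked dataset, `synthesize_grouped_dataset()`
builds an artificial dataset with the *same observation structure*: one
group per track, each group initially filled with as many draws as the
longest track, then truncated so the multiset of group sizes equals the
per-track observation counts -- with the assignment of counts to groups
chosen so the Spearman correlation between group size and group median
matches the dataset's observed bias. The matching uses rank coupling:
groups sorted by their full-sample medians receive sorted counts through a
partially shuffled permutation; the shuffle fraction is tuned by bisection
(more shuffle pulls the correlation towards zero) until the achieved
correlation, measured on the truncated medians, is within 0.05 of the
target. Truncation itself discards uniformly random observations, keeping
the pooled marginal unbiased. In turn mode, each group's observations are
clamped at the maximum discernible turn speed for its sampling interval --
an angle larger than measurable aliases to the measurable maximum.

Fitting minimises the two-sample Kolmogorov--Smirnov (KS) statistic between
the dataset's pooled speeds and the synthetic pooled speeds, over the
family's parameters. Three numerical choices matter:

* The objective is stochastic, so each fit fixes an internal seed (common
  random numbers) and the optimiser sees a deterministic surface; the five
  independent fits of the standard protocol use five distinct seeds.
* The search is the derivative-free Nelder--Mead simplex (Brent's method
  for one-parameter families), started from method-of-moments values with
  data-driven box constraints enforced by penalty. The KS surface is
  piecewise constant and non-smooth, which rules out gradient methods.
* The pooled-fitting objective synthesizes *without* the correlation
  matching step: truncation is uniformly random, so the pooled marginal
  distribution is invariant to which group receives which count, and
  skipping the matching makes each objective evaluation much cheaper.
  Correlation matching is applied in full wherever group medians are
  consumed.

After each fit, 100 bias-matched datasets are generated from the fitted
family and the KS between their group medians and the dataset's per-track
medians is recorded; 5 fits × 100 datasets give 500 values per family. A
family that cannot express track-to-track heterogeneity fits the pooled
data perfectly well but fails this median-capture stage -- that is the
entire point of the framework.

One honest caveat: the pooled KS objective only weakly identifies *how*
spread divides between the two levels of the heterogeneous hierarchy, so
the method-of-moments start determines which basin a fit explores. On data
generated homogeneously, the heterogeneous family therefore scores somewhat
worse at median capture than the homogeneous family (it retains its
start's heterogeneity), rather than exactly matching it. The framework
consequently never *falsely* prefers heterogeneity; the package's tests
assert exactly this directional form.

## The six walker models

All models share the state of a cell: a position and a unit heading.

* **Brownian motion** (1 parameter): every step, a fresh orientation
  uniform on the sphere and speed $|G(0, \sigma)|$.
* **Lévy walk** (4): straight runs at speed $s \sim L(\alpha_T, \beta_T)$
  for duration $d \sim L(\alpha_D, \beta_D)$, with uniform reorientation
  between runs. Internal state advances every 3 s (runs can be much
  shorter than a recording interval); recording still happens at the
  preset interval. Run speed is redrawn with each new run.
* **HomoCRW** (4): each step draws a turn speed
  $\phi \sim G(\mu_P, \sigma_P)$; the angle $|\phi| \cdot \Delta t/60$ is
  applied about a uniformly random axis perpendicular to the current
  heading (so successive turn planes are uncorrelated), then the cell
  advances at $\zeta = |G(\mu_T, \sigma_T)|$.
* **HeteroCRW** (8): as HomoCRW, but each cell's two Gaussians are bespoke,
  drawn once at creation from hyper-Gaussians.
* **IHomoCRW** (5) and **IHeteroCRW** (9): as their parents, but the drawn
  turn speed is scaled by $(\zeta_{max}^\beta - \zeta^\beta) /
  \zeta_{max}^\beta$ with $\zeta$ the current translational speed --
  fast-translating cells turn slowly. $\zeta_{max}$ is fixed at 25 µm/min,
  the empirical in vivo maximum. $\beta = 1$ is linear scaling; larger
  $\beta$ tolerates higher speeds before suppressing turns. A speed drawn
  above $\zeta_{max}$ would make the factor negative, so it is clamped at
  $\zeta_{max}$ inside the factor only (the translation itself is not
  clamped).

Two conventions the equations leave open: Gaussian turn draws may be
negative, and the rotation uses $|\phi|$ (the random rotation axis already
randomises turn direction); and the rotation axis is built by Gram--Schmidt
orthogonalisation of an isotropic Gaussian vector against the heading,
which makes the axis uniform on the perpendicular circle.

## The arena and its observation process

Cells are non-overlapping spheres (default radius 5 µm) in a continuous 3D
domain: the 412 × 412 × 100 µm tracked volume plus a 50 µm margin on every
face, so cells can exit and re-enter the imaged region. T-cell simulations
update and record every 30 s for 30 min; neutrophil simulations every 45 s
for 50 min. Proposed moves are truncated at first sphere contact (cells
processed in an order reshuffled each step); domain boundaries reflect.
Positions are recorded only while a cell is inside the tracked volume; a
cell leaving the volume closes its track and re-entry opens a *new* track
id, exactly as an imaging pipeline -- which cannot re-identify a returning
cell -- would see it.

The margin size, boundary rule, cell count (default 200 per replicate) and
radius are simulation-infrastructure choices: calibration compares
distributions, not counts, so the cell count trades Monte-Carlo variance
against runtime. Candidate evaluation pools 10 replicate simulations by
default.

This observation process is what makes heterogeneous-model ensembles
reproduce the in vivo bias signature -- negative Spearman correlation
between a track's observation count and its median translational speed,
positive with its median turn speed -- without any of it being imposed on
the recorded tracks directly.

## Calibration and model comparison

`nsga2_calibrate()` splits the target's tracks once (seeded) into 70%
training / 30% validation, builds both motility profiles, and evolves
candidate gene vectors with NSGA-II: non-dominated sorting with
crowding-distance truncation (elitist), binary-tournament parent
selection, blended (BLX-style, blend 0.1) crossover and Gaussian mutation
(SD 5% of each gene's box width, rate 1/genes) inside biologically scaled
gene bounds. Each candidate is scored by running a replicate ensemble and
taking the KS distance between simulated and target distributions on the
three objectives. Every evaluated candidate updates both a training and a
validation Pareto front; selection pressure comes from training scores
alone. The per-generation over-fitting metric is the fraction of
training-front members absent from the validation front (by candidate
identity -- floating-point-safe), and calibration halts early if it
exceeds 0.8. Population sizes scale with model arity: 20 (Brownian), 50
(Lévy, HomoCRW), 60 (IHomoCRW), 80 (HeteroCRW), 100 (IHeteroCRW), for up
to 40 generations; three independent calibrations per model are merged
(and re-filtered for dominance) into one overarching front.

Model comparison (`compare_models()`) runs three complementary analyses:
the full matrix of non-domination percentages with front sizes; the
distributions of each front's best (lowest) 30 Λ values, where
$\Lambda(m) = \alpha\,\overline{KS}(m)^2 + \sum_o (KS_o(m) -
\overline{KS}(m))^2$ with $\alpha = 1$ selects balanced centre-of-front
solutions; and per-objective KS-score distributions. Pairwise KS contrasts
are masked where p > 0.01. Λ values are only comparable under a common
$\alpha$, which is stored with every report. Exactly equal objective
vectors are mutually non-dominating and duplicates are retained on fronts,
so reported front sizes are not silently deflated.

An MSD-slope calibration variant replaces the meandering-index objective
with the absolute difference of MSD log--log regression slopes. Because
that objective is not a KS statistic, mixing it into a mean is
meaningless, and `lambda_score()` refuses MSD-mode objective vectors.

## Synthetic reference data

No tracked leukocyte data ship with the package; `fixture_preset()` +
`generate_reference_dataset()` generate datasets with the *structure* of
in vivo exports: hundreds of tracks (751 track and 1017 track presets at
30 s and 45 s sampling), tens of observations per track, finite-volume
censoring, and -- under the default inverse heterogeneous CRW generator --
the bias signature and negative speed/turn coupling of real data. The
default generator parameters (turn hyperpriors around 110 ± 45 °/min,
speed hyperpriors around 10 ± 4 µm/min, β = 2) were picked once to land
pooled speed medians in the leukocyte-plausible 5--15 µm/min range; they
are demonstration values, not estimates of any real cell population, and
the generator makes no attempt to mimic unpublished in vivo distributions
quantitatively. Fixture data are therefore fit for exercising and testing
every stage of the pipeline, but passing tests on them says nothing about
which model real cells follow.

## Problem sizes used by the test suite

The packaged tests and the acceptance script run the full protocol at
reduced scale, chosen so the complete suite runs in minutes on one core:
arenas of 15--100 cells for 15--60 recording intervals, 2--8 replicates
per ensemble, calibrations of 6--15 generations with populations of 6--24
(Brownian recovery uses the full population of 20), and 60-group fitting
targets. The full-scale protocol -- arity-scaled populations of 20--100,
40 generations, 10 replicates per evaluation, three runs per model --
remains the package default in `calibration_config()` and is what a real
analysis should use.

## Known limitations

* Nothing upstream of the track table is modelled: no spot detection,
  drift correction or track linking.
* Cells are featureless spheres; environmental structure (reticular
  networks, obstacles) and explicit morphology are out of scope, as are
  hybrid Lévy/CRW formulations.
* The heterogeneous-vs-homogeneous decision rests on the median-capture
  stage, not on pooled fits (see the caveat above).
* Pareto-front comparisons are relative to the models calibrated; they
  rank candidates, they do not certify that any candidate is "the" true
  model.
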