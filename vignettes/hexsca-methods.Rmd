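---
title: "Dispersal on hexagonal lattices: model, statistics and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dispersal on hexagonal lattices: model, statistics and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexsca)
```

`hexsca` simulates the spatial spread of a tree-killing insect population —
the motivating case is mountain pine beetle (MPB) outbreaks — with a
stochastic cellular automaton (SCA) on a hexagonal lattice, coupled to a
per-cell stochastic birth–death process. This vignette is the package's own
account of the model: the update rules and their assumptions, the
parameters and defaults, the numerical and design choices that were
genuinely open, and what the test suite does and does not establish.

## The macroscale automaton

The landscape is an `m × n` partition into flat-top hexagonal cells; cell
states are normalized densities $\pi_{ij}(t) \in [0,1]$ (0 = empty, 1 = at
carrying capacity). Hexagons are used because centroid spacing is identical
in all six directions, which removes the directional bias a square grid
imprints on spreading patterns. The package fixes a 1-based offset
convention in which even columns are shifted up half a cell; the six
neighbours of a cell are returned in a fixed cyclic order
(`moore_neighbors()`), off-grid positions materialize as *auxiliary* cells,
and `hex_distance()` is the shortest-path lattice metric computed through
cube coordinates.

Dispersal happens inside *interaction neighbourhoods*: maximal groups of
affected (positive-density) cells separated by at most two unaffected
cells, together with all their immediate unaffected neighbours (the halo).
`find_interaction_neighbourhoods()` implements the grouping metrically —
affected cells join the same neighbourhood when connected under pairwise
`hex_distance <= 3` — which the package computes exactly as the
hex-adjacency connected components of the affected mask dilated by one
step (two radius-1 disks contain adjacent cells precisely when their
centres are at distance three or less). The mask is padded so connections
routed through off-grid positions are honoured, since the metric lives on
the infinite lattice.

One macro step (`macro_step()`) runs four stages independently in every
neighbourhood:

1. **Inclusion.** Every member cell receives a Bernoulli draw with
   probability
   $p_I = \left[\frac{w^{\alpha}}{1+w^{\alpha}}\, d\right]^{\beta}$,
   where $w$ counts adjacent affected cells (+1 if the cell itself is
   affected) and $d$ is the maximum absolute density difference with its
   six neighbours. With the default $\alpha=\beta=1$ an isolated affected
   cell is included with probability half its density.
2. **Partition and pooling.** Included cells at or above the included-cell
   mean $\bar\pi$ are *contributors*; each donates
   $\gamma_1(\pi - \bar\pi)$ to the pool $\tilde\pi$. The tie convention
   $\pi \ge \bar\pi$ follows the update formula rather than the prose
   ("higher than"): ties contribute zero and still receive a share, which
   keeps the two readings numerically identical.
3. **Redistribution and survival.** Each of the $H+K$ included cells is
   allocated $\tilde\pi/(H+K)$; a fraction $1-\gamma_2$ is lost in
   transit. Non-contributing recipients must additionally pass a
   colonization draw with probability
   $p_S = \phi + \rho\,\arctan(\xi\,\pi)$; on failure the cell's density
   is removed entirely (or scaled by an optional retention factor).
4. **Boundary absorption.** Auxiliary cells take part in inclusion as
   zero-density cells, count in $H+K$, and any share they receive leaves
   the system (absorbing boundary). No survival draw is made for them
   because the share is removed either way.

Two readings of $p_S$'s density argument are defensible: the defining
formula evaluates it at the current density $\pi_{ij}(t)$, while the
printed single-cell worked update evaluates the arctangent at the incoming
share. The package defaults to the *prospective* density (current plus
incoming share), which reproduces the worked update exactly and reduces to
the formula for occupied cells receiving small shares; `ps_at = "current"`
selects the literal reading.

Every step keeps an exact mass ledger:
$\sum\pi(t{+}1) - \sum\pi(t) + (1-\gamma_2)\tilde\pi + \text{zeroed} +
\text{absorbed} = 0$ to machine precision, where *zeroed* is the
prospective density (prior plus allocated share) removed by failed
colonization draws and *absorbed* is the mass taken by auxiliary cells.
Post-step densities remain in $[0,1]$ by the update algebra alone — no
clipping — provided $\gamma_1$ is homogeneous within a neighbourhood; with
strongly heterogeneous per-cell $\gamma_1$ rasters the bound can fail, and
the step then stops with an error rather than silently clipping.

Each neighbourhood consumes an RNG substream derived from
`(seed, t, neighbourhood id)`, the id being the smallest column-major index
among its affected cells. The update is therefore block-diagonal in a
strong sense: a neighbourhood's outcome is bit-identical whether or not
other neighbourhoods exist on the grid, which the suite verifies by
equality of fields.

## The microscale model and the coupling

Within-cell population dynamics is a discrete-time birth–death chain on
$\{0,\dots,C\}$ with logistic births $b_n = n\,b\,(1-n/C)$ and linear
deaths $d_n = d\,n$, simulated with per-micro-step probabilities
$b_n\Delta\tau$ and $d_n\Delta\tau$, $\Delta\tau = 1/N$. The configuration
is validated against $\max_n (b_n+d_n)\Delta\tau \le 1$. State 0 is
absorbing: there is no immigration at the microscale, so empty cells stay
empty until dispersal reaches them.

The coupling is sequential, one handshake per macro step: at macro time
$t-1$ each positive cell seeds $M$ replicate chains at
$X(0) = \operatorname{round}(\pi C)$ (ties to even — the integerization is
unspecified in the source formulation), the chains run for $N$ micro steps
(one unit of macro time), and the cell density is replaced by the
replicate mean over $C$. Then one dispersal step advances the field to
$t$. Iterated alternatives (multiple handshakes per step) are reported in
the source literature not to change results materially and are not
implemented.

A point worth stating explicitly because it is easy to misread: a *single*
coupling spans unit time, over which the deterministic drift
$n \mapsto n + (b_n - d_n)\Delta\tau$ carries $X(0)=50$ only to about 63
for the default rates; the logistic fixed point $C(1-d/b) = 80$ is reached
under *iterated* coupling, in roughly five to ten macro steps. The test
suite checks both facts — single-coupling agreement with the
deterministic-recursion oracle, and quasi-stationary agreement with the
fixed point (10 unit-time blocks, a horizon chosen from that drift
analysis).

Annual forcing enters as multiplicative schedules on `b` and `d`:
`bd_schedule("sinusoidal", period = 20)` gives the cycle
$b_n(1 + \sin(2\pi t/T))$ with a 20-step year; `"endemic"` and
`"epidemic"` are stylized step-function years (births exceeding deaths
only in a short summer window, versus all year). The endemic/epidemic
shapes are stated in the source only graphically, so these presets are
declared approximations; their exact levels are documented in
`?bd_schedule` and overridable by passing any function of `t`.

## Pattern statistics

`pattern_summary()` and friends quantify snapshots:

* **Boundary complexity**, by two provably identical definitions: boundary
  edges (edges of affected cells whose opposite cell is not affected,
  domain exterior included) divided by the affected count $N_a$, and
  $(6N_a - \sum_a n_a)/N_a$ with $n_a$ the affected-neighbour count. The
  identity `6*Na - 2*adjacencies = boundary edges` is exercised on random
  patterns against a pairwise-distance oracle. A single cell scores 6;
  smooth large blobs score below 1.
* **Equal-area radius and centre of mass**: $r = \sqrt{N_a/\pi}$ with unit
  cell area (physical rescaling is the caller's concern), and the
  density-weighted centroid mean.
* **Dispersion rate**: first differences of the radius per interaction
  neighbourhood, tracked across time by maximal overlap of affected sets;
  a merged neighbourhood continues the larger parent's series.
* **Calibration statistics** (1)–(4): time-averaged affected count,
  time-averaged mean density *over affected cells* (the whole-grid average
  is just a rescaled affected count, so the affected-cell average carries
  independent information), time-averaged complexity, and the slope of a
  least-squares line through log complexity versus time. The log fit is
  used for all regimes for calibration consistency, even where a raw-scale
  fit would also be defensible.

Under the base parameter setting (`sca_params()` defaults plus
`bd_spec()` defaults, Table-style values $\gamma_1=\gamma_2=0.8$,
$\phi=\rho=1/3$, $b=1$, $d=0.2$, $C=N=100$, $M=20$), a single seed cell
grows into a roughly elliptical ragged patch that reaches the boundary of
a 50 × 50 grid after about 150 steps. Log complexity of the established
pattern decays linearly. The acceptance check fits the decay over the
window where mean complexity has fallen to $e^{0.71} \approx 2$ — the
level at which the reference fit's own intercept starts — because a
single-seed run spends its first ~30 steps in a transient (complexity 6
down to 2) that no linear fit should include; for a linearly growing
pattern the log-complexity slope over a window $[t_0, t_1]$ is
$-(\ln t_1 - \ln t_0)/(t_1 - t_0)$, so the fitted value depends on the
maturity of the pattern at the window start, and the reference value
$-0.01$ corresponds to a pattern roughly 40 steps old at the fit origin.

## Calibration

The calibration problem treats `(gamma1, phi)` as unknown on a box
$\Lambda$, holding $\gamma_2 = 0.8$ and $\rho = 1/3$ fixed — $\gamma_2$
and $\phi$ act near-identically on the dispersal statistics (both scale
the success of colonization), so they are not jointly identifiable, and
$\rho$ is much less influential than $\phi$. The forward map $Q(\lambda)$
is the expected statistic, estimated by averaging `R` replicate multiscale
runs of 30 macro steps from a standard initial pattern: a single cell of
density 0.5 at the centre of a 30 × 30 grid. The initial pattern is not
stated in the source and is recorded here (and in every run manifest) as
the package's declared choice. Defaults: $\gamma_1 \in [0.4, 1]$ and
$\phi \in [1/6,\, 1 - \rho\arctan\xi \approx 0.738]$ — the upper $\phi$
bound is the largest value for which the survival probability stays a
probability, which also caps any nominal $[1/6, 5/6]$ range.

The solution follows the consistent-Bayes (stochastic inverse problem)
construction with the non-informative uniform-ansatz prior: draw
`n_prior` parameter samples uniformly on $\Lambda$, push them through $Q$,
estimate the pushforward density and the observed-data density (Gaussian
kernels, Silverman bandwidth — appropriate at the ≤ 10³ sample sizes used
here), and weight each prior sample by the ratio of observed to
pushforward density at its forward value. By construction the posterior's
pushforward matches the observed-data distribution, and when the two
densities coincide the posterior *is* the prior — both facts are tested,
the first on the analytic toy map $Q(\lambda)=\gamma_1^2$ via a
Kolmogorov–Smirnov comparison, the second exactly (equal weights to
$10^{-14}$). Observations landing where the pushforward density is
numerically zero indicate a support mismatch and are dropped with a
warning rather than producing unstable weights.

Observation models: `synthetic_observations()` draws parameters from a
normal data-generating distribution (default $N((0.7, 1/3)^\top, 0.05^2)$,
truncated to $\Lambda$ by rejection) and averages `reps` runs per draw;
`noisy_observations()` adds $N(0, \sigma^2)$ noise to a single forward
value, with a user-supplied $\sigma$ (the source states the noisy-data
model with a fixed covariance but no value). `image_to_density()`
reproduces the survey-image pipeline: 256 grey levels, nearest-neighbour
resampling to the target grid, division by 256, zeroing below the 0.8
threshold, then $N(0, 0.2^2)$ noise on positive cells and $N(0, 0.6^2)$
on zero cells hex-adjacent to a positive cell, clamped to $[0,1]$. PNG
input (and bare matrices) are supported; the posterior heatmaps over all
1000 × 50 full-scale runs and the real survey analysis itself are outside
desk scale and out of scope.

At desk scale (100 observations × 10 replicate runs, 200 prior samples ×
2 runs, statistic (1)) the posterior reproduces the qualitative structure
reported at full scale: a ridge parallel to the $\gamma_1$ axis (no
resolution of $\gamma_1$ beyond its range — its marginal stays within
twice the uniform level) and a sharply peaked $\phi$ marginal with mode
within 0.1 of the generating value $1/3$.

## Problem sizes, determinism, and what the tests show

The suite's simulation scales — a 50 × 50 grid for 150 steps averaged
over 10 runs for the complexity-decay check, 30 × 30/30-step runs for
calibration, $10^4$ randomized single-step configurations for the mass
ledger, $10^3$ random patterns for the complexity-identity check — are the
package's chosen desk-scale study sizes; the corresponding full-scale
settings (1000 parameter samples × 50 runs) are documented but not run in
tests. All randomness flows from user seeds through deterministic
per-neighbourhood and per-coupling substreams, so identical manifests
yield byte-identical outputs, verified by rerunning a simulation from its
own written manifest.

What passing tests do *not* show: the synthetic fixtures emulate
homogeneous landscapes with at most simple barrier/wind structure, the
birth–death process is the only microscale model exercised, and
image-based calibration is validated on synthetic PNGs whose noiseless
round-trip is exact — none of which establishes fidelity to any particular
real outbreak. Known limitations: per-cell heterogeneous $C$, $N$, $M$
are not implemented (the generalization is mentioned in the source but
never exercised); hex distance and grouping assume the infinite-lattice
metric, so two blobs may be grouped through an off-grid route; and
`gamma1` rasters that vary strongly *within* a neighbourhood can violate
the no-clipping boundedness guarantee, which the step reports as an error.
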