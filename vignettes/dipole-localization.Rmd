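---
title: "Equivalent-dipole localization in a hemispherical head model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equivalent-dipole localization in a hemispherical head model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dipolefit)
```

## The problem

Localized neural activity recorded at the scalp is classically summarized by
equivalent current dipoles: point sources characterized by a position
$\ell \in \mathbb{R}^3$, a unit orientation $\mu$, and a moment magnitude
$s$. `dipolefit` addresses the two halves of that picture for a simplified,
phenomenological head model:

* the **forward problem** — synthesize the potentials an electrode array
  would record from a known set of dipoles, and
* the **inverse problem** — recover each dipole's seven parameters
  $p = (\ell_x, \ell_y, \ell_z, \mu_x, \mu_y, \mu_z, s)$ from a recorded
  multichannel signal matrix by constrained nonlinear least squares.

The head is a hemisphere of radius $r$ (default 10 cm; an 85 mm variant
matches the standard 64-channel montage comparisons), with the flat face at
$z = 0$, $+y$ through the nasion, $+x$ through the right ear. Dipoles live
strictly inside the hemisphere; electrodes sit on the curved surface.

## Forward model

The potential of dipole $i$ at sensor $j$ uses the inverse-square
(Biot–Savart-like) gain

$$ g_{j,i} = \frac{1}{4\pi\,\zeta_{j,i}} \cdot \frac{w_j - \ell_i}{d_{j,i}^3}, \qquad
   d_{j,i} = \lVert w_j - \ell_i \rVert , $$

where $w_j$ is the sensor position and $\zeta_{j,i}$ an *effective per-path
conductivity*. Because the signal from a given source to a given electrode
traverses a fixed but unknown stack of tissues (soft matter, spongy and
compact bone, skin), $\zeta_{j,i}$ is drawn once per (sensor, dipole) pair,
i.i.d. uniform on a configured range (default $U(0.1, 0.9)$), and held fixed
for the whole recording. Only the measurement noise varies across time
samples; this is the only reading under which longer recordings improve the
estimates.

Proximity additionally modulates received signal strength (RSS) through a
linear attenuation line

$$ \rho(d) = \beta - \alpha d, \qquad \rho(0) = 1, \quad \rho(2r) = 0.01 , $$

so $\beta = 1$ and $\alpha = 0.99 / (2r)$: a source directly under an
electrode is picked up at full strength, a source a full head diameter away
at 1%. The noiseless mean at sensor $j$ superposes all dipoles,

$$ \bar F_j = \sum_i \rho_{j,i}\, s_i \, g_{j,i}^\top \mu_i , $$

and each of the $N$ recorded columns adds i.i.d. Gaussian noise
$\mathcal{N}(0, \sigma^2)$, homoscedastic across sensors. $\sigma$ may be
given directly or derived from a target signal-to-noise ratio, defined as
the power ratio averaged over sensors:
$\mathrm{SNR} = \operatorname{mean}_j \bar F_j^2 / \sigma^2$. Dipoles are
fixed in position, orientation and magnitude over a recording.

Units are carried as tags only (lengths cm, signals µV, strength "A.cm");
no dimensional conversions are attempted.

## Inverse problem and solver

With $W$ a symmetric weight matrix (identity by default), the fit minimizes

$$ J = \tfrac{1}{2} \sum_{k=1}^{N} \big(F_{\cdot k} - \hat F\big)^\top W
       \big(F_{\cdot k} - \hat F\big)
  \quad \text{s.t.} \quad \lVert \hat\mu_i \rVert_2 = 1 \;\; \forall i , $$

where $\hat F$ is the candidate noiseless prediction. Summing over columns
is equivalent to a weighted fit of $\hat F$ against the row means, which the
implementation exploits. The 4-parameter orientation representation (unit
$\mu$ plus scalar $s \ge 0$) is kept with an explicit equality constraint;
constraining $s \ge 0$ removes the $(\mu, s) \leftrightarrow (-\mu, -s)$
sign ambiguity.

The constrained problem is solved by an augmented-Lagrangian scheme: each
outer round minimizes $J + \sum_i \lambda_i c_i + \tfrac{\rho}{2} c_i^2$
(with $c_i = \mu_i^\top\mu_i - 1$) by bounded L-BFGS with analytic
gradients, then updates the multipliers; the returned point satisfies the
first-order KKT conditions within the configured tolerances. A soft
quadratic penalty keeps candidate locations inside 97% of the head radius,
away from the scalp singularity. The optimizer works on the objective
scaled by the cost of predicting zero signal, so line searches behave
identically across the huge dynamic range of signal magnitudes the
$1/d^3$ gain produces.

### Multimodality, variable projection, and starts

The residual cost is multimodal in the locations: plain descent from a
distant guess reliably stalls in degenerate minima in which one dipole's
strength collapses to zero while its location stays near the guess — we
observed this even on noiseless data. The solver therefore exploits the
model's partial linearity: given locations, the moment vectors $v_i = s_i
\mu_i$ solve a weighted *linear* least squares exactly (variable
projection), and by the envelope theorem the profiled cost's gradient with
respect to the locations is the location block of the full gradient at the
solved moments. Every starting point is first refined by this
locations-only search, then polished by the full constrained solve (one
extra alternation round runs when it improves the cost).

Starts are: the user-supplied initial guess when given; `multistart` seeded
latin-hypercube location draws inside the head (default 8); and a
deterministic greedy initialization that adds one dipole at a time by
scanning a coarse interior grid with joint moment re-solves. In
"clairvoyant" mode (below) the per-path conductivity draws are tied to
dipole slots, so slot permutations of the greedy locations are tried as
separate starts. The best-cost KKT point over all starts is returned, with
the cost trace of its winning start.

Dipole correspondence for error reporting uses minimal-total-distance
assignment over permutations, since the cost is invariant to relabeling.

### Fitting-mode conductivity

The fitter cannot know the generator's random $\zeta_{j,i}$ draws on real
data. Two modes are provided:

* `"expected"` (default): every path's conductivity is fixed at the
  midpoint of the configured range, and the attenuation line is evaluated
  on the candidate geometry. This is the only model realizable in practice.
* `"clairvoyant"`: the true per-path draws stored with a synthetic
  recording are reused, making the fitted model identical to the
  generating one. This mode exists for verification: estimation error then
  reflects measurement noise alone.

The gap between the modes is large and instructive. Conductivity mismatch
acts as heavy multiplicative perturbation per sensor (the per-path gain
factor $0.5/\zeta$ has a coefficient of variation near 0.7 for the default
range), and it, not the additive noise, dominates expected-mode error: on
the bundled 85 mm benchmark the test suite computes sub-half-millimeter
single-source localization in clairvoyant mode and an expected-mode error
more than an order of magnitude larger on the same recording.

## Benchmark scenarios and identifiability

`make_fixture()` ships three scenarios: a three-dipole benchmark at three
depths inside the 10 cm head observed by 36 uniform-random electrodes (250
samples, SNR 20), the same trio transplanted into an 85 mm head observed by
the standard 64-channel montage, and a noiseless single-dipole scenario for
exactness tests. The 85 mm table publishes only locations; the fixture
reuses the first scenario's orientations and strengths, a package choice.

A central empirical finding, documented by the benchmark suite: the
three-dipole scenario is **nearly collinear with nearly parallel
orientations**, and its *joint* fit at SNR 20 is not identifiable at
sub-millimeter accuracy. The converged least-squares optimum lies
centimeters from the generating configuration — and has *lower* cost than
the truth, so this is a property of the estimation problem, not of the
optimizer; it persists at one hundred times the benchmark SNR. Two of the
benchmark blocks in `tests/testthat/test-acceptance.R` assert the
literature working point (two-decimal recovery; median joint-fit error
below 0.1% of head diameter) and fail for this reason; they are kept
failing deliberately, as an executable record of the discrepancy. Single
-source fits at the same conditions are well identified (location error
$\sim 10^{-2}$ cm), which is also why the sensitivity study below is
per-source.

## Sensitivity study

`run_sweep()` reproduces the Monte-Carlo protocol over a grid of (sensor
count, sample count) cells. For each cell and repeat a fresh uniform-random
montage is drawn, and each scenario dipole is studied in its own
single-source simulation, re-fitted from a perturbed initial guess (truth
shifted 1 cm in a seeded random direction, orientation tilted by 0.3 and
renormalized, strength scaled 1.5x). One absolute noise level per repeat is
derived from the *whole* scenario's signal power at the target SNR and
applied to every single-source recording, so deeper, weaker sources face
proportionally more noise — the mechanism behind the depth effect (deeper
source, weaker signals, larger error) that `depth_effect_report()` ranks.
Setting `joint = TRUE` instead simulates and fits all dipoles
simultaneously.

Per-parameter errors are reported as percentages, $100\,|\hat\theta -
\theta| / |\theta|$, with fallback scales where the truth is near zero (the
head radius for location coordinates, 1 for orientation components and
strength); a dipole's "total" error is the unweighted mean over its seven
parameters. Cell aggregates carry normal-approximation 95% confidence
intervals over repeats; `find_optimum()` returns the argmin cell, breaking
ties toward fewer sensors, then fewer samples. All cell/repeat seeds derive
from `base_seed` by counter, so sweeps are exactly reproducible.

## Numerical choices

* Tolerances: inner projected-gradient 1e-8 (on the scaled objective),
  constraint $|\,\lVert\mu\rVert - 1\,| \le$ 1e-6, at most 500 inner
  iterations per outer round, at most 40 outer rounds.
* Bounds: location coordinates within the head box with $z \ge 0$ and a
  soft ball constraint at 97% of the radius; $|\mu$ components$| \le 1.5$
  during iteration (the constraint pins the norm at the solution);
  $0 \le s \le$ `s_max` (default 10).
* Degenerate inputs: a candidate or dipole coinciding with a sensor is a
  singularity error in the gain construction; evaluation inside the
  optimizer clamps distances and returns a large cost so line searches back
  off. Source-free recordings are allowed (flagged) for noise-only studies;
  a target SNR is undefined there and rejected.
* Ties and ambiguities: dipole matching by minimal total distance;
  `find_optimum()` prefers the cheaper experiment on ties; the sign
  ambiguity is removed by $s \ge 0$.
* Problem sizes in the shipped tests are chosen to keep the default suite
  in the minutes range: sweeps use 6–10 repeats per cell on coarse grids;
  Monte-Carlo blocks use 20 repeats; exactness tests use 5–150 samples.

## What the generator does and does not emulate

The simulator reproduces the statistical structure the estimator assumes:
fixed sources, per-path random conductivity, linear RSS attenuation,
homoscedastic Gaussian noise. Real EEG violates most of this: sources have
temporal dynamics and spectra, conductivity is structured (layered tissue,
anisotropy) rather than i.i.d. across paths, noise is colored and spatially
correlated (artifacts, reference choices), electrode positions carry error,
and real heads are not hemispheres. Passing tests therefore demonstrate
correctness and statistical efficiency *within this model family*, not
clinical-grade localization. In particular the clairvoyant mode has no
real-data counterpart; expected-mode results are the honest proxy for
practical accuracy under conductivity uncertainty.

## Known limitations

* Single-shell hemisphere only; no BEM/FEM, no layered or anisotropic
  conductivity, no realistic surface meshes.
* Constant source moments; no time-varying waveforms, no moving dipoles,
  no model-order selection (the number of dipoles is user-supplied).
* No subspace scanning (MUSIC-family) or minimum-norm imaging solvers.
* The joint multi-dipole fit inherits the identifiability limits described
  above; for closely spaced, similarly oriented sources the per-source
  protocol or stronger priors are required.
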