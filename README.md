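# dipolefit

Multi-dipole EEG source localization in a hemispherical head model:
a forward simulator for scalp EEG-like signals and a constrained nonlinear
least-squares inverse solver that recovers each source's position, unit
orientation, and strength.

## Who this is for

Researchers studying the *estimation* side of EEG source localization —
how sensor count, sample count, noise level, source depth, and conductivity
uncertainty limit the accuracy of equivalent-current-dipole fitting —
using a transparent, fully reproducible phenomenological model rather than
a heavyweight BEM/FEM pipeline.

## The model in brief

An equivalent current dipole is the 7-parameter vector
p = (lx, ly, lz, mux, muy, muz, s) with ||mu|| = 1 and s >= 0, inside a
hemispherical head of radius r (flat face at z = 0, +y nasion, +x right
ear). Sensor j sees dipole i through an inverse-square gain

    g_ji = (w_j - l_i) / (4 * pi * zeta_ji * d_ji^3),

with a per-path conductivity zeta_ji drawn once per (sensor, dipole) pair
from U(low, high), times a linear received-signal-strength attenuation
rho(d) = beta - alpha*d pinned at rho(0) = 1 and rho(2r) = 0.01. Sensor
means superpose all dipoles; each time sample adds i.i.d. Gaussian noise,
scaled to a target signal-to-noise power ratio. The inverse solver
minimizes the weighted L2 residual of the measured matrix against the
model prediction subject to the unit-norm orientation constraints
(augmented-Lagrangian KKT solve with analytic gradients, preceded by a
variable-projection search over locations). See the methods vignette
(`vignettes/dipole-localization.Rmd`) for the full account, including the
identifiability analysis of the bundled three-dipole benchmark.

## Worked example

Simulate one dipole of the 85 mm-head benchmark under the standard
64-channel montage and localize it with the model-consistent
("clairvoyant") verification mode:

```r
library(dipolefit)

fx  <- make_fixture("table2", seed = 1)
rec <- simulate_recording(list(fx$dipoles[[1]]), fx$sensors, fx$head,
                          n_samples = 250, noise_model(target_snr = 20),
                          seed = 42)
rec
#> EEG recording: 64 sensors x 250 samples (synthetic, 1 dipole)
snr_of(rec)
#> [1] 20.0

fit <- fit_dipoles(rec, 1, solver_config(mode = "clairvoyant"))
fit
#> Dipole fit (1 dipole, clairvoyant conductivity mode)
#>          lx     ly     lz    mux    muy    muz      s
#> [1,] 0.9102 3.2035 3.8463 0.3174 0.1183 0.9409 0.1003
#> final cost J = 1.13663e-05; converged: KKT point within tolerances
#> localization error (cm): 0.00852
```

The true source sits at (0.911, 3.207, 3.854) cm with strength 0.1: the
fit lands 0.085 mm away and recovers the strength to 0.0003. The reported
cost is the weighted residual J at the solution; `localization error` is
the Euclidean distance between true and estimated locations (available
because the synthetic recording carries its generating truth). Replacing
`"clairvoyant"` with the default `"expected"` mode — the only mode
realizable on real data, where the per-path conductivities are unknown —
moves the error to the centimeter scale, which is the honest picture of
conductivity uncertainty in this model family.

A sensitivity sweep over sensor and sample counts, and the command-line
interface (`simulate`, `fit`, `sweep`, `fixture` subcommands via
`dipole_cli()` or the installed `inst/cli/dipolefit` script), are
documented in the function reference and the vignette.

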