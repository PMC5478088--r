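# shadowtrack

Batch reconstruction of full phase-space trajectories — position,
velocity and acceleration — from noisy, gappy, irregularly sampled
position fixes, such as GPS telemetry logged by miniature trackers on
flying birds.

GPS devices record position only, at limited accuracy and with dropouts.
Movement ecologists, however, need velocity and especially acceleration
(the quantity that exposes the forces acting on the animal), and direct
numerical differentiation of noisy positions is notoriously unstable.
`shadowtrack` implements a *shadowing filter*: instead of sequentially
updating a state estimate (Kalman-style), it finds, in one batch solve,
the trajectory that is consistent with Newtonian mechanics over the whole
observation window and closest to all the data at once.

## The model

Observations are noisy positions `P_i` at strictly increasing times
`t_i` (`i = 0, …, n`, `T_i = t_{i+1} − t_i`), with observation-error
variances `σ_i²`.  The reconstruction assumes piecewise-constant
acceleration `a_i` on each interval, so the state obeys

    p_{i+1} = p_i + ν_i T_i + ½ a_i T_i²,      ν_{i+1} = ν_i + a_i T_i,

and minimizes the penalized least-squares objective

    J(p, ν, a) = ½ Σ_i σ_i⁻² (P_i − p_i)²  +  η Σ_i T_i a_i²

over all Newton-consistent trajectories.  The smoothing weight `η`
trades data fidelity against acceleration energy: `η → 0` interpolates
the observations, `η → ∞` collapses to the weighted straight-line fit.
The default solver eliminates the constraints (unknowns `p_0, ν_0, a`)
and solves the weighted linear least-squares system by singular value
decomposition with the minimum-norm convention; an independent KKT solver
for the full stationarity system of the Lagrangian is included as a
cross-check.  Multi-dimensional tracks are filtered as independent scalar
problems per coordinate.

Two routes choose `η`:

* `eta_from_noise(beta)` — the published scaling relation
  `η_b ≈ 0.046 β³ + 0.054` from the device noise variance `β` (m²),
  valid for high sampling rates;
* `optimize_eta()` — replicated simulation sweeps: generate noisy
  replicates of a known track, average the true-trajectory RMS error per
  weight, and repeatedly narrow the grid around the argmin.

`windowing_test()` / `min_window_length()` determine how much data the
filter needs by filtering suffixes of increasing length and measuring
convergence of the most recent state.  `baseline_filter()` provides the
classical sliding-average + finite-difference pipeline for comparison,
and the `synthetic_*` functions generate Newtonian ground-truth tracks
with GPS-like noise, dropouts, and decimation for benchmarking.

## Worked example

Simulate a circling flight (30 s at 0.2 s fixes, 0.4 m² GPS noise, 36%
of fixes lost), filter it at the noise-derived weight, and segment
flight phases:

```r
library(shadowtrack)

spec  <- synthetic_spec(duration = 30, dt = 0.2, accel_model = "circular",
                        noise_variance = 0.4, missing_fraction = 0.36, seed = 42)
truth <- simulate_true_track(spec)
obs   <- observe_track(truth, spec, drop_missing = TRUE)
obs
#> <observation_series> 97 samples, 2 coordinate(s) [x, y]
#>   t in [0.4, 30] s; 0 interpolated fix(es)

eta <- eta_from_noise(0.4)   # 0.056944
fit <- filter_track(obs, filter_config(eta))

idx <- match(round(obs$times, 9), round(truth$times, 9))
rms_error(obs$values, truth$positions[idx, ])   # raw:      0.932 m
rms_error(fit$positions, truth$positions[idx, ])# filtered: 0.475 m

speeds <- sqrt(rowSums(fit$velocities^2))
segment_flight(speeds)       # one run: samples 1..97 (always airborne)
```

Despite 36% dropout and an irregular grid, the filtered positions halve
the raw RMS error, and the fit delivers velocities and per-interval
accelerations with no post-hoc differentiation.

## Command line

A thin launcher over the same functions lives at `inst/cli/shadowtrack.R`
(after installation: `system.file("cli", "shadowtrack.R", package =
"shadowtrack")`):

```sh
Rscript shadowtrack.R simulate --duration 30 --noise 0.4 --missing 0.36 \
    --seed 42 --output obs.csv --truth truth.csv
Rscript shadowtrack.R track --input obs.csv --beta 0.4 --exclude-interpolated \
    --output fit.csv
Rscript shadowtrack.R sweep --input obs.csv --grid default --reference truth.csv \
    --output sweep.csv
Rscript shadowtrack.R window-test --input obs.csv --eta 0.05 \
    --lengths 10,20,40,60,80,100,150 --output windows.csv
Rscript shadowtrack.R baseline --input obs.csv --window 5 --output base.csv
```

Track CSVs use the header `t,x[,y[,z]][,signal]` (seconds / meters;
`signal` 1 = device-logged fix, 0 = interpolated).

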