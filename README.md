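# girsanov

Girsanov path reweighting for stochastic molecular dynamics, in R.

Enhanced-sampling simulations add a bias potential to cross energy barriers
faster, but the biased trajectories no longer carry the kinetics of the
molecule of interest. **Girsanov reweighting** recovers the unbiased
dynamics exactly: because a stochastic (Langevin) integrator turns a
sequence of Gaussian random numbers into a path, the probability of the
*same* path under a different potential differs only by a computable shift
of those random numbers, and the likelihood ratio can be accumulated on the
fly, step by step, while the simulation runs. This package implements the
whole chain for users who want to study or prototype the method on
low-dimensional systems:

* **Langevin splitting integrators** built from the A (position drift),
  B (force kick) and O (friction + noise) update operators — ABO, ABOBA,
  AOBOA, BOAOB, OBABO, equivalently the RVO alphabet — with the per-step
  reweighting increment recorded in the inner loop (compiled core plus a
  step-identical pure-R reference engine).
* **Path weights** over sliding windows. With target and simulation
  potential related by a perturbation, `Vtilde = V + U` (a bias enters as
  `U = -U_bias`), a window starting at frame *k'* has

  `log W = -U(q_k')/RT - sum_{j=k'+1}^{k'+n} dS_j`,

  where `dS_j` is the per-recording-interval sum of
  `eta * delta_eta + delta_eta^2 / 2` and the random-number difference
  `delta_eta` is the integrator-specific kernel (e.g.
  `d * dt * grad U / f` for ABO, with `d = exp(-xi dt)` and
  `f = sqrt(RT M (1 - d^2))`). All five schemes are certified against an
  independent one-step inversion oracle.
* **Reweighted Markov state models**: a sliding-window transition-count
  estimator that adds `exp(log W)` instead of 1 to each count, row
  normalisation over the active state set, left eigenvectors/eigenvalues,
  and implied timescales `t_i = -tau / ln |lambda_i|`. With unit weights it
  reduces bit-for-bit to the ordinary count matrix.
* **Benchmark studies**: the two-dimensional Müller–Brown surface with
  linear and polynomial biases, and a 1D double-well surrogate with a
  quadrature Boltzmann oracle, each comparing direct / biased-unreweighted /
  biased-reweighted estimates.

See `vignettes/path-reweighting-methods.Rmd` for the full account of the
model, the per-scheme formulas and every numerical convention.

## Worked example

Simulate the linearly biased Müller–Brown surface for 100 ps and build a
reweighted MSM at a 0.5 ps lag:

```r
library(girsanov)

pair   <- potential_pair(mueller_brown(),
                         bias = bias_potential("linear", k = 1, ndim = 2))
params <- langevin_params(dt = 5e-4, xi = 5, temperature = 300,
                          masses = c(1, 1))
traj   <- simulate_langevin(pair, "ABOBA", params, q0 = c(-0.5, 1.5),
                            n_steps = 2e5, n_out = 10, seed = 7)
traj
#> <langevin_trajectory> ABOBA, 20001 frames x 2 dof, frame spacing 0.005 ps, with reweighting records
head(traj$records, 3)
#>   frame_index time_ps          dS U_kJ_per_mol
#> 1           0   0.000  0.00000000    0.5000000
#> 2           1   0.005 -0.01651723    0.4817374
#> 3           2   0.010 -0.01441169    0.4615148

grid  <- grid_discretization(c(-3.5, -1.5), c(1.5, 3.5), c(6, 6))
dtraj <- discretize(traj$q, grid)
lw    <- window_log_weights(traj, n_interval = 100)   # 0.5 ps windows
msm   <- msm_estimate(dtraj, lag = 100, n_states = grid$n_states,
                      log_weights = list(lw$log_w))
round(Re(msm$spectral$values[1:4]), 4)
#> [1]  1.0000  0.9511  0.4322 -0.1316
round(implied_timescales(msm$spectral$values, 0.5)[1:3], 2)
#> [1] 9.98 0.60 0.25
effective_sample_size(lw$log_w) / nrow(lw)
#> [1] 0.932
```

Reading the output: each record holds the log-weight increment `dS`
accumulated over the 10 integrator steps ending at that frame (the first
record is 0 by construction) and the perturbation energy of the frame, here
`-1 * x` for the linear bias at k = 1 kJ/mol/nm. The leading eigenvalue of
the reweighted transition matrix is exactly 1; the second eigenvalue,
0.9511 at this lag, is the slow equilibration across the largest barrier
(implied timescale about 10 ps from this single short run); deeper
eigenvalues are fast intra-basin relaxations. The effective sample size
shows the weights are well behaved for this mild bias (93% of the windows).

The full three-way study (direct vs biased vs reweighted, five replicas per
condition, lag sweep, negative control) is one call:

```r
res <- run_mb_experiment(mb_experiment_config(seed = 1))
res
#> <mb_experiment>
#>   TV(reweighted, direct)        = 0.0121
#>   TV(unreweighted, direct)      = 0.0731
#>   TV(negative control, direct)  = 0.1682
#>   slowest timescale (direct)    = 8.50 ps
```

Reweighting the biased simulation brings the stationary density within a
total-variation distance of about 0.01 of the direct unbiased estimate;
without reweighting the biased density is off by 0.07 (and by 0.17 for the
deliberately strong negative-control bias).

There is also a thin command line (`inst/scripts/girsanov-cli`) with
`simulate`, `msm`, `experiment` and `fixtures` subcommands over the same
functions.

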