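---
title: "Girsanov path reweighting for Langevin splitting integrators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Girsanov path reweighting for Langevin splitting integrators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(girsanov)
```

## The problem

Molecular kinetics are usually estimated from long stochastic simulations,
but the processes of interest — barrier crossings, conformational changes —
are often far slower than what an unbiased run can reach. Enhanced-sampling
simulations add a bias potential to speed things up, at the price of
corrupting the dynamics. Girsanov path reweighting removes that corruption
*exactly*, at the resolution of the integrator: every simulated path is
assigned the ratio of its probability under the target potential to its
probability under the simulation potential, and any path-based estimator
(here: Markov state model transition counts) is averaged with these weights.

The key observation is that for a *stochastic* integrator a path is fully
determined by its starting state and the sequence of Gaussian random numbers
that drove it. The same geometric path could have been generated at a
different potential by a slightly shifted noise sequence, and the ratio of
the two Gaussian likelihoods is computable step by step, during the
simulation, at negligible cost.

## Dynamics and conventions

The package integrates underdamped Langevin dynamics

$$ M\,\dot v \;=\; -\nabla V(q)\;-\;\xi M v\;+\;\sqrt{2RT\xi M}\,\eta(t), $$

in molar units: positions in nm, momenta in amu·nm/ps, energies in kJ/mol,
the gas constant $R = 8.314\times10^{-3}$ kJ/(mol·K). One integrator step
composes three update operators acting per degree of freedom:

* **A** (drift): $q \leftarrow q + (\Delta t/M)\,p$
* **B** (kick): $p \leftarrow p + \Delta t\,(-\nabla V(q))$
* **O** (bath): $p \leftarrow d\,p + f\,\eta$, with
  $d = e^{-\xi\Delta t}$ and $f = \sqrt{RT\,M\,(1-d^2)}$

A letter that occurs twice in a symmetric sequence (e.g. the A and B of
ABOBA) is applied with $\Delta t/2$ — the primed parameters $d' =
e^{-\xi\Delta t/2}$, $f' = \sqrt{RT M (1-d'^2)}$. They satisfy $d'^2 = d$
and $f'^2(1+d'^2) = f^2$, which is how two half O-steps compose into a full
one; both identities are asserted in the test suite. The RVO alphabet is
the same algebra written for velocities ($v = p/M$); `parse_scheme()` maps
R→A and V→B, and the two formulations agree to floating-point precision
(this twin check is part of the acceptance suite).

**Sign convention.** The simulation potential $V$ and the target potential
$\tilde V$ are related by a perturbation $U$:

$$ \tilde V(q) = V(q) + U(q), \qquad U = -U_\mathrm{bias}. $$

A `potential_pair()` can be built from either viewpoint (`perturbation =`
or `bias =`); internally only $U$ is used. The choice matters: with a bias
$U_\mathrm{bias}$ *added* to the simulation (the enhanced-sampling case,
$V = \tilde V + U_\mathrm{bias}$), the initial-state reweighting factor
must be $e^{+U_\mathrm{bias}(q_0)/RT} = e^{-U(q_0)/RT}$, the familiar
umbrella-sampling weight. Both signs in the package are certified by
density-ratio oracles rather than trusted from transcription.

## The path weight

For a window of $n$ steps starting at state $x_0$ drawn from the Boltzmann
distribution of $V$, the weight factorises as $W = g \cdot M$:

* $\log g = -U(q_0)/RT$, the Boltzmann ratio of the initial state
  (the partition-function constant $Z/\tilde Z$ is omitted — it cancels
  when transition-matrix rows are normalised);
* $\log M = -\sum_k s_k$, with the per-step increment
  $s_k = \sum_l \left(\eta\,\Delta\eta + \tfrac12\Delta\eta^2\right)$
  summed over degrees of freedom and noise channels.

$\Delta\eta$ is the *random-number difference*: the shift that would make
the recorded step, generated at $V$ with noise $\eta$, coincide with the
same step generated at $\tilde V$. It is integrator specific. The package
derives it per scheme by endpoint inversion (implemented independently in
`invert_step_noise()`, which is also the test oracle):

| scheme | noise/step | $\Delta\eta$ (perturbation force $\nabla U$) | evaluated at |
|--------|-----------|-----------------------------------------------|--------------|
| ABO    | 1 | $d\,\Delta t\,\nabla U / f$ | after position update |
| ABOBA  | 1 | $(1+d)\,\Delta t\,\nabla U / (2f)$ | intermediate position |
| AOBOA  | 2 | $d'\Delta\eta^{(1)}+\Delta\eta^{(2)} = d'\,\Delta t\,\nabla U / f'$ | intermediate position |
| BOAOB  | 2 | $\Delta\eta^{(1)} = d'\,\Delta t\,\nabla U/(2f')$, $\Delta\eta^{(2)} = \Delta t\,\nabla U/(2f')$ | before / after |
| OBABO  | 2 | $\Delta\eta^{(1)} = \Delta t\,\nabla U/(2f')$, $\Delta\eta^{(2)} = d'\,\Delta t\,\nabla U/(2f')$ | before / after |

For a bias force the sign flips ($U = -U_\mathrm{bias}$). Any other
splitting string is refused for reweighting.

**Two-noise schemes.** For BOAOB and OBABO the position update sits between
the two O half-steps, so the endpoint pins *both* noise channels and exact
per-channel differences exist. For AOBOA both position updates are
noise-free within the step; the endpoint determines only the combination
$\eta^\mathrm{comb} = d'\eta^{(1)} + \eta^{(2)} \sim N(0, 1+d'^2)$. Since
the path itself depends on the noise only through this combination, the
marginal likelihood ratio in $\eta^\mathrm{comb}$ *is* the exact path
weight for every path observable, and that is what the package computes:
$s_k = (\eta^\mathrm{comb}\Delta + \tfrac12\Delta^2)/(1+d'^2)$. The
suite certifies all five schemes against the inversion oracle at about
$10^{-13}$.

**Numerical handling.** All weights are carried as logarithms end to end;
exponentials appear only inside the count-matrix accumulation after a
global max-log shift, which cancels in row normalisation. This matters
because $\log M$ grows linearly with window length and raw weights
underflow for long paths.

## On-the-fly recording

The increments $s_k$ are accumulated in a buffer inside the integrator's
inner loop (compiled code, `src/simulate.cpp`, with a step-identical pure-R
reference engine used for cross-validation). Every `n_out` steps a frame is
written: positions, the flushed buffer `dS` (the increment of the interval
*ending* at that frame; the first record is 0), and the perturbation energy
$U(q_{k'})$. Storing the interval that ends at the frame lets a sliding
window start at any recorded frame without look-ahead: for a window of
`n_interval` recording intervals starting at record $k'$,

$$ \log W = -U(q_{k'})/RT \;-\; \sum_{j=k'+1}^{k'+n_\mathrm{interval}} dS_j. $$

Both trajectory files are plain TSV with a header (`write_position_file()`,
`write_reweighting_file()`); the round trip is lossless at 17 significant
digits and misaligned files are rejected with the first offending row.

## Reweighted Markov state models

Positions are binned on a regular grid (half-open bins, closed last bin,
out-of-range frames clipped to edge bins with a warning — or dropped on
request). The reweighted transition-count estimator adds
$e^{\log W_m - \max\log W}$ to $C_{ij}$ for every window that starts in
state $i$ and ends in state $j$ after the lag; with unit weights it reduces
bit-for-bit to the direct sliding-window counter. Rows are normalised into
a transition matrix after dropping states without outgoing weight
(iteratively; no connectivity trimming beyond that, and reversibility is
*not* enforced — the estimator is genuinely nonreversible, so complex
eigenvalue pairs can occur deep in the spectrum and are surfaced, not
hidden). Left eigenvectors and eigenvalues come from base `eigen()` on the
transpose, sorted by modulus with a real-part tie-break; implied timescales
are $t_i = -\tau/\ln|\lambda_i|$, with NA for nonpositive or unit-modulus
eigenvalues. Window weights are recomputed per lag from the stored `dS`
sums — a cheap cumulative sum — rather than cached as exponentials.

## The benchmark studies and what they show

`run_mb_experiment()` reproduces, at desk scale, the standard
two-dimensional benchmark: the four-term exponential (Müller–Brown)
surface with amplitudes (−20, −10, −17, 1.5) kJ/mol, simulated with ABOBA
at $\Delta t = 0.5$ fs, $\xi = 5\,\mathrm{ps}^{-1}$, $T = 300$ K, unit
mass, frames every 10 steps, a 6×6 grid over $-3.5 \le x \le 1.5$,
$-1.5 \le y \le 3.5$ and lags 0.5–4.5 ps. The biased condition adds a
linear bias $k\,x$ with $k = 1$ kJ/mol/nm. Deliberate deviations from the
full-scale study, chosen once as the package's desk-scale conditions:
$5\times10^6$ steps per replica (5 replicas per condition) instead of
$2.5\times10^8$, and the lag list truncated below 5 ps — minutes, not days,
on one CPU, at the price of larger estimator noise (the slowest implied
timescale at these settings is ≈ 8–9 ps and still drifts slightly with
lag, a known finite-lag effect of crisp discretizations).

Design choices that the study conditions left open:

* **Initialisation.** Positions are drawn uniformly over the grid box but
  redrawn until the simulation potential is below 0 kJ/mol: the box
  corners of this surface reach thousands of kJ/mol, where a 0.5 fs step
  is unstable. Momenta are Maxwell–Boltzmann at 300 K. A configurable
  burn-in ($5\times10^4$ steps by default) is discarded before any window
  enters an estimator, because the theory assumes Boltzmann-distributed
  window starts.
* **Negative control.** At $k = 1$ kJ/mol/nm the equilibrium shift of the
  biased, *unreweighted* stationary density is itself modest (total
  variation ≈ 0.06–0.08 against the direct estimate, close to the 0.05
  acceptance threshold). The dedicated negative control therefore runs at
  $k = 3$ kJ/mol/nm — a clearly strong bias whose unreweighted TV is
  ≈ 0.17 — while the reweighting comparison itself stays at the benchmark
  value $k = 1$. Both numbers are reported by `scripts/acceptance.R`.
* **Replicate spread.** Timescale uncertainty is quantified by the spread
  over the five replicas (mean ± 2 s.e.), not a full bootstrap: with five
  independent trajectories the replicate spread is the more honest
  estimate at this scale. Reweighted eigenvectors are systematically more
  accurate than reweighted timescales, and the tests reflect that
  (TV threshold for the stationary vector, interval overlap for $t_1$).

`run_doublewell_experiment()` replaces the solvated ion-pair system of the
original full-scale study by a 1D surrogate: a quartic double well
$V = h\,(q^2-q_0^2)^2/q_0^4$ with $h = 5$ kJ/mol (two barriers per RT,
so crossings are frequent at desk scale), minima at $q_0 = \pm 0.15$ nm,
a 50-state grid over $[-0.3, 0.3]$ nm, $\Delta t = 1$ fs,
$\xi = 2\,\mathrm{ps}^{-1}$, and the linear bias strength
$k = 5$ kJ/mol/nm carried over from the original system. Because the
surrogate is one-dimensional, its target stationary density is available
by quadrature (`boltzmann_reference()`), giving an oracle that the
simulated comparisons cannot provide: the reweighted density matches the
discretized Boltzmann distribution of the *target* potential (TV ≈ 0.03),
the biased one does not (TV ≈ 0.14), and the slowest left eigenvector
changes sign once near the barrier bin.

## What the synthetic systems do and do not show

The generators emulate the features that matter for the estimator —
metastability, Gaussian noise at the integrator's resolution, a bias along
one coordinate, recording-interval bookkeeping — under exactly the
conditions stated above. They do not emulate high-dimensional force
fields, solvent degrees of freedom, constraints, or biases that shift the
transition-path ensemble itself. Passing tests therefore certify the
*mathematics* of the weights and the estimator; on large molecular systems
the known practical caveats remain: the weight variance grows
exponentially with window length (watch the effective sample size that
every run summary reports), and reweighted implied timescales carry much
larger uncertainty than reweighted eigenvectors.

## Degenerate inputs and edge cases

* $\xi = 0$ or $T = 0$: simulation is allowed (the O-step becomes
  deterministic), reweighting is refused — $f = 0$ makes $\Delta\eta$
  undefined.
* Splitting strings outside the supported five are simulated on request
  but never reweighted.
* Simulation blow-up (non-finite state or $|q|$ beyond a bound) aborts
  with the step index.
* An all-zero count matrix, non-stochastic transition-matrix input, and
  misaligned reweighting files are errors, not warnings.
* $\lambda_i \le 0$ or $|\lambda_i| \ge 1$ yield NA timescales rather than
  exceptions.

## Reproducibility

A single seed controls everything: initial conditions, Maxwell–Boltzmann
momenta and every noise draw, in a documented order (step, O-occurrence,
degree of freedom) shared by the compiled and the reference engine, both
driven by R's own RNG stream. Re-running any experiment with the same
config and seed reproduces every output file byte for byte; a committed
20-step golden trajectory per scheme guards the draw order across
releases.
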