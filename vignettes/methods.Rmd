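---
title: "From critical integrate-and-fire dynamics to pairwise Ising thermodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From critical integrate-and-fire dynamics to pairwise Ising thermodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(NeuroIsing)
```

## Overview

NeuroIsing implements a complete pipeline from a biologically inspired
spiking-network simulation to an equilibrium statistical-mechanics
description of its activity:

1. **Network construction** — a spatially embedded, scale-free, directed
   graph of integrate-and-fire (IF) neurons.
2. **Plastic IF dynamics** — threshold firing with short-term synaptic
   depression, per-avalanche neurotransmitter recovery, a one-timestep
   refractory period, Hebbian shaping of synaptic strengths, and a weak
   stochastic external drive.
3. **Criticality tuning** — a search over the recovery increment
   $\delta u_{rec}$ until avalanche sizes and durations follow the
   mean-field branching exponents $\tau_S = 1.5$, $\tau_D = 2$.
4. **Maximum-entropy inference** — the binarized firing statistics
   ($\langle\sigma_i\rangle$, $\langle\sigma_i\sigma_j\rangle$) are matched
   by a pairwise Ising model at unit temperature via Boltzmann-machine
   learning (the inverse Ising problem).
5. **Thermodynamics** — magnetization, susceptibility and specific heat of
   the learned model over a temperature grid, via Metropolis Monte Carlo
   and the fluctuation-dissipation relations.

## The IF model and its parameters

Neurons sit at uniform random positions in a cube of side
$L = (N/\rho)^{1/3}$ with density $\rho = 0.016$ per unit volume.
Out-degrees follow $P(k_{out}) \propto k_{out}^{-2}$ on $[2, 20]$ and a
source's targets are drawn without replacement with probability
$\propto e^{-r/r_0}$, $r_0 = 5$ (open boundaries; the kernel is
normalized per source). Every neuron is guaranteed at least one incoming
edge by a repair step that draws a donor with the same distance kernel.

Each neuron carries a membrane potential $v_i$ (threshold $v_c = 1$,
floor $v_{min} = -1$) and a normalized neurotransmitter pool
$u_i \in [0, 1]$. When neuron $i$ fires, each non-refractory target $j$
receives

$$\Delta v_j = \pm\, v_i\, u_i\, \frac{g_{ij}}{\sum_k g_{ik}},$$

with the sign set by the presynaptic neuron's excitatory/inhibitory
identity. The out-strength-normalized efficacy is the convention of the
scale-free IF model family this package follows: it makes the branching
ratio of a firing event approximately $v_i u_i$, so the recovery
parameter genuinely drives the system through criticality. The raw
per-edge form $\Delta v_j = \pm v_i u_i g_{ij}$ is available as
`dynamicsConfig(normalizeOut = FALSE)`; with initial strengths of order
0.05 and mean out-degree near 4 it caps the branching ratio around 0.2
and the network cannot leave the subcritical regime, whatever the
recovery increment.

After firing, $u_i \to u_i (1 - \delta u)$ with $\delta u = 0.05$,
$v_i \to 0$, and the neuron is refractory (neither fires, receives, nor
is driven) for one timestep. One uniformly chosen neuron receives an
external kick $\delta v = 0.1\,v_c$ per timestep, also during avalanches;
a kick aimed at a refractory neuron is dropped. Updates are synchronous:
all threshold crossings are collected from the state at $t$, all
propagations applied simultaneously, then the drive, then refractory
bookkeeping.

An **avalanche** is a maximal run of timesteps with at least one firing;
its size $S$ is the number of firings, its duration $D$ the run length,
and single-firing events are counted. At every avalanche end all pools
recover, $u_i \to \min(1, u_i + \delta u_{rec})$.

**Long-term plasticity (shaping).** Starting from strengths uniform on
$[0.04, 0.06]$, every transmission adds $\beta\,|\Delta v_j|$
($\beta = 0.04$) to the used synapse, and at each avalanche end all
synapses are decreased by the mean accumulated increment, so total
strength is conserved at avalanche boundaries. Shaping stops after
$10^4$ avalanches or when a strength first reaches
$g_{min} = 10^{-5}$. At these parameter magnitudes shaping redistributes
a small amount of strength toward used synapses; it does not change the
mean.

**Initial conditions.** $u_i = 1$ (fully recovered pools) and $v_i$
uniform on $[0, v_c)$; a configurable burn-in (default $10^4$ timesteps)
is discarded before measurement.

## Criticality tuning

`tuneCriticality()` simulates a fixed number of avalanches at each
candidate $\delta u_{rec}$ on a log-spaced grid, fits discrete
maximum-likelihood power laws to sizes and durations, and minimizes
$|\tau_S - 1.5| + |\tau_D - 2| + (KS_S + KS_D)$. Because the exponents
move quickly with the recovery increment, a refinement pass evaluates a
finer multiplicative neighborhood of the coarse argmin.

**Fit ranges.** Sizes are fitted on $[2, q_{99}]$. Durations are fitted
on $[4, q_{99}]$: the external drive operates during avalanches, so the
head of $P(D)$ ($D \le 3$) is padded with drive-triggered one- and
few-step events and decays with local slope near $-1$, while from
$D \approx 4$ the distribution decays with slope near $-2$; the
Kolmogorov-Smirnov statistic of the truncated fit confirms the choice
(it improves from about 0.04 at $x_{min} = 2$ to about 0.026 at
$x_{min} = 4$). Both bounds are arguments and every test states the
range it uses.

## Binarization and moments

Rasters are cut into half-open bins of $\Delta t_b = 5$ timesteps;
$\sigma_i^k = +1$ if neuron $i$ fired at least once in bin $k$ (the
trailing partial bin is dropped). `computeMoments()` returns
$\langle\sigma_i\rangle$, $\langle\sigma_i\sigma_j\rangle$, the connected
correlations $C_{ij}$, the simultaneous up-count distribution $P(K)$,
and optionally three-point connected correlations $T_{ijk}$ (all triples
when $\binom{N}{3}$ is small, otherwise a random subsample). Moment
standard errors are sample SD over $\sqrt{N_b}$, ignoring bin
autocorrelation; that is the convention used throughout for
standard-error bands.

## The maximum-entropy model and its learning

The least-structured distribution over $\sigma \in \{-1,+1\}^N$ matching
the means and pairwise products is the pairwise Ising model

$$P(\sigma) = \frac{1}{Z} e^{-H(\sigma)}, \qquad
H(\sigma) = -\sum_i h_i \sigma_i - \sum_{i<j} J_{ij}\sigma_i\sigma_j,$$

at reference temperature $T_0 = 1$. `bmFit()` starts from
$h_i = \langle\sigma_i\rangle$, $J = 0$ and iterates the first-order
moment-matching updates with learning rates
$\eta_h(x) = 2\eta_J(x) = \eta_0 x^{-\alpha}$
($\alpha = 0.4$ for $N \le 40$, $0.6$ for $40 < N \le 120$, $1.0$
above; $\eta_0 = 0.5$ by default, keeping the first steps below the
$\pm 1$ moment scale). Model moments per iteration come either from
exact enumeration ($N \le 20$; the oracle used by the parameter-recovery
tests — moment matching is the concave maximum-likelihood problem of an
exponential family, so the exact-gradient optimum is the generator) or
from single-spin-flip Metropolis chains.

**Chain protocol.** One "configuration" is one attempted flip of a
uniformly chosen spin. Per iteration the chain is restarted, burned in
for $150N$ attempts ($N \le 120$; $100N^2$ above, configurable), and
every $2N$-th configuration is retained. For learning on sparse-firing
targets the chains start from the all-down state by default: the data's
typical configuration is close to all-down
($\langle\sigma_i\rangle \approx -0.95$), so the short per-iteration
burn-in thermalizes with far less bias than a random start, whose
residual disorder otherwise inflates the learned parameters. A
persistent-chain option (state carried across iterations) exists as a
speed variant; the restarted chain is the reference protocol.

**Pruning.** `pruneMask()` pins $J_{ij} = 0$ wherever
$C_{ij} < \eta \max(C_{ij})$; learning then touches only the surviving
couplings, which is how system sizes beyond the fully connected budget
are handled.

## Thermodynamics

For a learned model, `thermoSweep()` runs an independent chain at each
temperature of a 30-point grid on $[0.1, 3.0]$ (no annealing) and
evaluates $m = \langle M\rangle/N$,
$\chi = (\langle M^2\rangle - \langle M\rangle^2)/T$ and
$C_v = (\langle E^2\rangle - \langle E\rangle^2)/T^2$ with batch-means
standard errors ($k_B = 1$). Peaks are reported as the grid argmax with
half-grid-step uncertainty, without interpolation.

Per-temperature burn-in defaults to the learning default but the sweeps
used in the packaged analyses set it equal to the sampling effort
$M_c$: near the fluctuation peak the integrated autocorrelation time is
far larger than $150N$ attempts, and an under-thermalized chain biases
the peak location upward.

Two initialization policies expose different physics below $T_0$: random
starts scatter across metastable states of the rugged (spin-glass-like)
landscape, producing a cloud of replica-dependent values at low $T$;
all-down starts (the ground-state basin for mostly negative fields)
yield smooth curves. The package reproduces this contrast as a variance
ratio across replicas at $T = 0.2$.

## What the synthetic fixtures emulate

`sampleIsingRaster()` (exact enumeration for $N \le 12$, Metropolis
above), `sampleIndependentRaster()` and the deterministic `toyRaster()`
catalog generate binned rasters with known ground truth, mimicking the
statistical structure the inference assumes: sparse firing
($\langle\sigma_i\rangle < 0$), small mostly positive pairwise
correlations, exponential-tailed $P(K)$. They contain no measurement
artifacts of real recordings — no spike-sorting errors, electrode
subsampling, jitter or nonstationarity — so green tests certify the
inference machinery, not robustness to experimental noise.

## Problem sizes and numerical choices

The packaged analyses run at desk scale: networks of 20-180 neurons,
$2\times10^5$ to $10^6$ bins, learning budgets of 5000 iterations with
$3\times10^4$ configurations per iteration, and sweeps of
$3\times10^5$ configurations per temperature. Full-scale settings
($N_b = 10^7$ bins, 60000 iterations, $3\times10^5$ configurations per
iteration, $3\times10^6$ per temperature) are plain configuration
values. Two desk-scale behaviors are worth knowing:

* The susceptibility of learned $N = 40$ models is a broad plateau over
  $T \in [1.2, 1.5]$; its grid argmax therefore carries more than the
  half-grid-step uncertainty, and heavier learning budgets move it
  toward the lower edge of the plateau.
* The fluctuation peaks grow with $N$ only when the fits are comparably
  converged; under-converged couplings at larger $N$ depress the
  collective peak. The cross-size comparison therefore scales the
  learning budget with system size (documented in the test that makes
  the comparison).

Degenerate inputs are rejected loudly: fewer than 100 in-range samples
or a constant sample set for power-law fits, enumeration beyond
$N = 20$, exact sampling beyond $N = 12$, non-positive temperatures,
masked updates touching pruned couplings. Ties in the local subnetwork
selection break by neuron index; the cube center is the geometric
center $(L/2, L/2, L/2)$.

## Reproducibility

All randomness flows through R's RNG (Mersenne-Twister), including the
compiled samplers; any seeded entry point is bit-reproducible.
`runExperiment()` derives independent per-run, per-stage seeds from one
global seed, so adding a stage or changing a replicate count does not
perturb the RNG stream of the others, and writes a manifest from which
`reportExperiment()` rebuilds its tables deterministically.

## Known limitations

* Exponent estimates at desk scale carry finite-size cutoffs
  ($S_{max} \sim 10^2$); the fitted windows are narrow.
* The pairwise model's known failure modes are reproduced, not fixed: it
  overestimates three-point correlations and misses $P(K)$ at large $K$;
  subnetwork restriction ignores inputs from unobserved neurons.
* No replica/overlap order parameters: the spin-glass statement is the
  qualitative initialization-dependence contrast only.
* CPU cost of learning grows roughly as $N^2$ per iteration; fully
  connected fits beyond $N \approx 120$ at converged quality are outside
  the desk budget (pruning is the supported route).
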