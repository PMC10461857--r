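---
title: "Low-rank structure in spiking and rate networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-rank structure in spiking and rate networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lowrankSNN)
```

This vignette documents the models implemented in `lowrankSNN`, the
assumptions behind them, the tunable parameters and their defaults, and the
numerical and design choices made where more than one reasonable option
existed. It is the package's methods reference; the README shows a worked
example.

## The two models

**Rate network.** `simulate_rate()` integrates, with forward Euler,

$$\tau \dot x_i = -x_i + \sum_j P_{ij}\,\phi(x_j) + I_i\,u(t),
\qquad \phi(x) = 1 + \tanh(x - x_\mathrm{off}),$$

where the recurrent matrix is a rank-$R$ sum of outer products
$P_{ij} = \frac1N \sum_r m_i^{(r)} n_j^{(r)}$. The transfer function is a
positive sigmoid bounded in $(0, 2)$; the offset $x_\mathrm{off}$
(default 2.9, dimensionless) places the resting state on the low branch so
that the quiescent rate $\phi(0) \approx 0.006$ is nearly silent. The
recurrent term is always applied in factored $O(NR)$ form.

**Spiking network.** `simulate_lif()` integrates a network of leaky
integrate-and-fire neurons,

$$\tau_m \dot V_i = -V_i + \mu_0 + I_i u(t) + \text{noise} + \text{synapses},$$

with threshold $V_\mathrm{thr} = 20$ mV, reset $V_r = 10$ mV, refractory
clamp at $V_r$ for $\tau_\mathrm{ref}$, and delta synapses: each presynaptic
spike produces an instantaneous jump of $J_{ij}$ mV in the postsynaptic
potential, delivered after the synaptic delay $\tau_\mathrm{del}$ through a
ring buffer. The connectivity is the sum of a sparse random
excitatory-inhibitory matrix $J^{EI}$ (fixed in-degree $C$, 80% excitatory
synapses of strength $J$, inhibitory $-gJ$; `sample_ei_matrix()`) and the
same low-rank matrix $P$ as the rate model (`compose_connectivity()`). The
integration loop is compiled (Rcpp); noise and initial conditions are drawn
from R's RNG so a seed fully reproduces a raster.

Two discretization conventions deserve a note:

* *Noise.* The white-noise term is realized as a per-step voltage jump
  $\sigma_0\sqrt{dt/\tau_m}\,\eta$ ($\eta \sim N(0,1)$), giving an
  uncoupled neuron the stationary variance $\sigma_0^2/2$ — the convention
  of the classic sparse E-I network literature. A
  `noise_convention = "sqrt_dt"` switch selects the alternative reading
  $\sigma_0\sqrt{dt}\,\eta$; all presets use the default.
* *Delays and refractoriness* are realized in whole steps,
  `round(tau/dt)` with a minimum one-step delay. Exact divisibility is not
  required because the standard parameter set pairs $dt = 1$ ms with
  $\tau_\mathrm{del} = 1.5$ ms.

Threshold crossings are detected at the end of a step, without
interpolation; the noiseless single-neuron rate then matches the closed-form
inter-spike interval $\tau_\mathrm{ref} + \tau_m
\log\frac{\mu_0 - V_r}{\mu_0 - V_\mathrm{thr}}$ to within one step.

## Gaussian connectivity statistics

All structured vectors — the right/left connectivity vectors $m^{(r)}$,
$n^{(r)}$, the input vectors $I^{(s)}$ and the readout $w$ — are sampled
i.i.d. per neuron from one joint Gaussian described by `vector_stats()`.
The sampler factorizes the covariance with a pivoted triangular
factorization, which generalizes the usual explicit three-vector
construction to arbitrary rank and input count and handles degenerate
covariances (e.g. an input exactly aligned with $n$). Positive
semi-definiteness is checked before sampling and violations are reported by
variable pair. Units: $m, w$ dimensionless; $n, I$ in mV for spiking
presets; rate presets are dimensionless throughout.

Input amplitudes in the spiking presets are quoted as overall Euclidean
norms $|I|$ of a unit-standard-deviation pattern; `sample_vectors()`
rescales the sampled column to that exact norm. An input "along the global
axis" has constant entries $|I|/\sqrt N$.

One seed spawns named substreams (`spawn_seeds()`) for vectors, E-I
topology, membrane noise and stimulus, so changing one component's
realization leaves the others fixed.

## Latent dynamics and the mean-field theory

For low-rank connectivity the activations stay in
$\mathrm{span}\{m^{(r)}, I^{(s)}\}$, so
$x_i(t) = \sum_r \kappa_r(t)\, m_i^{(r)} + \sum_s v_s(t)\, I_i^{(s)}$.
Three levels of description are implemented and cross-checked:

1. `simulate_latent_empirical()` integrates the $(R + N_\mathrm{in})$-dimensional
   system using the empirical finite-$N$ sum
   $\frac1N \sum_i n_i^{(r)} \phi(\cdot)$. For initial conditions inside
   the span this reduction is *exact* (the tests verify agreement with the
   full network at machine precision).
2. `simulate_latent_meanfield()` replaces the sum by its $N \to \infty$
   Gaussian integral (Stein's lemma), $F(\kappa) = \langle n\rangle
   \langle\phi(\mu, \Delta)\rangle + (\sigma_{nm}\kappa + \sigma_{nI}v)
   \langle\phi'(\mu, \Delta)\rangle$ with $\mu = \langle I\rangle v +
   \langle m\rangle\kappa$, $\Delta = \kappa^2\sigma_m^2 + v^2\sigma_I^2$.
   The deviation between a sampled network's latent trajectory and this
   limit shrinks as $1/\sqrt N$.
3. `latent_from_trajectory()` recovers $(\kappa, v)$ from any full
   trajectory as the least-squares coordinates of the orthogonal projection
   onto the span. When the basis is orthogonal this is exactly
   $x^\top m / \|m\|^2$; for sampled vectors it removes the $O(1/\sqrt N)$
   cross-talk between directions. Least squares was chosen over sequential
   Gram–Schmidt because the coefficients are unique and basis-order
   independent.

**Gaussian integrals.** `gaussian_expectation()` evaluates
$\langle f(\mu, \Delta)\rangle$ by Gauss–Hermite quadrature (default) or
Monte Carlo. The default order is 512: with $\sqrt\Delta \gtrsim 5$ the
sigmoid's transition becomes narrow on the scale of the node spacing and
order 128 leaves errors of order $10^{-2}$, which the Stein cross-check
against $10^5$-coordinate empirical sums exposed; order 512 brings the
quadrature within sampling error of the empirical sums across the tested
parameter range at negligible cost (nodes are cached).

**Fixed points and bifurcations.** `solve_fixed_points_rank1()` brackets
sign changes of $\kappa - F(\kappa)$ on a grid and bisects. Because the
positive transfer function produces low-activity roots at
$|\kappa| \sim \langle n\rangle\,\phi(0) \ll 1$ next to $O(1)$ unstable
companions, the grid combines uniform coverage of $\pm 5\max(\sigma_n,
2|\langle n\rangle|, \sigma_{mn}/\sigma_m, 1)$ with a logarithmic
refinement near zero. Stability comes from the sign of
$-1 + F'(\kappa^*)$ (central difference). `scan_bifurcation()` follows the
stochastic protocol: at each swept overlap, $F$ is averaged over 50
re-sampled vector pairs (Monte-Carlo integration), roots are solved on the
averaged curve, and branches are classified against a threshold
$\kappa_\mathrm{thr}$ separating the zero/low state from the high or
symmetric states. The default threshold is half the smallest clearly
nonzero root magnitude at the strongest feedback, where "clearly nonzero"
excludes roots below 1% of the largest magnitude — those are the zero root
under Monte-Carlo jitter, not a branch.

With the standard offset $x_\mathrm{off} = 2.9$, the mean-driven sweep
($\sigma_{mn} = 0$, increasing $\langle n\rangle$) produces an asymmetric
low/high pair with very different population rates, while the
covariance-driven sweep (zero means, increasing $\sigma_{mn}$) produces a
$\pm\kappa^*$ pair with *identical* population rates on both branches —
the qualitative signature that separates the two feedback mechanisms. The
symmetric branch appears subcritically: the zero state remains locally
stable at overlap 11.2 because $\sigma_{mn}\phi'(0) \approx 0.13 < 1$
there; the $\pm\kappa^*$ states coexist with it.

**Rank two.** `rank2_rhs()` / `simulate_rank2_flow()` implement the
two-dimensional flow with gain $\langle\phi'(0, \Delta)\rangle$, and
`analyze_overlap_matrix()` classifies the regime from the eigenvalues of
$\phi'(0)\,P^{\mathrm{ov}}$, $P^{\mathrm{ov}}_{rs} = \mathrm{cov}(n_r, m_s)$:
stable origin, complex-oscillatory (limit cycle), degenerate-ring, or
real-bistable.

## State-space geometry

`run_pca()` follows the trajectory-matrix recipe exactly: column-center the
time × neuron matrix, eigendecompose $X_c^\top X_c$, report explained
variance as eigenvalue fractions. When $T < N$ the spectrum is computed
through the dual Gram matrix $X_c X_c^\top$ — mathematically identical
components, verified against the direct path and against an independent
SVD in the tests. `pc_alignment()` reports signed cosines of components
with named raw (not orthogonalized) directions; `subspace_alignment()`
gives the alignment with a plane. PCA is run per trial for rate networks
and on trial-averaged rates for spiking networks.

`filter_spikes()` converts rasters to instantaneous rates by the exact
event-driven exponential filter ($\tau_f\dot r = -r + \sum_k\delta(t-t_k)$):
decay between samples, within-bin spike offsets applied exactly, one spike
integrating to unity. `filter_timescale_sweep()` repeats
filter → trial-average → PCA across $\tau_f$ values and records PC1
alignments; samples before `t_min` are discarded because the filter starts
at zero and its burn-in (a coherent everyone-ramps-up transient along the
global axis) would otherwise dominate PC1 at long $\tau_f$. Analyses in
the tests use `t_min = 500` ms ≈ 5 filter time constants.

## The synthetic-data generator as study conditions

There is no external data: `sample_vectors()`, `sample_ei_matrix()` and the
stimulus constructors *are* the data-generating process, and the preset
registry (`preset()`) pins the published parameter sets — vector statistics,
$C$, $J$, $g$, $\mu_0$, delays, run lengths, trial counts — for each studied
configuration. What the generator reproduces: Gaussian-correlated structure
vectors, fixed in-degree E-I topology, white membrane noise, step or noisy
scalar stimuli. What it does not: heavy-tailed or degree-heterogeneous
connectivity, conductance synapses, non-Gaussian structure — so green tests
say nothing about those regimes.

Values the published parameter sets leave open were fixed once,
as follows:

* Rate-model network sizes are not part of the published sets for the
  autonomous-dynamics configurations; defaults are $N = 2000$ (rank-1 scans) and $N = 1000$
  (rank-2), large enough that finite-size scatter does not obscure branch
  structure.
* The input-driven rate configurations leave the step amplitude and
  offset open; amplitude 1 with $x_\mathrm{off} = 2.9$ is used.
* The rank-2 tables label vector dispersions with a superscript that could
  be read as squaring; read as variances the printed numbers make the
  covariance matrices non-positive-semi-definite (correlations above 1),
  so they are read as standard deviations of $n^{(1)}, n^{(2)}$ etc.
* $x_\mathrm{off}$ is absent from the rank-2 parameter sets; 0 is used
  because the gain $\phi'(0) = 1$ makes the printed overlap eigenvalues
  ($2 \pm 0.8i$, $\{2, 2\}$) supercritical, which the oscillatory and ring
  regimes require; the rank-1 value 2.9 would leave the origin stable.
* $\mu_0$ is absent from the rank-2 spiking parameter sets; 40 mV (the
  asynchronous-irregular background with the same $J, g$) is used.

### Reduced-scale protocol

Spiking analyses in the test suite run at $N = 2500$, $C = 250$ with
$J$ scaled to preserve $CJ$ (same mean recurrent drive), the published
parameters otherwise unchanged. Two calibration choices make the reduced
scale faithful to the full-scale geometry:

* the input vector keeps its full-scale Euclidean norm $|I|$ (the
  input-driven variance along $I$ scales as $|I|^2$, so this preserves the
  signal-to-noise of the state-space analysis), and
* spiking PCA averages 12 trials: trial-incoherent residual global
  fluctuations and filter noise shrink with the trial count while the
  stimulus-locked low-rank response does not, which is what makes the
  PC1 flip (global axis at $\tau_f = 1$ ms, $(I, m)$ plane at
  $\tau_f = 100$ ms) resolvable per seed at this size.

The rank-2 *rate* orbit check runs at $N = 4000$: at $N = 1000$ the
$1/\sqrt N$ sampling perturbation of the overlap matrix is comparable to
the slow mean-field rotation (angular speed
$\sigma_w\langle\phi'\rangle \approx 0.4/\tau$ on the cycle) and can
phase-lock the rotation into a fixed point — a genuine finite-size effect
worth knowing about, not a numerical artifact.

## The decision-making task

`build_dm_network()`, `run_trial()` and `psychometric()` implement the
evidence-integration task: a noisy scalar stimulus
$u(t) = \bar u + \psi(t)$ (mean $\pm 0.512$, per-step noise SD
$\sigma_u = 1$; 100 ms fixation, 800 ms stimulation, 100 ms delay, 20 ms
decision) drives the network along $I$; the readout is
$z = \frac1N\sum_i w_i r_i$ on 100 ms-filtered rates, averaged over the
decision epoch and thresholded at zero (ties → label 0).

Two design decisions required resolving internal inconsistencies in the
printed task statistics:

* The quoted task overlaps ($\sigma_m^2 = 0.02$, $\sigma_{mn} = 0.016$,
  $\sigma_{nI} = 0.26$) are dimensionally incompatible with the mV scale
  of the spiking model and with the accompanying statement that the
  feedback overlap should sit near the critical value ($\approx 1$ in
  rate-model units): with $\sigma_m\sigma_n = 0.14 \times 20$ mV the
  feedback overlap is capped at 2.8 mV, two orders below the measured
  critical overlap of the spiking background, and the measured readout
  separation is indistinguishable from zero at any network size. The task
  preset therefore places the vectors on the same mV scale as every other
  spiking configuration ($\sigma_m = 2$, $\sigma_n = 20$ mV), reads
  $\sigma_{nI} = 0.26$ as a correlation (covariance $5.2$ mV²), and sweeps
  the feedback overlap $\mathrm{cov}(m, n)$ in mV toward criticality.
  `dm_stats()` defaults remain the printed values, so the printed
  covariances are still what the sampling machinery recovers.
* The printed readout construction contains a garbled variance formula;
  the readout is therefore built explicitly as
  $w = (\sigma_{mw}/\sigma_m^2)\, m + \sigma_{w,\mathrm{extra}} Z$, which
  honors the quoted $\mathrm{cov}(m, w)$ for any residual variance. The
  default residual is zero (minimum-variance readout).

Finite-size correlations between the readout and the baseline firing
pattern give each network realization a static readout offset that a fixed
zero threshold cannot absorb. Each trial is therefore preceded by a 400 ms
settling period (discarded; it also lets the 100 ms filter converge) and
the decision statistic is the decision-epoch readout minus the
fixation-epoch readout. The label rule itself is unchanged. With these
choices the zero-evidence condition is unbiased (label-1 fraction ≈ 0.5)
and the positive/negative separation grows with the feedback overlap, as
the psychometric analysis in the test suite measures.

## Numerical choices, degenerate inputs, limitations

* Euler steps follow the presets ($dt = 1$ ms rate and spiking, 10 ms for
  the slow rank-1 scans; `lif_params()` defaults to 0.1 ms for
  single-neuron accuracy checks). Halving $dt$ changes latent endpoints at
  first order, as tested.
* Divergence guards abort rate simulations at configurable $|x|$ bounds
  and spiking simulations at a population-rate cap, both with diagnostics.
* Degenerate inputs are flagged, not silently processed: constant
  trajectory matrices yield a `degenerate` PCA result, zero-norm
  directions error, and non-PSD covariances name the offending pair.
* Dale sparsification (`dale_sparsify = TRUE`) masks $P$ onto the nonzero
  pattern of $J^{EI}$ and verifies column signs; violations (possible when
  $|P_{ij}| > |J^{EI}_{ij}|$) warn with a count rather than error.
* Limitations: no event-driven (exact-time) spiking integration; no
  conductance synapses or Poisson external drive; no spiking mean-field
  transfer function (spiking bifurcation points are located by simulation,
  not predicted); fixed in-degree topology only; `run_experiment()`
  pipelines cover the preset families, not arbitrary compositions.

## Persistence

Artifacts are plain text: rasters as `time_ms neuron trial` tables with a
header (`write_raster()`), trajectories and PCA/alignment summaries as CSV,
bifurcation diagrams and manifests as JSON, sparse matrices as 0-based
coordinate lists. `run_experiment()` writes each preset family's artifact
set plus a manifest with the seeds used; a thin command-line front end
(`inst/cli/lowranksnn.R`) wraps the same pipelines.
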