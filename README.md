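# lowrankSNN

Networks of spiking neurons whose connectivity superposes a **low-rank
structure** on sparse random excitatory–inhibitory coupling can be
understood — and designed — through the mean-field theory of low-rank *rate*
networks. `lowrankSNN` implements the full modeling stack needed to study
that correspondence:

* correlated Gaussian sampling of connectivity, input and readout vectors
  (`vector_stats()`, `sample_vectors()`), factored low-rank matrices, and
  fixed in-degree E-I matrices with optional Dale-preserving sparsification
  (`sample_ei_matrix()`, `compose_connectivity()`);
* leaky integrate-and-fire network simulation with synaptic delays,
  refractoriness and white-noise input, in a compiled core
  (`simulate_lif()`), plus exact exponential spike filtering
  (`filter_spikes()`);
* rate-network integration and the reduced latent dynamics at three levels —
  full network, empirical finite-N reduction, and the mean-field limit
  (`simulate_rate()`, `simulate_latent_empirical()`,
  `simulate_latent_meanfield()`, `latent_from_trajectory()`);
* mean-field analysis of the collective variables: Gaussian integrals via
  Stein's lemma, rank-1 fixed points and stability, Monte-Carlo bifurcation
  scans, and rank-2 overlap-matrix regimes (limit cycles, ring attractors)
  (`F_rank1()`, `solve_fixed_points_rank1()`, `scan_bifurcation()`,
  `analyze_overlap_matrix()`);
* state-space geometry: projections, the trajectory-matrix PCA recipe, and
  principal-component alignment against named directions (`run_pca()`,
  `pc_alignment()`, `filter_timescale_sweep()`);
* a perceptual decision-making task built on the same machinery
  (`build_dm_network()`, `psychometric()`).

It is aimed at computational neuroscientists who want to reproduce the
rate-to-spiking correspondence, or to construct spiking networks with
prescribed low-dimensional dynamics, from nothing but connectivity
statistics.

## The core model

The rate network is $\tau\dot x_i = -x_i + \sum_j P_{ij}\phi(x_j) +
I_i u(t)$ with the positive sigmoid $\phi(x) = 1 + \tanh(x -
x_\mathrm{off})$ and a rank-$R$ matrix $P_{ij} = \frac1N\sum_r m_i^{(r)}
n_j^{(r)}$. Activity is confined to $\mathrm{span}\{m^{(r)}, I\}$, with
coordinates $\kappa_r$ obeying, for $N \to \infty$ Gaussian vectors,

$$\tau\dot\kappa = -\kappa + \langle n\rangle\,\langle\phi(\mu,\Delta)\rangle
  + (\sigma_{nm}\,\kappa + \sigma_{nI}\,v)\,\langle\phi'(\mu,\Delta)\rangle ,$$

so fixed points, bistability, limit cycles and ring attractors are read off
the means and covariances of the vector statistics — the overlap matrix
$P^{\mathrm{ov}}_{rs} = \mathrm{cov}(n_r, m_s)$ and its eigenvalues. The
spiking model replaces each unit by a leaky integrate-and-fire neuron
riding on a sparse E-I background, with the *same* low-rank structure added
to the synaptic matrix. The methods vignette
(`vignettes/low-rank-spiking-networks.Rmd`) derives and documents all of
this in detail.

## Worked example

Covariance-driven feedback between the left and right connectivity vectors
creates a pair of symmetric states on top of the quiescent one:

```r
library(lowrankSNN)

st <- rank1_stats(sd_m = 2, sd_n = 6, cov_mn = 11.2)
fp <- solve_fixed_points_rank1(st, x_off = 2.9)
print(fp, digits = 3)
#>    kappa  slope stable
#> 1 -4.222 -0.844   TRUE
#> 2 -0.639  1.679  FALSE
#> 3  0.000 -0.865   TRUE
#> 4  0.639  1.679  FALSE
#> 5  4.222 -0.844   TRUE

predicted_population_rate(fp$kappa[fp$stable], st, x_off = 2.9)
#> [1] 0.732766027 0.006036833 0.732766027
```

The collective variable $\kappa$ has stable fixed points at $0$ (quiescent,
population rate $\phi(0) \approx 0.006$) and at $\pm 4.22$ — two states
with *different activity patterns but identical population-averaged rates*
(0.733), the signature of covariance- rather than mean-driven feedback.
A sampled network's empirical overlap converges to the configured
covariance:

```r
ens <- sample_vectors(st, N = 10000, seed = 1)
empirical_overlaps(ens)$P_ov
#>         m1
#> n1 11.4951
```

The same statistics placed on a spiking E-I background (reduced scale
$N = 2500$, $C = 250$, $J$ scaled to preserve $CJ$) give an
asynchronous-irregular network:

```r
reg <- regime_preset("AI", N = 2500, C = 250)
reg$ei$J <- 0.5  # preserve C J of the full-scale network
ei <- sample_ei_matrix(reg$ei, seed = 2)
conn <- compose_connectivity(ei, lowrank_matrix(
  sample_vectors(rank1_stats(sd_m = 2, sd_n = 20), 2500, seed = 3)))
ras <- simulate_lif(conn, params = reg$lif, seed = 4)
population_rate(ras)
#> [1] 39.934
```

i.e. irregular firing at ≈ 40 spk/s. `filter_spikes()` + `run_pca()` +
`pc_alignment()` then quantify how much of the trajectory lives in the
$(I, m)$ plane versus along the global axis; `preset()` lists every
published parameter set (`preset_ids()`), and `run_experiment()` runs a
preset end to end, writing rasters, PCA/alignment CSVs, bifurcation JSONs
and a manifest.

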