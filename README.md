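# fretjump

Photon-by-photon inference of biomolecular kinetics from single-photon
smFRET traces recorded under continuous-wave illumination — including
the number of conformational states, learned jointly with all
transition rates by a Bayesian nonparametric MCMC sampler.

## Who this is for

Single-molecule spectroscopists with timestamped two-channel photon
data (immobilized or slowly interconverting molecules, CW excitation)
who want state counts and rate matrices with honest posterior
uncertainty, without binning photons, without pre-segmenting dwells,
and without committing to a model dimension in advance.

## The model in brief

The molecule switches among system states $\sigma_1, \dots,
\sigma_{M_\sigma}$; each pairs with three photophysical states of the
dye pair (ground, donor-excited, acceptor-excited) to form superstates.
The composite evolves as a Markov jump process with generator $G$,
$\mathrm{d}\rho/\mathrm{d}t = \rho G$: excitation at
$\lambda_\mathrm{ex}$, donor relaxation at $\lambda_d$, energy transfer
at $\lambda_{\mathrm{FRET},i}$ (so state $i$ has FRET efficiency
$\varepsilon_i = \lambda_{\mathrm{FRET},i}/(\lambda_{\mathrm{FRET},i} +
\lambda_d)$), acceptor relaxation at $\lambda_a$, and system rates
$\lambda_{\sigma_i \to \sigma_j}$ connecting equal photophysical
states. Detection mixes cross talk, detection loss and per-channel
Poisson background through routing probabilities $\varphi$ obtained by
normalizing a calibrated route correction matrix.

The likelihood of a trace with interphoton intervals $\tau_k$ and
channels $c_k$ is the alternating propagator product

$$
L \propto \rho_\mathrm{start}\, e^{H\tau_1} D_{c_1} e^{H\tau_2} D_{c_2}
\cdots D_{c_K}\, e^{H\tau_\mathrm{end}} \mathbf{1}^\top,
\qquad \rho_\mathrm{start} G = 0,
$$

where $D_j$ holds the detected flux of channel $j$ plus its background
and $H$ the undetected remainder. The number of states is inferred by
placing a Bernoulli *load* on each of $M_{\sigma\max}$ candidate
states; loads gate blocks of $G$ on and off and are Gibbs-sampled from
their likelihood ratios, while all rates carry Gamma priors and are
updated by Metropolis-Hastings in log space. See the methods vignette
(`vignettes/photon-by-photon-inference.Rmd`) for the full account.

## Worked example

Simulate a two-state molecule (escape rates 4.3 and 23.0 s⁻¹, FRET
efficiencies 0.0 and 0.8, realistic cross talk and background), then
let the sampler discover the states:

```r
library(fretjump)

bench <- make_benchmark("robustness_two_state", photons = 1e4, seed = 7)
prior <- prior_config(m_max = 4, lambda_ref_ex = 1e4, lambda_ref_sys = 10)
chain <- run_sampler(bench$trace, bench$truth$det, prior,
                     sampler_config(n_sweeps = 400, burn_in = 100, seed = 8))
summarize_states(chain)
#> <fret_summary> MAP 2 system states (conditioned on 2; 147 sweeps)
#>
#> State-count posterior:
#> # A tibble: 3 × 2
#>   n_states   prob
#>      <int>  <dbl>
#> 1        2 0.49
#> 2        3 0.477
#> 3        4 0.0333
#>
#> Per-state posterior medians [95% CI], states ordered by efficiency:
#> # A tibble: 2 × 7
#>   label efficiency_lo efficiency efficiency_hi escape_lo escape escape_hi
#>   <int>         <dbl>      <dbl>         <dbl>     <dbl>  <dbl>     <dbl>
#> 1     1      0.000694    0.00451        0.0112      1.06   4.52      8.56
#> 2     2      0.782       0.798          0.832       5.95  14.5      30.8
#>
#> Median system-rate matrix (1/s):
#>        [,1]    [,2]
#> [1,] -4.522   4.522
#> [2,] 14.478 -14.478
#>
#> Steady-state populations: 0.76 0.24
```

Reading the output: the most probable model has two system states. The
low-efficiency state (ε ≈ 0.005, unbound-like) escapes at ≈ 4.5 s⁻¹,
right on the ground truth of 4.3; the high-FRET state recovers ε ≈ 0.80
exactly and its escape rate carries a wide interval at this deliberately
small photon budget of 10⁴ — the 95% interval [6, 31] covers the truth
of 23. Longer traces (the published designs use 2×10⁵–2×10⁶ photons)
tighten these intervals; `photon_budget_index()` tells you in advance
which rates a given budget can support. Diagnostics:
`autoplot(chain)`, `plot_state_count(chain)`,
`plot_joint_posterior(chain)`; `tidy()`/`glance()` give tibbles.

A thin command-line interface covers the same pipeline
(`exec/fretjump simulate|fit|summarize|benchmark`), reading YAML run
configurations and writing CSV traces/chains with JSON metadata
sidecars.

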