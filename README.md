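# metakin

Stochastic force-balance modelling and Bayesian inference for metaphase
sister-kinetochore dynamics.

During metaphase, bi-oriented sister kinetochore (KT) pairs oscillate
quasi-periodically along the spindle axis, driven by their K-fibers
switching between polymerising (pushing, +) and depolymerising (pulling, −)
states. `metakin` is for researchers analysing 1D KT trajectories normal to
the metaphase plate (e.g. from lattice-light-sheet tracking): it infers the
biophysical parameters of each sister pair, decides which of a nested
family of mechanical models the trajectory supports, and runs the
population-level analyses — spatial organisation across the plate, sister
asymmetry, temporal tuning toward anaphase, and oscillation-quality
clustering.

## The model

The displacements $X^1_t, X^2_t$ of a sister pair follow the Euler-discretised
force balance

$$X^1_{t+\Delta t}-X^1_t = \Delta t\big({-v_{\sigma^1_t}} - \kappa(X^1_t - X^2_t - L\cos\theta_t) - \alpha X^1_t\big) + \sqrt{\Delta t}\,N(0,\tau^{-1}),$$

(mirrored for sister 2), where the hidden joint K-fiber state
$\sigma_t \in \{++, +-, -+, --\}$ is a Markov chain with per-sister stay
probabilities $p_{coh}$ (coherent states $+-$, $-+$) and $p_{incoh}$
(incoherent $++$, $--$). Speeds $v_- \le 0 \le v_+$, centromeric-spring rate
$\kappa$, centralising rate $\alpha$, noise precision $\tau$, natural length
$L$. Seventeen model variants (sister-asymmetric and exponentially
time-dependent extensions) nest around this vanilla model; marginal
likelihoods come from the forward algorithm, posteriors from adaptive MCMC,
model choice from bridge-sampled Bayes factors navigated over the nesting
network, and hidden states (and LIDS/TIDS/joint switch choreography) from
backward sampling.

## Worked example

Simulate one pair at the reference population medians, fit the vanilla
model, and annotate its hidden states:

```r
library(metakin)
ref <- reference_params()
tr  <- simulate_pair(ref$params, ref$sp, T = 300, seed = 11)
fit <- sample_posterior(tr, "M0", seed = 5)
fit
#> <posterior_fit M0 on cell1/pair1: 6000 draws, max split-Rhat 1.007>
#>             tau  kappa  alpha v_minus v_plus      L  p_coh p_incoh
#> median 673.1987 0.0301 0.0105 -0.0458 0.0081 0.7850 0.9622  0.8287
#> PIR     65.2430 0.0079 0.0014  0.0060 0.0059 0.1549 0.0152  0.0670
```

The posterior medians sit on the generating values (tau 673.7, kappa 0.022,
alpha 0.009, v− −0.041, v+ 0.010, p_coh 0.949, p_incoh 0.760) to within the
posterior spread of a single 300-frame trajectory; `L`'s posterior
reproduces its informative prior (it is not identifiable from the
dynamics). Pooling 10 such pairs recovers every parameter to a few percent
— that experiment is exactly what `scripts/acceptance.R` reruns.

The full analysis workflow lives under `analysis/` as numbered drivers
over the package functions:

```sh
Rscript analysis/01_simulate.R   # synthetic study population + QC -> results/data/
Rscript analysis/02_fit.R        # vanilla-model fits, state annotation -> results/
Rscript analysis/03_select.R     # Bayes-factor model selection reports
Rscript analysis/04_plate.R      # radial trends, drag check, asymmetry null,
                                 # variance components, transverse organisation, tuning
Rscript analysis/05_cluster.R    # oscillation-quality DTW clustering
```

Each step prints what it found and writes its tables under `results/`.

## Package layout

- `R/` — model core (simulation, transition chain, drag scaling, tuning
  law), likelihood/MCMC/bridge sampling, model selection, population
  statistics, DTW clustering, the synthetic-population generator, and the
  packaged experiments.
- `src/` — Rcpp forward filter, backward sampler and banded DTW.
- `vignettes/metaphase-dynamics.Rmd` — the methods write-up: model,
  priors, missing-data treatment, selection rule, generator assumptions and
  limitations.
- `tests/testthat/` — unit, property and end-to-end acceptance tests.
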