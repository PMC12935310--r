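---
title: "Switching force-balance models of metaphase sister-kinetochore dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Switching force-balance models of metaphase sister-kinetochore dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metakin)
```

## The model

During metaphase, bi-oriented sister kinetochores oscillate quasi-periodically
along the spindle axis. `metakin` models the 1D displacements $X^1_t, X^2_t$
of a sister pair normal to the metaphase plate as an Euler-discretised pair of
stochastic difference equations driven by a hidden directional state:

$$X^1_{t+\Delta t} - X^1_t = \Delta t\left(-v_{\sigma^1_t} -
\kappa\,(X^1_t - X^2_t - L\cos\theta_t) - \alpha X^1_t\right) +
\sqrt{\Delta t}\,N(0, \tau^{-1}),$$

with the mirrored equation (sign of the K-fiber force flipped) for sister 2.
Each sister's K-fiber is either polymerising (pushing, $+$, speed
$v_+ \ge 0$) or depolymerising (pulling, $-$, speed $v_- \le 0$); the joint
state $\sigma_t \in \{++, +-, -+, --\}$ follows a discrete-time Markov chain.
The chain is built product-form from per-kinetochore stay probabilities:
each sister independently keeps its direction over a frame with probability
$p_{coh}$ when the pair is coherent ($+-$, $-+$; both sisters translating the
same way) and $p_{incoh}$ when incoherent ($++$ compressing, $--$ stretching
the centromeric spring). All forces are drag-normalised, so $\kappa$ (spring)
and $\alpha$ (centralising force) have units of s$^{-1}$ and the K-fiber
terms are speeds in $\mu$m/s; $\tau$ is the precision of the diffusive noise
and $L$ the spring natural length. Saw-tooth oscillations emerge when
coherent states are longer-lived than incoherent ones.

Around the symmetric "vanilla" model sit sixteen extensions forming two
nested families (17 models in all, `model_ids()`): sister-*asymmetric*
models in which any subset of $\{v_-, v_+, \tau\}$ differs between sisters
($\kappa$, $\alpha$, $L$ are physically shared), and *time-dependent* models
in which any subset of $\{v_-, v_+, \tau, \kappa, \alpha\}$ evolves
exponentially, $p(t) = p_0 e^{p_1 t}$, preserving sign while approximating
weak linear drift. A combined variant ([combined_params()]) relaxes
per-sister forces toward shared anaphase-ready set points and is provided
for simulation.

Three further ingredients close the biology: a position-dependent drag
profile $\gamma(r)$ rescales all mechanical parameters exactly
([apply_drag_scaling()]: speeds and rates divided by $\gamma$, precision
multiplied by $\gamma^2$), which yields the testable prediction that under a
pure drag explanation $v_\pm, \kappa, \alpha, \tau^{-1/2}$ share one radial
profile; and the tuning law $dv_-/dt = (a v_- + b)\,v_-$ with closed form
$1/v_-(t) = -a/b + e^{-bt}(1/v_-(0) + a/b)$, whose stable fixed point
$-b/a$ is the anaphase-ready pulling speed.

## Inference

The hidden chain is marginalised analytically: the likelihood of a
trajectory is computed by the forward algorithm over the 4 joint states with
independent per-sister Gaussian increment emissions (exactly the Euler
discretisation above — no higher-order scheme, so the likelihood and the
simulator agree by construction). This makes the continuous-parameter
posterior available to any MCMC kernel. The packaged sampler is a
MAP-initialised mixture kernel in unconstrained space (log for positives,
logit for probabilities): 70% adaptive independence proposals from a
moment-matched multivariate-t approximation, 30% adaptive random-walk moves.
Two chains are run; convergence is flagged at split-$\hat R < 1.01$ with one
automatic retry at doubled length, and non-converged fits are marked for
exclusion rather than silently used.

Priors are weakly informative with supports matching the sign constraints:
gamma on $\tau$, half-normal on $\kappa$, $\alpha$, $v_+$, negative
half-normal on $v_-$, uniform on the stay probabilities, normal on time
rates. $L$ is special: it is practically unidentifiable from the dynamics,
so it carries an informative truncated normal prior centred on the
accessory spindle-free measurement of 0.78 $\mu$m with s.d. 0.1225 $\mu$m
(variance 0.015). That width was chosen so the prior, not the trajectory,
pins $L$ — the fitted posterior should and does essentially reproduce the
prior, which the tests assert.

**Missing data.** A frame with a missing sister contributes no emission
factor while the chain still propagates through the transition matrix. An
increment spanning $k$ missing frames is treated as a single $k\Delta t$
Gaussian whose drift is evaluated at the last observed positions
(first-order hold) and attached to the state at the end of the gap. This is
exact for the dominant single-frame gaps and a documented approximation for
longer ones; the unit tests pin the exact semantics against a hand-built
oracle.

**Hidden-state annotation.** Conditional on parameter draws, exact state
paths are drawn by backward sampling from the forward filter. Directional
switches (one coherent state to the opposite one) are classified by which
sister moved first: the leading (pulling) sister initiating gives a LIDS and
passes through $++$; the trailing sister a TIDS through $--$; a single-frame
transition is a joint switch. On symmetric-model simulations LIDS and TIDS
are equally frequent by model symmetry — any empirical imbalance is a data
property, not a model one.

## Model selection

Marginal likelihoods are estimated by iterative optimal bridge sampling
against a moment-matched Gaussian proposal in unconstrained space (1000
proposal draws, bridge-identity tolerance $10^{-6}$), with a Monte-Carlo
standard error; if the bridge iteration fails the estimator falls back to
plain Gaussian importance sampling and flags reduced reliability. Bayes
factors use the evidence scale with half-open categories at 3.2 / 10 / 100
(substantial / strong / decisive, lower bounds closed). The preferred model
per pair is found by navigating the nesting network: keep models beating
vanilla by BF > 3.2; prune any model not beating *every* kept nested
submodel (the stricter all-ancestors reading); pick the survivor with the
highest BF against vanilla, breaking ties within one combined standard
error toward the simpler model. The default asymmetric candidate set is the
five models reported in the population analysis (`asym_candidates()`); the
full family sits behind `full = TRUE`.

## The synthetic-data generator

`generate_population()` emulates the tracked populations the analysis
assumes, with every stochastic choice recorded in a ground-truth table. Its
defaults are the study conditions: cells of on average 40 pairs, 300 frames
at $\Delta t = 2.05$ s, base parameters at the reference population medians
($\tau = 673.7$, $\kappa = 0.022$ s$^{-1}$, $\alpha = 0.009$ s$^{-1}$,
$v_- = -0.041$, $v_+ = 0.010$ $\mu$m/s, $L = 0.808$ $\mu$m,
$p_{coh} = 0.949$, $p_{incoh} = 0.760$). Radial positions are drawn
uniformly over a 5 $\mu$m disc; each mechanical parameter follows a
multiplicative trend, linear in the radial quantile, anchored so the
centre-to-periphery drops equal the reported percentages (38% $v_-$, 25%
$v_+$, 53% $\kappa$, 9% $\alpha$, and a 10% rise of $\tau^{-1/2}$).
Sister asymmetry is *not* labelled: each kinetochore draws its forces
log-normally with a negative correlation (default $-0.5$) between pulling
and pushing strength, so asymmetry is a continuum and "asymmetric pairs"
arise only downstream from model selection — matching the interpretation
that sister differences equal differences between random kinetochores. A
tuned fraction (default 46.6%) carries exponential force rates lying on the
tuning line toward set points $v_-^* = -0.033$, $v_+^* = 0.003$ $\mu$m/s.
Missing data follow a geometric-gap renewal process calibrated to a target
missing fraction. A nocodazole-washout-like preset shifts the base values
($v_+$ $-37.5$%, $|v_-|$ $-5.8$%, $\tau$ $+20$%, $\alpha$ $+15$%, $\kappa$
$-40$%).

What the generator does *not* emulate: 3D spindle geometry and projection
effects (cos$\theta_t$ is generated near 1; swivel is not modelled),
inter-pair mechanical coupling, anaphase dynamics, and tracking artefacts
beyond random gaps. Passing recovery tests therefore demonstrate that the
inference machinery is correct and well calibrated under the model's own
assumptions — not that those assumptions hold in any particular imaging
dataset.

## Population analyses

- **Oscillation summaries**: mean-removed mid-point ACF with per-lag
  pairwise-complete normalisation; depth = global ACF minimum; period = lag
  of the first local maximum after the first minimum (both read-outs chosen
  here; the literature uses them informally).
- **Plate width**: square root of the smallest covariance eigenvalue of a
  kinetochore point cloud.
- **Anaphase alignment**: $t = 0$ at the cell's median pair onset;
  mid-metaphase (330–230 s before onset) and late metaphase (130–30 s)
  windows are named selections.
- **Radial partition**: equal-count groups by mean radial position, ties
  broken by stable pair id; the drag-consistency check compares
  centre-to-periphery relative changes of $v_\pm, \kappa, \alpha,
  \tau^{-1/2}$ and flags spreads beyond tolerance.
- **Randomised-pairing null**: sister pairings shuffled within radial groups
  (so spatial trends do not masquerade as pairing structure), compared by
  Mann-Whitney and Kolmogorov-Smirnov tests on absolute differences.
- **Variance decomposition**: additive cell + location two-way ANOVA for
  significance with random-intercept variance components; cells must
  contribute at least 3 pairs per occupied radial group.
- **ACF clustering**: banded dynamic-time-warping distances (Sakoe-Chiba
  half-width 10 lags by default) with agglomerative clustering cut at 5;
  labels are renumbered by centroid depth so cluster 1 is always the
  deepest (strongest-oscillator) class.

A structural point shapes the clustering work. Because the switching chain
has constant per-frame probabilities, directional dwell times are geometric
and the direction process has a monotone autocorrelation; single-pair
mid-point ACFs under this model are therefore monotone mixtures of decays —
the model cannot produce a genuine periodic ACF lobe at the observed ~84 s
period (empirical lobes require switching coupled to position or tension,
which this model family deliberately omits for identifiability). The
oscillation-quality archetypes are accordingly built as a ladder of
directional-persistence times: strong oscillators alternate direction
quickly (deep, fast-dropping ACF), poor oscillators combine weak forces
with slow switching (flat, featureless ACF). Force magnitudes decrease from
strong to poor presets; the empirical weak-drive reading of poor pairs
(diffusion-dominated position noise) produces ACF estimates too variable to
cluster and is noted as a generator limitation. For the planted-archetype
recovery experiment the ACFs are sampled on a geometric lag grid (dense
below 10 s, extending to 210 s), archetype trajectories run 1200 frames to
stabilise the per-pair estimate, and the DTW machinery is run with a zero
warping band, Ward linkage and a few medoid-reassignment passes after the
cut: the planted classes differ exactly by decay time scale, which is
precisely the feature a warping band removes, so widening the band
degrades planted-class recovery.

## Numerical choices and limitations

Simulation and likelihood share the Euler discretisation, so there is no
discretisation mismatch to tune. The forward recursion is scaled per step
(no underflow for the trajectory lengths involved). Initial hidden states
default to the chain's closed-form stationary distribution; initial
positions default to the deterministic fixed point of the starting state.
The time origin of the exponential laws is the first fitted frame.
Degenerate inputs fail loudly: all-missing trajectories, non-constant time
grids, probabilities outside $[0,1]$, non-positive drag factors and
single-cell variance decompositions raise errors; a zero-slope tuning
regression returns a flagged undefined set point rather than a number.

Problem sizes in the packaged experiments (10-pair recovery runs, 20-pair
selection arms, 30–50 pairs per archetype) were fixed once as the smallest
populations at which the Monte-Carlo error of each summary is comfortably
inside the tolerance being checked; they are the package's own choices and
are recorded in `R/experiments.R`.

Known limitations: the sampler is a general-purpose Metropolis scheme, not
Hamiltonian — long trajectories with extreme parameter correlations may need
the built-in retry or more draws; bridge-sampling errors are approximate for
autocorrelated draws (an effective-sample-size correction is applied); the
gap treatment is approximate beyond single-frame gaps; and model selection
over the time-dependent family inherits the weak identifiability of slow
rates on short trajectories — on 300-frame series only strong tuning is
reliably detected, which is why the tuning experiment regresses over pairs
rather than trusting single-pair rates.
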