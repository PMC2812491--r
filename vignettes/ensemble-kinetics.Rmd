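---
title: "Ensemble kinetic modeling of signaling networks with enkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble kinetic modeling of signaling networks with enkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enkin)
```

## The modeling problem

Signal transduction networks are naturally written as systems of mass-action
ordinary differential equations,

$$\frac{dx}{dt} = S\, r(x; k), \qquad
  r_q = k_q \prod_{j \in \mathcal{R}_q} x_j^{\sigma_{jq}},$$

where $S$ is the stoichiometric matrix (species $\times$ reactions,
negative entries for consumption), $x$ the species concentrations and $k$
the rate constants. Every reversible interaction is split into two
irreversible steps, so each reaction carries exactly one rate constant and
the parameters fall into three families — association, dissociation and
catalytic constants. Because the rate laws are polynomial, the state
Jacobian $A = \partial(S r)/\partial x$ and the parameter derivative matrix
$B = \partial(S r)/\partial k$ have closed forms, which `enkin` generates
automatically from the network definition and feeds to the stiff
integrator (`deSolve::lsoda`) and to the sensitivity machinery.

Training data for such models are typically immunoblot densitometry
series: *arbitrary units*, accurate only up to an unknown multiplicative
constant per blot. Because of that, and because dozens to hundreds of rate
constants can never be identified uniquely from a handful of blots, the
package does not fit one best parameter vector. It estimates an *ensemble*
of parameter sets consistent with the data and propagates the ensemble —
not a point estimate — through every downstream analysis.

## Model scoring with unknown measurement scales

An observation $M_{ij}$ of species $j$ under condition $i$ with standard
deviation $\sigma_{ij}$ is compared against the simulated value
$\hat{x}_{ij}$ after an optimal per-(dataset, species) scale factor

$$\beta_j = \frac{\sum_i M_{ij}\hat{x}_{ij}/\sigma_{ij}^2}
                 {\sum_i \hat{x}_{ij}^2/\sigma_{ij}^2},$$

the closed-form least-squares minimizer, clamped at zero (concentrations
cannot change sign). The normalized mean squared error is

$$E(k) = \frac{1}{N_{\mathrm{obs}}}\sum_{i,j}
         \left(\frac{M_{ij} - \beta_j \hat{x}_{ij}}{\sigma_{ij}}\right)^2 .$$

The denominator convention (total observation count) is a package choice;
it only sets the scale of the acceptance temperature below. Observations
without a reported error get $\sigma = 0.1\,|M|$; observations flagged as
unclearly quantified get an augmented fraction between 20% and 100%.
Every simulated condition starts from a windowed approximate steady state:
the model is integrated in windows of $T = 10$ simulated hours until
$\lVert x(t+T) - x(t) \rVert_2 < 0.01$ (plain Euclidean norm over the full
state vector; both the window and the tolerance are overridable defaults).

## The Metropolis ensemble

Starting from a hand-tuned guess $k_0$, new parameter sets are proposed by
a random walk in natural-log space, $\log k' = \log k + \mathcal{N}(0,
\Lambda^2)$ elementwise, which respects positivity and the orders-of-magnitude
spread of rate constants. A proposal is accepted with probability 1 when it
does not increase $E$, and with probability $\exp(-\Delta E / E_0)$
otherwise. The Boltzmann form is a package decision: $E_0$ is exactly the
"temperature" that tunes the acceptance rate, and the rule reduces to
greedy descent as $E_0 \to 0$ (a tested property). Defaults follow the
values used in this family of studies: $\Lambda = 0.05$ and $E_0 = 0.5$
for the bundled recovery experiment.

Consecutive chain states are correlated. The package computes the
autocorrelation function of the scalar error series, fits
$C(\tau) = e^{-\tau/\tau_c}$ to its positive part, and keeps every
$\lceil \tau_c \ln 20 \rceil$-th accepted state — the lag at which the
fitted autocorrelation has dropped to 5% of its initial value. The error
series is used (rather than per-parameter series) because it is the single
well-defined scalar the acceptance rule itself sees. On a synthetic AR(1)
series with $\rho = 0.9$ the fitted interval lands within a few steps of
the analytic value $\ln 20 / \ln(1/\rho) \approx 28$.

## Sensitivity analysis

First-order sensitivities $s_{ij}(t) = \partial x_i/\partial k_j$ solve the
linear matrix ODE $\dot{s}_j = A(t)\, s_j + b_j(t)$ with $s_j(0) = 0$ for
rate-constant parameters. States and all requested sensitivity columns are
integrated jointly as one extended system, so $A$ and $b_j$ are always
evaluated on the exact trajectory. Sensitivities are aggregated into one
Overall State Sensitivity Coefficient per parameter,

$$\mathrm{OSSC}_j = \sqrt{\frac{1}{N_T N_x}\sum_t \sum_i
  \left(\frac{k_j}{\max(x_i(t), \varepsilon)}\, s_{ij}(t)\right)^2},$$

an RMS of log-scaled sensitivities with $\varepsilon = 10^{-6} \times$ the
maximum state value guarding near-zero states. **This is the one
reconstructed formula in the package**: the aggregation follows the OSSC
lineage of the sensitivity literature, and it is isolated in a single
function (`ossc()`) so an alternative normalization can be swapped in.
The scanning protocol is fixed: run the clone to its approximate steady
state, add the hormone stimulus (10 A.U.), and integrate sensitivities for
100 s on 101 uniform points. Parameters are ranked by OSSC magnitude —
large rank = fragile, ties broken deterministically by parameter order —
and rank shifts between clones are assessed per parameter with a Welch
two-sided t-test across ensemble members, flagged "large" beyond one
standard deviation of all shifts. No multiple-testing correction is
applied by default (`p_adjust = "BH"` enables one), so ~5% of null
parameters will flag as significant, a behavior the test suite checks.

## Perturbation analyses

*Robustness.* The effect of knocking a protein in (×10), down (×0.1) or
out (×0) on a marker is the ratio of time-integrated marker concentration
in the perturbed versus unperturbed system, both run from their own steady
states, stimulated at 1 h and integrated to 72 h after the stimulus
(trapezoid rule on 500 log-spaced points). A perturbation scales both the
species' initial pool and — for synthesized species — every reaction whose
only net product is that species (zero-order expression and catalytic
synthesis such as translation). Scaling only the initial pool would let
constitutive expression regenerate the protein over 72 h, which would
contradict a knock-out.

*Synergy.* For two signaling axes A and B, the steady states of four
systems are compared: wild type, each single knock-out, and the double
knock-out as the control. With $\Delta_A = q_A - q_{\mathrm{ctrl}}$ etc.,

$$\alpha_j = \frac{\Delta_{AB} - \Delta_A - \Delta_B}{q_{\mathrm{wt}}},$$

so $\alpha > 0$ marks super-additive coupling. Normalizing by the
wild-type value (rather than the control) is a package decision, made
because the wild type is the only state defined for every quantity in both
conventions under consideration; the contrast is isolated in one internal
function. Classification over the ensemble uses the percentile 95%
interval (2.5–97.5%) rather than a normal approximation — no
distributional claim is made about ensemble spread.

## The bundled synthetic model

The package ships a 29-species, 35-reaction network that is a *structural*
surrogate for hormone-responsive signaling: a growth-factor receptor with
auto-activation, a phosphatase that deactivates the receptor and whose own
expression is repressed by the active hormone receptor, a three-tier
kinase cascade, a PI3K/Akt/TOR branch that liberates the translation
initiation factor from its sequestering complex, a chaperone-sequestered
hormone receptor activated both by hormone and by the terminal cascade
kinase (the "outlaw" route), and transcription/translation of a secreted
marker (PSA-like), a proliferation marker (cyclin-D-like) and the
phosphatase itself. Translation requires mRNA, free initiation factor and
ribosome simultaneously — the bimolecular coupling that lets the two axes
show positive synergy on the proliferation marker. Clone variants scale
the phosphatase expression rate: 1.0 (hormone-dependent), 0.5
(intermediate), 0.01 (hormone-independent), and reproduce the designed
phenotype ordering: the independent clone has a several-fold higher basal
marker level, while the dependent clone shows the larger *relative*
response to hormone addition.

Ground-truth rate constants were hand-placed so that the hormone-dependent
clone sits at a low-activity basal state (active receptor ≈ 0.2 A.U.,
phosphatase ≈ 20 A.U.) and the independent clone at a high-activity one;
degradation rates of ~1e-4/s put expression dynamics on the multi-hour
scale so the 10 h steady-state window and the 72 h stimulation horizon are
meaningful. The chain start `k0` is the truth under one fixed log-normal
15% jitter, shipped as a text file — mimicking a hand-tuned initial guess
that already roughly replicates the data.

### What the data generator emulates — and what it does not

`generate_training_data()` simulates seven datasets at the ground truth
(hormone time courses per clone, short cascade-activation dynamics, ±50%
steady-state perturbations of receptor and kinase levels, a two-dose
hormone response and a basal signaling panel), multiplies each
(dataset, species) series by a hidden scale drawn log-uniformly from
[0.1, 10], adds 10% Gaussian noise and records that 10% as the observation
error. This emulates pseudo-immunoblot series well enough to exercise
every pipeline stage: the scale factors must absorb two orders of
magnitude of unit arbitrariness, and in noiseless mode the fitted betas
recover the hidden scales and the error at the truth is exactly zero
(both tested). It does **not** emulate real blot pathologies — saturation,
baseline subtraction artifacts, correlated errors within a lane, or
model-structure error (the generating model is the fitted model). Passing
tests therefore demonstrate the machinery's correctness, not robustness of
the biology to misspecification.

## Problem sizes and numerical choices

The bundled recovery experiment runs 2 chains × 300 Metropolis steps
(about 600 steady-state-conditioned scoring evaluations) and thins them to
an ensemble of order ten members; these sizes were chosen so the complete
workflow — fitting, OSSC ranking, rank shifts, robustness panel and
synergy screen — finishes in minutes on a single core while still giving
a non-degenerate ensemble. Consequences of the small scale are stated
honestly: ensemble coefficients of variation mostly reflect random-walk
diffusion around the optimum rather than fully explored posterior widths,
so CV contrasts between well- and poorly-constrained parameters are not
resolved (the z-score recovery check is the meaningful statement at this
scale). A production run would use the same code with thousands of steps
per chain and many chains.

Other numerical choices: integration tolerances 1e-6 (relative) / 1e-9
(absolute) for simulation, tightened to 1e-8/1e-12 for the sensitivity
system because finite-difference cross-checks at 1e-4 demand it; event
times handled by stopping and restarting the integrator so discontinuities
are exact; hormone addition implemented as an *increment* (ligand is added
to the medium on top of basal levels, not clamped); knock-outs keep rate
constants at 1e-300 rather than 0 to preserve the strict-positivity
invariant of the parameter container while being numerically silent;
states are clamped at zero inside the right-hand side to absorb integrator
round-off of order 1e-12. Steady-state detection declares failure after
200 windows and the scoring function converts any simulation failure into
an infinite error, which the Metropolis rule rejects automatically.

## Known limitations

- Deterministic, population-averaged kinetics only; no stochastic
  simulation, no spatial gradients, and no separate nuclear compartment
  (membrane/cytosol/extracellular tags are bookkeeping, not transport).
- The OSSC normalization is reconstructed (see above) and rank-based
  conclusions should be read as ordering statements, not absolute
  sensitivities.
- Autocorrelation thinning is the only decorrelation device; no
  cross-chain correlation constraint is applied when pooling chains.
- The toy network is a structural surrogate: its numbers are not
  predictions about any cell line.

## A short tour

```{r tour, eval = FALSE}
bundle <- build_toy_network()
training <- generate_training_data(bundle, seed = 1)

# ensemble estimation
rec <- recovery_experiment(bundle, seed = 1)
glance(rec$ensemble)

# fragility ranking for the hormone-independent clone
ranking <- ossc_protocol(bundle$network, bundle$theta_star, "AI", bundle$clones)
autoplot(ranking)

# knock-in / knock-down / knock-out panel
panel <- robustness_panel(bundle$network, rec$ensemble,
                          markers = bundle$markers, targets = bundle$targets,
                          clone = "AI", clones = bundle$clones)
autoplot(panel)

# synergy screen between the cascade and the Akt branch
screen <- synergy_screen(bundle$network, rec$ensemble, "K1", "AKT",
                         "AI", bundle$clones)
autoplot(screen)
```
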