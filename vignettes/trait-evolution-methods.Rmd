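---
title: "Models, bridges and rate scans: the methods behind traitbridge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, bridges and rate scans: the methods behind traitbridge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

traitbridge analyses a single continuous trait on a rooted time tree. This
vignette explains the models, the estimation machinery, the simulation and
visualization method, and the design choices made where several defensible
options existed. Time runs from the root (height 0) towards the tips, and
all rates are per unit of that (usually relative) time scale.

## The model battery

All families are Gaussian processes along the branches, so the tip values
are jointly multivariate normal with a mean vector and covariance matrix
determined by the tree, the model, and a *regime painting* — a
piecewise-constant assignment of a regime label to every point of every
branch (class `regime_map`). Along a painting segment of duration $dt$ in
regime $k$:

* **Ornstein–Uhlenbeck** ($\alpha_k > 0$): the conditional mean relaxes
  towards the optimum, $m \mapsto \theta_k + (m-\theta_k)e^{-\alpha_k dt}$,
  and the conditional variance evolves as
  $v \mapsto v e^{-2\alpha_k dt} + \sigma^2_k(1-e^{-2\alpha_k dt})/(2\alpha_k)$.
* **Brownian-type** ($\alpha = 0$): the mean is unchanged and the variance
  grows by the integrated rate — $\sigma^2_k\,dt$ for BM1/BMS, and
  $\sigma_0^2(e^{r t_2}-e^{r t_1})/r$ for the ACDC family whose rate is
  $\sigma^2(t)=\sigma_0^2 e^{rt}$ ($r<0$ decelerating/early burst, $r>0$
  accelerating).

The covariance of two tips is the variance accumulated at their most recent
common ancestor times the $e^{-\alpha\,dt}$ decay factors along both
descending paths. This single recursion (implemented once, in C++) serves
the likelihood, the simulator's sanity checks, and the envelope math; its
correctness is pinned by a test that rebuilds covariances per tip pair by
numerically integrated path sums on random painted trees for every family
(agreement to $10^{-8}$).

**Root handling.** For OU families the root state is fixed at the optimum
of the root regime (a non-stationary start). This convention makes OU1 with
$\alpha \to 0$ collapse exactly onto BM1 with $x_0 = \theta$, keeps the
parameter count at the conventional values (OU1: 3; OUM: $m+2$; OUMV/OUMA:
$2m+1$; OUMVA: $3m$; BM1: 2; BMS: $m+1$; ACDC: 3), and avoids an extra
weakly identified root parameter. The root regime is read from the parent
end of the first root-child edge; paintings produced by the package always
give the root's children a common starting regime.

**Measurement error.** Three modes: none; fixed per-tip standard errors
added to the covariance diagonal as $SE^2$; or one common SE estimated as
an extra free parameter (adds 1 to $k$) — the usual robustness check
against spurious support for parameter-rich models.

## Fitting and model comparison

BM-type likelihoods are evaluated in $O(n)$ by Felsenstein pruning with
per-branch variances; OU-type likelihoods build the full covariance (also
$O(n^2)$ after the recursion) and profile the optima analytically by
generalized least squares at every step — the mean is linear in
$(\theta_1,\dots,\theta_m)$, so given the variance parameters the ML optima
are a GLS solve (rank-deficient designs, which arise as $\alpha \to 0$, are
resolved by a minimum-norm SVD solution). The remaining free parameters are
optimized on the log scale by `L-BFGS-B` from a deterministic grid of five
starts (selection strengths log-spaced on $[0.1/T,\,20/T]$, rates anchored
at the single-rate ML estimate), with bounds $\sigma^2 \in [10^{-8},
100\,\mathrm{var}(x)/T]$, $\alpha \in [10^{-8}, 50/T]$, $r \in [-10/T,
10/T]$. Because the optima are profiled they are not box-constrained; in
practice they land inside the data range for identifiable fits.

Model comparison uses $AICc = -2\ln L + 2k + 2k(k+1)/(n-k-1)$ with $n$ the
number of tips, $\Delta AICc$ against the best model, and Akaike weights
$\omega_i = e^{-\Delta_i/2}/\sum_j e^{-\Delta_j/2}$. Models within 0.01
AICc units are ordered by parameter count (simpler first). Blomberg's K is
computed from its definition: the observed ratio of the mean squared
deviation from the phylogenetically corrected mean over the GLS mean
squared error, scaled by its Brownian expectation
$(\mathrm{tr}(V) - n/\mathbf{1}'V^{-1}\mathbf{1})/(n-1)$; it is
cross-checked against an independent implementation in the test suite.

## Regime paintings from binary characters

`fit_mk2()` fits a two-state Markov model (equal-rates or all-rates-
different) by pruning over the closed-form 2×2 transition probabilities,
with rate bounds $[10^{-8}, 100/T]$ and three log-spaced starts, and
returns marginal ancestral probabilities from the standard up/down pass.
The default root prior is flat; stationary is available. Paintings
discretize the marginals by arg-max, breaking ties towards the parent's
state so that paintings stay parsimonious, and each edge carries the state
of its child node (the common multi-regime-OU convention). Whether marginal,
joint, or stochastic reconstructions should define regimes is a genuinely
open choice; arg-max marginals are used because they are deterministic and
reproducible, at the cost of ignoring reconstruction uncertainty.

## The rate scan (reversible-jump MCMC)

The multi-rate Brownian posterior is sampled over states $(S, r)$: a set of
shift edges $S$ (era semantics — a shift governs its whole descendant clade
until overridden) and one rate per class. Priors, unstated in the tradition
this follows and therefore chosen weakly informative: the number of shifts
is truncated Poisson with mean $\log 2$, shift locations are uniform over
edge subsets, and log rates are Normal centred on the log single-rate ML
estimate with SD 1.5. The likelihood marginalizes the root state under a
flat prior (the contrast/REML likelihood), which keeps the target proper
and is computed by the same $O(n)$ pruning as the ML fits. Proposals mix
birth (new class rate drawn from its prior, so the acceptance ratio reduces
to the likelihood ratio times $\lambda/(k+1)$), death, a move to an
adjacent edge (with the exact Hastings correction for neighbourhood sizes),
and a Normal random-walk update of one log rate. Default chain settings are
100,000 generations, sampling every 100, 25% burn-in (750 retained
samples); a run aborts with diagnostics after 1,000 consecutive rejections.
Correctness is checked two ways: per-branch posterior painting frequencies
on a 4-tip tree match direct quadrature enumeration of the posterior within
Monte Carlo error, and calibration/power behave as expected at scale (no
spurious shifts on single-rate data; a ten-fold clade shift is recovered
with high posterior probability).

Two AIC summaries mirror common practice: `map_painting_ml()` refits the
era painting of a chosen shift set by ML (the non-censored approach,
$k = \#\text{classes}+1$), and `best_sample_aic()` summarizes the chain
itself. The latter returns the *minimum per-sample AICc* (each sample
penalized by its own class count) rather than the AICc of the single
highest-likelihood sample: the two coincide on single-class chains, and the
minimum is monotone under chain extension, which the literal reading is
not.

## Simulation and the traitgram

`simulate_ensemble()` draws exact Gaussian transitions segment by segment —
no Euler discretization — so ensemble moments converge to the analytic
moments at the Monte Carlo rate (tested at $10^4$ realizations on a 5-tip
tree for BM1, OU1 and OUMVA within 3 Monte Carlo SEs). One seeded stream
drives the whole ensemble with one vectorized draw per painting segment;
realization $i$ is column $i$ of those draws. This replaces per-realization
substreams: it preserves the determinism contracts that matter (a fixed
seed reproduces the ensemble bit-for-bit; `n_real = 1` reproduces a single
realization) while making large ensembles cheap in R. Root states are drawn
from an explicit Normal(mean, sd) — the posterior-of-root-states sampling
that motivated this interface is emulated by passing the ML root estimate
and a user-chosen sd (default 0), since no root-posterior machinery is in
scope. Values at interior painting boundaries are recorded during
simulation so that every bridge segment has exact endpoints.

For visualization, each branch segment is interpolated with the OU bridge
anchored at both simulated endpoints; Brownian segments use the straight
line (the $\alpha \to 0$ limit). The bridge's second term is anchored at
the *right* endpoint value $x(t_j)$: the variant that circulates with both
numerators anchored at $x(t_i)$ fails the $t = t_j$ boundary condition and
is provided only behind `variant = "printed"` for comparison. The sinh
ratios are computed as $e^{a-b}\,\mathrm{expm1}(-2a)/\mathrm{expm1}(-2b)$
so that large $\alpha$ cannot overflow, and $\alpha(t_j-t_i) < 10^{-8}$
falls back to linear interpolation.

`envelope()` summarizes an ensemble on a grid of 512 uniform time points
plus all node heights (so node times are exact): for each realization and
time it takes the min and max over all lineages alive at that time, then
reports the 2.5th percentile of the minima and the 97.5th percentile of the
maxima — a band of *trait ranges*, not of pooled values, which is the
reading that matches "minimum and maximum trait values across clades at any
time". Branches cover the half-open interval from the parent's height
(inclusive) to the child's (exclusive), so a node's value is counted once
on the child side; tip branches include the final time.

## The synthetic-data generators

`yule_tree()` simulates the pure-birth process forward (exponential waiting
times, uniform lineage choice, cut at the next unrealized event) and
rescales heights to $T = 1$, the relative-time convention of the analyses;
`rescale = FALSE` exposes the nominal time scale, on which the
lineage-through-time slope matches the birth rate (a test property).
`make_recovery_dataset()` composes a seeded Yule tree, an optional one-shift
era painting on the largest clade holding 20–40% of the tips, and one exact
simulation of the requested model; it is a pure function of (parameters,
seed). These generators emulate the shape of comparative datasets —
ultrametric trees, a clade-structured regime, Gaussian trait dynamics —
but not their complications: no fossil/non-ultrametric sampling, no
topology or painting uncertainty, no non-Gaussian tails, and measurement
error only as specified. Passing tests therefore certify the estimators and
samplers under their own assumptions, not robustness to violations of them.

Test problem sizes were chosen to make the statistical checks sharp at
desk scale: rate-recovery runs use 100 replicates of 200 tips (single-rate
BM) and 50 of 300 tips (OUMVA), selection-consistency 50 replicates of 200
tips, K calibration 1,000 simulations on one 50-tip tree, and the MCMC
checks 200,000 generations.

## Numerical choices and degenerate inputs

Likelihood evaluations that hit a singular covariance (duplicate
zero-length tips, $\sigma^2 \to 0$) raise an explicit error rather than
returning `-Inf` silently; inside optimization, failed Cholesky factors are
treated as rejected parameter values. Zero-length edges are allowed but
flagged, since they only create ties in node heights. `expm1`/log-space
forms are used wherever $e^{-\alpha t}$ terms could underflow. Paintings
are validated for exact edge coverage at tolerance $10^{-9}$ relative to
tree height. Painting TSVs identify edges by child node id, which follows
the numbering of the tree as read from its Newick file — a painting must be
read back against the same tree file it was written from.

## Known limitations

Single trait only (no correlated-trait models), no Pagel-style
transformations, no trend models, two states only in the Mk module, and no
OU-shift (optimum-jump) MCMC. The rate scan analyses one tree at a time;
replicating it over a posterior tree sample is left to scripting over the
workflow functions. ML estimates of weakly informed OU parameters (small
$\alpha$ relative to the regime's time span) carry the well-known upward
bias and wide spread of that regime's $\alpha$ and $\theta$; the test suite
documents this honestly rather than hiding it, and users should read
per-regime OU parameters on short-lived regimes with corresponding caution.
Similarly, AICc selection between Brownian motion and clade-painted OU
models on a single tree has a non-trivial false-positive rate for the OU
side — chance clade mean shifts under BM are absorbed by the optima — which
is a property of the method, not of this implementation.
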