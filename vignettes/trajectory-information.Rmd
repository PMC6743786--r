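---
title: "Estimating information carried by stochastic response trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating information carried by stochastic response trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajinfo)
```

## The problem

Cells encode information about their environment in the *time courses* of
molecular species, not only in steady-state snapshots. Given a discrete
environmental input $U \in \{u^{(1)}, \ldots, u^{(q)}\}$ with prior $p_U$
(uniform throughout this package's benchmarks) driving a chemical reaction
network, the quantity of interest is the mutual information

$$I(X;U) = H(X) - H(X \mid U)$$

between the input and the response trajectory $X$ observed on $[0, T]$ —
either the full continuous-time event record, or the same path sampled on a
uniform grid of $d$ points, as a microscope would record it. `trajinfo`
computes this quantity exactly (by Monte Carlo, when the network is known),
brackets it with decoding-based lower and upper bounds, and benchmarks
model-free estimators that work on data alone.

## Model-based computation

For a mass-action network, the chemical master equation $\dot p = M p$
assigns every continuous path $x = (\mathbf{s}, \mathbf{t})$ an exact
likelihood: a product of jump rates $M_{s_i s_{i-1}}$ and exponential
survival factors $e^{M_{s_i s_i} t_i}$, with the final interval contributing
survival only. For grid-sampled paths the factors become matrix-exponential
propagators $W = e^{M\Delta t}$. Entropies are then Monte-Carlo averages of
exact log-likelihoods over paths simulated with the Gillespie algorithm:
$\tilde H(X)$ averages $-\log_2 p_X(x)$ (the prior-weighted mixture over
inputs, evaluated by log-sum-exp) and $\tilde H(X|U)$ averages the
conditionals. The difference is the exact Monte-Carlo information — $I^*$
for continuous paths, $I(d)$ for sampled ones, with $I(d) \le I^*$ and
convergence as the grid is refined (information cannot be created by
resampling, a data-processing fact the tests verify).

Numerical choices worth knowing:

* **State-space truncation.** $p(t)$ is infinite-dimensional; generators are
  built on $\{0..X_{\max}\}$ (a lattice product for several species) with
  $X_{\max} = \lceil \bar x_{ss} \rceil + \lceil 10\sqrt{\bar x_{ss}}
  \rceil$, floored at $x_0 + 20$, where $\bar x_{ss}$ is the largest
  steady-state mean across inputs and rate segments (solved from the linear
  mean dynamics; nonlinear networks must supply caps). Poisson-like tails
  make the dropped mass $\sim 10^{-10}$; the generator reports the dropped
  outflow per boundary state as a leak diagnostic, and model constructors
  additionally raise the cap above the largest state actually visited by
  the dataset at hand.
* **Piecewise-constant rates.** Time-dependent inputs are restricted to
  finitely many rate breakpoints (all the benchmarks need is one switch at
  $t = 1000$). The simulator crosses breakpoints exactly by re-proposing the
  dwell from the breakpoint (valid by memorylessness); likelihoods split
  dwell intervals into segment-wise survival terms; grid steps spanning a
  breakpoint multiply the segment propagators.
* **Sampling convention.** The state at a jump instant is the post-jump
  state (right-continuous step functions), which makes resampling
  deterministic and nested grids consistent.
* **Impossible paths** carry an explicit $-\infty$ log-likelihood that
  propagates safely through log-sum-exp; a dataset whose marginal is
  $-\infty$ under every input aborts with a mismatch diagnostic.
* **Units.** All information bookkeeping is in bits; natural-log internals
  are converted once at the boundary.
* **Error bars** default to the standard deviation over 20 independent
  replicate estimations.

## Decoding bounds

A decoder $\hat u = F_\omega(x)$ forms the Markov chain
$U \to X \to \hat U$, so the plug-in information of the $q \times q$
confusion matrix $\epsilon_{ij}$ (joint frequencies of true versus decoded
input) lower-bounds $I(X;U)$. The best possible decoder is maximum a
posteriori (MAP) under the exact path likelihoods, so $I_{\mathrm{MAP}}$ is
the benchmark every model-free decoder is measured against. The same
confusion matrix also yields an upper bound of the Feder–Merhav type:
$I \le H(U) - \sum_{\hat u} p_{\hat U}(\hat u)\, \phi(\pi_{\hat u})$ with
$\pi_{\hat u}$ the column-conditional error and $\phi$ an interpolation of
$\log_2$ between $\lfloor 1/(1-\pi) \rfloor$ and $\lceil 1/(1-\pi) \rceil$.

Two conventions are deliberate. The confusion matrix is stored as a *joint*
table (counts over all test paths) rather than row-conditionals, because the
plug-in formula needs both marginals; with balanced sampling and a uniform
prior the two descriptions differ only by the constant factor $1/q$. MAP
ties are broken toward the smallest label index so repeated runs are
reproducible; random tie-breaking would perturb $\epsilon$ by the order of
the tie fraction. No small-sample debiasing is applied to the plug-in
information by default ($q \le 5$ and $N \ge 100$ in every packaged
experiment; the label-shuffle control verifies the residual bias is
negligible at these sizes).

## Model-free estimators

All decoders share one protocol: a stratified 70/30 train/test split,
fitting on the training part only, decoding the held-out part, and averaging
the confusion-matrix information over (default 20) random re-splits.

* **SVM** (linear and radial-basis-function kernels). The soft-margin dual
  is solved by a maximal-violating-pair SMO iteration written for this
  package (no SVM library exists in the target stack); its solutions are
  checked against an independent reference implementation in the tests.
  $C \in \{0.1, 1, 10, 100\}$ and the rbf width $\sigma \in$ (median
  pairwise distance) $\times \{0.25, 0.5, 1, 2, 4\}$ are chosen by 5-fold
  cross-validation on training data only — grids are a package choice, as
  only the use of cross-validation itself is prescribed. More than two
  classes are handled dendrogram-style: average-linkage clustering of class
  means fixes a binary tree with an SVM at each internal node.
* **Gaussian decoder**: per-class mean and covariance with diagonal (ridge)
  regularization $\Sigma + \lambda I$; $\lambda$ maximizes held-out
  validation likelihood over a log-spaced grid $10^{-4}..10^1$ relative to
  the mean diagonal variance. Decoding is posterior maximization, so the
  estimate stays a true lower bound even though the Gaussian model is wrong
  for counts.
* **MLP**: fully connected network, default 300–200 hidden ELU
  ($\alpha = 1$) units, He initialization, Adam with batch normalization
  and dropout, early stopping on a 15% validation split (max 200 epochs,
  batch 128 — a budget the package fixes, since only the architecture is
  prescribed).
* **knn mutual information** (not a decoder — it targets $I(X;U)$ itself and
  may exceed $I_{\mathrm{MAP}}$): the discrete-label Kraskov variant, using
  max-norm distances to the $k$-th within-class neighbour and digamma
  counts. On raw integer trajectories, whole lattice shells tie at the
  neighbour radius and the count terms explode, driving the estimate far
  negative; iid Gaussian jitter with $\mathrm{sd} = 10^{-3}$ (any value
  $\ll 1$ behaves the same) breaks the ties and is exposed as an option.
* **Gaussian approximation**: analytic conditional entropy plus Monte-Carlo
  mixture entropy. It is *not* a bound and can overestimate; it is included
  as the cautionary baseline and warns when it exceeds $H(U)$.
* **Exponential filtering** (causal low-pass with timescale $\tau$) is
  available for sensitivity analyses; filtering is not applied by default
  since it did not help the Gaussian decoder on the benchmarks it was
  proposed for.

## The packaged benchmarks (what the generator emulates)

Three single-species birth-death networks
$\emptyset \xrightarrow{\alpha(U)} X \xrightarrow{\beta(U)} \emptyset$ with
$q = 2$ equiprobable inputs and $T = 2000$ stylize common signaling motifs:

1. **Steady-state coding** — $x_0 = 0$, $\beta = 0.01$,
   $\alpha = 0.1$ vs $0.07$: the input sets the stationary mean
   ($\alpha/\beta = 10$ vs $7$).
2. **Transient (adaptive) coding** — $\alpha = 0.1$ vs $0.05$ until
   $t = 1000$, then $\alpha = 5\cdot 10^{-4}$ for both inputs: all the
   evidence lives in the pre-switch window, and the information curve is
   flat afterwards. The multilevel variant tiles the same dynamic range with
   $q$ early-phase rates $\alpha_i = 0.1\, i/q$ (the grid excludes zero —
   a zero rate would collapse level 1 into the post-switch regime and
   $q = 2$ would no longer recover the original parameters).
3. **Correlation-time coding** — $x_0 = 10$, rates scaled so both inputs
   share the constant mean 10 while relaxation is two-fold faster under one
   input: nothing is linearly decodable; only trajectory statistics beyond
   the mean carry information.

An extrinsic-noise wrapper perturbs each simulated cell's degradation rate
once by $N(0, \sigma)$ (default benchmark value $\sigma = 10^{-3}$, a 10%
spread on $\beta = 0.01$), held fixed through time, with a $10^{-6}$
positivity floor — a package safeguard, since the additive draw can cross
zero even if it essentially never does at the benchmark settings.

These generators reproduce *intrinsic* reaction noise under exactly known
dynamics. They do not emulate measurement noise, fluorophore maturation or
bleaching, partial observation of species, or cell-to-cell variability
beyond the single-rate extrinsic-noise option. A green test therefore
establishes the estimators' behaviour on an idealized channel whose true
information is computable — it does not certify performance on any
particular experimental dataset, where these unmodeled effects change the
response statistics.

Initial conditions are deterministic in all benchmarks (the model type
accepts a distribution over the truncated space, but nothing exercises it —
the published examples all fix $x(0)$, and the deterministic reading is
also adopted for the grid-sampled case, where every one of the $d$ steps
from the known $x^0$ contributes one propagator factor; the alternative of
discarding the first factor would throw away the informative first step).

## Design choices on open points

* The SVM dual is implemented in the standard soft-margin form with a bias
  term; the bias-free variant changes none of the benchmark conclusions but
  the biased form is what reference implementations solve, which makes the
  cross-check against them meaningful.
* The knn estimator counts within-class neighbours directly against the
  discrete label rather than embedding the label as a jittered coordinate;
  the direct form is exact for mixed discrete–continuous pairs. Jitter on
  the *response* coordinates remains an option because that is where integer
  ties arise.
* `default_state_cap()` refuses nonlinear networks rather than guessing:
  a wrong silent cap would bias every likelihood downstream.
* Scaled-down defaults (`run_benchmark()` uses $N = 300$, $d = 50$, 5
  replicates) keep an interactive run in minutes; the published operating
  point ($N = 10^3$–$10^4$, $d = 100$, 20 replicates) is reached by passing
  those values explicitly.

## Known limitations

* Pure-R SSA and SMO loops: comfortable up to $\sim 10^4$ trajectories and
  $n \sim 10^3$ training points; the $N = 10^5$ deep-training regime for the
  MLP (see `scripts/nn_fullscale.R`) takes hours of CPU.
* Exact computations require every species to be observed; marginal
  likelihoods over hidden species are out of scope.
* Channel-capacity optimization over the input prior is not implemented;
  all benchmarks use the uniform prior.
* The matrix-exponential propagator is dense: multi-species state spaces
  grow as the product of per-species caps and become expensive beyond a few
  thousand states.
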