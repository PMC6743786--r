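# trajinfo

Estimating the information that time-varying stochastic responses of
biochemical reaction networks carry about a discrete environmental input.

Single-cell time series (transcription-factor nuclear localization, ERK or
Ca²⁺ signaling, reporter fluorescence, ...) encode the state of the
environment in whole response *trajectories*, not just in steady-state
levels. The question this package answers, for an input
$U \in \{u^{(1)},\ldots,u^{(q)}\}$ with prior $p_U$ driving a reaction
network: how many bits of mutual information

$$I(X;U) \;=\; H(X) - H(X\mid U)$$

does the response path $X$ on $[0,T]$ — continuous-time, or sampled at $d$
uniform time points — carry about $U$, and how much of it can practical
estimators recover from a finite sample of labeled trajectories?

It is aimed at systems-biology users who either (a) have a mass-action
model (chemical master equation) and want exact, model-based information
values and decoding bounds, or (b) have only labeled single-cell
trajectory tables and want robust model-free lower-bound estimates.

## What it computes

**Model-based (network known).**

* Exact Gillespie (SSA) path sampling, with input-dependent and
  piecewise-constant-in-time rates.
* Exact Monte-Carlo information: path likelihoods
  $p(x|u) = p(s_1)e^{M_{s_1s_1}t_1}\prod_i M_{s_is_{i-1}}e^{M_{s_is_i}t_i}$
  for event lists, propagator products ($W = e^{M\Delta t}$) for sampled
  paths; entropies as Monte-Carlo averages of exact log-likelihoods.
* MAP decoding: the optimal decoder's confusion matrix gives the plug-in
  lower bound $I(\hat U;U)$ and a matching Feder–Merhav-type upper bound
  $I \le H(U) - \sum_{\hat u} p_{\hat U}(\hat u)\,\phi(\pi_{\hat u})$,
  bracketing the exact value.

**Model-free (data only).** Decoding estimators sharing one stratified
70/30 split-and-replicate protocol — linear and rbf-kernel SVM (SMO solver
implemented in-package), diagonally regularized Gaussian decoder,
multilayer perceptron (300–200 ELU units, Adam, batch norm, dropout) — plus
the k-nearest-neighbor mutual-information estimator (discrete-label Kraskov
variant, with optional tie-breaking jitter) and the Gaussian-approximation
baseline. Label-shuffle controls are built in.

**Benchmarks.** Three birth-death networks
$\emptyset \xrightarrow{\alpha(U)} X \xrightarrow{\beta(U)} \emptyset$
stylizing steady-state coding, transient (adapted) coding, and
correlation-time coding with identical means, plus a multilevel-input
variant and an extrinsic-noise wrapper; `run_benchmark()` runs all methods
on identical simulated data and returns a tidy table.

## Worked example

```r
library(trajinfo)

ex <- make_example(1)           # alpha = 0.1 vs 0.07, beta = 0.01, x0 = 0
tset <- simulate_dataset(ex$network, ex$ensemble, ex$x0, T_end = 2000,
                         n_per_input = 300, seed = 1)
model <- path_model(ex$network, ex$ensemble, ex$x0, T_end = 2000, caps = 45L)

exact_info(model, tset)
#> Mutual information (continuous mode): 0.9670 bits

dat <- resample_dataset(tset, d = 100)        # what a microscope records
exact_info(model, dat)
#> Mutual information (discrete mode): 0.9129 bits

b <- map_info_bound(model, dat)
sprintf("I_MAP = %.3f bits, I_UB = %.3f bits, accuracy = %.3f",
        b$I_MAP, b$I_UB, b$accuracy)
#> "I_MAP = 0.832 bits, I_UB = 0.950 bits, accuracy = 0.975"

estimate_info(dat, decoder_spec("svm-rbf"), replicates = 5, seed = 2)
#> Mutual information (decoder mode): 0.7488 bits +- 0.0716 (std over replicates)
```

Reading the numbers: the continuous-time paths carry 0.97 of the 1-bit
maximum for two equiprobable inputs; sampling at $d = 100$ retains 0.91
bits; optimal decoding of the sampled paths certifies at least 0.83 bits
(with the upper bound confirming the true value is below 0.95 here); and a
model-free rbf-SVM, trained on 70% of 600 trajectories and tested on the
rest, already recovers 0.75 bits without knowing the network.

For imported data, `read_discrete_dataset()` accepts wide CSV tables (one
row per cell: id, label, d samples) and every estimator above applies
unchanged. A command-line front end is installed at
`system.file("cli", "trajinfo", package = "trajinfo")` with subcommands
`simulate`, `exact-info`, `map-bound`, `estimate`, `benchmark`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch at the published operating point (N = 1000 SSA
paths per input, T = 2000): the percentage of the 1-bit maximum captured by
the exact continuous-time information on each of the three benchmark
networks (reported as the minimum over examples), the percentage of that
information retained after resampling the same paths at d = 100, and the
bits extracted by the regularized Gaussian decoder on the pre-switch window
of the transient benchmark (d = 50, 20 train/test replicates), writing the
three values as JSON.

`scripts/nn_fullscale.R` is the opt-in, hours-long N = 10⁵ neural-network
decoding run; the default test suite exercises the same code path at
reduced scale.
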