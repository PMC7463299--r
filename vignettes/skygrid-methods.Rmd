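---
title: "Skygrid coalescent inference: model, samplers and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skygrid coalescent inference: model, samplers and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skygridmc)
```

## The model

The skygrid is a nonparametric coalescent model for inferring effective
population size through time from one or more dated genealogies. Time runs
backwards from the most recent sample (t = 0) into the past. A user-chosen
grid $x_1 \le \dots \le x_M$ (with $x_0 = 0$) partitions the past into
$M + 1$ intervals on which the demographic function is constant:
$N_e(t) = \theta_k$ for $x_{k-1} \le t < x_k$ and $\theta_{M+1}$ beyond the
cutoff $x_M$. Note that $M$ grid points always yield $M+1$ population-size
parameters; the package exposes $M$ directly.

With $v$ lineages present, pairs coalesce at rate $v(v-1)/(2\theta_k)$.
Writing $\gamma_k = \log \theta_k$, the likelihood of $m$ independent loci
reduces to per-interval sufficient statistics: the coalescent count $c_k$
and the pair-weighted waiting time $S_k = \sum v(v-1)\Delta t/2$
accumulated in interval $k$ over all loci,

$$\log P(\mathbf g \mid \boldsymbol\gamma) =
  \sum_{k=1}^{M+1} \left[-\gamma_k c_k - S_k e^{-\gamma_k}\right] + const.$$

All $\gamma$-independent constants (the binomial factors of the interval
likelihood) are dropped throughout: only posterior ratios and gradients are
ever needed.

Smoothness of the trajectory is encoded by an intrinsic first-difference
GMRF prior with precision $\tau$,

$$P(\boldsymbol\gamma \mid \tau) \propto
  \tau^{M/2} \exp\!\left[-\tfrac{\tau}{2}
  \sum_{i=1}^{M}(\gamma_{i+1}-\gamma_i)^2\right],$$

which informs only the increments, not the overall level. The precision
receives a Gamma($a$, $b$) hyperprior with the conventional uninformative
default $a = b = 0.001$ (overridable via `gmrfSpec()`). The structure
matrix $Q$ is tridiagonal with diagonal $(1, 2, \dots, 2, 1)$ and
off-diagonals $-1$; every precision matrix the samplers touch is therefore
tridiagonal and all linear algebra is $O(M)$ banded Cholesky (a dense path
exists in the tests and agrees to $10^{-10}$).

### Conventions and degenerate inputs

* **Interval boundaries.** Intervals are half-open $[x_{k-1}, x_k)$; an
  event exactly on a grid point belongs to the older interval. Exact ties
  among event times are stable-sorted with sampling events before
  coalescent events; zero-length spans contribute nothing to $S_k$. These
  choices only matter on sets of measure zero but make results
  deterministic. One consequence: a coalescence landing exactly on a grid
  point produces $c_k > 0$ with $S_k = 0$ in the older interval, which the
  containers deliberately accept.
* **Multiple loci with different most-recent samples.** All loci are
  anchored to the single most recent tip over the whole data set (each
  locus keeps an `offset`). The model itself does not prescribe the
  anchoring; this is our reading, and the `offset` field makes it explicit.
* **Empty intervals** ($c_k = S_k = 0$) are legal; their $\gamma_k$ is
  identified by the GMRF prior alone.
* **Date consistency.** Tip dates and branch lengths must imply the same
  root time along every root-to-tip path within an absolute tolerance of
  `1e-6` time units (float round-trip through text formats); violations
  are reported with the worst path discrepancy.

## Samplers

Three transition kernels target the same unnormalised posterior
$P(\boldsymbol\gamma, \tau \mid \mathbf g)$; their agreement is itself one
of the package's tests.

### Block-updating MCMC (`runBUMCMC`)

One iteration proposes the pair $(\tau^*, \boldsymbol\gamma^*)$ jointly:

1. $\tau^* = \tau f$ with $f$ drawn from the density $\propto f + 1/f$ on
   $[1/F, F]$ (`sampleScaleFactor`; default $F = 2$, a conventional
   moderate scale — the kernel's originators give no value).
2. Newton–Raphson (started at the current $\boldsymbol\gamma$, max-norm
   tolerance $10^{-6}$, cap 50 iterations, step halving) finds the mode
   $\hat{\boldsymbol\gamma}$ of the full conditional under $\tau^*$; a
   second-order Taylor expansion there yields a Gaussian with precision
   $\tau^* Q + \mathrm{Diag}(S_k e^{-\hat\gamma_k})$ from which
   $\boldsymbol\gamma^*$ is drawn.
3. Accept/reject by the Metropolis–Hastings ratio.

Two derivations here were done from scratch rather than transcribed. First,
the linear term of the Taylor-expanded full conditional is
$b_k = -c_k + S_k e^{-\hat\gamma_k}(1+\hat\gamma_k)$; with this sign the
approximation mean equals the Newton–Raphson mode, a property the test
suite checks directly (the opposite sign, which one may encounter in
derivations of this kernel, breaks mode-centring). Second, although the
scale density $f + 1/f$ is sometimes described as symmetric, the standard
change of variables for the multiplicative proposal $\tau^* = \tau f$
yields the non-unit Hastings factor $g(1/f)/(f\,g(f)) = 1/f$; the kernel
applies the explicit $-\log f$ correction, and the three-sampler agreement
test arbitrates that this is the invariant choice.

The reverse-move proposal density uses the mode-centred approximation at
the *current* $\tau$: because Newton–Raphson converges to the unique
$\tau$-conditional mode from any start, the approximation is a function of
$\tau$ alone and the ratio is well defined without re-centring on
$\boldsymbol\gamma^*$. This also lets a chain cache the approximation and
rebuild it only after an accepted move. Newton–Raphson non-convergence
rejects the proposal (robustness early in a chain) rather than aborting.

### Hamiltonian Monte Carlo (`runHMC`)

Auxiliary momenta $p \sim N(0, \mathbf M)$ with identity mass matrix (a
diagonal override exists; adaptive/Hessian preconditioning is out of
scope), leapfrog integration with step size $\varepsilon$ and $n$ steps per
proposal, acceptance probability $\min\{1, e^{-\Delta H}\}$, full momentum
refresh each iteration. Defaults: $n = 20$, initial
$\varepsilon = 0.1/\sqrt d$, dual-averaging adaptation of $\varepsilon$
toward acceptance 0.8 during the first 10% of iterations, frozen
thereafter. These are standard practice choices, all overridable.

The precision parameter is handled in one of two modes, and their agreement
is a test:

* `gibbs` (default): HMC on $\boldsymbol\gamma$ only, then an exact
  conjugate draw $\tau \sim \mathrm{Gamma}(a + M/2,\, b +
  \boldsymbol\gamma'Q\boldsymbol\gamma/2)$. Simplest correct scheme.
* `joint`: HMC on $(\boldsymbol\gamma, \log\tau)$ with the $+\log\tau$
  Jacobian added to the log target. Provided because one may also read the
  position vector as including $\tau$; the log transform handles
  positivity.

### Reference random-walk sampler (`runRWMH`)

A deliberately simple univariate random-walk Metropolis sweep over the
$\gamma_k$ plus a log-scale random walk on $\tau$, sharing no code with
the other kernels beyond the posterior itself. It exists to arbitrate
correctness: all kernels must produce the same posterior moments within
Monte-Carlo error.

## The simulator

`simulateGenealogy` draws heterochronous genealogies from the exact
generative process of the likelihood: lineages enter at the given
backwards sampling times, and waiting times to coalescence are generated by
time rescaling, integrating the piecewise-constant intensity
$v(v-1)/(2\theta_k)$ analytically across grid and sampling breakpoints
(never by thinning), with a fresh exponential draw whenever the lineage
count changes. Coalescing pairs are uniform; topology does not enter the
likelihood but is produced for valid Newick output. The most recent sample
is anchored at calendar 2000.0 by default (arbitrary, configurable).

What the simulator deliberately does *not* emulate: sequence data (trees
are treated as observed), phylogenetic uncertainty, recombination,
population structure. Passing parameter-recovery tests therefore
demonstrates correctness of the likelihood/sampler stack on fixed, known
genealogies — the regime where the model is exact — and says nothing about
tree-estimation error in real analyses.

## Diagnostics

Effective sample size uses Geyer's initial monotone positive sequence
estimator on FFT autocovariances — chosen over AR-spectral alternatives
because it is dependency-free, well defined for reversible chains, and
pinned by an AR(1) closed-form test ($\mathrm{ESS} \to n(1-\rho)/(1+\rho)$).
HPD intervals are the shortest contiguous interval containing
$\lceil \mathrm{level}\cdot n\rceil$ sorted points; trajectory summaries
report them on the $\theta = e^\gamma$ scale (the conventional display
scale) alongside $\gamma$-scale medians. Sampler efficiency is compared as
ESS per wall-clock second: minimum and median across the $\gamma_k$, with
$\tau$ reported separately. Absolute ESS/second values are
hardware-dependent; only within-run ratios between kernels are
meaningful, which is how `runBenchmark` reports them.

## Study conditions used by the checks

The test-suite experiments fix their problem sizes as follows, chosen once
as realistic small phylodynamic studies:

* *Sampler agreement*: one fixed data set of 3 loci × 20 heterochronous
  tips (10 at t = 0, 5 at 1, 5 at 2), M = 9, cutoff 8, simulated under a
  boom-bust trajectory $\theta = (30, 45, 60, 45, 30, 18, 10, 6, 4, 2)$
  (recent to past) — a realistically non-constant truth whose increments
  identify the smoothing precision well, so every kernel actually mixes in
  $\tau$ and the invariance comparison is informative (see the funnel
  limitation below). Each kernel runs 2×10^5 iterations; means of every
  $\gamma_k$ and $\log\tau$ are compared pairwise on ESS-based standard
  errors.
* *Parameter recovery*: 20 replicate data sets of 100 loci × 10 tips under
  constant $\theta = 10$, M = 4, cutoff 12 (interior intervals and the
  tail interval all receive events at this depth given
  $E[\mathrm{TMRCA}] = 18$).
* *Simulator closed forms*: pairwise coalescent times ($n=2$,
  $E[T_2]=\theta$) and TMRCA ($n=10$, $E = 2\theta(1-1/n)$) at
  $\theta = 5$.

## Configuration files

Runner configs are flat YAML with keys mirroring the function arguments
(`yaml` is the one structured-text format with a parser in the package's
dependency footprint; files are human-diffable and comment-friendly).
Command-line flags of the thin wrapper in `inst/scripts/skygrid-tool.R`
override file keys. One global seed drives each run; benchmark replicates
derive per-replicate seeds deterministically from it.

## Known limitations

* The GMRF/precision pair exhibits a funnel geometry when the data barely
  inform the trajectory's shape (e.g. truly constant $N_e$ with few
  events): $\tau$ mixes slowly in all kernels and ESS-based standard
  errors become optimistic. The `joint` HMC mode is the most affected — a
  single frozen step size cannot serve both the wide and narrow parts of
  the funnel, and on a deliberately pathological tiny data set it fails to
  traverse the $\tau$ range within practical run lengths even though its
  target and gradient are exact (the `gibbs` mode, whose $\tau$ draw is
  conjugate, matches numerical quadrature on the same problem). The
  agreement experiment uses a non-constant truth for this reason; analyses
  of very weakly informative data should prefer `gibbs` mode, run longer
  chains and inspect $\tau$ traces.
* Grid placement is the user's responsibility; only even spacing is
  automated.
* Covariate extensions of the skygrid, sequence likelihoods, molecular
  clocks and tree inference are out of scope: genealogies are data here.
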