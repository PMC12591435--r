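---
title: "Partial-correlation networks with a hierarchical matrix-F prior: model, tuning, and edge selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partial-correlation networks with a hierarchical matrix-F prior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmfgraph)
```

## The model

Gaussian graphical models encode conditional dependence in the precision
matrix $\Omega = \Sigma^{-1}$ of jointly Gaussian variables: variables $i$
and $j$ are conditionally dependent given all others exactly when
$\omega_{ij} \neq 0$, with partial correlation
$-\omega_{ij}/\sqrt{\omega_{ii}\omega_{jj}}$. Estimating $\Omega$ from $n$
samples of $p$ variables is ill-posed when $p$ is comparable to or larger
than $n$, so some form of regularization is mandatory.

Here the regularization is Bayesian. The likelihood for centered data with
sample covariance $S = Y^\top Y/n$ is
$p(Y \mid \Omega) \propto |\Omega|^{n/2}\exp\{-\tfrac12\mathrm{tr}(nS\Omega)\}$,
and $\Omega$ carries a matrix-F prior expressed as a scale mixture of
Wisharts with scaled targets:

$$
\Omega \mid \Phi \sim W\!\big(\nu, ((\nu - p - 1)\Phi)^{-1}\big), \qquad
\Phi \mid B \sim W\!\big(\delta + p - 1, ((\delta + p - 1)B)^{-1}\big),
$$

with $B$ diagonal and $b_{ii} \sim \mathrm{Gamma}(\epsilon_1, \epsilon_2)$,
$\epsilon_1 = \epsilon_2 = 0.001$. The tiny gamma constants approximate a
flat prior on $\log b_{ii}$ (scale invariance) while keeping the posterior
proper also when $p > n$. The hierarchy matters: the auxiliary scale $\Phi$
sits between the data and the diagonal target, so the prior adapts its
center instead of pulling everything to a fixed matrix.

The degree-of-freedom parameters are awkward to reason about, so the package
works with two shrinkage weights instead:

$$
\alpha = \frac{\nu - p - 1}{\nu + n - p - 1} \in [0, 1), \qquad
\beta = \frac{\delta + p - 1}{\delta + \nu - 2} \in (0, 1],
$$

chosen so that the full-conditional modes become convex blends,

$$
\mathrm{Mode}(\Omega \mid \cdot) = (\alpha\Phi + (1-\alpha)S)^{-1}, \qquad
\mathrm{Mode}(\Phi \mid \cdot) = (\beta B + (1-\beta)\Omega)^{-1},
$$

the first of which has the familiar Ledoit-Wolf linear-shrinkage form.
$\alpha$ is how little the sample covariance is trusted (large for $p > n$),
$\beta$ how hard off-diagonals are shrunk towards the diagonal target.
One subtlety follows from the reparameterization: the admissible range of
$\beta$ depends on $\nu$ ($\delta > 0$ requires
$\beta > (p-1)/(\nu-2)$), so very small $\alpha$ is incompatible with a
fixed $\beta$; the condition-number search below intersects its bracket
with this admissible region.

## MAP estimation: GEM, and a Gibbs reference

All three full conditionals are standard distributions (two Wisharts, one
gamma), so cycling their *modes* — $b_{ii}$, then $\Phi$, then $\Omega$,
from identity starts — is a generalized EM / iterated-conditional-modes
algorithm whose fixed point is the posterior mode. `gem_fit()` implements
exactly this sweep (the inner loop in compiled code), stopping when the
relative Frobenius change of $\Omega$ drops below `stop_criterion`
(default `1e-6`, at most 1000 sweeps). The iteration is deterministic: no
randomness enters the point estimate.

`gibbs_fit()` cycles *draws* from the same three conditionals in the same
order, using Bartlett-decomposition Wishart sampling. It is the reference
for the posterior's shape; taking conditional modes instead of draws
reproduces the GEM trajectory exactly, which is also how the unit tests pin
the two routes to each other. Defaults (5000 iterations, half discarded, no
thinning) are deliberate overkill for the $p \le 20$ problems the sampler
is meant for.

Numerical choices: every inverse goes through a Cholesky factorization of a
symmetric positive-definite blend, and results are re-symmetrized once at
the end to suppress floating-point drift. A non-PD blend (e.g. $\alpha = 0$
with a singular $S$) raises an error advising a larger $\alpha$ rather than
limping on. At large $\alpha$ (the $p \gg n$ regime pushes
$\alpha \approx 0.9$) the fixed-point contraction is slow and a cold start
can exhaust the 1000-sweep cap with relative change a few times above the
tolerance; the returned `converged` flag reports this honestly. The effect
on downstream edge z-scores is at the $10^{-4}$ level, far below decision
thresholds.

## Tuning $\alpha$: the condition-number constraint

Rather than cross-validation, $\alpha$ is chosen as the smallest value whose
MAP precision matrix is acceptably well conditioned:
$\hat\alpha = \arg\min_\alpha \{\mathrm{Cond}(\hat\Omega_\alpha) < \kappa_{\max}\}$,
with $\mathrm{Cond}$ the extreme-eigenvalue ratio. The limit
$\kappa_{\max}$ is not a user knob by default: it is the condition number of
the Ledoit-Wolf linear-shrinkage covariance of the same data (identical for
the covariance and its inverse), so the estimate is required to be at least
as well conditioned as the classic shrinkage benchmark. The Ledoit-Wolf
estimator is implemented from its published closed form (shrinkage towards
$\mu I$, $\mu = \mathrm{tr}(S)/p$, analytic intensity) and is verified in
the tests against an independent reference implementation to ten decimal
places.

`select_alpha_cc()` finds $\hat\alpha$ by bisection on
$[0.001, 0.999]$ (intersected with the $\beta$-admissible region) to a
bracket width of `alpha_tol = 0.005`, warm-starting each GEM fit from the
previous solution. Warm starts change runtime only — the tests compare
against an exhaustive cold-start grid. Bisection presumes the condition
number is non-increasing in $\alpha$; this holds on every fixture we
generate, and the returned weight is always the feasible upper end of the
final bracket, so the constraint is satisfied by construction. The bracket
endpoints and tolerance are implementation choices, not sacred numbers.

A second, deliberately larger preset $\alpha = 10p/(10p+n)$
(`alpha_heuristic()`) trades edge accuracy for denser, more clustered
estimates that help community detection.

$\beta$ defaults to 0.9 everywhere and is exposed but rarely worth moving:
with $\alpha$ chosen by the constraint, its influence on the selected
network is secondary.

## Edge selection: approximate credible intervals, permutations, and width selection

The MAP estimate is dense; edges are declared by asking whether zero lies
outside an approximate credible interval. Each off-diagonal entry's
posterior is approximated by
$N(\hat\omega_{ij}, \widehat{\mathrm{Var}}(\hat\omega_{ij}))$ with the
Wishart-conditional variance
$\widehat{\mathrm{Var}}(\hat\omega_{ij}) = (\nu + n)(\hat w_{ij}^2 + \hat w_{ii}\hat w_{jj})$,
$\hat W = (nS + (\nu - p - 1)\hat\Phi)^{-1}$. The equal-tailed interval is
$\hat\omega_{ij} \pm \Phi^{-1}((1+\gamma)/2)\,\sqrt{\widehat{\mathrm{Var}}}$
— note the square root: a normal interval scales the probit quantile by the
standard deviation, and the package treats any flatter reading of the
formula as a typographical slip. Declaring an edge when $0 \notin$ CI is
identical to thresholding the z-score $|\hat\omega_{ij}|/\mathrm{sd}_{ij}$,
which makes edge counts exactly non-increasing in $\gamma$ and is how the
implementation scans candidate widths: the observed per-edge z-scores are
themselves the exhaustive set of decision thresholds, so both selectors see
every achievable graph rather than a fixed $\gamma$ grid (a 512-point grid
interface remains for interoperability).

How wide should the interval be? Two data-driven answers, both built on the
same permutation null: shuffle the values *within each sample* (so every
row keeps its multiset of values, but all between-variable correlation
dies), refit with the same $(\alpha, \beta)$, and count selected edges at
every threshold. The median count over 50 permutations estimates the
false-positive count $\widehat{FP}(\gamma)$; subtracting it from the
observed edge count gives $\widehat{TP}(\gamma)$. Then either

- **target FDR**: the smallest $\gamma$ (narrowest interval, most
  discoveries) with $\widehat{FP}/\mathrm{edges} \le$ target, or
- **maximal estimated F1**:
  $\hat F_1 = 2\widehat{TP}/(2\widehat{TP} + \widehat{FP} + \widehat{FN})$
  with $\widehat{FN} = K - \widehat{TP}$, $K$ a working guess at the true
  edge count (default $K = p$; ties break towards the sparser graph).

$\widehat{FN}$ is deliberately *not* clamped at zero: in graphs holding
more than $K$ true edges the estimated F1 exceeds 1 and keeps growing as
long as genuine edges keep arriving, so the selector does not artificially
cap dense graphs at $K$ edges. The within-sample shuffle assumes comparably
scaled variables — hence standardization defaults to on, and the
permutation machinery warns if it is not. Permutation $k$ uses the
deterministic child seed `seed + k`, so serial and parallel execution give
identical results. The real-data $\alpha$ is reused for every permutation
refit; re-running the condition-number search per permutation would change
the null being estimated (and an order of magnitude more compute) for no
conceptual gain.

## The simulators: what they emulate, and what they do not

Two ground-truth generators mirror the two reference simulation styles used
in comparative GGM studies at $p = 100$, $n \in \{35, 75, 150, 300\}$:

- **scale-free**: a preferential-attachment tree ($p - 1$ edges, hubs and
  leaves);
- **five-cluster**: near-equal groups with no between-group edges; within
  each cluster a random spanning tree plus independent extra edges, so the
  graph has exactly five components *by construction* (plain
  Erdős–Rényi clusters occasionally disconnect). The within-cluster
  density defaults are calibrated so the mean average clustering
  coefficient of the true networks at $p = 100$ is $\approx 0.303$
  (fixed-weight style) and $\approx 0.195$ (random-weight style), the two
  levels the reference generators produce.

Weights come in two schemes. The *fixed* scheme gives every edge the same
raw weight (0.3), inflates the diagonal just past positive definiteness,
and rescales — all partial correlations equal, difficulty set by $p$. The
*random* scheme targets the reference generator that samples partial
correlations across the whole of $(-1, 1)$. For tree supports we draw the
precision matrix exactly from the G-Wishart$(3, I)$ restricted to the tree:
trees are decomposable, so the draw is a short closed-form Cholesky
construction, not an MCMC sampler. We adopted it after measuring that a
uniform-weight diagonally-dominant surrogate produces only about half the
reference's share of weak edges ($|{\rm pc}| < 0.15$: 17% vs 33%), making
simulated recovery substantially easier than the generator being emulated.
Non-decomposable cluster supports keep the uniform-weight
diagonal-dominance scheme (margin 0.1). In every scheme the covariance is
rescaled to unit diagonal and the precision support equals the adjacency
exactly.

What passing these simulations does *not* show: real expression or
abundance data are non-Gaussian, zero-inflated, compositional, and
heteroscedastic. The `nonparanormal_transform()` (rank → shrunken ECDF,
truncated at $1/(4 n^{1/4}\sqrt{\pi\log n}$) → normal quantiles → unit
variance) addresses marginal non-normality only; dependence structure
beyond a Gaussian copula, and zero-inflation in particular, remain outside
the model's assumptions.

## Metrics

Recovery is scored over unordered pairs: MCC, F1, FDR, TPR with explicit
degenerate-corner conventions (FDR of an empty estimate is 0, MCC with a
zero marginal is 0). Cluster recovery uses the average clustering
coefficient (degree-<2 nodes contribute 0) and normalized mutual
information between the estimate's communities and the true labels. NMI
normalizes mutual information by the arithmetic mean of the two entropies —
the most common convention, cross-checked against an independent graph
library — and community labels come from greedy modularity by default
(robust to a single spurious bridge between clusters), with connected
components as the alternative; results should state which labelling was
used.

## Problem sizes used in the shipped checks

The test suite reproduces simulation cells at $p = 100$ with 6 replicates
per cell and the FDR-calibration check with 12, and the acceptance script
uses 20 replicates per cell (50 for the true-network clustering level,
which needs no model fits); these sizes were chosen so the whole suite runs
comfortably on one CPU while keeping Monte-Carlo standard errors a few
times smaller than the tolerances being checked. Oracle comparisons
(independent fixed-point implementation, exhaustive grids and scans,
reference shrinkage values) are exact-tolerance and run in seconds.

## Known limitations

- The point estimate is a posterior mode, not a mean; credible intervals
  are normal approximations whose quality degrades for the largest
  $|\hat\omega_{ij}|$ in very small samples.
- Bisection for $\alpha$ assumes monotone conditioning; a detected
  inversion falls back to a warning-laden grid scan, but pathological
  non-monotone cases are untested territory.
- The permutation null assumes exchangeable, comparably scaled variables
  within a sample; grossly different scales or strong sample effects break
  it.
- $K = p$ is a heuristic; when the expected edge count is known to be far
  from $p$, set `K` explicitly.
- Slow GEM convergence at $\alpha \gtrsim 0.9$ can leave `converged =
  FALSE` at the default cap; raise `max_iters` if exact fixed-point
  residuals matter.
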