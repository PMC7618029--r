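---
title: "Energy-based novelty detection with predictive coding networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-based novelty detection with predictive coding networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the modelling idea

Recognition memory — deciding whether a stimulus has been encountered
before — has enormous capacity in humans, and cortical recordings show
*repetition suppression*: neurons respond strongly to novel stimuli and
progressively less as the stimulus repeats. `pcnd` models this with
energy-based learning. A model adjusts its parameters to lower a scalar
energy on each training pattern; after training, the energy of a query is
its novelty signal. In predictive coding networks the energy is the summed
squared activity of prediction-error neurons, so the novelty signal is
literally the population activity of error units, and its decline over
repeated exposures is repetition suppression.

```{r}
library(pcnd)
```

## The recurrent network

`rpcn()` fits the single-layer recurrent model. Each value neuron is
predicted from all the others through a weight matrix $W$ with zero
diagonal (a neuron may not predict itself, which would trivially solve the
problem with $W = I$), plus a bias $\nu$:

$$E(x) = \tfrac12\lVert x - Wx - \nu\rVert_2^2, \qquad \operatorname{diag}(W) = 0 .$$

Learning is gradient descent on $E$, and the gradient is local:
$\Delta\nu = \alpha\,\varepsilon$ and
$\Delta W = \alpha\,\varepsilon x^\top$ restricted off-diagonal, each entry
a product of a presynaptic value activity and a postsynaptic error
activity. The two parameter sets are updated jointly. We fix the update
orientation by the gradient: entry $(j,k)$ of the weight step is
$\alpha\,\varepsilon_j x_k$, the error neuron being the postsynaptic
factor. The convexity of $E$ in $(W, \nu)$ under this linear model means
initialisation affects only speed, so we start from $W = 0$, $\nu = 0$,
which is exactly reproducible.

Full-batch training is the default. Because the full-batch gradient depends
on the data only through $XX^\top/N$ and $\bar x$, the implementation
iterates on those sufficient statistics when $N \ge d$ ($O(d^3)$ per epoch
rather than $O(d^2 N)$) and on the raw patterns otherwise; both paths apply
the identical update and the test suite asserts their equality. When no
learning rate is given, $\alpha = 0.9/(\hat\lambda_{\max} + 1)$ with
$\hat\lambda_{\max}$ a power-iteration estimate of the top eigenvalue of
$XX^\top/N$, which keeps descent stable for any input scale — under a
uniform pairwise covariance $c$ the top eigenvalue grows like
$1 + (d-1)c$, so a fixed default would either diverge or crawl. Training
stops when the relative change of mean energy over an epoch falls below
`tol` (default $10^{-8}$; the closed-form comparisons below use
$10^{-10}$); non-convergence is recorded on the fit object rather than
raised.

## Why correlation does not hurt: the metric view

At the fixed point of learning on data with covariance $\Sigma$, row $j$ of
$W^*$ holds the regression coefficients of coordinate $j$ on all other
coordinates (`converged_rpcn_weights()`), and the energy becomes a member
of the distance family $c\,\lVert L(q - \bar x)\rVert_2^2$ with

$$L_{\mathrm{rPCN}} = \operatorname{diagMat}\!\big(\mathbf 1 \oslash \operatorname{diag}(\Sigma^{-1})\big)\,\Sigma^{-1},$$

each precision-matrix row rescaled to a unit diagonal (`l_rpcn()`). The
transform expands precisely the directions of low data variance, so a query
that deviates from the training cloud in an atypical direction is flagged
as novel even if its Euclidean distance from the mean is unremarkable. The
classical Hopfield energy on centered data is the same family with
$L = \Sigma^{1/2}$ and an inverted sign (`l_hn()`): it stretches the
directions the data already vary in most, which is why its discrimination
collapses under correlated pixels.

Two conventions deserve note. The network energy carries a factor
$\tfrac12$, so the comparison in `theorem1_check()` uses $c = \tfrac12$ and
asserts equality, not mere proportionality. And although the closed form is
naturally stated for patterns centered at zero, the bias makes centering
unnecessary: $\nu$ converges to $(I - W^*)\bar x$, so the check centers at
the sample mean and holds for uncentered data too; a fit built directly
from the closed form reproduces the energy to $10^{-10}$ relative error,
and a gradient-trained fit to better than $10^{-3}$. The matrix square
root uses a symmetric eigen-decomposition with eigenvalues floored at
$10^{-12}$; $L_{\mathrm{rPCN}}$ is invariant to rescaling $\Sigma$, so the
$1/N$ covariance normalisation is immaterial (asserted in the tests).

```{r}
S <- uniform_cov_matrix(2, 1, 0.7)
l_rpcn(S)$L          # unit diagonal, negative off-diagonal
converged_rpcn_weights(S)
```

## The hierarchical network

`hpcn()` stacks the same principle: layer $l$ is predicted top-down,
$\varepsilon^l = x^l - W^{l+1} f(x^{l+1})$, the top layer is predicted by a
bias, and the total energy is $\sum_{l=0}^{L} \tfrac12\lVert\varepsilon^l\rVert^2$.
We include the sensory layer $l = 0$ in the total: its error term is what
the bottom-level novelty readout measures, so it must be part of the
objective the activities minimise. For each input, layer 0 is clamped and
the hidden activities follow the energy gradient
($\eta$ = `infer_step`, default 0.05, with a divergence guard that aborts
with a diagnostic if the energy explodes); weights then take one Hebbian
step $\Delta W^l = \alpha\,\varepsilon^{l-1} f(x^l)^\top$ through the
connectivity mask, so masked entries are exactly zero at all times.

Choices the model leaves open, and what we chose:

* **Nonlinearity** — `tanh` by default (smooth, bounded, standard for
  these generative hierarchies), with `identity` and `relu` available. The
  identity option is what the test suite uses to compare inference against
  the direct linear-system solution.
* **Hidden initialisation for inference** — zeros, for reproducibility; at
  the convergence tolerances used the minimiser of the clamped landscape,
  not the start point, determines the result.
* **Batching** — full-batch by default, with inference warm-started from
  the previous epoch's converged activities: the weight step moves the
  energy landscape only slightly, so warm-started inference needs a
  handful of iterations, and the fixed point is the same as for
  per-pattern updates (`batch_size = 1` restores those exactly).
* **Weight initialisation** — Gaussian with standard deviation
  $1/\sqrt{\text{fan-in}}$, seeded.

## The experimental harness

`twoafc_error()` implements the forced-choice protocol: each familiar item
is paired with one novel item (random pairing under a seed), the item with
lower energy is chosen, ties score one half. The error is invariant to any
joint strictly increasing transform of the energies, so models with
arbitrary energy scales are comparable. `retained_count()` converts error
to a Standing-style capacity, $N(1 - 2p_{\mathrm{err}})$ — the standard
two-alternative correction for guessing, which retains zero at chance and
$N$ at perfect discrimination. `dprime()` uses the equal-weight pooled
variance, $|\bar a - \bar b| / \sqrt{(s_a^2 + s_b^2)/2}$, reporting
`Inf` explicitly in the degenerate zero-variance case. Where a familiar
and a paired novel energy tie exactly, half credit keeps the chance
calibration unbiased.

`capacity_curve()` sweeps models over training-set sizes and seeds (five
simulated networks per point by default in our experiments), regenerating
familiar and novel sets from the same generative specification — novelty
here is in-distribution, which is the harder and more meaningful test.
For the Hopfield energies there is no training phase; queries are centered
with the training mean so the covariance form of the classical energy
applies. `hierarchy_report()` reports per-layer squared error norms
$\lVert\varepsilon^l\rVert^2$ (twice the layer energy — the scale used in
the violin-plot convention) and the d′ matrix over all query-set pairs.

## What the synthetic generators emulate

`sample_gaussian()` draws patterns from a zero-mean Gaussian whose
covariance has a common variance (default 1, so the pairwise covariance
doubles as a correlation) and a common covariance $c$ between every pair
of coordinates. $c = 0$ reproduces the uncorrelated benchmark; $c = 0.4$
the correlated one. Zero mean is the analytic convention; a nonzero mean
can be supplied to exercise bias learning.

`make_class_images()` is a procedural stand-in for handwritten-digit
classes: per class a fixed stroke-based prototype, per exemplar a smooth
random warp of that prototype plus pixel noise, clipped to $[0,1]$. The
defaults (side 20, deformation amplitude 2 pixels, noise 0.05) were chosen
so that the within-class spread is substantial — comparable in spirit to
the variation among exemplars of one handwritten digit — while classes
remain far apart; the tests assert the between-class distance exceeds the
within-class distance. What it does *not* reproduce is the heavy-tailed,
spatially inhomogeneous statistics of natural images or real handwriting,
so passing results here demonstrate the mechanism (memorisation of
exemplar detail at the bottom, class structure at the top), not
performance on any real dataset. Real data enter through
`read_mnist_idx()` (IDX files, pixels scaled to $[0,1]$) and
`read_image_folder()` (PNGs, grayscale, resized, $[0,1]$; centering for
the Hopfield baselines is applied by the harness, not the loader).

## Problem sizes used in the shipped experiments

The repository's tests and `scripts/acceptance.R` run, per seed:
the closed-form consistency check at $d = 20$, $N = 500$, $c = 0.4$,
convergence tolerance $10^{-10}$, 100 queries; the capacity contrast at
$d = 100$, $N \in \{150, 300, 500\}$, five networks per point (the
smallest $N$ is kept above $d$ so the sample covariance that the
closed-form comparison uses is well conditioned); repetition suppression
on a single 20×20 image-like stimulus at $\alpha = 3\times10^{-4}$ (2500
epochs for the recurrent network, 6000 for the hierarchical one — the rate
is fixed by the protocol, so the epoch counts are what convergence below
1% of the initial energy requires); and the hierarchy experiment with
layers $400\!-\!144\!-\!72$, 9×9 receptive fields between layers 0 and 1
(so $20 - 9 + 1 = 12$, i.e. $144$ layer-1 neurons), 100 training exemplars
of one class, five seeds. The hidden layer is deliberately larger than the
training-set size: with fewer hidden units than patterns the network
generalises instead of memorising and the bottom-layer familiar/novel
separation disappears — which is itself the behaviour the architecture
choice is about.

## Numerical choices and degenerate inputs

* Convergence is always measured as relative change of a mean energy, with
  an absolute floor to make zero-energy fits terminate.
* Empty pattern sets are explicit values (d rows, zero columns) accepted by
  constructors and splitters but rejected by anything that needs
  statistics.
* `mchn_energy()` evaluates its log-sum-exp stably (tested at dot products
  of $10^4$).
* `param_matched_hidden()` floors the hidden size at 1; the variational
  model's extra log-variance head changes the parameter count, so its
  matching formula divides by $3d + 2$ rather than $2d + 1$.
* All randomness flows through explicit `seed` arguments evaluated in a
  temporary RNG state, leaving the caller's RNG stream untouched;
  `seed = NULL` uses the ambient stream.

## Known limitations

The autoencoder baselines use plain full-batch gradient descent with tanh
hidden units; no attempt is made to match any particular published
training schedule, and their absolute capacities should be read with that
in mind. The forced-choice pairing rule (one novel item per familiar item)
is one natural reading of the protocol; averaging over all
familiar × novel pairs is a configurable alternative that changes the
variance, not the expectation, of the error estimate. The retained-count
transform is the standard correction for guessing and may differ from
other operationalisations by a constant factor. Memory retrieval (pattern
completion) through the error-to-value feedback pathway is outside the
scope of this package, as are convolutional weight sharing (masks are
local but untied) and temporal sequences.
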