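---
title: "Fisher information networks: model, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fisher information networks: model, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finet)
```

## The model

A trained probabilistic classifier carries more geometric information than
its hard labels: the posteriors $p(c \mid x)$ define, at every point $x$ of
feature space, how *sensitive* class membership is to a small displacement.
The data-space Fisher information matrix

$$
FI(x) \;=\; \sum_{c} p(c \mid x)\,
  \nabla_x \log p(c \mid x)\, \nabla_x \log p(c \mid x)^{\!\top}
\;=\; -\sum_c p(c \mid x)\, \nabla_x^2 \log p(c \mid x)
$$

is symmetric positive semi-definite and acts as a Riemannian metric: the
squared length of an infinitesimal step is
$d(x, x+\Delta x)^2 = \Delta x^{\top} FI(x)\, \Delta x$. Directions that
cross decision boundaries are long; directions along which the posteriors
are flat are short. The two forms above (outer product of score vectors,
negative expected Hessian) are algebraically identical for any model whose
posteriors sum to one; the package computes the first and tests the second
by finite differences.

A Fisher information network is built from this metric in four steps:

1. **Local distances.** Exact geodesics require solving the geodesic ODE,
   which is disproportionately expensive; between *nearby* cases the metric
   varies slowly, so the segment length
   $\int_0^1 \sqrt{\Delta^{\top} FI(x + t\Delta)\, \Delta}\;dt$ along the
   straight line is a good local surrogate (`segment_distance()`).
2. **Global distances.** Nearby cases are wired into a $k$-nearest-neighbour
   graph with segment lengths as weights; all-pairs shortest paths
   (Floyd–Warshall) then approximate geodesic distances by hopping through
   neighbours, exactly as Isomap does for an ordinary Euclidean metric
   (`build_graph()`, `all_pairs_geodesic()`).
3. **Network and embedding.** The Gaussian kernel
   $A = \exp(-D^2/\sigma_G^2)$ converts distances to connection weights,
   with $\sigma_G$ the mean geodesic distance between cases sharing the
   same *predicted* label; classical multidimensional scaling of $D$ gives
   latent coordinates for visualisation (`kernel_adjacency()`,
   `mds_embed()`).
4. **Unseen cases.** A new case is connected to its Euclidean-nearest
   training anchors by fresh segment distances, routed through the fixed
   training geodesics, and placed into the latent space by the Gower
   out-of-sample formula — training structures are never refit
   (`fin_project()`).

### Assumptions

* The classifier's posteriors are meaningful (trained to convergence on
  representative data) — the network characterises *the model's* geometry,
  which reflects reality only insofar as the model does.
* The posterior surface is smooth between neighbouring cases (needed by
  both the quadrature and the neighbour-hopping approximation).
* The feature density is high enough that $k$-NN hops follow the data
  manifold rather than short-cutting across it.

## The bundled posterior model

Posteriors are estimated by a one-hidden-layer MLP with softmax output,
trained by mini-batch gradient descent with classical momentum and L2
weight decay. The defaults follow the reference configuration for this
methodology:

| parameter | default | meaning |
|---|---|---|
| `hidden_units` | 30 | hidden layer width |
| `learning_rate` | 0.01 | SGD step size |
| `momentum` | 0.9 | classical momentum coefficient |
| `weight_decay` | 0.2 | L2 penalty, summed-error convention (below) |
| `max_epochs` | 500 | fixed epoch budget (no early stopping) |
| `batch_size` | 32 | mini-batch size |
| `hidden_activation` | sigmoid | hidden nonlinearity (tanh available) |

Two points are deliberately explicit because the conventions vary across
toolboxes:

* **Loss.** Categorical cross-entropy — the canonical partner of a softmax
  output (the stated configuration names only the output activation).
* **Weight decay.** A "rate of 0.2" is ambiguous. In the classical MLP
  formulation (Bishop; the netlab toolbox) the penalised objective is
  $E = \sum_i E_i + \tfrac{\alpha}{2}\lVert W\rVert^2$ with the data term
  *summed* over cases, so the effective coefficient relative to a mean
  loss is $\alpha/n$. That is the default (`decay_mode = "sum"`). Read
  instead as a raw coefficient on the mean loss (`decay_mode = "mean"`),
  0.2 is a very strong penalty that visibly underfits even cleanly
  separable data; both modes are available and tested.

The gradients $\nabla_x \log p(c \mid x)$ the metric needs are computed
analytically (backpropagation to the inputs) and verified against central
finite differences. The whole Fisher machinery is written against a small
posterior *contract* (`predict_posteriors()`, `grad_log_posteriors()`), so
closed-form models — e.g. `linear_softmax_model()`, whose Fisher matrix is
known algebraically — share the code path and serve as oracles.

## Tunable parameters that matter

* **`variance_threshold` (PCA, default 0.90).** Features are centred by the
  training mean and reduced to the smallest number of principal components
  reaching 90% cumulative explained variance. Features are *not* rescaled
  to unit variance by default: covariance PCA is the convention for CNN
  activations, whose scales are meaningful; a `standardise` flag exists.
  Test data are always transformed with the training mean and components —
  never refit.
* **`k` (graph neighbours, default 10).** No reference value is stated for
  the neighbourhood size; 10 is the common Isomap-scale choice for a few
  hundred cases. Too small risks disconnection (bridged automatically, see
  below); too large lets shortest paths shortcut off the manifold.
* **`n_steps` (segment quadrature, default 10).** Midpoint-rule resolution
  per edge. Ten points suffice for smooth posteriors at neighbour spacing;
  correctness is guarded by a convergence property (halving the step size
  shrinks the error) rather than by matching a fixed closed form.
* **`ridge` (default 1e-8 in graphs, 0 elsewhere).** In posterior-flat
  regions (deep inside one class) $FI \to 0$ and all local distances
  collapse; a tiny diagonal ridge keeps edge weights strictly positive so
  shortest paths and duplicate detection stay well behaved. This is an
  implementation safeguard, not part of the metric's definition.
* **`m` (latent dimension, default 2).** Chosen for visualisation; the MDS
  eigenvalue spectrum (`embedding$eigenvalues`) shows how much structure
  higher dimensions would carry.

## The synthetic data generator

`simulate_cases()` emulates the *shape* of the real use case — a few
thousand PCA-reduced convolutional features with a handful of classes — as
a Gaussian mixture: class means at the vertices of a regular simplex in the
first $C-1$ feature dimensions (pairwise separation controlled by a single
`separation` parameter, in units of the within-class standard deviation),
isotropic within-class noise, multinomial class assignment, and an optional
inflated-dispersion "background" class. Defaults are 5 classes and
separation 6, i.e. clearly but not trivially separated blobs.

What a green end-to-end test establishes: the pipeline recovers known
cluster structure, the embedding's neighbourhoods are label-pure where the
classifier is accurate, and projection places held-out cases among their
own class. What it does **not** establish: fidelity to real convolutional
feature distributions, which are anisotropic, heavy-tailed and
manifold-structured in ways no Gaussian mixture claims to capture — the
generator is a stand-in for testing, not a model of CNN features.

## Numerical choices and edge cases

* **Quadrature symmetry.** The midpoint rule makes
  `segment_distance(x, y) == segment_distance(y, x)` exact (the midpoint
  set is reversal-invariant), so the graph is symmetric by construction.
* **Neighbour selection space.** Candidate neighbours are chosen by
  Euclidean distance *before* Fisher weighting (the standard Isomap-style
  pre-screen); this keeps metric evaluations at $O(nk)$ and is the natural
  reading of "nearest neighbour" when no metric is specified for the
  candidate step. Ties are broken by case index for determinism.
* **Disconnected graphs.** When the $k$-NN graph splits, components are
  bridged by the cheapest inter-component Fisher edge, with candidates
  ranked by Euclidean distance (capped at `bridge_candidates`); every added
  edge is recorded in `graph$augmented`.
* **Floyd–Warshall vs Dijkstra.** Floyd–Warshall is the reference
  (vectorised over the intermediate node, $O(n^3)$ but fast in practice to
  a few thousand cases); `method = "dijkstra"` (igraph) is provided for
  larger problems and tested to produce identical distances.
* **MDS flavour.** Classical (Torgerson) scaling by default — deterministic
  and exact on Euclidean inputs; optional SMACOF stress-majorisation
  refinement (`refine = TRUE`), initialised from the classical solution so
  it too is deterministic. Which flavour the methodology originally used is
  unstated; classical was chosen because it pairs with an exact
  out-of-sample formula.
* **Negative eigenvalues.** Geodesic matrices are generally non-Euclidean;
  negative MDS eigenvalues are clamped to zero (standard Isomap practice)
  and their share of total eigenvalue mass is reported as
  `embedding$clamped_mass`.
* **Orientation.** Each latent axis is flipped so its largest-magnitude
  coordinate is positive; embeddings are reproducible across runs and
  permutation-equivariant.
* **Out-of-sample coordinates.** The Gower formula
  $y = \tfrac{1}{2}\Lambda^{-1/2} V^{\top}(\bar\delta - \delta)$ is exact on
  Euclidean configurations and reproduces a training case's coordinates
  exactly from its own distance row. If the embedding was stress-refined,
  coordinates are polished by direct least squares on the distance
  residuals from the Gower start. How the original methodology solved this
  step is unstated; this choice is exact where exactness is testable.
* **$\sigma_G$ uses predicted labels**, pooled over all unordered
  same-label pairs — the network should reflect the classifier's own view
  of the data, and predicted labels exist for unlabelled future cases too.
* **Retrieval distances.** Neighbour reports rank by geodesic (or projected
  geodesic) distance, not by 2-D embedded distance: the similarity claim
  rests on the network's connection weights, and the 2-D view is a lossy
  rendering of them.
* **Determinism.** Every stochastic stage (generator, MLP initialisation
  and shuffling) is seeded through one master seed; RNG state is saved and
  restored so library calls never perturb the caller's stream. Identical
  seeds give bitwise-identical embeddings, projections and reports.

## Known limitations

* All-pairs shortest paths and the dense MDS eigendecomposition are
  $O(n^3)$: practical to a few thousand cases on one CPU, beyond which
  landmark methods (out of scope here) become necessary.
* The network inherits the classifier's biases; a confidently wrong model
  produces a confidently wrong map. The misclassification table
  (`misclassification_table()`) and the predicted-vs-true colour modes of
  `render_latent_plot()` are the intended diagnostics.
* Segment quadrature under-resolves posteriors that change faster than the
  neighbour spacing (raise `n_steps`, or `k` to shorten edges).
* Projection quality degrades for cases far from the training support —
  the anchor mechanism extrapolates linearly through the nearest training
  cases; `projection$residual` flags poor placements.
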