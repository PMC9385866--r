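# finet — Fisher Information Networks for case similarity mapping

`finet` turns any probabilistic classifier into a similarity map of its
cases. It was built for the setting where a deep model classifies medical
images (e.g. mammogram patches into background / benign and malignant
calcifications / benign and malignant masses) and clinicians need more than
a label: they need to see *where a patient sits among all other patients*,
and which previously diagnosed cases are most like them — a
"patient-like-me" view that supports diagnosis, flags borderline cases and
helps explain what the classifier has learned.

## The method

Given a classifier with posteriors `p(c|x)`, the data-space **Fisher
information matrix**

```
FI(x) = Σ_c p(c|x) ∇x log p(c|x) ∇x log p(c|x)ᵀ
      = − Σ_c p(c|x) ∇²x log p(c|x)
```

is a positive semi-definite, position-dependent metric: moving in a
direction that changes the predicted class costs a lot of "distance",
moving parallel to a decision region costs almost nothing. `finet` builds a
**Fisher Information Network (FIN)** on top of this metric:

1. **Posteriors** — a one-hidden-layer softmax MLP (30 hidden units,
   learning rate 0.01, momentum 0.9, weight decay 0.2) is trained on
   PCA-reduced features (90% retained variance). Input gradients
   `∇x log p(c|x)` are computed analytically by backpropagation. Any model
   implementing the posterior contract can be substituted.
2. **Local distances** — the length of the straight segment between
   neighbouring cases, `∫₀¹ √(Δᵀ FI(x+tΔ) Δ) dt`, by midpoint quadrature.
3. **Geodesics** — a k-nearest-neighbour graph weighted by those segment
   lengths, then all-pairs shortest paths (Floyd–Warshall; an identical
   repeated-Dijkstra route is available for large n).
4. **Network & embedding** — the Gaussian kernel adjacency
   `A = exp(−D²/σ_G²)`, with `σ_G` the mean geodesic distance between
   same-*predicted*-label pairs, and a 2-D latent space by classical
   multidimensional scaling of `D`.
5. **New cases** — an unseen case is linked to its nearest training
   anchors by Fisher segments, routed through the training geodesics, and
   placed in the *fixed* embedding by the Gower out-of-sample formula;
   its ranked neighbours, kernel similarities and metadata form the
   patient-like-me report.

Since the original imaging data and pretrained CNN are external, the
package ships a synthetic generator (`simulate_cases()`) producing
multi-class Gaussian-mixture features that stand in for PCA-reduced
convolutional features.

## Worked example

```r
library(finet)

sim <- simulate_cases(500, n_classes = 5, n_features = 50,
                      separation = 6, seed = 1)
fit <- fin_fit(sim$features, sim$labels, seed = 1)
fit
#> <fin_model> 500 training cases; 50 -> 40 PCA dims; sigma_G = 0.1737
#>   training accuracy 100.0%; embedding stress 0.462

new_sim <- simulate_cases(25, n_classes = 5, n_features = 50,
                          separation = 6, seed = 2)
proj <- fin_project(fit, new_sim$features)
fin_neighbours(fit, proj$projections[[1]], k = 5)
#> <fin_neighbours> query case_0001, k = 5
#>     case_id distance predicted_label true_label similarity
#> 1 case_0441  0.08995               1          1     0.7647
#> 2 case_0116  0.10349               1          1     0.7011
#> 3 case_0266  0.10514               1          1     0.6931
#> 4 case_0449  0.11350               1          1     0.6524
#> 5 case_0298  0.11773               1          1     0.6316
#> majority label: 1 (100% of votes)
```

The projected case's five nearest training cases all carry label 1 — the
query's true class — with kernel similarities (`exp(−d²/σ_G²)`) quantifying
how close each neighbour is on the network. The latent space separates
classes far better than a linear view of the same features: mean 10-NN
label purity is **0.943** in the FIN embedding versus **0.784** in the
first two principal components (same data, same PCA).

Plots and text exports:

```r
render_latent_plot(fit$embedding, sim$labels, projections = proj$coords,
                   file = "latent.png")
write_embedding(fit, "embedding.csv")
```

A command-line interface covering the same pipeline lives in
`inst/cli/fin` (subcommands `simulate`, `fit`, `project`, `report`).

## Documentation

The methods vignette (`vignettes/fisher-information-networks.Rmd`) explains
the model, every tunable parameter, what the synthetic generator does and
does not emulate, and the numerical design choices.
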