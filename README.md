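# prosim

Disease-gene prioritization on protein–protein interaction (PPI) networks.

Given a query disease with a handful of known causal genes, `prosim` ranks
every other protein in a PPI network by its likely involvement in that
disease. It combines three signals:

1. **Edge reliability.** Each interaction `(v, u)` gets three features — a
   small-world clustering coefficient
   `C_vu = -log P(X >= |N(v) ∩ N(u)|)` (the hypergeometric tail probability
   of the observed shared-neighbor overlap), the Pearson correlation
   `rho_vu` of the two genes' expression profiles (population-moment
   convention), and a binary subcellular-localization compatibility
   `loc_vu` over a 12-compartment vocabulary. A logistic regression trained
   on balanced positive (interacting) and negative (non-interacting) edge
   sets turns the triple into a probability of true interaction,
   `Pr(T_vu | X) = 1 / (1 + exp(-b0 - b1 C - b2 rho - b3 loc))`,
   which becomes the edge weight.
2. **Proximity.** A random walk with restart (restart probability
   `r = 0.75`, uniform restart over the seed genes) on the
   reliability-weighted network yields `Pro(v)`, each protein's proximity
   to the known disease genes.
3. **Disease-similarity prior.** A phenotype similarity matrix
   `S ∈ [0,1]` is mapped through the calibrated logistic
   `L(x) = 1 / (1 + exp(-15 x + log 9999))` (so `L(0) = 1e-4`,
   `L(1) ≈ 0.997`), and each protein receives
   `Y(v) = L(max_p S(q, p))` over its associated diseases `p`.

The final relevance score is the fixed point of the propagation

```
F_t = alpha * W' F_{t-1} + (1 - alpha) * (Y + Pro),     alpha = 0.9
```

where `W' = D^{-1/2} W D^{-1/2}` is the degree-normalized weighted
adjacency. Candidates (all non-seed proteins) are ranked by `F`.

The package also ships the evaluation protocol used to study such methods —
leave-one-out cross validation with a rank threshold of 100, mean
enrichment (`50 / rank`), ROC/AUC, tenfold edge-removal cross validation,
and comparison against the proximity-only and prior-only ablations — plus a
seeded synthetic-data generator (scale-free network with a planted disease
module, factor-model coexpression, localization bias, block disease
similarity, negative edge set) so everything runs without downloads.

## Worked example

```r
library(prosim)

# synthetic study: 500-protein scale-free network, a 25-gene disease
# module, 10 known disease genes
bundle <- generate_prosim_data(synth_config(seed = 42))

pos <- build_edge_features(bundle$network, bundle$expression,
                           bundle$localization)
neg <- build_edge_features(bundle$negatives, bundle$expression,
                           bundle$localization)
model <- train_reliability(pos, neg, seed = 42)
wnet <- weight_network(bundle$network, model, pos)

res <- score_disease(wnet, bundle$similarity, bundle$associations, "D1")
head(res$ranking, 3)
#>   rank protein         F         Y         Pro
#> 1    1   P0487 0.4252575 0.7841065 0.020361888
#> 2    2   P0285 0.4226860 0.7841065 0.008403317
#> 3    3   P0135 0.4112604 0.7841065 0.007029801

compare_methods(wnet, bundle$similarity, bundle$associations, "D1")
#>   method hit_fraction mean_enrichment n_trials
#> 1 prosim            1       13.876679       10
#> 2    rwr            1        8.664944       10
#> 3  prior            1       13.819444       10
```

The top candidates are planted module members that are also associated
with a phenotypically related disease (similarity 0.7, hence the prior
`Y = L(0.7) ≈ 0.784`) and sit close to the seeds in the network
(`Pro` well above background). In leave-one-out cross
validation every held-out disease gene returns within the top 100
candidates for all three scorers on this instance (`hit_fraction = 1`),
and the combined score recovers them at better mean ranks than the plain
random walk (mean enrichment 13.9 vs 8.7).

A thin command-line wrapper is installed as `exec/prosim`
(`prosim simulate`, `prosim weight`, `prosim prioritize`,
`prosim evaluate`) over the same functions.

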