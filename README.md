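# graphDTI

Drug-target interaction (DTI) prediction for computational chemists and
method developers who need an offline, fully testable implementation of a
structure-aware DTI classifier: contact-map protein graphs, a residual
graph convolutional network with multiset-transformer attention pooling,
bilinear drug-protein fusion, and a multi-task objective that combines
focal loss (for the ~3.8:1 inactive:active imbalance typical of curated
affinity corpora) with similarity-masked contrastive learning over drug
and protein representations. The package also provides cold-start
evaluation protocols, Monte Carlo dropout uncertainty, and grad-CAM
residue attribution that localises predicted binding pockets.

## The model in brief

A protein with Calpha coordinates becomes a residue graph: an edge joins
residues closer than 8 A. With per-residue features H(0) (from a protein
language model, supplied as sidecar files, or from the deterministic
fixture provider), L = 3 residual graph convolutions

    H(k) = ReLU(A H(k-1) W(k)) + H(k-1)

(A the symmetrically normalised adjacency) are pooled by multi-head
attention onto learned seeds and mapped through an MLP; the drug branch
is an MLP over molecular embeddings (or Morgan fingerprints). A bilinear
layer fuses both embeddings into one logit. The loss is

    L = alpha * L_focal + beta * L_ntxent(drugs) + gamma * L_ntxent(targets)

with focal parameters w = 0.5, t = 2, temperature tau = 0.07, similarity
thresholds 0.8 (Tanimoto, drugs) and 0.5 (proteins), alpha = 1,
beta = gamma = 0.05. Positives in the contrastive terms are pairs of
distinct entities whose structural similarity exceeds the threshold.

## Worked example

Everything below is self-contained: the synthetic generator plants
spatially clustered binding pockets and similarity-clustered drug
families, so the full pipeline runs without downloads.

```r
library(graphDTI)

sim <- simulateBundle(SimConfig(seed = 11))   # 150 drugs, 40 targets, ~2000 pairs
provider <- fixtureProvider(seed = 11,
                            signal = list(drugClass = sim$truth$drugClass,
                                          pockets = sim$truth$pockets))
feats <- prepareFeatures(sim$bundle, provider)
ints <- interactions(sim$bundle)
folds <- stratifiedKfold(ints$label, k = 5, seed = 1)

fit <- trainModel(feats, ints, folds[[1]]$train, folds[[1]]$test,
                  ModelConfig(), LossConfig(),
                  TrainConfig(lr = 2e-3, epochs = 12, patience = 12,
                              monitor = "bacc", seed = 1),
                  sim$drugSim, sim$targetSim)
ev <- evaluateModel(fit$model, feats, ints[folds[[1]]$test, ])
round(unlist(ev[c("bacc", "precision", "recall", "f1", "mcc", "auroc")]), 4)
#>      bacc precision    recall        f1       mcc     auroc
#>    0.9243    0.9659    0.8586    0.9091    0.8842    0.9234
```

Held-out balanced accuracy 0.92 on a task with 5% label noise; the model
has learned the planted drug-key/pocket-class match rather than the
class prior. Attribution then recovers the planted pocket:

```r
pair <- ints[ints$label == 1, ][1, ]
g <- feats$targetInputs[[pair$target_id]]
att <- gradcamResidues(fit$model, feats$drugX[pair$drug_id, ], g)
pocket <- sim$truth$pockets[[pair$target_id]]$residues
pocketRecall(att, pocket)        # fraction of true pocket residues in the
#> [1] 0.7                       # top-k attribution, k = pocket size
```

Across 60 such true-interaction pairs the mean recall is ~0.66 against a
random-selection baseline of ~0.13 (the `k/|V|` matched-proportion
chance level); the acceptance script below recomputes both numbers.

A thin command-line front-end covering simulate / split / train /
predict / explain / uncertainty ships in `inst/scripts/dti-tool.R`.

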