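# mvgat

Drug–target interaction (DTI) prediction from a **multi-view heterogeneous
graph** of drugs, proteins and diseases, using per-view **graph attention**
message passing, learned softmax **view fusion**, and **prior chemical /
sequence attributes**, with an MLP pair scorer — plus a seeded synthetic
network generator so the whole pipeline is testable end-to-end without any
external database.

## Who this is for

Computational drug-discovery researchers who want a self-contained,
inspectable implementation of attention-based multi-view DTI prediction:
every stage (similarity graph construction, fold protocol, negative
sampling, cold-start analysis, ablations) is an exported, unit-tested R
function, and all benchmarks run on synthetic worlds with planted ground
truth.

## The model

A heterogeneous graph `G = (V, E)` holds one weighted edge set ("view")
per relation: drug–drug chemical similarity (Tanimoto over fingerprint
bits), protein–protein sequence similarity (normalized Smith–Waterman),
drug–disease and protein–disease associations, and the known-interaction
bipartite graph restricted to training pairs.  Per view, node embeddings
are updated by dot-product attention,

    a_ij = softmax_{j∈N(i)} (Q_i · K_j),
    h_i' = ReLU( Σ_{j∈N(i)} a_ij W h_j ),

per-view embeddings are fused by a learned convex combination
`z = Σ_v α_v h_v` (`α = softmax(logits)`), and a pair `(d, p)` is scored
as

    ŷ = sigmoid( MLP([ z_d ; z_p ; f_prior ]) ),   f_prior = [f_chem ; f_seq],

trained end-to-end with binary cross-entropy, Adam, and early stopping on
validation AUC.  Ablation switches give the uniform-weight GCN variant
(`use_attention = FALSE`) and the attribute-free variant
(`use_attributes = FALSE`).  See the methods vignette
(`vignettes/multiview-attention-dti.Rmd`) for the full model description,
design decisions and limitations.

## Worked example

Simulate a 100-drug × 100-protein × 30-disease world (15 views, ~6%
interaction density), then run the rotating 80/10/10 five-fold protocol:

```r
library(mvgat)
cfg <- run_config(seed = 42)          # generator + training defaults, k = 5
cmd_simulate(cfg, "fixtures/")        # entities.tsv, 15 edge files, FASTA, ...
rep <- cmd_train("fixtures/", cfg, "run/")
print(rep)
#>     fold    acc    sen   spec    pre    mcc    auc   aupr
#>        1 0.6571 0.5429 0.7714 0.7037 0.3228 0.7965 0.7912
#>        2 0.7000 0.7000 0.7000 0.7000 0.4000 0.7757 0.7718
#>        3 0.7000 0.5143 0.8857 0.8182 0.4308 0.8139 0.8295
#>        4 0.6714 0.7857 0.5571 0.6395 0.3522 0.7412 0.6824
#>        5 0.7429 0.8000 0.6857 0.7179 0.4889 0.8045 0.7840
#>  Average 0.6943 0.6686 0.7200 0.7159 0.3990 0.7864 0.7718
```

Each row is one fold's held-out test set (70 positives + 70 sampled
negatives here): accuracy, sensitivity, specificity and precision at the
validation-chosen Youden threshold, Matthews correlation, ROC AUC and PR
AUC.  The Average row is the across-fold mean — a mean test AUC of 0.79
on this small world, against a Bayes ceiling of ~0.95 for its planted
logistic interaction model.  The ablation runner makes the attribute
contribution visible, especially on cold-start pairs:

```r
cmd_ablate("fixtures/", cfg, "ablation/")
#>         variant    auc   aupr
#>            full 0.7965 0.7912
#>    no_attention 0.7920 0.7881
#>   no_attributes 0.6347 0.6120
```

The same pipeline is scriptable from a shell via `exec/mvgat`
(`simulate`, `train`, `evaluate`, `ablate`, `sweep`, `predict`), e.g.

```sh
Rscript exec/mvgat simulate --out fixtures --seed 42
Rscript exec/mvgat train --in fixtures --out run --seed 42
```

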