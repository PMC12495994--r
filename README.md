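# ceRNAdis

Higher-order graph learning for predicting associations between competing
endogenous RNA (ceRNA) triplets and diseases.

## The problem

lncRNAs, miRNAs and mRNAs regulate one another through shared miRNA binding:
an lncRNA that sponges a miRNA de-represses that miRNA's target mRNAs. A
*ceRNA triplet* is an lncRNA–miRNA–mRNA trio whose internal interactions
(lncRNA–miRNA, miRNA–mRNA) are experimentally validated. ceRNAdis scores
candidate (triplet, disease) associations from a heterogeneous molecular
network — the link-prediction setting behind biomarker screening and
regulatory-axis discovery. It is aimed at computational biologists who have
edge lists of validated interactions and known RNA–disease associations (or
want a fully synthetic benchmark) and need a reproducible prediction
pipeline with honest evaluation protocols.

## The method

1. **Similarity.** Biased second-order random walks (return parameter $p$,
   in-out parameter $q$) plus skip-gram with negative sampling
   ($P_n(v) \propto d(v)^{3/4}$) embed all nodes of the heterogeneous graph;
   per-type RNA similarity blocks are cosine similarities of the embeddings.
   Disease similarity uses ontology shared-ancestor semantics with decay
   $\mu = 0.5$ per generation,
   $DS(i,j) = \sum_{X \in N_i \cap N_j}(D_i(X)+D_j(X)) / (DV(i)+DV(j))$,
   with a Gaussian interaction-profile (GIP) kernel fallback
   $GS_1(i,j) = \exp(-\Delta_d\lVert\beta_i-\beta_j\rVert^2)$ for diseases
   without ontology annotations.
2. **Higher-order structure.** Triangle motifs of a support graph
   (association edges plus intra-type similarity edges at threshold $\tau$)
   drive two constructions: GAT-style attention coefficients shared across
   each triangle at their maximum, added to the similarity blocks (enhanced
   adjacency $A_e$); and binary triangle co-occurrence blocks (higher-order
   adjacency $A_h$).
3. **Propagation and scoring.** A two-layer GCN
   $H = A_h\,\mathrm{LeakyReLU}(A_e H^{(0)} W^{(1)})\,W^{(2)}$ produces node
   embeddings; triplet embeddings combine the three member embeddings (MLP
   or learned weighted average); the link score is
   $\hat y = \sigma(h_\mathrm{triplet} W_p h_\mathrm{disease})$, trained
   with binary cross-entropy and Adam.
4. **Structure-consistent negatives.** Negative samples keep a positive's
   miRNA fixed, redraw the lncRNA/mRNA among that miRNA's validated
   partners, and pair the triplet with a non-associated disease, so
   negatives are structurally indistinguishable from positives.
5. **Classifier head and evaluation.** A gradient boosted tree ensemble on
   the concatenated triplet/disease embeddings produces final scores;
   evaluation covers repeated holdout, disease-stratified (cold-start)
   cross-validation, Welch significance tests, fold-similarity diagnostics,
   network topology profiles (AEC/ACC/ADC) and top-k ranking.

See the vignette (`vignettes/higher-order-cerna-disease.Rmd`) for the model
assumptions, parameter table and design rationale.

## Worked example

```r
library(ceRNAdis)

bundle <- generate_benchmark(synth_preset("mid", seed = 0))
bundle
#> benchmark_bundle
#> hetero_graph: 60 lncRNA, 120 miRNA, 180 mRNA, 40 disease nodes; 1016 edges
#>   edges by relation: lnc-mi=207, lnc-mr=63, lnc-dis=5, mi-mr=682, mi-dis=21, mr-dis=38
#>   400 positive triplet-disease associations, 6 modules, signal 0.90, seed 0

res <- run_pipeline(bundle, pipeline_config(seed = 0))
res$metrics
#> AUC-ROC 0.8559 | AUC-PR 0.8125 | ACC 0.8187 | P 0.7525 | R 0.9500 | F1 0.8398 (threshold 0.271; 80 pos / 80 neg)
```

The benchmark plants a modular signal (90% of positive associations link a
triplet to a disease of the same regulatory module). `run_pipeline` splits
the positives 80/20, builds the network representation from training
associations only, trains the higher-order GCN for 300 epochs, and reports
held-out metrics: an AUC-ROC of 0.86 means the planted module signal is
recovered well above chance; the same pipeline with permuted training
labels (`permute_labels = TRUE`) drops to ≈0.5, confirming the signal is
learned rather than leaked.

The same workflow is scriptable from a shell:

```sh
Rscript inst/cli/ceRNAdis.R simulate --preset mid --seed 0 --out bench/
Rscript inst/cli/ceRNAdis.R train --dir bench/ --seed 0 --out run/
Rscript inst/cli/ceRNAdis.R cv --dir bench/ --mode disease_stratified --k 5 --out cv.tsv
Rscript inst/cli/ceRNAdis.R rank --dir bench/ --k 20 --out top20.tsv
```

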