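# lpiboost

Sequence-based prediction of lncRNA–protein interactions (LPIs) with an
imbalance-aware boosting ensemble that alternates two weak-learner
families: voting forests of extremely randomized trees and
exhaustive-search decision trees.

## Who this is for

Computational biologists who have lncRNA and protein sequences (FASTA)
plus a list of known interacting pairs (TSV), and want to rank the
unlabeled pairs — including pairs involving entirely new lncRNAs or
proteins ("cold start"), where network propagation methods cannot help.
Annotated LPI collections are severely imbalanced (positive fractions of
roughly 0.04–0.31), and unannotated pairs are candidate negatives rather
than verified non-interactions; the pipeline is built around both facts.

## The method

1. **Descriptors.** lncRNAs: zCurve, GC content, (A+T)/(G+C), cumulative
   skews, k-mer composition (k ≤ 3) and eight gapped k-mer families
   (gaps 1–5).  Proteins: amino-acid and dipeptide composition, CTD,
   conjoint triad, quasi-sequence order, pseudo amino-acid composition,
   Moreau–Broto autocorrelation.
2. **Pair vectors.** Each descriptor table is standardized and reduced by
   PCA to *d* = 100 dimensions; a pair is the 2*d* concatenation.
3. **Classifier.** AdaBoost-style loop: odd iterations pick the best of 5
   candidate extra-tree forests (split quality = normalized Shannon
   information gain, Score = 2I/(H<sub>c</sub>+H<sub>s</sub>)), even
   iterations grow an information-gain decision tree; learner weight
   α = ½ ln((1−ε)/ε); sample weights update by w ← w·e<sup>−αpy</sup>;
   early stopping on validation AUC with patience 10.  Prediction is
   sign(Σ α<sub>t</sub> f<sub>t</sub>), with Σ α f / Σ α as ranking
   score.
4. **Evaluation.** 5-fold cross-validation over lncRNAs (`cv_l`),
   proteins (`cv_p`) or pairs (`cv_lp`), with all pairs of held-out
   entities on the test side, fold-internal PCA, and six metrics
   (precision, recall, accuracy, F1, AUC, AUPR).

A seeded synthetic generator plants a motif-mediated interaction rule in
random sequences, so the whole pipeline is testable without downloads.

## Worked example

```r
library(lpiboost)

d <- simulate_lpi(synthetic_spec(seed = 1))   # 120 lncRNAs x 30 proteins
dataset_stats(d$matrix)
report <- run_experiment(d$rna, d$protein, d$matrix,
                         cv_scheme("cv_lp", repeats = 1, seed = 1))
report
```

```
lncRNAs: 120  proteins: 30  known LPIs: 934  pairs: 3600  ratio: 0.2594
<lpi_report> cv_lp, 1 repeat(s) x 5 fold(s)
    metric      mean         sd
 precision 0.8629358 0.01956507
    recall 0.8620236 0.02731279
  accuracy 0.8624235 0.01469722
        f1 0.8621868 0.01598993
       auc 0.9056657 0.01606875
      aupr 0.9035422 0.01594874
```

The report rows are per fold; `ratio` is the positive fraction of the
interaction matrix, the six metrics are computed on each held-out fold
and averaged.  An AUC near 0.91 here means the ensemble recovered the
planted motif rule from sequence alone; on permuted labels the same
pipeline returns AUC ≈ 0.5.

The same steps run from a shell via the bundled CLI:

```sh
inst/cli/lpiboost simulate --out run1 --seed 1
inst/cli/lpiboost stats --fasta-lnc run1/lnc.fasta \
    --fasta-prot run1/prot.fasta --pairs run1/pairs.tsv
inst/cli/lpiboost evaluate --fasta-lnc run1/lnc.fasta \
    --fasta-prot run1/prot.fasta --pairs run1/pairs.tsv --cv lp --out run1/eval
```

## Layout

- `R/` — io, features, reduce (PCA/pairs), trees, ensemble, evaluation,
  synthetic, serialization, CLI
- `tests/testthat/` — unit, property and end-to-end acceptance tests
- `vignettes/lpi-boosting-methods.Rmd` — model, assumptions, design
  decisions, limitations
- `inst/extdata/` — auditable descriptor property tables (TSV)
- `inst/cli/lpiboost` — command-line entry point
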