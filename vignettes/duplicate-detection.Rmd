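---
title: "Detecting duplicate nucleotide records with supervised learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting duplicate nucleotide records with supervised learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqdedup)
```

## The problem

Nucleotide sequence databases accumulate duplicate records: several entries
that describe the same underlying coding sequence, submitted at different
times, by different groups, as fragments or as re-sequenced near-copies.
Simple identity thresholds (e.g. "90% sequence identity means duplicate")
both over- and under-call: truly distinct records can share near-identical
sequence, and true duplicates can be fragments or diverged variants that an
identity cutoff misses. `seqdedup` treats de-duplication as supervised
pairwise classification: a pair of records is represented by 22 similarity
features and a classifier trained on expert-labelled pairs predicts whether
the pair is duplicate (`DU`) or distinct (`DI`), or — in multi-class mode —
which *kind* of duplicate it is.

## The pair representation

For records $D$ and $R$ the package computes:

* **Metadata features.** Token-set Jaccard similarity of the DEFINITION
  descriptions (lower-cased, stopword-free, lemmatized); a literature
  similarity with a rule cascade (shared PubMed IDs → Boolean match, else
  journal-reference titles → token Jaccard, else author-set Jaccard) plus a
  `has_literature` indicator; and a submitter comparison
  (`SAME`/`DIFFERENT`/`NA`) that follows the database update policy of
  crediting any shared original submitter.
* **Whole-sequence alignment features.** Length ratio
  $\min(|D|,|R|)/\max(|D|,|R|)$; a hit indicator; best-HSP local identity;
  the E-value and an over-threshold flag (E-value strictly greater than
  $10^{-3}$); and the aligned proportion
  $$\mathrm{AP} = \frac{\mathrm{len}(I)}{\max(\mathrm{len}(D), \mathrm{len}(R))},$$
  where $I$ is the set of locally aligned identical bases — a cheap estimate
  of global identity that never runs a global alignment.
* **Coding-region features.** The same alignment statistics for the *first*
  CDS of each record (nucleotide mode) and for the first CDS's protein
  translation (BLOSUM62 protein mode), with `has_cds`/`has_trs` indicators.

Missing-value semantics are part of the contract: when an alignment has no
hits, its dependent numeric features are *missing* (not zero) and the
over-threshold flag is `Yes`, since "no significant similarity" is the
extreme of a non-significant alignment. The `has_*` indicators retain the
missingness signal after imputation, so classifiers can distinguish "no
evidence" from "evidence of dissimilarity".

## Alignment engines and their statistics

The default engine is an exact Smith–Waterman affine-gap local aligner
(dynamic programming via Biostrings) with classic pairwise-BLAST scoring:
match +2, mismatch −3, gap open 5, extend 2 for nucleotides; BLOSUM62 with
gap open 11, extend 1 for proteins. E-values come from the Karlin–Altschul
formula $E = K m n e^{-\lambda S}$ with the published gapped parameters for
those schemes ($\lambda = 0.625, K = 0.410$ nucleotide;
$\lambda = 0.267, K = 0.041$ protein), using raw sequence lengths for
$m, n$. Suboptimal HSPs are recovered by iteratively masking the previous
alignment's footprint in both sequences. An external NCBI BLAST+ backend
(`blastn`/`blastp` with dust/seg off and word sizes 4/2, the
high-sensitivity settings) is available behind the same contract; the two
engines agree on the best HSP to within a couple of terminal positions,
differing only where alignment heuristics trim ends.

Numerical choices worth stating: the report cutoff is the conventional
E ≤ 10 (significance at 0.001 is a downstream feature, not an alignment
filter); HSPs are ordered by E-value, then raw score, then leftmost start in
either sequence — a tie-break chosen so that feature extraction is exactly
symmetric in the order of the two records (the engine also canonicalises
argument order internally, since tracebacks among co-optimal alignments are
otherwise order-dependent); `identity` uses the BLAST convention of dividing
identical positions by aligned columns including gaps; and `AP` uses the
best HSP's identical-base count by default (summing overlapping HSPs could
exceed the sequence length; a non-overlapping union mode is available as an
option).

## Duplicate subtypes

Duplicates are subtyped from the whole-sequence features with precedence
NS → ES → EF:

* **NS** (non-significant alignment): no hit, or E-value strictly over
  0.001. Such pairs carry no trustworthy identity evidence, so NS is carved
  out first.
* **ES** (near-exact sequence): identity ≥ 0.9 **and** AP ≥ 0.9, both
  inclusive.
* **EF** (near-exact fragment): a significant hit below the ES criteria.

The boundaries matter and are tested: E-value exactly 0.001 is *not* over
the threshold, and 0.9 qualifies for ES. The ES rule is evaluated on
whole-sequence features only, not CDS-level ones, matching the printed
definition. The package also provides the `Seq90` baseline — duplicate if
identity and length ratio are both at least 0.9 — which serves as the
reference point that the learned models are meant to beat; a pair without
an alignment hit is classified distinct by the baseline, which cannot claim
duplication without an alignment.

## Models

Three algorithms are supported, in binary and multi-class modes: Gaussian/
categorical naive Bayes (`e1071`), a CART decision tree with default
cost-complexity pruning (`rpart`), and an RBF-kernel C-SVM (LIBSVM via
`e1071`, one-vs-one for multi-class). Encoding keeps categoricals as fixed-
level factors for the first two and one-hot encodes them for the SVM, whose
inputs are scaled to $[0,1]$ with parameters estimated from the training
fold only; test values outside the training range are clipped, which is the
standard guard against scaling leakage. Missing numerics are imputed
(similarities to 0, E-values to the report cutoff of 10) because margin-
based models cannot consume missing values; the paired indicator features
preserve the information. One numerical guard: on cleanly separable
synthetic data a feature can have zero within-class variance, which
degenerates the naive Bayes Gaussian density, so fitted standard deviations
are floored at $10^{-6}$.

## Evaluation protocols

* `cross_validate()`: stratified, seeded k-fold (default 10) with pooled
  out-of-fold predictions — one confusion matrix over all folds (micro
  pooling), per-class precision/recall and one-vs-rest AUROC.
  Stratification is variance-reducing and near-neutral on balanced data; a
  multi-class stratum smaller than k falls back to unstratified folds with
  a warning.
* `learning_curve()`: training fractions ascend geometrically from 1% and
  terminate at exactly 100%; each point is repeated 20 times with derived
  seeds, holding out one CV fold and subsampling the rest. The growth
  factor is a parameter (default 1.05); the examples in this package use
  coarser grids (e.g. ×10) to keep demonstration runs small.
* `ablate()`: cross-validates the six feature sets `Meta`, `Seq`, `SQ`,
  `SQC`, `SQM`, `All` on a *shared* fold assignment and reports
  class-averaged precision/recall, so differences are attributable to the
  features alone.
* `error_profile()`: mean of each numeric feature over false positives and
  false negatives, with missing values excluded from the means rather than
  zero-filled, plus instance counts.
* `relative_type_accuracy()`: compares binary and multi-class models per
  duplicate subtype, crediting the binary model for any `DU` prediction and
  the multi-class model for predicting *any* duplicate subtype.
* `cross_dataset()` / `transfer_sweep()`: train on one dataset, test on
  another; n datasets produce n(n−1) ordered reports.

Every report embeds its configuration and a hash of it, so any artifact can
be traced to the exact run that produced it.

## The synthetic corpus generator

Real expert-labelled collections at the scale used to develop this method
are not redistributable, so the package ships a seeded generator
(`synth_config()`, `generate_corpus()`) that emulates the phenomenology the
classifier must handle. Records carry descriptions drawn from a shared
vocabulary, literature references with or without PubMed IDs, sometimes-
absent submitter sets, sequences of 300–1500 nt, and a single valid ORF
(ATG, stop-free codons, stop) with a standard-code translation. Pair
classes: **ES** — copy plus point substitutions at 0.5%/site with highly
shared metadata; **EF** — a contiguous fragment covering 30–70% of the
parent; **NS** — independently drawn sequences with shared metadata, i.e.
duplicates detectable only through metadata; **DI** — independent records;
**DI_hard** — near-identical sequences with disjoint metadata, mirroring
real distinct pairs that are "similar coding sequences for different
proteins". Mutations are substitution-only by default so the ES/EF boundary
is controlled by a single parameter. Metadata-sharing probabilities
(0.8–0.85) are set so that duplicate metadata is informative but not
deterministic.

Two derived fixtures are used throughout the tests: a *separable* corpus
(ES at zero mutations with fully shared metadata vs. independent DI pairs
whose lengths are forced to differ) on which any sensible classifier should
approach perfect accuracy, and a balanced {NS, DI} corpus in which NS and
DI sequence pairs are drawn from the *same* process, so a sequence-only
baseline like Seq90 is at chance by symmetry while metadata-aware models
are not. These constructions make the expected outcomes derivable rather
than tuned.

What the generator does **not** emulate: organism-specific subtype
distributions, sequencing-error models, indel-rich divergence, EMBL/DDBJ
dialects, and the long-tailed metadata quirks of real submissions. Passing
tests on synthetic corpora therefore demonstrate that the machinery is
correct and that the qualitative contrasts (baseline failure on NS,
metadata value, transferability under a shared generating process) hold —
not that the specific accuracies will be reproduced on real data.

## Worked example

```{r example, eval = FALSE}
corpus <- generate_corpus(synth_config(seed = 1))
feats <- label_subtypes(
  compute_feature_matrix(corpus$pairs, corpus$records))
report <- cross_validate(feats, "decision_tree", "binary", "SQM",
                         k = 10, seed = 1)
report
```

The demonstration problem sizes in the tests and the acceptance script
(2,000-pair separable corpora, 600-pair NS/DI corpora, five 120-pair
datasets for generalisation) were chosen as the smallest sizes at which the
sampling noise of the measured quantities is well inside the asserted
bands.

## Known limitations

* Only the first CDS of each record enters the representation; records
  whose duplication evidence lives in a later CDS are under-served (the
  printed method has the same property, and its ablation suggests CDS
  features can even hurt).
* The internal aligner is exact but quadratic; sequences beyond a
  configurable cap (20 kb) are rejected rather than approximated. The
  external BLAST+ backend is the right tool at scale.
* Class imbalance is out of scope: corpora are balanced by design, and no
  reweighting is implemented.
* All-pairs comparison is quadratic in the number of records; metadata
  blocking (cheap pre-filtering) is the natural extension and is not
  implemented here.
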