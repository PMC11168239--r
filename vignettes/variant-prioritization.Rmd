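---
title: "Phenotype-aware prioritization of causative exome variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype-aware prioritization of causative exome variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A whole-exome sequencing run yields roughly 40,000 variants per proband.
For a patient with a suspected rare Mendelian disorder, usually one (or a
handful) of them is the diagnosis. varranker implements a pipeline that
narrows the exome to a few hundred deleterious candidates and then orders
them by an estimated probability of being disease-causing, combining two
kinds of evidence:

* **variant-level pathogenicity** — functional-prediction rank scores,
  ACMG/AMP clinical-interpretation criteria, population allele frequency,
  gene constraint, curated database assertions;
* **gene-phenotype relevance** — how strongly the variant's gene is linked,
  in free text, to the patient's phenotype keywords.

A random forest trained on labelled exomes turns these into one ranking
per patient. The intended reader of the ranked list is a clinical
geneticist who will inspect the top ~10 candidates.

```{r, eval = FALSE}
library(varranker)

cfg  <- sim_config(seed = 1, n_patients = 50, variants_per_patient = 300,
                   signal = "strong", universe_seed = 99)
corp <- generate_corpus(cfg)
fit  <- variant_prioritizer(generate_cohort(cfg, corp), corp, seed = 1)

test <- generate_cohort(sim_config(seed = 2, n_patients = 20,
                                   variants_per_patient = 300,
                                   signal = "strong", universe_seed = 99),
                        corp)
ranked <- predict(fit, test)
topk_stats(ranked, mode = "patient")
```

## Candidate filtering

The filter keeps a variant iff

1. its **maximum allele frequency** across population databases is at most
   0.01 *or is missing* — absence from the databases is treated as rarity,
   not as unknown; and
2. it matches at least one **consequence class**: nonsynonymous missense,
   stop gain, splice, frameshift, initial codon (start lost), deletion,
   insertion, in-frame deletion, or the exonic/splice-site catch-all.

Within a class, any listed column (coding consequence, Sequence-Ontology
terms, region class, variant type) containing any listed value is a match;
classes are combined as a union, while the frequency gate is conjunctive. A
pure union would retain every common benign polymorphism, defeating the
point of a deleteriousness filter.

One interpretation is worth flagging: the exonic/splicing catch-all, read
literally, would also sweep in every *synonymous* exonic variant, which
would multiply the candidate load several-fold. varranker therefore
suppresses region-only matches for records whose only affirmed consequence
is synonymous (`synonymous SNV` / `synonymous_variant`). A record that
additionally carries a damaging term (say a synonymous change annotated
with `splice_region_variant`) still passes. The criteria table is an
ordinary R list (`default_filter_criteria()`), so a user who disagrees can
override it per run.

## Gene-phenotype similarity

Gene descriptions — one document per gene per source, emulating OMIM,
GeneReviews, Entrez Gene and PubTator — are ranked against the patient's
keywords in two ways.

**Okapi BM25.** For document $D$ and query $Q = q_1 \dots q_n$:

$$\mathrm{score}(D,Q) = \sum_i \mathrm{IDF}(q_i)\,
  \frac{f(q_i,D)\,(k_1+1)}{f(q_i,D) + k_1\left(1 - b + b\,\frac{|D|}{\mathrm{avgdl}}\right)},
  \qquad
  \mathrm{IDF}(q_i) = \ln\!\left(\frac{N - n(q_i) + 0.5}{n(q_i) + 0.5} + 1\right)$$

with $k_1 = 1.2$ and $b = 0.8$.

**RANK.** The feature actually fed to the model replaces IDF with the
Robertson–Spärck-Jones weight and adds query-term-frequency saturation:

$$\mathrm{RANK}(D,Q) = \sum_i \omega(q_i)\,
  \frac{(k_1+1)\,tf}{K + tf}\,\frac{(k_3+1)\,qtf}{k_3 + qtf},
  \qquad K = k_1\left[(1-b) + b\,\frac{dl}{\mathrm{avgdl}}\right]$$

with $k_1 = 1.2$, $b = 0.75$, $k_3 = 8$, and
$\omega = \log\frac{(r+0.5)(N-n-R+r+0.5)}{(R-r+0.5)(n-r+0.5)}$. The two
$b$ values are deliberately kept as separate parameters
(`bm25_params()$b_bm25` vs `$b_rank`) rather than reconciled: they belong
to two different formulas with two different stated constants. With no
relevance judgments available, $R = r = 0$, under which $\omega$ reduces to
$\log\frac{N-n+0.5}{n+0.5}$; $\omega$ is floored at zero so that a very
common term can never *subtract* similarity.

Design choices where the upstream full-text engine leaves the details
open:

* **Tokenization** is lowercase, split on non-alphanumerics, no stemming
  or stop-word removal — the simplest fully reproducible choice.
  Multi-word keywords are decomposed into tokens and pooled into one query.
* **Logarithms** are natural in both IDF and $\omega$.
* **The 0–1000 ordinal scale.** The upstream engine reports RANK as
  ordinal integers 0–1000 without publishing its scaling. varranker
  min-max scales the raw RANK scores across all genes *per (query,
  source)* to $[0, 1000]$ and rounds; an all-constant score vector stays
  at 0. The per-query maximum and minimum across sources become the two
  model features `sim_max` and `sim_min`; a gene absent from a source
  contributes 0 for that source.

## The feature matrix

Each retained variant becomes one row of a 94-column matrix, declared in a
single registry (`feature_schema()`) so that deviations are a configuration
change, not a code change:

| block | columns |
|---|---|
| prediction rank scores (SIFT … SiPhy) | 20 |
| MaxEntScan significance | 1 |
| HGMD rank score | 1 |
| ClinVar significance one-hot | 8 |
| ACMG weighted score + 14 criterion indicators | 15 |
| gene constraints pLI, pRec, syn_z, mis_z | 4 |
| inheritance-pattern counts | 11 |
| genotype one-hot (hom/het/hem) | 3 |
| region one-hot | 12 |
| coding-consequence one-hot | 10 |
| variant type one-hot | 3 |
| quality, read depth, max allele frequency | 3 |
| phenotype similarity max/min | 2 |
| sex indicator | 1 |

The **ACMG score** is the Xrare-style weighted sum over the 14 weighted
criteria (PVS1:6, PS1:4, PM1/PM2/PM4/PM5:2, PP2/PP3:1; BA1:9, BS1/BS2:3,
BP3/BP4:1, BP7:2). Benign criteria *subtract* their weight: the score is a
pathogenicity score, and letting stand-alone benign evidence (BA1, a
common polymorphism) *raise* pathogenicity would be nonsensical. This sign
convention is an interpretation, flagged as such.

**MaxEntScan significance** is 1 iff the alternate-allele score is below 3
and the relative score change is below 30% in absolute value, as printed;
the rule plausibly inverts the usual ">30% drop" convention for splice
disruption, but it is implemented as stated, and the threshold logic is
isolated in one function (`maxentscan_significance()`) should a user want
the other reading.

**Hemizygous correction**: upstream genotype annotation carries no
hemizygous calls, so all chromosome-X genotypes of male patients are
replaced by `hem` before encoding. Unknown sex is treated as female (no
replacement) — the conservative choice, since wrongly hemizygosing a
female's X would fabricate evidence for X-linked recessive fit.

**Preprocessing.** Missing values are imputed per the registry — training
column mean for assay-like continuous columns (prediction scores, quality,
depth, constraints), semantic zero for score-like columns where absence
means "no evidence" (HGMD rank, similarity scores, MaxEntScan
significance, allele frequency, where missing ≈ unobserved ≈ rare).
Continuous and count columns are then min-max normalized
($X_{norm} = (X - X_{min})/(X_{max} - X_{min})$) with the min/max learned
on training rows only; at transform time values are clipped to $[0,1]$ and
training-constant columns map to 0. One-hot categories unseen in training
encode as all-zero vectors.

## Feature selection and the ranking model

Features are ranked by estimated **mutual information** with the 0/1
causative label and the top 60% (56 of 94) are kept, computed on training
rows only. Most of the schema is indicators and small counts, for which
the discrete plug-in estimator
$\sum_{x,y} p(x,y)\ln\frac{p(x,y)}{p(x)p(y)}$ is exact; genuinely
continuous columns are discretized into eight quantile bins first. The
binning route was chosen over a nearest-neighbour estimator because it is
deterministic (no estimator seed), fast at cohort scale, and its
discrete core is the same code the tests verify against hand-computed
values. Ties are broken by column order, so selection is fully
reproducible.

The ranker is a **probability random forest** (Gini impurity splits) with
class-balanced weights — causative rows are ~0.4% of training rows
(Table-2-like proportions: 478 of 125,693), and unweighted training
collapses to the majority class. Hyperparameters can be chosen by grid
search (`prioritizer_grid()`: trees {100, 300, 500}, depth {unlimited, 10,
20}, mtry {sqrt, log2}) with 10-fold cross-validation maximizing top-10
accuracy. Folds are **patient-grouped**: all variants of a patient stay in
one fold, because rows of one exome share the patient's keywords, sex and
gene-similarity table, and splitting them across folds would leak. The
shipped defaults (500 trees, unlimited depth, sqrt mtry) sit at the top of
that grid on the synthetic cohorts, and the package's own test and
acceptance runs fit with fixed hyperparameters rather than the full grid —
a problem-size choice; the grid machinery itself is exercised on a small
cohort in the unit tests.

Within a patient, variants are ordered by predicted probability; ties
break by ACMG score descending, then by `(chrom,pos,ref,alt)` — so a
ranking is a pure function of the variant set, invariant to input order.

## Evaluation

`topk_stats()` reports the percentage of causative variants recovered at
ranks 1, 5, 10, 20, 50, 100 under three denominators: **variant** (each
causative variant counts separately), **patient** (a patient counts at
$k$ if *any* of its causative variants ranks $\le k$), and **gene**
(variant ranks collapse to genes by each gene's best variant, with dense
re-ranking — the protocol used when comparing against gene-level tools).
A causative variant missing from a ranked list is an error, not rank
$\infty$: the reference denominators contain only diagnosed, retained
variants. `cumulative_distribution()` gives the corresponding step curve.

## What the synthetic data does and does not emulate

Real training corpora (clinical exomes with diagnosed causative variants,
plus licensed OMIM/GeneReviews text) cannot ship with a package, so
varranker generates its own study material.

`generate_corpus()` builds, per source, one document per gene: background
tokens drawn from a Zipf-weighted common vocabulary plus 3–8 gene-specific
"phenotype tokens" planted at elevated frequency.
`generate_cohort()` gives each patient a causal gene, keywords (a noisy
subset of that gene's phenotype tokens plus distractors), and a variant
table whose background rows mix common, rare and missing allele
frequencies, low-skewed Beta prediction scores, sparse ACMG evidence and
the full range of consequence classes — so the filter, the imputation and
the one-hot encoders all have realistic work to do. Causal rows are
guaranteed to survive the filter. Under the `strong` preset they carry
shifted distributions (rare or absent allele frequency, high prediction
scores, PVS1/PM2/PP3-style evidence, a genotype consistent with the gene's
inheritance pattern and the patient's sex); under `null` they are
background draws conditioned only on filter survival, and keywords carry
no planted tokens. The gene universe (gene–chromosome map, constraints,
inheritance, phenotype tokens, corpus documents) is controlled by a
separate `universe_seed`, so train and test cohorts share genes and
corpora without sharing any patient-level randomness.

Chosen study sizes: the full-scale defaults mirror a filtered exome
(~741 variants per patient); the package's end-to-end test and the
acceptance script run 50 training and 20 test patients at ~300 variants
each over 200 genes and 2 sources, which preserves the class imbalance
(~1 causative in ~95 post-filter candidates) at a size a laptop fits in a
couple of minutes. The `strong` preset is calibrated so that top-10
recovery of at least 90% of test patients is achievable — the synthetic
stand-in for the recovery levels reported on real clinical exomes, which
are not reproducible without the protected data.

What passing these tests shows: the pipeline's plumbing, formulas,
preprocessing, selection and ranking behave as specified, end to end, and
recover planted signal of a plausible shape. What it does not show:
performance on real exomes — the generator has no linkage structure, no
transcript-level annotation conflicts, no correlated prediction scores
(real predictors agree with each other far more than independent Beta
draws), no shared phenotype vocabulary between related diseases, and its
corpus documents are token soup rather than prose.

## Numerical and degenerate-input conventions

* IDF and $\omega$ are defined at $n = 0$ (query term absent everywhere);
  $\omega < 0$ is floored to 0.
* A gene absent from a corpus scores 0 (logged miss, not an error); an
  empty keyword list warns and yields all-zero similarity features.
* Min-max scaling of a constant column yields 0, both in the 0–1000 RANK
  scaling and in feature normalization; transform-time values outside the
  training range clip to $[0,1]$.
* Multi-allelic VCF rows split into one record per ALT allele, each
  interpreting the shared GT field; indel annotation join is exact string
  match on normalized `(chrom,pos,ref,alt)` — the pipeline assumes one
  annotation run produced both files, so no re-normalization is attempted.
* Duplicate variant keys within a patient are an error naming the key;
  unmatched annotation rows are dropped with a warning; unmatched VCF rows
  keep all-missing annotations and flow through imputation.
* All randomness (simulation, fold assignment, forest) derives from one
  seed via a mixing hash, so two runs with an identical config are
  byte-identical.

## Limitations

The 94-column schema is a reconstruction: the reference feature list is
not fully published, so the composition (category levels of the one-hot
blocks, the 11 canonical inheritance patterns) was fixed once in
`feature_schema()` as the most defensible reading, and the registry is the
single place to amend it. ACMG criteria arrive as upstream annotation
flags and are not re-derived from raw evidence. The BM25 corpus treats
each gene's description as a bag of words; negation, section structure and
ontology relationships (HPO) are out of scope. Performance claims
transfer to real data only to the extent the synthetic generator's
assumptions hold.
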