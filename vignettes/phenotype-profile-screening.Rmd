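---
title: "Phenotype-profile screening: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype-profile screening: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoscreen)
```

## The model

`phenoscreen` ranks candidate drugs for a disease by comparing weighted
mouse-phenotype profiles. The premise is that a disease's associated genes
and a drug's target genes both perturb biology in ways that mouse
gene–phenotype annotations record; if the two perturbations look alike in
phenotype space, the drug is a repositioning candidate.

**Profiles.** The disease profile contains every phenotype term directly
annotated to at least one disease gene, weighted by the number of distinct
disease genes carrying it; terms with weight strictly below the median of
all the profile's weights are then removed, concentrating the profile on
recurrent phenotypes. A drug's profile contains every term annotated to at
least one of its target genes, weighted by the sum of the drug–target
confidence scores of those genes. Profile membership deliberately uses
*direct* annotations only: ancestor closure is applied when computing
information content, not when building profiles, because closing profiles
would flood them with generic high-level terms that carry no discriminative
signal.

**Information content.** With the true-path rule (a gene annotated to a term
is implicitly annotated to all its ancestors), a term's annotation frequency
is the fraction of annotated genes whose closed set contains it, and its
information content is the negative log of that frequency. The root is
reached by every gene, so its IC is 0, and IC never decreases from parent to
child. The p(t) denominator is the number of distinct annotated genes in the
loaded corpus, not a fixed constant, so corpora of any snapshot can be used.

**Similarity.** Terms are compared by the Resnik score — the maximum IC over
their common ancestors, taken over *reflexive* ancestor sets so that a
term's self-similarity equals its own IC rather than collapsing to a
parent's. Profiles are compared by the best-match average: each term of one
profile is matched to its most similar term in the other, the matches are
averaged, and the two directions are averaged to symmetrize. The average is
unweighted: the profile weights drive the median filter and the category
report, while the similarity treats every surviving term equally (a
weighted-mean mode is available behind a flag for experimentation). Natural
logarithms are used; the base is a global factor on all IC values and
provably cannot change a ranking, which the test suite asserts directly.

**Ranking and evaluation.** Drugs are sorted by descending similarity; ties
share the average of their positional ranks, so tied drugs have equal
percentiles and the result is independent of input order. A drug's
percentile is rank / n × 100. Evaluation uses the median percentile per
labeled set — the median, not the mean, because one drug ranked near the
bottom should not dominate the summary — plus two-sided paired t-tests on
percentiles over the drugs two lists share, the raw (uninterpolated)
precision–recall step curve, and average precision as the mean of the
precisions at the positive hits; with a single disease query, mean average
precision equals average precision.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `score_scale` | 1000 | divisor turning raw drug–target scores into [0, 1] confidences (1000 for STITCH-style integers, 1 for unit reals) |
| `min_confidence` | 0 | drop links with scaled confidence below this; 0 keeps all links, since no principled threshold is dictated by the model |
| `median_filter` | on | apply the median filter to the disease profile; drug profiles are not filtered by default |
| `weighted` | off | weight the best-match average by normalized profile weights |
| `virtual_root` | off | graft multi-root ontologies under a synthetic root (which receives p = 1, hence IC 0, and is therefore similarity-neutral) |

Duplicate drug–gene links collapse to their maximum confidence, which avoids
double-counting one interaction reported through several evidence channels.
Genes appearing as drug targets but absent from the annotation corpus simply
contribute nothing to profiles. Drugs whose whole profile lacks IC entries
have *undefined* similarity — reported as excluded, never silently scored 0,
because a zero is a meaningful "maximally dissimilar" statement the data
cannot support. Evaluation drugs absent from a ranked list are likewise
excluded from that list's metrics (with counts reported) rather than imputed
a worst rank; an imputation mode exists for sensitivity analysis.

## Numerical and degenerate-case conventions

- Even-length weight vectors use the midpoint-mean median; with the
  strict-inequality filter rule ("remove weights strictly below the
  median") this affects only edge cases, and the filter can never remove
  more than half the terms.
- Category ranking breaks score ties lexicographically by category id, so
  reports are deterministic.
- Paired t-tests with all-zero differences return t = 0, p = 1; non-zero
  constant differences return t = ±Inf, p = 0.
- Pairwise term similarities are memoized across a screen; the cache is a
  performance device only and results are bit-identical without it.

## The synthetic generator

The generator emulates the five inputs the screen consumes. Its defaults
are the package's standard benchmark: a 200-term, 6-layer ontology whose
layer sizes grow geometrically from a single root, each term drawing up to 3
parents from the layer above; 500 genes with on average 8 direct annotations
drawn with probability proportional to `0.5^depth`, so deep, specific terms
are rare and IC grows with depth — the property of real corpora (MGI-scale:
thousands of genes, tens of annotations each) that gives Resnik scores their
signal, scaled down to keep a full screen in seconds; 25 disease genes
(mirroring the ~1–2% of the annotated genome a disease gene list covers);
100 drugs averaging 5 targets with confidences on the thousandths grid in
[0.4, 0.9] (so integer-score files round-trip exactly); and 10 planted
positives drawing 80% of their targets from the disease gene set. All
randomness flows through one integer seed via fixed sub-seeds per stage, so
generated studies are byte-identical across runs and platforms.

What the generator does *not* emulate: correlated annotations between
functionally related genes, polypharmacology structure among drugs, biased
ascertainment of disease genes, and real identifier schemes. Passing tests
on synthetic studies therefore demonstrate that the machinery is correct and
that planted signal of realistic strength is recovered — not that any
particular real disease's candidates are right, which depends entirely on
the annotation corpora supplied.

## Design choices where the design was open

- **Profile weights vs. similarity.** Weighted profiles are built, yet the
  best-match average is unweighted; the weights act through the median
  filter and the category scores. Both behaviors are exposed and the
  unweighted form is the default contract.
- **Categories** are the root's direct children, traced through is-a only.
  The number of categories is whatever the ontology release provides; it is
  reported, not forced.
- **Drug profiles are not median-filtered** by default; a flag enables it
  for experimentation.
- **Percentile-scale paired tests.** Comparing two methods' lists uses
  percentiles rather than raw ranks so lists of different lengths are
  commensurable; the report records this choice.
- **Similarity direction.** The quantity is a similarity (higher = more
  alike); ranking treats larger as better throughout.

## Problem sizes used in the checks

The test suite validates the optimized implementation against exhaustive
reference implementations (path-enumeration ancestors, triple-loop
similarities, sort-based filters and metrics) on studies of up to 50 terms
and 20 genes, where brute force is instant, across 100 seeds; the
planted-positive and null-condition checks run the full default benchmark
(200 terms / 500 genes / 100 drugs), the null condition over 50 seeds.
These sizes make the whole suite run in about three minutes on one CPU
while leaving the oracle comparisons exact.

## Known limitations

- Only is-a edges are traversed; part-of and other relations are ignored by
  design, and OWL ontologies are out of scope (convert to OBO first).
- Gene and drug identifiers are opaque strings; the package performs no
  identifier mapping, so input files must already agree on symbols.
- Resnik/best-match-average is the only similarity measure; Lin,
  Jiang–Conrath or simGIC variants are not provided.
- One disease per run; batch screening is a loop over diseases.
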