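---
title: "Methods: ortholog-augmented GO annotation and gene-set comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ortholog-augmented GO annotation and gene-set comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goforge)
```

## The problem

Human functional annotation in the Gene Ontology (GO) is dominated by
experiments on adult tissue and cultured cells, so gene-set analyses of fetal
and neonatal expression data routinely miss developmental biology that is well
characterized in the mouse. goforge implements a pipeline for closing part of
that gap computationally: it transfers mouse developmental GO annotations to
human genes through strict one-to-one orthology, merges them with the human
corpus, rebuilds true-path-propagated gene-set collections, and quantifies how
the augmentation changes the outcome of enrichment analyses.

The package is organized so that every stage is a plain function over tabular
data (tibbles in, tibbles out), with the DAG and gene-set collection as the
two non-tabular containers.

## Ontology model

`parse_obo()` loads `[Term]` stanzas from an OBO 1.2 file. Only `is_a` and
`part_of` relationships create edges; the regulates family and every other
relationship type are discarded. This single relation set is used both for
annotation propagation (the true path rule) and for developmental-subtree
membership. Using one relation set for both keeps the semantics coherent:
a gene annotated to a term is implicitly annotated to exactly the terms its
set will be propagated into. We considered admitting `regulates` edges for
subtree membership, which would widen the transfer scope, but regulation of a
developmental process is not itself a developmental process, so the narrower
reading is the safer default and the one implemented.

Obsolete terms are retained and flagged but never given edges, and
`build_collection()` skips (and counts) records that reference them — a GAF
file citing a dead term should be visible, not silently absorbed. `alt_id`
accessions resolve to their primary term during lookups.

The developmental subtree defaults to GO:0032502 ("developmental process")
but is a parameter (`dev_root`), since other branches may be used to scope a
transfer.

## Evidence-code policies

Two hardcoded (but overridable) policies drive filtering:

* **transfer policy** — whitelist EXP, IDA, IPI, IMP, IGI, IEP; blacklist the
  ISS family (ISS, ISO, ISA, ISM) plus IEA, TAS, NAS, IC, ND. Transferring an
  annotation across species re-generalizes it, so only direct experimental
  evidence is eligible, and anything that may itself derive from orthology or
  from statements rather than assays is excluded.
* **gene-set policy** — whitelist IDA, IPI, IMP, IGI, IEP, ISS, TAS, the
  evidence filter conventionally used for GO-derived gene-set collections.
  Ortholog-derived records bypass this policy inside `build_collection()`;
  they were already vetted by the stricter transfer policy and carry their
  mouse evidence code.

Records with evidence codes outside the known set are retained on read (with
a warning) but rejected by every policy, so corpus audits can see them while
analyses cannot be contaminated by them.

## Ortholog transfer

`transfer_annotations()` applies four independent gates: evidence passes the
transfer policy; the term lies in the developmental subtree; the mouse symbol
has a strictly one-to-one human ortholog; and the record is not
NOT-qualified. Negative findings are never transferred — whether a "NOT"
observed in mouse generalizes to human is exactly the kind of inference the
evidence gates exist to prevent. Transferred records keep the original GO
term and mouse evidence code, record the mouse reference in the with/from
column, and carry provenance `ORTHOLOG`. The ortholog map drops every row
participating in a one-to-many or many-to-one relationship (with a count),
so the surviving map is injective in both directions.

Records whose taxon column is present and not mouse are excluded by default
(`taxon = "10090"`); the check can be disabled for corpora with mixed or
missing taxon fields.

## Consolidation and gene-set construction

Annotations from different sources collapse on the key
`(symbol, term_id, NOT-status)`. References, dates and assigning databases
deliberately do not participate: gene-set semantics depend only on signed
gene–term pairs, and the per-record provenance union preserves the audit
trail. Gene identity is the uppercased symbol so human records and
ortholog-derived records collide correctly after mapping.

`build_collection()` filters first (NOT exclusion, then the evidence policy)
and propagates second, so an excluded record contributes nowhere — the
alternative order would let a blacklisted record leak into ancestor sets.
Propagation uses ancestor sets computed once per ontology in topological
order. The resulting collection satisfies, by construction, the monotone
subset invariant: along every is_a/part_of edge, the child's gene set is
contained in the parent's.

Size bounds for analysis are inclusive at both ends, 7 and 150 by default:
below about 7 genes permutation p-values lack granularity, and sets beyond
about 150 genes are broad, uninformative categories. Effective size — the
intersection with the expression dataset's gene universe — is what the bounds
test, not raw set size. `max_size = NULL` gives release mode (only the
minimum applies), and `min_size = NULL` disables that too.

## Enrichment analysis

`run_gsea()` implements the weighted running-sum enrichment statistic. For a
ranked list of $N$ genes and a set with $k$ members in the list, hits
increment the running sum by $|s_i|^w / N_R$ (with $N_R$ the sum of
$|s_i|^w$ over hits) and misses decrement it by $1/(N-k)$; the enrichment
score (ES) is the maximum-magnitude excursion, a signed value in $[-1, 1]$.
The default weight is 1; weight 0 recovers the classic Kolmogorov–Smirnov
form. The implementation evaluates the excursion only at hit boundaries
(*O(k)* per set after sorting), which the test suite checks against an
explicit *O(N)* walk and an independent implementation. Magnitude ties
between the positive and negative extremum — possible on the weight-0
rational grid — resolve to the extremum reached first in list order.

Two-class ranking uses the signal-to-noise ratio
$(\mu_1 - \mu_0) / (\sigma_1 + \sigma_0)$ with each class standard deviation
floored at $\max(0.2\,|\mu|,\ 0.2)$. The flooring constants follow the
convention of the widely used desktop implementation and are exposed in code
rather than user-facing options. Ties are broken by gene symbol so rankings
are deterministic.

The pre-ranked mode accepts any ranked list; `preranked_statistic()`
implements the log-max-p statistic for combining two comparisons of the same
genes, $\log_{10} \max(p_a, p_b)$, with the most extreme negative scores
(significant in both comparisons) at the bottom of the descending list. The
statistic is agnostic about whether the caller supplies one-sided or
two-sided p-values; that choice belongs to the upstream differential test
and both are accepted.

### Permutation nulls and the p-value rule

Phenotype mode permutes class labels and recomputes the full ranking per
permutation; gene mode permutes set membership over the universe. With $b$
of $n$ permutations reaching $|ES|$ at least as large as observed, the
reported p-value is

$$p = \frac{b + 1}{n + 1}.$$

Counting the observed value into both numerator and denominator keeps
p-values strictly positive, and comparing magnitudes over *all* permutations
gives every set the same $1/(n+1)$ granularity and makes the null
distribution exactly uniform on that grid (the observed score is exchangeable
with the permuted ones). We deliberately did not condition the count on the
observed ES sign: conditioning only the numerator makes null p-values pile up
below 0.5, while conditioning both sides gives different sets different
denominators, so "which set has the smallest p" stops being well-defined.
The ES sign still reports the direction of enrichment.

Reproducibility: phenotype permutations are drawn once from the master seed
before iterating over sets, and gene-mode permutations use a per-term seed
derived by hashing the term accession into the master seed. Results are
therefore bit-identical across reruns and independent of set iteration
order.

## Collection comparison

`classify_sets()` partitions the union of terms by whether each meets the
size window under the augmented collection, the baseline, or both; terms
failing both are dropped. `tally_significance()` counts strictly
(`p < alpha`, so a p-value equal to the threshold does not count) and rounds
percentages half-up — `round_half_up(3.125, 2)` is 3.13 — because that is
the convention that reproduces published summary tables digit-for-digit;
ties-to-even rounding does not. One published percentage cell (16/55 printed
as 29.10) is not reproducible under any standard rounding and recomputes to
29.09; the package reports the recomputed value.

`fisher_one_sided()` delegates to the exact hypergeometric test in
`stats::fisher.test()` and is verified in the tests against a brute-force
tail summation over all 2×2 tables with margins up to 60.

Newly significant accounting treats a term absent from an analysis as not
significant there, so a set that only exists (within bounds) under the
augmented collection and reaches `p < alpha` counts as newly significant.
This is the only rule under which unique and common sets combine into a
single gained/lost ledger.

## Synthetic data generators

The generators exist so the full pipeline is testable with no downloads, and
they are first-class, tested code. Design choices:

* `simulate_ontology()` draws parents only from earlier-indexed terms, so
  acyclicity and developmental-subtree membership are exact bookkeeping, not
  post-hoc traversals. Edge types are is_a/part_of at 70/30, roughly the
  proportion seen in the biological-process branch of real releases.
* `simulate_corpus()` concentrates mouse annotations on developmental terms
  (probability 0.7) and human annotations away from them (0.3), emulating the
  premise that makes transfer worthwhile: mouse developmental annotation is
  rich where human annotation is sparse. The evidence mix spans experimental,
  computational and statement codes so every policy branch is exercised, and
  5% of records carry NOT qualifiers. Its ground-truth sidecar — the exact
  (human symbol, term) pairs a correct transfer must produce — is derived
  from the generator's own bookkeeping, never from the package's ontology
  queries, so end-to-end tests assert exact set equality.
* `simulate_expression()` plants differential signal by shifting the class-1
  mean of every member gene of the planted sets by `effect_size` noise
  standard deviations over i.i.d. Gaussian noise.

What the generators do *not* emulate: array-platform probe structure,
normalization artifacts, correlated background expression, and realistic GO
topology (term fan-out and depth distributions). Passing tests on this
synthetic data therefore demonstrate algorithmic correctness — exact
recovery of the constructed ground truth and calibrated permutation
p-values — not performance on real microarray corpora.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at deliberately compact
scales chosen to exercise every code path while keeping the suite quick:
ontologies of 30–200 terms, corpora of 200–1000 annotations, expression
matrices around 1000 genes × 20 samples, 200–500 permutations, and 50
replicates for the power check (planted 20-gene set, effect 1.0 sd, 10+10
samples — recovered as p-minimal in ≥90% of replicates, in practice all 50).
Statistical assertions use fixed seeds; the null-uniformity check uses a
Kolmogorov–Smirnov test at α = 0.01 on one seeded collection run, since
p-values of overlapping sets sharing one permutation stream are correlated
and the KS sampling distribution only approximately applies.

Degenerate inputs are handled explicitly: empty collections and empty
comparisons produce empty reports with `NA` percentages; a gene set with no
genes in the ranked list is an error (its ES is undefined); zero-total
Fisher margins are errors; `n_permutations = 1` is legal and forces
p ∈ {0.5, 1}.

## Known limitations

* One-to-one orthology discards informative many-to-many homology, and
  developmental stages are not aligned between species; both are inherent to
  the transfer design, which trades recall for precision.
* No FDR or normalized enrichment scores are reported: the comparison
  framework analyzes raw p-values because false-discovery rates are not
  comparable between collections of different sizes and overlap structure.
* The GAF dialect is 2.0 (17 columns); GPAD and GAF 2.2 are out of scope.
* Cross-ontology axioms (`intersection_of`, OWL imports) are not parsed.
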