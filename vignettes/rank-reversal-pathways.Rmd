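---
title: "Detecting disrupted pathways from within-sample expression orderings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting disrupted pathways from within-sample expression orderings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reopairs)
library(dplyr)
```

## The problem and the model

Case/control comparison of transcriptomes usually compares quantitative
expression levels, which makes it hostage to batch effects and
between-sample normalization: samples measured by different labs,
platforms or batches are not directly comparable, and many disease
studies (brain tumors are the canonical example) contain few or no
normal controls of their own. `reopairs` sidesteps the problem by using
only the *within-sample relative ordering* of gene pairs. For genes
$i, j$ with values $(G_i, G_j)$ in one sample, the ordering
$R_{ij}$ is 1 if $G_i > G_j$ and 0 if $G_i < G_j$; exactly tied values
exclude the pair from that sample. Any strictly increasing per-sample
transformation — log, affine rescaling, quantile shifts applied to a
whole sample — leaves every $R_{ij}$ unchanged, which is precisely the
kind of distortion batch effects produce. Case samples from one
experiment can therefore be combined with control samples from another
without any cross-normalization (`merge_datasets()`).

The analysis has three stages.

**1. Differentially ranked (DR) gene pairs.** For every unordered pair
of background genes, count cases with $G_i > G_j$ ($n_1$) and
$G_i < G_j$ ($n_2$), and likewise $m_1, m_2$ among controls. The null
hypothesis of no association between ordering and phenotype is tested
with Fisher's exact test on $[[n_1, n_2], [m_1, m_2]]$; p-values are
Benjamini–Hochberg adjusted across all tested pairs, and pairs with
adjusted $p < 0.05$ are DR pairs. Each DR pair carries a direction:
Pattern 1 when the case odds of the $G_i > G_j$ ordering exceed the
control odds ($n_1/n_2 > m_1/m_2$, evaluated as the cross-product
comparison $n_1 m_2$ vs $n_2 m_1$ so zero cells need no special
handling), Pattern 2 otherwise.

**2. Reproducibility of two DR lists.** Two analyses of the same
disease (different cohorts, platforms, or borrowed controls) are
compared on their common pairs. Among the $M$ pairs significant in
both lists with an unambiguous direction, $M_1$ share the same Pattern;
the concordance ratio is $M_1/M$, and the probability of at least $M_1$
concordant pairs by chance is the exact binomial tail

$$P = \sum_{i=M_1}^{M} \binom{M}{i} p_0^i (1 - p_0)^{M - i},
\qquad p_0 = 0.5,$$

since a random pair falls in one of two mutually exclusive directions.

**3. Pathway enrichment over gene pairs.** With $N$ background genes
there are $n = N(N-1)/2$ background pairs; a pathway with $g$
background genes contributes $m = g(g-1)/2$ of them. If $k$ of the $n$
pairs are DR and $x$ of those lie (both genes) in the pathway, the
enrichment probability is the cumulative hypergeometric tail

$$P = 1 - \sum_{i=0}^{x-1}
\frac{\binom{m}{i}\binom{n-m}{k-i}}{\binom{n}{k}},$$

adjusted across all pathways (BH) with significance at FDR < 0.05.
Because a single strongly dysregulated gene reverses its ordering
against many partners at once, a pathway can be significantly enriched
in DR pairs even when almost none of its genes pass a conventional
differential-expression test — this is what makes the pair-level view
useful on weak-signal data.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `fdr` / `fdr_pairs` | 0.05 | BH threshold for calling a pair DR |
| `fdr_pathways` | 0.05 | BH threshold for calling a pathway significant |
| `alternative` | `two.sided` | Sidedness of the Fisher test; two-sided is the natural reading of "no association", one-sided tails are available for directed questions |
| `p0` | 0.5 | Null concordance probability; 0.5 follows from the two exclusive directions |
| `block_size` | 1024 | Genes per streaming block in pair counting; affects memory, never results |
| `min_shared_genes` | 1000 | Floor on the gene-id intersection when merging matrices from two files; far fewer shared ids almost always means mismatched identifier spaces |

The unit of all expression inputs is irrelevant by construction: only
within-sample orderings enter the statistics.

## Design choices

Several points are genuinely open in a pair-ordering analysis; the
package resolves them as follows.

* **Background-first analysis.** The background is the set of measured
  genes annotated in at least one set of the collection, and pair
  counting is restricted to it from the start. Testing unannotated
  genes' pairs would enlarge the BH family with pairs that can never
  contribute to enrichment, costing power for nothing.
* **Canonical pair keys.** Pairs are keyed $(i, j)$ with $i < j$ in
  sorted gene-id order, so tables from different runs and datasets join
  without remapping. The orientation of the key interacts with the
  Pattern label: both tables in a concordance comparison must have been
  computed with the same case/control orientation (swapping the labels
  swaps Pattern 1 and Pattern 2 — a property the tests assert).
* **Ties.** Exact equality of two values in a sample excludes the pair
  from that sample's counts, so $n_1 + n_2 \le n$. No epsilon is
  applied; on continuous expression scales ties are rare and
  intentional (e.g. zero-inflated data), and an epsilon would make
  results depend on the measurement unit.
* **All-tie pairs.** A pair tied in every sample of a phenotype has an
  empty margin and no defined test; such pairs are skipped and counted
  in the run summary rather than treated as errors.
* **Pattern ties.** Equal cross-products give an `ambiguous` label.
  Ambiguous pairs stay in the DR table (they are significant) but are
  excluded from concordance counting, where $p_0 = 0.5$ presumes
  exactly two outcomes.
* **Pair membership for enrichment.** $x$ counts pairs with *both*
  genes in the pathway — the only reading consistent with
  $m = g(g-1)/2$ pathway pairs. Pathways with fewer than two background
  genes define no pairs and are excluded; pathways with $x = 0$ are
  still tested, keeping the BH family fixed a priori.
* **Duplicate gene ids** in an expression file are collapsed to the row
  with the largest mean across samples (the usual probe-collapse
  convention); rows with missing values are dropped. Both are warned
  about, and id matching is exact, case-sensitive string equality.

## Numerical implementation

The scale-critical step is the Fisher test: a genome-scale background
(say 8,000 genes) defines ~32 million 2×2 tables. The package batches
them: tables are grouped by their margin triple (row totals and first
column total), each distinct triple's hypergeometric support is
enumerated once with `dhyper`, and every member table's two-sided
p-value is read off a sorted cumulative mass (point probabilities no
larger than the observed one, with the conventional $1 + 10^{-7}$
relative guard). With fixed sample sizes the number of distinct margin
triples is tiny compared to the number of pairs, so the cost is
effectively the counting, not the testing. The result matches
`stats::fisher.test` exactly; tests verify agreement with brute-force
margin enumeration at $10^{-12}$ relative tolerance. Pair counting
itself streams over gene blocks (`block_size`), keeping peak memory
proportional to the block, never to the pair count, and results are
bit-identical for any block size.

The binomial and hypergeometric tails are computed through the exact
survival functions `pbinom` and `phyper` (never a normal
approximation), which remain accurate for tens of millions of pairs.
BH adjustment is `p.adjust(method = "BH")` behind input validation.
Expression TSVs are parsed with `strtod` semantics and written with 17
significant digits, so a write/read round trip reproduces doubles
bit-exactly; result files carry a provenance comment (version,
parameters, input hashes, deliberately no timestamp) so identical runs
are byte-identical.

## What the simulator emulates — and what it does not

`simulation_spec()` / `simulate_two_phenotype()` generate the
two-phenotype structure the detector targets: per-gene baseline levels
(log2-like scale, evenly spread over 4–12 by default, shuffled across
gene ids), i.i.d. Gaussian within-sample noise (`noise_sd`, default
0.5), and a planted set of gene pairs whose baseline ordering is
reversed in cases, with the reversed means pushed apart to
`effect_size` (default 2) times their original gap. Planted pairs are
disjoint in genes and, unless given explicitly, drawn among pairs whose
baselines differ by at least one log2 unit: a reversal between genes of
near-identical baseline is unresolvable at realistic noise and would
be a meaningless ground truth. Defaults of 30 cases and 30 controls
mirror a moderately sized cohort study. The `spec_frozen` element
returned by the simulator fixes the drawn baselines and planted pairs,
so changing only its seed yields an independent replicate of the same
generative model — the device used for replication and concordance
analyses.

The simulator deliberately does *not* model probe-level artifacts,
RNA-seq library-size or count noise, correlated gene modules, or real
batch structure. Since the method consumes only within-sample
orderings, the noise family only needs to perturb orderings, and
monotone-transform invariance is tested directly rather than simulated.
Consequently, passing tests demonstrate the statistical machinery and
its operating characteristics under clean reversal signal; they do not
certify performance on any particular real platform, and
population-level confounders (ethnicity, sex composition differing
between cohorts) can contribute disease-irrelevant DR pairs that no
within-sample statistic can remove.

## Operating characteristics checked by the test suite

The suite exercises the pipeline at sizes chosen to run comfortably on
a laptop while leaving no asymptotic behaviour untested: 300 genes
(44,850 pairs) with 30 + 30 samples for the statistical checks, smaller
fixtures for the exact oracles. At those sizes the tests verify that
(i) 50 null simulations produce essentially no DR calls (BH control,
with Fisher's discreteness making calls conservative), and near-zero
significant pathways; (ii) 50 planted reversals are recovered with the
correct Pattern at ≥ 95% averaged over 20 seeds; (iii) two replicates
of the same generative model give a concordance ratio at or near 1;
and (iv) shuffling phenotype labels on planted-signal data collapses
the significant-pathway count. The acceptance script
(`scripts/acceptance.R`) recomputes the pathway pair-counting reference
value (a 24-gene pathway forms 276 pairs) through the full
simulate → background → detect → enrich path.

## Known limitations

* Power tracks sample size sharply; with very few samples per group the
  discrete Fisher p-values cannot reach genome-wide significance at
  all. At least ~10 samples per group is a realistic floor for
  pair-level discovery.
* The binomial concordance test treats overlapped pairs as independent;
  pairs sharing a gene are not independent, so its p-value is a
  calibrated summary rather than an exact error rate (its ratio is the
  quantity to interpret).
* The hypergeometric enrichment model likewise treats DR pairs as
  exchangeable among background pairs; a single hub gene can dominate
  $x$ for its pathways. Inspecting per-gene pair frequencies in the DR
  table (`dplyr::count(tidy(dr), gene_i)` and `gene_j`) is the
  recommended diagnostic.
* Only flat gene-set collections are supported (GMT); ontology
  structure is ignored by design.
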