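---
title: "Signature-reversal connectivity mapping for diet and disease: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature-reversal connectivity mapping for diet and disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutriconnect)
```

# The model

`nutriconnect` rests on one premise: a disease state that manifests as a
genome-wide expression signature can be countered by an intervention whose
own signature reverses it. The pipeline quantifies this premise in four
complementary spaces:

1. **Signature space** — a bidirectional Kolmogorov–Smirnov enrichment score
   (ES) asks whether a food's up-regulated genes concentrate at the bottom
   of a disease's fold-change-ranked gene list and its down-regulated genes
   at the top (reversal, ES < 0), or the opposite (mimicry, ES > 0).
2. **Pathway space** — hypergeometric over-representation of each entity's
   differential genes, aggregated into per-(disease class × entity class)
   proportion scores and decomposed by PCA, separates the mechanisms by
   which diets and drugs act.
3. **Network space** — the closest-distance proximity of an entity's
   differential genes to a disease's gene module on the interactome,
   z-scored against degree-matched random sets, asks whether the
   intervention acts in the disease's network neighbourhood.
4. **Combination space** — directional-overlap, correlation and
   rank-aggregation scores over pairs of foods predict synergistic
   combinations, evaluated against a literature-reference-count gold
   standard.

Every quantitative claim the package makes about these statistics is backed
by a test against an independent oracle (brute-force enumeration, closed
form, or planted synthetic truth); this vignette records the modeling
assumptions and the choices made where the design was genuinely open.

# Differential expression by rank product

Fold change is the **unpaired difference of arm means on the log2 scale**;
case/control arms of curated intervention datasets are typically unpaired,
and the synthetic generator produces unpaired arms. Per dataset, genes are
ranked by fold change (rank 1 = most extreme in the queried direction,
average ranks on ties) and a gene's statistic is the geometric mean of its
ranks over the `k_g` datasets that measured it. Genes present in fewer than
half the datasets are excluded: with cross-platform unions, a gene observed
once among five datasets carries too little replication for a meta-analytic
rank statistic.

Significance is a permutation **pfp** (proportion of false prediction): the
null pools `n_perm` independent permutations of each dataset's observed rank
vector, `p_g = (#{null RP ≤ RP_g} + 1)/(n_genes·n_perm + 1)`, and
`pfp_g = p_g · n_genes / rank(RP_g)`. Defaults: 200 permutations in
`rp_significance()` (100 in the pipeline driver) — the per-gene null pool is
`n_genes`-fold larger than a per-pair permutation null, so modest draw
counts already give fine resolution. Both directions use the same seed: the
null pool depends only on the rank multiset, so swapping the case/control
labels swaps the up/down calls exactly — a symmetry the tests assert.

A gene significant in both directions (possible with tied, heavily
discretized ranks) is assigned to the direction with the smaller pfp,
keeping the up/down sets disjoint as the ES requires. The ranked list is
ordered by combined log fold change with a deterministic secondary sort on
gene identifier.

Rank products reward *consistency* across replicates, not magnitude: a
modest but reproducible shift outranks a large but irreproducible one. The
flip side, visible in the tests, is that with only one or two datasets and
heavy ties the pfp is conservative by construction.

# Preprocessing rules

Probes mapping to multiple gene identifiers are removed, as are probes with
missing values in **more than** 20% of samples — the boundary case (exactly
20%) is retained, reading the rule as a strict inequality. Probes of one
gene are averaged per sample, ignoring missing entries; any cell still
missing afterwards is imputed with the gene's row mean, because the rank
statistics need complete columns. Model-organism genes are relabeled to
human orthologs; genes without an ortholog are dropped and many-to-one
mappings are averaged after relabeling, consistent with the probe rule. The
imputation and many-to-one policies are this package's choices — both are
the simplest rules compatible with the downstream rank machinery.

# The enrichment score

The tag statistic is the unweighted two-sided KS statistic of
connectivity-mapping tradition: with tag positions `pos(1..t)` ascending in
a list of length `n`, `a = max_j(j/t − pos(j)/n)`,
`b = max_j(pos(j)/n − (j−1)/t)`, score `a` if `a ≥ b` else `−b`. A tag set
covering the entire list carries no positional information and scores 0 by
an explicit degenerate-case rule. Expression magnitudes never enter — only
positions — so the score is invariant to any monotone transform of the
reference profile.

The directional ES combines the up- and down-tag scores with the
**same-sign-zero** rule (a signature whose halves drift the same way is not
discordantly placed; score 0), else `(ks_up − ks_down)/2`. The pair ES is
the arithmetic mean of the two directions — query tags in the reference
list and reference tags in the query list — making the score symmetric in
its arguments up to each entity's own tag sets.

**Tag-set size** is dynamic: the significant DE genes per direction, ordered
by absolute combined fold change, capped at 250 per direction (the usual
connectivity-mapping scale; an uncapped 2,000-gene tag set dilutes the
statistic), with a minimum of 5 per direction below which a pair is left
unscored rather than scored noisily.

Significance is a **two-sided** permutation test: null queries redraw
up/down sets of the observed sizes uniformly (disjointly) from the reference
list, both directions, averaged identically; `p = (#{|ES_null| ≥ |ES_obs|} +
1)/(n_perm + 1)` with ties counted as exceeding. BH-FDR is applied across
each query-entity class (foods and drugs separately): the two batches are
separate experiments with different signature quality, so pooling them would
let one class's signal dilute the other's correction. Class assignment
follows the sign convention: anti-correlated requires ES < 0 and FDR <
0.05.

For disease clustering, ES profiles across drugs use `1 − Pearson` as the
distance with average-linkage agglomeration; missing entries are imputed as
0 (the null score) for clustering only, and a zero-variance profile is
pushed to the maximal distance 2 rather than propagating an undefined
correlation. Multiscale-bootstrap support values are intentionally out of
scope; the dendrogram is serialized as Newick via `ape`.

# Pathway space

Over-representation is the one-sided hypergeometric upper tail — the
standard enrichment test — with the **universe defined as the genes of the
entity's ranked list**, since that is the population from which DE genes
were drawn. Only anti-correlated pairs enter the score matrix; each
(disease class × diet/drug) group scores each pathway by the proportion of
its entities enriched for it, which removes group-size bias. PCA centers
columns but does **not** scale them: the entries are already commensurable
proportions, and unit-variance scaling would inflate rarely-enriched
pathways. A variable's "contribution" is its squared loading summed over
PC1–PC2, reported for the top 30.

# Network proximity

The proximity measure is the *closest* variant: the average over the
entity's DE genes (union of significant up and down sets, uncapped —
network neighbourhood membership does not benefit from fold-change capping)
of the hop distance to the nearest disease gene, on the largest connected
component. The null replaces **both** sets with degree-matched random sets:
degree bins are built by merging adjacent degrees until each bin holds ≥
100 nodes (single-bin fallback with a warning on small graphs), and sampling
is without replacement within bins; 1,000 draws by default. `Z_c < 0` is
proximal; the boundary `Z_c = 0` is labeled distant, reading the proximal
criterion as a strict inequality. A degenerate null (`σ = 0`) flags the
result rather than dividing by zero.

# Chemical similarity

Fingerprints are circular Morgan fingerprints of radius 2 (ECFP4), computed
through the OpenBabel backend (`ChemmineR`/`ChemmineOB`), hashed to the
backend's native 4,096 bits, binary. The Tanimoto coefficient is computed by
this package (`|a∩b|/|a∪b|`; two empty fingerprints score 0 with a flag).
Food–drug pairs are retained when **any** compound pair reaches Tanimoto ≥
0.4, evaluated at the (food, drug) level regardless of compound
multiplicity. The shared-disease comparison uses the normal-approximation
Wilcoxon rank-sum test, since shared-disease counts are small integers with
heavy ties that preclude the exact distribution.

# Synergy

Core genes are those significantly DE in at least one food of a pair. The
Rank 2 score `(concordant − discordant)/|core|` normalizes by the core size
so scores are comparable across pairs. Its null **conditions on the DE
sets** and permutes only each food's direction calls across its own DE
genes: the question is whether the *directional agreement* on shared genes
exceeds chance, given which genes responded. A pair is called synergistic
when the score is positive and the upper-tail add-one permutation p is
below 0.05. Rank 9 aggregates expression correlation, pathway-set Jaccard
and function-set Jaccard by mean rank (Borda) — transparent, and exactly
preserving unanimity. Recovery for the score-only methods (Rank 4, Rank 9)
is evaluated among their top-k pairs with k matched to the number of Rank 2
calls, so the three methods are compared on equal footing.

The gold standard reads the reference-count criterion as the **joint sum**
over shared diseases of both foods' counts, strictly greater than 10; the
per-food alternative reading is documented here as rejected because the
criterion describes the pair's combined literature support.

# What the generator emulates — and what it does not

The generator plants, per study: a preferential-attachment interactome
(heavy-tailed degrees, like real PPI networks) whose nodes are genes;
connected disease modules grown by seeded random expansion; disease
signatures = module genes plus an equal number of off-module genes with
random directions; food/drug signatures that flip a `reversal_fraction`
share of one disease signature (anti-correlated), copy a share
(correlated), or split one disease's reversal across two foods with partial
overlap (synergy: each partner covers `max(0.6, reversal_fraction)` of the
signature, so each is anti-correlated alone while the union covers it
fully); unrelated DE genes (`extra_de_fraction` of the universe) on every
entity; pathway collections seeded so ≥ 60% of each module appears in one
pathway; probe maps with 1–3 probes per gene and a configurable ambiguous
share; an ortholog table with configurable dropout; compound tables drawn
from a built-in library of ~30 valid SMILES with designated identical
food/drug compounds; and a reference table whose gold pairs are exactly the
planted synergy pairs (shared-disease counts 6 + 6 = 12 > 10; all other
associations get count 3).

Ground-truth pair labels are *recomputed from the realized signatures* by a
fixed rule — anti-correlated when opposite-direction shared genes outnumber
same-direction ones and reach 25% of the disease signature, symmetrically
for correlated — so the labels are exactly reproducible from the truth
object, and a zero reversal fraction yields no anti-correlated labels at
all.

Expression data follow a two-group Gaussian shift on the log2 scale:
control values i.i.d. `N(baseline_mean, baseline_sd²)` per gene, case
values adding `±effect_size` on signature genes plus `N(0, noise_sd²)`
case-arm noise. Defaults — 5 samples per arm, 3 datasets per entity,
`effect_size = 1.5`, `noise_sd = 0.5`, `baseline_sd = 0.5` (a typical
within-arm log2 spread for array data), `reversal_fraction = 0.8` — are the
study conditions under which the package validates itself: an
effect-to-noise ratio of 3 with modest replication, deliberately not a
trivially separable regime.

The generator does **not** emulate: platform batch effects or
array-specific intensity distributions (no RMA — the pipeline consumes
normalized matrices); gene–gene correlation structure; paired designs;
species-specific expression divergence beyond ortholog dropout; or dose
dependence. Consequently, passing tests demonstrate that the *algorithms*
behave as specified under a clean generative model — they do not certify
performance on real cross-platform collections, where violations of these
assumptions (correlated genes, batch structure, unmodeled confounding) will
reduce power in ways the synthetic study cannot reveal.

# Numerical choices and degenerate inputs

* Geometric means run through `exp(mean(log(·)))`; oracle comparisons use a
  `1e-9` tie tolerance at permutation-count boundaries.
* Ranks average over ties everywhere; ordered outputs break remaining ties
  by identifier so runs are byte-reproducible.
* All randomness derives from one master seed through fixed per-stage
  offsets (kept below 2³¹), so stages are independently re-runnable and a
  repeated pipeline run is byte-identical — asserted at file level in the
  test suite.
* Empty DE sets, unscorable pairs, empty cores, zero-variance vectors and
  degenerate nulls yield flagged `NA`s, never silent zeros; empty probe
  output after filtering is a warning, not an error.
* The interactome generator rejects `n_nodes ≤ edges_per_new_node + 1`,
  where growth would force a complete graph with no attachment structure.

# Validation scale

The test suite validates at deliberately small, fast scales chosen as the
package's own validation design: 1,000-gene universes for calibration (200
null signature pairs at 1,000 permutations each), 20 planted reversal pairs
for recovery, 50 random graphs (≤ 60 nodes) against a brute-force BFS
oracle plus 50 seeded in-module proximity simulations, 20 seeded synergy
studies, exhaustive rank-product enumeration at 5 genes × 2 datasets
((5!)² rank assignments), and hypergeometric enumeration for all universes
up to 25 genes. The analysis scripts run one full study at the default
conditions (master seed 2026).

# Known limitations

* The ES is the unweighted tag statistic; a weighted (GSEA-style) variant
  would respond to magnitude as well as position and is out of scope.
* pfp is conservative under heavy rank ties (few datasets, discrete ranks).
* Degree-matched sampling without replacement can exhaust small bins on
  small graphs; the single-bin fallback weakens degree matching there.
* The Rank 9 aggregation is plain Borda; more elaborate rank-aggregation
  schemes (e.g. Markov-chain methods) were not implemented.
* Proximity cannot judge the *direction* of an effect — a harmful
  intervention can be exactly as proximal as a therapeutic one; it
  complements, never replaces, the signed ES.
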