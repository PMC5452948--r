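---
title: "Modeling promoter architecture from structural motif features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling promoter architecture from structural motif features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promoarch)
```

## The problem

Genes that are expressed together — in the same developmental stage, tissue
or condition — tend to share regulatory logic in their promoters: not just
the *identity* of transcription factor binding motifs, but their
*arrangement*. Two promoters may contain the same motifs yet behave
differently depending on where the motifs sit relative to the transcription
start site (TSS), on which strand, how far apart, and in what order.
`promoarch` models this combinatorial arrangement. Given a cohort of
co-expressed genes, a control cohort of non-expressed genes, and a
collection of motif matrices, it learns a small set of *structural
features* whose weighted occurrence counts discriminate the co-expressed
promoters, and then scores any promoter for the same architecture.

The promoter is taken as the window from 1.5 kb upstream to 500 bp
downstream of the TSS, always read in gene orientation. Internally
coordinates are 0-based and half-open: sequence index `p` corresponds to
TSS-relative position `r = p - 1500`, so index 1500 is the TSS base itself.

## From sequences to occurrences

Motifs are position weight matrices (PWMs) over A/C/G/T. A bespoke log-odds
scanner slides each PWM along both strands of each promoter and reports
every window whose score (in bits, against a configurable background) is at
least a fraction of the maximum attainable score for that matrix. The
reference workflow delegates site finding to external discovery tools and
never states a match threshold, so the relative threshold is an explicit
parameter; 0.8 is the default. Minus-strand hits are reported in gene
orientation coordinates. `N` bases score `-Inf` and can never match.

Redundant matrices in a motif collection are removed by a matrix-distance
test: the distance between two PWMs is the minimum over all ungapped
alignments (overlap of at least one column, both orientations) of the mean
per-column Euclidean distance; significance comes from an empirical null of
random PWM pairs of the same lengths with Dirichlet(1,1,1,1) columns. For
pairs with p <= 0.001 the matrix with lower information content is dropped.
One consequence of minimising over single-column overlaps is that two
*deterministic* matrices sharing any one letter anywhere are at distance 0
and always test as similar; the pipeline therefore skips deduplication for
synthetic consensus-word motif sets, which are distinct by construction,
and applies it to file-supplied collections, where matrices come from motif
discovery and databases and are genuinely redundant.

Motif-level enrichment uses an overrepresentation index (ORI): the ratio of
occurrences per kilobase in the target promoters versus background
(non-promoter) regions, multiplied by the fraction of target promoters
containing at least one occurrence. Because the exact index is less
important than its calibration, significance is assessed by drawing random
promoter subsets of the same size from the whole promoter universe and
recomputing the ORI for each; the p-value is the fraction of random values
strictly exceeding the observed one. Motifs with p < 0.01 enter the feature
stage. The default is 10,000 permutations; the full-scale analysis uses one
million and is purely a budget question.

## Six classes of structural features

Every feature is a binary predicate on a promoter's occurrence set, written
in a canonical string grammar:

| class | example | meaning |
|---|---|---|
| presence | `PRES:M` | M occurs anywhere, any strand |
| oriented presence | `PRESO:M:-` | M occurs on the minus strand |
| TSS-relative position | `POS:M:+:[-300,-200)` | a plus-strand M starts in that 100-bp window |
| pairwise distance | `PDIST:A(+)>B(+):[100,200)` | start-to-start separation of an A,B pair falls in the bin (A is the start point) |
| order | `ORDER:up:A(-)>B(+)` | upstream of the TSS, an A(-) occurrence precedes a B(+) occurrence |
| pair-to-TSS distance | `PTSS:A:B:[200,300)` | the closer motif of an A,B pair starts that far from the TSS |

Windows are 100 bp in steps of 100 bp: 20 position bins tile
`[-1500, +500)`, 20 separation bins cover `[0, 2000)`, and 15 bins cover
the pair-to-TSS distance (which cannot exceed 1500; the last bin is closed
there). An occurrence belongs to the bin containing its start (5' end in
gene orientation) — the windowing itself is from the reference procedure,
the anchoring of an occurrence to its start is a choice made here. Order
fixes each motif's orientation but compares positions only, separately for
the regions upstream and downstream of the TSS. Self-pairs (a motif with
itself) are enumerable in all pair classes, since repeated-motif
architectures occur in practice. Pair-to-TSS features are enumerated
strand-agnostically to keep the candidate space from tripling; oriented
spacing is already captured by the pairwise-distance class. For `m` motifs
the default enumeration yields `43m + 95 m(m+1)/2 + 8m^2` descriptors
(2,541 for six motifs).

Candidate features are detected in the promoters of the
*feature-computation* gene subset and its control half, giving a binary
promoters x features matrix (counts of qualifying occurrences or
occurrence pairs are kept alongside for the scoring scheme).

## The correlation filter

The candidate set is large and highly redundant, so it is pre-filtered with
a fast correlation-based filter (FCBF) built on symmetrical uncertainty

$$SU(X,Y) = \frac{2\,IG(X;Y)}{H(X)+H(Y)},$$

the mutual information normalised by the marginal entropies (bits;
`0 log 0 = 0`; SU is defined as 0 when either variable is constant).
Features are ranked by SU with the class label; a feature is discarded when
some higher-ranked retained feature predicts it at least as well as it
predicts the class (`SU(f', f) >= SU(f, class)`). The rank threshold
`delta` defaults to 0 — any positive class correlation admits a feature,
and redundancy removal does the real work. Ties in the ranking break by
canonical descriptor order so the result is independent of column order.
Constant columns are removed up front: they carry no information and would
otherwise survive on a technicality.

A deliberate consequence: when a planted positional feature and the plain
presence of the same motif are nearly identical columns, the filter keeps
exactly one representative of the group — whichever has the higher class
SU — not necessarily the most specific descriptor. Models should be read
at the level of these equivalence classes.

## Scoring: Kullback–Leibler feature weights

A promoter region's score is
$\mathrm{score} = \sum_i w_i n_i$, where $n_i$ counts the feature's
qualifying occurrences (occurrence *pairs* for pair features — the only
reading under which $n_i > 1$ is possible for them) and the weight is

$$w_i = \frac{\sum_j P(o_{ij})\, D_{KL}(C \mid o_{ij})}
            {-\sum_j P(o_{ij}) \log P(o_{ij})},\qquad
  D_{KL}(C \mid o_{ij}) = \sum_c P(c \mid o_{ij})
  \log\frac{P(c \mid o_{ij})}{P(c)}.$$

All probabilities are maximum-likelihood frequencies from the
feature-computation matrix, whose positive/control labels define the
classes; natural logarithms are used internally, though the ratio is
base-independent. Weights are deliberately *not* renormalised to sum to
one across features, so informative features keep large weights. A
perfectly separating feature on a balanced cohort has $w = 1$; a
class-independent feature has $w = 0$; a constant column leaves the
denominator at zero and the weight is defined as 0 and flagged.

## Feature-subset optimisation

Informative subsets of the filtered features are selected by a genetic
algorithm on the *model-construction* gene subset and its control half.
Each individual is a bit mask over the candidate features; a promoter is
predicted positive when it contains at least one selected feature, and
fitness is the F-score

$$F = \frac{2PR}{P+R}, \quad P = \frac{TP}{TP+FP}, \quad
  R = \frac{TP}{TP+FN}$$

of the resulting confusion counts (degenerate denominators give 0). The
population size equals the number of training promoters; evolution uses
uniform crossover, per-bit mutation at 0.05, tournament selection (k = 2 by
default, roulette available) and one elitist copy of the best-ever
individual. Initial masks are sparse (each bit Bernoulli 0.1), matching
the small informative sets the method is after. Three stopping rules run
in this order each generation: an iteration cap (10,000 by default), a
fitness threshold (stop once a solution reaches F >= 0.8), and a
score-separation criterion — stop when more than 50% of the positive
regions score above the 0.9 quantile of the control scores under the
weighted scoring scheme. Equal-fitness ties resolve toward fewer selected
features.

Model construction is wrapped in stratified fivefold cross-validation: the
GA trains on four folds, its best chromosome is evaluated on the held-out
fold, and the model's overall F-score is the mean of the five test
F-scores. The *consensus* feature set — the trained model — contains the
features present in at least four of the five fold-best masks, with
weights computed on the feature-computation matrix.

Two behaviours of this design are worth understanding before interpreting
consensus sets. First, the any-feature prediction rule means each
additional feature raises recall a little and can cost precision; when
individual features are already highly penetrant in the positive class,
small masks are F-optimal and the GA has no pressure to assemble the
complete architecture. Second, the F >= 0.8 stop halts the search as soon
as *any* adequate mask appears, so on strongly separable cohorts the five
folds can return different small masks and the 4-of-5 consensus may be
small or even empty (an empty consensus yields a degenerate model that
scores everything 0; the pipeline flags it rather than failing). Both
effects are inherent to the published fitness and stopping rules, not
implementation accidents; they mean the consensus is a *sufficient
discriminative summary*, not an inventory of every real feature.

## Validation

A trained model ranks an arbitrary promoter universe by score (training
genes excluded, ties broken by gene id for reproducibility). The top 100
genes are compared against an independently defined expressed set with a
hypergeometric upper-tail test, and p-values across models are adjusted
with Benjamini–Hochberg FDR (`stats::p.adjust(method = "fdr")`, the same
procedure the reference analysis calls). Model significance is also
assessed by label shuffling: the any-feature F-score is recomputed under
random label permutations and the p-value is the fraction of shuffled
scores strictly above the observed one. Finally, predicted occurrences can
be intersected with annotated regulatory intervals under a strict
containment rule — an occurrence counts only when it lies entirely inside
an interval (GenomicRanges `findOverlaps(type = "within")`).

## The synthetic cohort generator

Real inputs (RNA-seq derived gene sets, a genome assembly, curated motif
databases) are deliberately out of scope; a generator produces cohorts
with known ground truth instead. Background sequences are 0-order i.i.d.
at a configurable GC content (default 0.42, fly-like). Each planted
feature descriptor is instantiated per promoter with its class penetrance:
motif instances are sampled from the PWMs and written at positions,
strands and separations satisfying the descriptor, uniformly over
satisfying placements, with rejection against previously planted instances
so plants never overwrite each other. Control promoters receive the same
features at their (lower) control penetrance, emulating the imperfect
class separation of real cohorts. A truth table records every planted
instance.

The default study conditions — also what `scripts/acceptance.R` runs — are
200 positive + 200 control promoters, six 8-bp consensus motifs at
sharpness 1, and four planted features (one each from the position,
oriented-presence, pairwise-distance and order classes) at penetrance 0.9
versus 0.1, with an independent 150 + 350 promoter universe for
validation. Sharpness 1 makes planting penetrance and detection penetrance
coincide, so the class structure is exactly the nominal one; softer
matrices shift detection rates downward at any fixed scanner threshold and
would silently change the study conditions.

What the generator does *not* emulate: higher-order sequence composition,
repeats, CpG-like heterogeneity, correlated motif co-occurrence beyond the
planted features, or expression noise. Passing tests on synthetic cohorts
therefore demonstrate that the machinery — scanning, feature algebra,
filtering, optimisation, calibration — behaves as specified, not that the
biological signal in any particular real cohort is detectable.

## Numerical choices and conventions

* Coordinates 0-based half-open everywhere; promoter `[-1500, +500)`;
  minus-strand promoters reverse-complemented at extraction.
* Near-duplicate promoters (>60% similar) are pruned greedily by
  containment Jaccard of 12-mer *sets*, longest sequence first. Word sets
  of this length give ~0 similarity for unrelated 2-kb sequences, 1 for
  identical ones, and approximately the shared fraction for block
  overlaps; very short words would saturate (any two 2-kb sequences share
  essentially all 3-mers) and call everything similar.
* Gene-set split 40/20/40 (motif-prediction / feature-computation /
  model-construction) by largest-remainder rounding after a seeded
  shuffle; controls halved with the extra member going to the
  feature-computation half.
* All randomised steps (splits, GA, permutation tests, generator) take
  explicit seeds and restore the caller's RNG state; rerunning a pipeline
  configuration reproduces byte-identical model JSON.
* Default problem sizes in the examples and acceptance script (cohorts of
  hundreds of promoters, 10,000 permutations, GA capped as configured) are
  chosen so a complete run takes on the order of a minute on one core;
  every size is a configuration value, and the published full-scale
  settings (one million permutations) are reached by changing
  configuration only.

## Known limitations

* The ORI formula follows the density-ratio x containment form; the
  original index it stands in for is cited but not restated in the
  reference description. It is isolated in one function, and all
  downstream decisions depend only on the permutation p-value.
* The motif-distance null (Dirichlet columns) is a simplification of
  Tomtom-style nulls; only the similar / not-similar decision at
  p <= 0.001 feeds the workflow.
* Consensus sets identify equivalence classes of features, not unique
  descriptors (see the filter and GA sections); complete recovery of a
  redundantly planted architecture is not an optimum of the published
  fitness and should not be expected from any faithful implementation.
* Scanning is exhaustive per promoter and written for cohort-scale use
  (thousands of promoters), not whole-genome scans of large genomes.
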