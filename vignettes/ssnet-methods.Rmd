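---
title: "Single-source scoring and integration of functional networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-source scoring and integration of functional networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssnet)
```

## The problem

Functional interaction data are heterogeneous: large high-throughput (HTP)
screens carry substantial false-positive and false-negative rates, while
small targeted low-throughput (LTP) studies are far more reliable.
Probabilistic functional integrated networks (PFINs) deal with this by
scoring each dataset's quality and weighting its interactions accordingly,
so that noise is down-weighted rather than hand-curated away. The
traditional quality yardstick is an external Gold Standard — a pathway
database or an ontology — which introduces identifier mapping between
resources, redundancy between Gold Standard and scored data, bias toward
the Gold Standard's biological focus, and an outright gap for organisms
that have no curated Gold Standard at all. This package scores and
integrates from a single curated interaction database, using the database's
own LTP content as the Gold Standard.

## The procedure

**Partition.** Interaction records are grouped by publication. A study
whose unique, unordered, self-interaction-free pair count is at least the
threshold `T` (default 100) becomes one HTP evidence dataset, named
`[Author].[PubMed ID]`; all other records pool into the LTP data. Study
size is measured in unique pairs, not raw rows, because curation rows
duplicate pairs across experimental systems and orientations. A publication
contributing both physical and genetic rows is still one study. The
boundary is `size ≥ T → HTP`.

**Scoring.** For an evidence dataset $E$ and a Gold Standard with positive
pair set $P$ over universe $U$ (negatives implied: all other unordered
pairs over $U$), the log-likelihood score is

$$lls(E) = \ln \frac{P(L|E)\,/\,\lnot P(L|E)}{P(L)\,/\,\lnot P(L)}$$

computed from frequencies: the dataset's pairs are restricted to those with
both genes in $U$ (a pair with an unseen gene is not evidence either way),
and the observed odds of hitting a positive are compared with the prior
odds $|P| / \binom{|U|}{2} - |P|$ in natural-log units. Three rules govern
the edge cases:

* no positive overlap — the dataset cannot be scored and is discarded;
* finite score ≤ 0 — the dataset links pairs no better than chance and is
  discarded;
* no negative overlap (perfect overlap) — the score is infinite and is
  replaced by $\lceil \max h \rceil + 1$, one above the ceiling of the
  largest finite score $h$ in the same scoring batch, so it exceeds every
  real score. If a batch contains only infinite scores the replacement is
  1.0, a documented fallback.

**Two-stage single-source scoring.** Stage one scores every HTP study
against the pooled LTP pairs (`LTP_GS`). Stage two splits the LTP pool by
experimental type and scores each type against the pool of the remaining
types — leave-one-type-out, so no dataset is ever scored against data that
includes itself. Both stages are finalised as a single batch: the infinity
replacement sees one score set spanning HTP and LTP, keeping the two sides
comparable at integration time. At least two LTP types are required,
otherwise the leave-one-type-out Gold Standard is empty.

**Integration.** Each unordered pair observed in at least one scored
dataset becomes an edge. With its supporting scores sorted
$L_1 \ge \dots \ge L_n$, the weight is

$$WS = \sum_{i=1}^{n} \frac{L_i}{D^{(i-1)}}, \qquad D \ge 1 .$$

`D = 1` (the default) adds evidence with equal weight; as `D` grows the sum
approaches $L_1$ and corroborating evidence stops mattering. Ties among
scores are broken by dataset name only for the stored evidence list — the
weight is permutation-invariant. The same `D` applies to HTP-study and
LTP-type evidence, which are integrated in one step.

**Evaluation.** Function prediction uses the Maximum Weight rule: a
protein's score for a term is the weight of its heaviest edge to a
neighbour annotated with that term, zero if it has none. This graded score
reduces to "adopt the top edge's annotation" at any decision threshold, and
the target protein's own annotations are masked, which is exactly
leave-one-out validation of known annotations. Per term, ROC AUC $\theta$
is the tie-aware Wilcoxon statistic and its standard error the
Hanley–McNeil closed form

$$SE(W) = \sqrt{\frac{\theta(1-\theta) + (C_p-1)(Q_1-\theta^2) +
(C_n-1)(Q_2-\theta^2)}{C_p C_n}},
\quad Q_1 = \frac{\theta}{2-\theta},\; Q_2 = \frac{2\theta^2}{1+\theta}.$$

Terms are eligible when their genome-wide annotation count — measured on
the propagated, IEA-excluded annotation set, not just on network nodes —
lies in `[min_count, max_count]` (defaults 100–1000). Positives are network
nodes annotated to the term; negatives are network nodes with at least one
process annotation but not that term. Two networks are compared per term
with a two-sided z-test on $\Delta\theta$ using combined standard errors
($|\Delta\theta| > 1.96\sqrt{SE_a^2+SE_b^2}$).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `threshold` | 100 unique pairs | HTP/LTP study-size split |
| `D` | 1.0 | rank-decay of corroborating evidence |
| `min_count`, `max_count` | 100, 1000 | term eligibility window for evaluation |
| `exclude_iea` | `TRUE` | drop un-curated electronic annotations |
| `inflation` | 2.0 | MCL granularity (larger → more, smaller clusters) |

The threshold trades Gold Standard size against reliability: raising it
moves borderline studies into the Gold Standard; lowering it starves the
Gold Standard of coverage. `threshold_sweep()` reports pair/protein counts
and HTP–LTP overlap across candidate thresholds to make that choice
visible.

## Design choices where the design was open

* **Gene identity** is the systematic-name column of the interaction file;
  an optional two-column mapping table translates external identifiers.
  Whether scoring joins on systematic names or database-numeric identifiers
  is immaterial to the method, so both are supported through the table.
* **Self-interactions are removed** everywhere: every downstream construct
  (Gold Standard odds, guilt-by-association) is defined on pairs of
  distinct genes.
* **Negatives are implied**, never curated: $\lnot P$ counts the complete
  pair complement within the universe. No sampled negative set is used.
* **The threshold is applied after de-duplication** (unique pairs per
  publication), consistent with counting unique interactions everywhere
  else.
* **Annotation propagation** follows the true-path rule over `is_a` and
  `part_of` within `biological_process`; obsolete terms and NOT-qualified
  rows are dropped; rows naming unknown terms are skipped with a message; a
  cyclic ontology is a fatal error. IEA exclusion is applied for evaluation
  and is configurable for the GO-derived Gold Standards.
* **The genome-size denominator** for the fraction-mode GO Gold Standard
  (processes covering less than 10% of the genome) defaults to the number
  of genes with at least one process annotation, and is configurable — any
  fixed denominator only shifts the eligibility cut-off.
* **Evaluation negatives** are annotated network nodes lacking the term,
  not all genes in the genome: genes without any annotation are unknowns,
  not known negatives.
* **Hanley–McNeil variance**: the whole three-term numerator is divided by
  $C_p C_n$. The degenerate checks pin this down: $SE(1, \cdot, \cdot) = 0$
  and $SE(0.5, 1, 1) = 0.5$.
* **Power-law fit** is an ordinary least-squares regression of log
  frequency on log degree over non-zero-frequency degrees, reporting the
  correlation and $R^2$; no claim is made to replicate any particular GUI
  plugin's curve fitting.
* **MCL** is implemented natively on a dense column-stochastic matrix:
  self-loops at each node's maximum incident weight (standard
  regularisation), expansion by matrix squaring, inflation by entry-wise
  power with column renormalisation, pruning of entries below $10^{-5}$,
  convergence when the largest entry change falls below $10^{-6}$ or after
  100 iterations, clusters read as connected components of the limit
  matrix's support. Edge weights are used as similarities by default, with
  an unweighted option.

## The synthetic generator

`simulate_interactome()` writes a complete, parseable input set — a TAB3
interaction archive, GAF annotations, a small OBO ontology, a pathway
table — with planted ground truth. Genes partition into modules; each study
draws a fixed quota of unique within-module pairs (its true-positive
fraction of its size, drawn without replacement) and fills the rest with
unique cross-module noise pairs, so the emitted within-module fraction
equals the configured quality up to rounding. Each module maps to one
ontology term (under a two-branch ancestor DAG) and one pathway.

The reference conditions are 200 genes in 10 equal modules; three HTP
screens of 150–400 pairs at qualities 0.9, 0.5 and 0.1, spanning the range
from near-clean to mostly-noise screens; and 150 LTP studies of 5–40 pairs
at quality 0.95 across four experimental types. The LTP volume is chosen so
the pooled LTP data covers most of the within-module pair space — exactly
the data-accumulation premise that makes an internal Gold Standard viable;
with a sparse LTP pool the method degrades gracefully but its scores
compress toward zero.

What the generator does **not** emulate: scale-free degree structure,
correlated re-discovery of the same pairs across experimental types,
study-specific biases (bait selection, sticky proteins), curation errors
and retractions, and incomplete annotation. Passing tests on generated data
therefore demonstrate that the machinery recovers planted signal under
clean modular truth — not that any particular biological network will reach
the same AUCs.

On these conditions the expected qualitative behaviour, asserted by the
test suite, is: the HTP quality ordering is recovered on the raw
log-likelihood scale; the mostly-noise screen is discarded; and LTP type
scores sit in a high range overlapping the best HTP screen — above the
median HTP score, though not necessarily above every single HTP score,
since a 0.9-quality screen is nearly as clean as the 0.95-quality LTP data
and the leave-one-type-out Gold Standard is slightly smaller than the full
pool used for HTP scoring.

## Numerical notes and degenerate inputs

* All scores are natural-log units; no rounding is applied internally.
* A Gold Standard with no implied negatives (a single pair, or positives
  saturating the universe) makes the prior odds undefined and is rejected.
* `finalize_scores` on an all-discarded batch warns and returns an empty
  table; `ssnet()` then fails at integration, naming the stage.
* Path metrics of a single-node network are reported as not applicable;
  degree centralization needs at least three nodes.
* The power-law fit needs at least three distinct degrees, else `NA`.
* MCL non-convergence (rare; cap 100 iterations) warns and interprets the
  current matrix.

## Problem sizes

The test suite and the acceptance script run entirely on generated data at
desk scale: 60–200 genes, studies of 2–500 pairs, networks of up to ~2,200
edges, exhaustive oracle enumeration over 4–6 gene universes, 200-fold
permutation nulls, and 1,000-fold random checks of the integration algebra.
These sizes make every oracle comparison exact and the full suite fast while
exercising each code path; real BioGRID archives (hundreds of thousands of
records) stream through the same functions, with runtime dominated by the
per-type Gold Standard unions.

## Limitations

* The log-likelihood score assumes dataset errors are independent of the
  Gold Standard given the truth; with an internal Gold Standard the
  leave-one-study/leave-one-type construction enforces disjointness, but
  correlated experimental biases across types remain unmodelled.
* Integration treats datasets as independent lines of evidence; the
  rank-decay sum is a heuristic, not a posterior.
* Only the top-weight decision rule is implemented for evaluation;
  neighbour-voting and diffusion rules are out of scope.
* The method needs *enough* LTP volume: with very few LTP pairs most HTP
  datasets fail to overlap the Gold Standard and are discarded.
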