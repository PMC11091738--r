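---
title: "Mixed classification trees with relative-expression splits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed classification trees with relative-expression splits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retree)
```

## The model

`retree` induces a binary classification tree over a samples × attributes
table in which each internal node may carry one of three test families:

* a **C4.5-style univariate test** — `attribute >= t` for continuous
  attributes, `attribute == category` for nominal ones;
* a **Top-Scoring-Pair (TSP) test** — `attribute1 < attribute2`, a rank
  comparison of two features *within the same sample*. Because it only
  looks at the ordering of two measurements, it is invariant under any
  monotone per-sample transformation, which makes it attractive for
  expression data moved between platforms or normalisation pipelines;
* a **weighted TSP (WTSP) test** — `attribute1 < w * attribute2` with
  `w > 0`, which additionally detects *proportional* shifts between two
  features, not just ordering reversals.

A tree that mixes families is still a plain binary decision tree: an
instance satisfying the node's predicate goes to the left child,
otherwise right, and prediction is the label of the unique leaf reached.

All three families are ranked by one criterion, the **Gain Ratio**

$$GR = \frac{H(\text{parent}) - \tfrac{n_L}{n}H(\text{left}) - \tfrac{n_R}{n}H(\text{right})}
            {-\tfrac{n_L}{n}\log_2\tfrac{n_L}{n} - \tfrac{n_R}{n}\log_2\tfrac{n_R}{n}}$$

where $H$ is class entropy in bits. The denominator (split information)
penalises very uneven partitions; a split leaving one side empty has
split information 0 and is excluded everywhere as degenerate. The classic
TSP literature ranks pairs by a class-conditional score instead; here the
gain ratio is used uniformly for all three families so that candidates
from different families are directly comparable at a node.

## Search procedures

**Thresholds.** For a continuous attribute the candidate thresholds are
the midpoints between consecutive distinct sorted values present at the
node — the classical C4.5 candidate set, which contains an optimum
because the predicate only changes at observed values. Nominal
attributes contribute one binary equality test per category present
(multiway splits would contradict the binary tree structure).

**TSP.** All ordered pairs of continuous, non-ignored attributes are
scanned exhaustively. Both orders are scored: with tied values routing
right under the strict `<`, the two orders of a pair are not exact
complements.

**WTSP.** For each ordered pair the per-row ratios $r_i = v_1/v_2$ are
formed and candidate weights are taken at midpoints between consecutive
distinct sorted ratios — the exact analogue of threshold search in ratio
space. Since the predicate $v_1 < w\,v_2 \iff r < w$ changes only at
observed ratios, this finds the optimum over *all* real weights. Pairs
in which any row has $v_2 \le 0$ are skipped entirely: the method
targets expression-scale (non-negative) data and the ratio semantics are
otherwise undefined. The weight search makes WTSP markedly more
expensive than TSP — one threshold search per ordered pair.

Setting `max_pairs` in the configuration caps the pair scan via a
variance-ranked attribute prefilter (off by default); with hundreds of
thousands of features, prior feature selection is the better answer.

**Canonical tie-break.** Searches are fully deterministic: candidates
are ordered by higher gain ratio, then higher information gain, then
family (`c45` < `tsp` < `wtsp`), then lowest attribute indices, then
smaller threshold/weight, then earliest category. Gain-ratio and
info-gain comparisons treat differences of at most `1e-12` as ties —
without a tolerance the canonical choice between mathematically tied
candidates would depend on last-ulp floating-point noise. Midpoints are
guarded so that a midpoint that rounds onto the lower of two adjacent
values is replaced by the upper value, keeping the scored partition and
the routed partition identical.

## Induction and its stopping rules

Induction is top-down and greedy: the best split at the node is
installed and the rows are redirected to the children, breadth-first,
until a stopping rule fires. The rules are checked in a fixed order —
`min_size` (fewer than `2 * min_node_size` rows, so no legal pair of
children exists), `max_depth`, `entropy` (node entropy at or below
`entropy_threshold`), `budget` (`max_nodes` internal nodes already
created, counted in breadth-first creation order; remaining frontier
nodes become leaves), and `no_split` (no candidate has positive
information gain with both children holding at least `min_node_size`
rows). "Maximum tree size" is deliberately enforced both as a depth
limit and as a node budget; either can be disabled by setting it large.
`min_node_size` is enforced on children rather than on the parent, since
parent-only enforcement would permit empty children.

**No post-pruning is ever applied.** Pruning is an explicit user action
(`fold()`), which is the point of the interactive design: the analyst,
not a pruning heuristic, decides which subtrees are noise.

Defaults — `min_node_size = 5`, `max_depth = 10`, `max_nodes = 50`,
`entropy_threshold = 0` bits, `suggestion_k = 5`, `families = "c45"` —
are conventional decision-tree settings chosen once for this package;
with `entropy_threshold = 0` only pure nodes stop on entropy. The class
count is not restricted to two: entropy and gain ratio generalise, and
the tree remains binary in structure.

## Editing semantics

All edits are pure functions from tree to tree; the input tree is never
mutated, and every edit returns reports recomputed from scratch, so the
displayed statistics can never go stale.

* `fold()` collapses a subtree to a leaf labelled with the majority
  class of the training rows reaching it (ties break to the earliest
  class level, everywhere).
* `unfold_once()` expands a leaf by exactly one best split — useful to
  see how one split divides the data — optionally with a family override
  differing from the tree's configuration. It enforces split legality
  (positive gain, child sizes) but not the depth/entropy/budget rules:
  it is an explicit user request for one split.
* `unfold_all()` runs full recursive induction at the leaf, with depth
  counted from the root and the node budget counted tree-wide, so
  unfolding never exceeds `max_nodes`. Folding a subtree and unfolding
  it again under the same configuration restores it exactly (greedy
  induction is deterministic).
* `update_test()` replaces a node's test but preserves the descendant
  structure; instances are re-routed from the edited node downwards and
  every descendant's counts *and leaf labels* are refreshed. Labels are
  recomputed deliberately: refreshing counts but not labels would
  display leaf accuracies inconsistent with the counts next to them. A
  leaf left with no rows predicts the majority class of its nearest
  ancestor that still holds rows — a state only edits can create.
* `rebuild_subtree()` replaces the test (or re-searches it) and then
  re-induces both children from scratch; rebuilding at the root with no
  replacement reproduces `induce()` exactly.

Test-set rows are routed and reported, but never influence structure,
split choice, or labels — strict train/test separation. Nodes are
addressed by left/right paths from the root (`"L.R"`), which are stable
under serialization.

## Data handling and the JSON format

Datasets are plain CSV (RFC 4180, header row). A column is continuous
iff every cell parses as a finite real, otherwise nominal; explicit
overrides win (e.g. integer-coded categories). Empty or unparseable
cells are a hard error — silent imputation would change split statistics
invisibly. Class levels are ordered by first appearance, which fixes the
confusion-matrix layout and tie-breaking everywhere. Ignored attributes
stay in the dataset but are excluded from every search. A nominal test
value unseen in training is kept as an out-of-vocabulary category and
routes right under any category test; a test-set class label unseen in
training is an error, since it has no row in the confusion matrix.

Trees serialise to a canonical JSON format (`format_version` "1.0";
JSON-Schema in `inst/extdata/tree.schema.json`): fixed key order,
numbers in shortest round-trip decimal form, and the left-routing
convention recorded in the header, so export is byte-stable and
export → import → export is byte-identical. Counts are validated on
import (children must sum to their parent) and corrupted documents are
rejected with the JSON path of the offence.

## What the generator emulates — and what it does not

`simulate_planted()` draws attribute values i.i.d. log-normal
(`meanlog = 0`, `sdlog = 1` by default), giving the strict positivity
and right skew typical of expression scales and guaranteeing WTSP
eligibility, then labels samples by a planted rule and flips labels
independently with probability `noise_rate`. This exercises everything
the inducer must do — impurity handling, weight recovery, non-perfect
splits — but deliberately models no gene–gene correlation, batch
effects, or platform noise. Passing the recovery properties therefore
shows the search machinery is correct, not that real cohorts will yield
trees this clean.

## Study sizes used by the checks

The property checks in `tests/testthat/test-acceptance.R` and the
quantities recomputed by `scripts/acceptance.R` use: 200 random small
datasets (n ≤ 30, p ≤ 6) for brute-force oracle equivalence of all
three searches; 20 seeds at n = 200, p = 50 for noise-free planted-rule
recovery (pair, and weighted pair with w = 1.5, where the recovered
weight must land between the two observed ratios straddling the true
value); 50 fixtures each for conservation/monotonicity, edit
consistency, and JSON round trips; and a single n = 100, p = 200 search
as the tractability check for exhaustive TSP/WTSP scans. These sizes
were chosen as representative desk-scale conditions for the method.

## Known limitations

* No missing-value support (by design: fail fast, no surrogate splits).
* No oblique/linear-combination tests, multiway nominal splits, k-TSP
  ensembles, or cost-sensitive weighting.
* No cross-validation, ROC/AUC, or calibration — evaluation reports
  accuracy and the confusion matrix, which is what the interactive
  workflow displays.
* Exhaustive WTSP search is quadratic in attributes with an inner sort;
  use `max_pairs` or prior feature selection beyond a few hundred
  attributes.
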