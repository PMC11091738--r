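# retree

Interactive mixed classification trees with relative-expression splits.

## What problem this solves, and for whom

Decision trees are among the few classifiers a biologist can read, but
standard tools show only the final tree and give the analyst no say in
its structure, and their axis-parallel tests (`gene >= threshold`) are
fragile across platforms and normalisation pipelines. `retree` is for
analysts of transcriptomic and other omics tables (samples × features,
one class column) who want to *build, inspect, and revise* an
interpretable tree — and who want node tests that capture within-sample
relative expression, which survives any monotone per-sample
transformation of the data.

Each internal node of a tree may carry one of three test families, mixed
freely and all ranked by the same criterion:

| family | test | detects |
|---|---|---|
| C4.5 | `attr >= t` (continuous), `attr == category` (nominal) | absolute level |
| TSP  | `attr1 < attr2` | ordering reversal between two features |
| WTSP | `attr1 < w * attr2`, `w > 0` | proportional shift between two features |

Splits are chosen by the **Gain Ratio**: information gain of the split
divided by the entropy of the branch-size distribution (bits throughout).
Thresholds are searched at midpoints between consecutive distinct sorted
values; WTSP weights at midpoints between consecutive distinct sorted
per-row ratios `v1/v2` — exhaustive over all real weights, since the
predicate changes only at observed ratios. Induction is greedy,
top-down, deterministic, and never post-pruned: pruning (`fold`),
expansion (`unfold_once` / `unfold_all`), and test replacement
(`update_test` / `rebuild_subtree`, with partial-test completion and
top-k split suggestions) are explicit, reproducible user operations that
always return freshly recomputed train/test statistics. Trees round-trip
through a canonical JSON format (schema in `inst/extdata/`).

## Worked example

```r
library(retree)

# expression-like data (log-normal, strictly positive) with a planted
# rule "g2 < g5" and 10% label noise
train <- simulate_planted(planted_pair(2, 5), n_samples = 120,
                          n_attributes = 20, noise_rate = 0.1, seed = 2024)

cfg  <- induction_config(families = c("c45", "tsp"),
                         min_node_size = 5, max_depth = 4)
tree <- induce(train, cfg)
tree
#> <retree> 7 internal node(s), 8 leaf(s), depth 4, classes: pos, neg
#> [r] g2 < g5 (59/61)
#>   [rL] g1 >= 0.5090125015997968 (51/5)
#>     [rLL] leaf -> pos (41/0)
#>     ...
```

The root recovered the planted pair rule; the deeper C4.5 and TSP nodes
are chasing the 10% label noise (exactly the subtrees an analyst would
fold away). Evaluation:

```r
evaluate(tree, train)
#> <retree_report> n=120 accuracy=0.9750
#>       predicted
#> actual pos neg
#>    pos  58   1
#>    neg   2  59
```

Training accuracy 0.975 against a noise ceiling of roughly 0.9 — the
tree has memorised noise. On an independent draw of 60 samples the
accuracy drops to 0.783, and folding the left subtree down to a leaf
(`fold(tree, "L", train)`) trades train accuracy down to 0.9417 for a
simpler model. The node's alternatives show why the root was chosen:

```r
suggest_top_splits(train, families = c("c45", "tsp", "wtsp"), k = 3,
                   min_child = 5)
#>   rank family test                        gain_ratio info_gain split_info
#> 1    1 tsp    g2 < g5                          0.509     0.507      0.997
#> 2    2 tsp    g5 < g2                          0.509     0.507      0.997
#> 3    3 wtsp   g2 < 1.003274347964616 * g5      0.509     0.507      0.997
```

Trees serialise losslessly: `export_tree(tree, "t.json")`,
`import_tree("t.json")`. `tidy()`, `glance()`, and `autoplot()` methods
give tibble and ggplot views of trees and reports.

The same workflow is scriptable from a shell via the bundled launcher
(`system.file("cli", "retree.R", package = "retree")`):

```sh
Rscript retree.R simulate --rule pair --attr1 2 --attr2 5 --n 120 --p 20 --seed 2024 --out d.csv
Rscript retree.R induce --train d.csv --class-col class --tests c45,tsp --out t.json
Rscript retree.R edit --tree t.json --train d.csv --class-col class --node L --fold --out t2.json
```

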