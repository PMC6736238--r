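---
title: "Reconstructing gene cascades from wild-type vs. mutant expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing gene cascades from wild-type vs. mutant expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genecascades)
```

## The problem

Maternal translational regulators — in *C. elegans* early embryogenesis,
RNA-binding polarity mediators such as SPN-4, MEX-1 and MEX-3 — control
blastomere fate by binding target mRNAs and regulating their translation.
Because the regulation is translational, knocking the regulator out
barely changes the *mRNA* level of its direct targets, which makes the
targets invisible to ordinary differential-expression analysis. This
package turns that observation into a prediction method: direct targets
are the genes whose expression ratio stays *inside* the bulk of the
mutant/wild-type ratio distribution, intersected with annotation evidence
(transcription-factor status, shared expression timing, shared mutant
phenotype), and each target is then expanded into its downstream cascade
through the curated interaction graph.

## The ratio model and its assumptions

For gene $i$, with wild-type level $x_i$ and mutant level $y_i$ in RPKM,
the change rate is $R_i = y_i / x_i$. Let $M$ and $Q$ be the median and
the quartile deviation — the semi-interquartile range $(Q_3 - Q_1)/2$ —
of the $R_i$ over all genes with a defined ratio. A gene fluctuates when

$$R_i < M - Q \quad\text{or}\quad M + Q < R_i,$$

and is stable when

$$M - Q < R_i < M + Q.$$

One $M$ and one $Q$ are computed per dataset (the band is global, not
per-gene). The method assumes most genes are unaffected by the mutation,
so the median tracks "no change" and the band width tracks biological and
technical ratio noise. It is a rank-based, normalization-free criterion:
multiplying every mutant level by a constant rescales $M$, $Q$ and both
bounds by the same constant and leaves every gene's class unchanged
(a property the test suite checks). No count-model testing
(DESeq2/edgeR-style) is attempted; RPKM ratios are taken as given.

Numerical choices:

* **Quartile convention.** "Quartile" is not a single convention; the
  package defaults to linear interpolation between order statistics
  (`stats::quantile` type 7) and exposes `quartile_type` because the
  convention materially changes the stable-gene count. On
  $\{1,2,3,4,5\}$ this gives $Q_1 = 2$, $Q_3 = 4$, $Q = 1$, band
  $(2, 4)$.
* **Strict bounds.** Both defining inequalities are strict, so a ratio
  exactly equal to $M \pm Q$ satisfies neither; such genes go to an
  explicit `boundary` class rather than being silently absorbed. With
  continuous data the class is almost always empty, but on small or
  discretised tables it is not, and the four classes
  (stable/fluctuating/boundary/undefined) always partition the input.
* **Division by zero.** $R_i$ is undefined at $x_i = 0$; those genes are
  classified `undefined` and excluded from the $M$/$Q$ estimate. An
  optional pseudocount $\varepsilon$ (default off) switches to
  $(y_i + \varepsilon)/(x_i + \varepsilon)$ when a user prefers to keep
  zero-wild-type genes in the analysis.
* **At least four defined ratios** are required — quartiles of fewer
  points are not meaningful.

## Direct-target criteria

`find_direct_targets()` applies four boolean filters: stability (above),
transcription-factor membership, shared expression timing, and shared
phenotype. Two of them required interpretation:

* *Simultaneous expression* is implemented as a non-empty intersection of
  categorical life-stage term sets (the timing data available in curated
  worm annotation are categorical), not as a quantitative co-expression
  score.
* *Phenotypic similarity* is implemented as set intersection with a
  configurable minimum overlap (`min_phenotype_overlap`, default 1 shared
  term). Any weighted similarity score would claim more precision than
  the underlying term lists support.

The query gene is always excluded from its own target list. For ablation
studies the `criteria` argument can drop any single filter; the test
suite uses this to verify that each planted decoy is rejected for exactly
the criterion it violates.

## Cascade expansion

`expand_cascade()` runs a breadth-first fixpoint from the target:
candidates are the targets of outgoing *regulatory* edges (directed) plus
the partners of *genetic* and *physical* edges (undirected — a
protein-protein interaction has no inherent direction), and a candidate
is accepted only if annotated as expressed in `"early embryo"` or
`"embryo"` (configurable vocabulary, `allowed_stages`). The visited set
makes termination a structural guarantee on any finite graph, cycles
included; edges between accepted nodes, including cycle-closing ones, are
retained. Downstream expansion applies only the stage filter — the
TF/phenotype criteria are target-selection criteria, not traversal
criteria. Each node carries a tier: `early_embryo` when the gene has the
"early embryo" term, `embryo` otherwise (the presumptive-early class in
network renderings).

*Bottom genes* are the nodes with zero outgoing regulatory edges inside
the cascade; genetic/physical edges carry no downstream meaning, so they
do not count toward out-degree, and self-loops are ignored. A cascade in
which every node regulates another (a pure regulatory cycle) has no such
leaf; the fallback returns the terminal strongly-connected components,
computed by a per-node reachability check (a node is terminal when
everything it reaches also reaches back). Cascades are small, so the
quadratic check is preferred over pulling in a graph library.

## Domain over-representation

The functional read-out of a cascade is the domain content of its bottom
genes. The score is the classic binomial over-representation tail: with
$n$ domain-annotated bottom genes, $k$ of them carrying a domain whose
background frequency is $p_0 = K/N_{bg}$,

$$p = P(X \ge k), \qquad X \sim \mathrm{Binomial}(n, p_0).$$

The background universe is the set of genes from the input expression
table that carry at least one domain annotation — the measured genes are
the population from which the bottom genes were drawn. Fisher's exact
(hypergeometric) tail is available via `test = "fisher"`; it differs
appreciably only when $n$ is a sizeable fraction of $N_{bg}$. The default
significance level is $\alpha = 0.05$ with no multiple-testing
correction, matching standard practice for this style of
per-cascade domain summary; results carry all of $k, n, K, N_{bg}$ so any
correction can be applied downstream.

Two policy functions sit on top:

* `filter_transcription_cascades()` removes cascades whose significant
  bottom-gene domains include a user-supplied transcription-related
  accession — a cascade ending in transcription machinery acts after the
  early-embryo window of interest. The accession list is a configuration
  input (no fixed list is hard-coded), the filter is a flag (default on,
  vacuous when the list is empty), and removals are logged with the
  triggering accession.
* `categorize_domains()` maps significant domains to functional
  categories and scores each category by the number of distinct bottom
  genes hit. Unmapped domains are tallied as `Unknown`; categories
  scoring below `min_score` (default 1) fold into `Others`. Category
  scoring runs on the *pre-filter* enrichment set in `run_pipeline()`:
  the transcription filter answers "does this cascade act later?",
  whereas the category table describes everything that was predicted —
  including transcription-flavoured cascades, which is why a
  Transcription row can coexist with the filter.

## What the synthetic generator emulates — and what it does not

`generate_fixture()` builds a complete input bundle with planted truth:

* Background genes receive log-normal ratio noise (log2 ratios
  $\mathcal{N}(0, 0.6)$) with a 15 % fluctuating tail displaced by
  `fluct_shift` (default 2 log2 units), so the median/quartile machinery
  sees a realistically skewed, heavy-shouldered distribution in which
  roughly half the genes fall outside the band — comparable to real
  mutant-vs-wild-type comparisons, where under half of the detected genes
  classify as stable.
* Planted targets are TFs sharing a stage and phenotype with the query;
  their ratios are clamped into the inner decile band of the background
  ratios, and the generator *asserts* they classify stable (construction,
  not luck). Four decoys each violate exactly one criterion.
* Each target roots a regulatory tree (`branching` branches of depth
  `cascade_depth`) over embryo-annotated genes; the first branch's leaf
  has a physically interacting embryonic partner (exercising undirected
  traversal; it is itself a bottom gene) and each target has a larva-only
  neighbor the stage filter must exclude. Bottom genes of a cascade share
  a signature domain accession, making the cascade's function
  recoverable by enrichment.
* Defaults: 200 genes, 3 targets, depth 4, branching 2, 15 % TFs, 70 %
  embryonic background. These sizes keep the full suite fast while
  leaving every code path (cycles aside) exercised; cyclic and
  adversarial graphs are covered separately by randomized property tests
  against an independent reachability oracle.

The generator does **not** simulate read counts, length/GC biases,
replicate variance, or the incompleteness and bias of curated interaction
databases. Passing the planted-recovery tests therefore shows the
*algorithmic* contract (exact recovery when the annotation evidence is
complete and noiseless), not expected performance on real data, where
annotation gaps dominate the error budget.

## Known limitations

* Ratio thresholding inherits RPKM's weaknesses; genes with $x_i = 0$
  are unclassifiable without a pseudocount, and low-expression genes have
  noisy ratios that the global band treats like any other.
* The direct-target definition requires curated TF, stage and phenotype
  annotation; a true target missing any annotation is unrecoverable.
* Cascade membership is boolean — no edge confidence, no weighting — and
  expansion is as complete (or incomplete) as the interaction extract.
* The binomial test treats domains independently; genes carrying many
  domains contribute to several tests.

## End-to-end run

```{r pipeline}
dir <- tempfile()
fix <- generate_fixture(fixture_spec(seed = 1))
write_fixture(fix, dir)
out <- file.path(dir, "out")
cfg <- run_config(expression = file.path(dir, "expression.tsv"),
                  annotations_dir = dir, query_gene = "qry-1",
                  out_dir = out)
res <- run_pipeline(cfg)
str(res$manifest$counts)
res$categories
```

The manifest records every filter's in/out counts, so the bookkeeping of
an analysis (genes in, stable genes, targets, cascades, bottom genes,
enriched domains) is reproducible from the output directory alone; two
runs on identical inputs are byte-identical.
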