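---
title: "Trio-based differential methylation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio-based differential methylation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methtrio)
```

## The problem

Families in which a child and exactly one parent share a phenotype — here,
genetic generalized epilepsy — offer a built-in contrast: at any CpG site
where methylation tracks the phenotype, the affected child–parent pair
should sit together and apart from the unaffected parent. methtrio turns
that idea into a scored, testable pipeline for Illumina 450K-style beta
values (methylation fractions in $[0,1]$, computed from intensities as
$\beta = M/(M+U+100)$).

The pipeline has two arms. The **trio arm** is threshold- and score-based:
it calls per-CpG methylation states, applies the trio rule, scores
qualifying CpGs, aggregates to gene lists, and hands those lists to an
active-subnetwork pathway enrichment. The **pooled (dual) arm** compares
all affected samples against all unaffected samples with conventional
sitewise tests and provides gene-level group means for dual-color pathway
annotation. The two arms are deliberately independent: in cohorts of this
size the pooled t-test typically yields nothing after FDR control, and the
dual arm serves annotation and visualization rather than discovery.

## Methylation states and the trio rule

A beta value is **hypo-methylated** when $\beta \le 0.2$ and
**hyper-methylated** when $\beta \ge 0.8$; everything between is
intermediate. The bands are implemented as closed intervals — the sources
for such cutoffs say "between 0.0 and 0.2" without specifying openness,
and closing them makes the boundary triples that attain the minimum score
representable. Both cutoffs are arguments (`hypo_max`, `hyper_min`)
throughout.

A CpG **qualifies** for a trio when child ($C$) and affected parent
($PA$) are both in one band and the unaffected parent ($PU$) is in the
opposite band. Qualifying CpGs are scored with the trio-based scoring
scheme (TbSSch):

$$\mathrm{TbSSch} = \frac{(C-0.5) + (PA-0.5) + (0.5-PU)}{1.5}
\quad\text{(affected pair hyper)}$$

and the mirrored expression for the affected-hypo direction. Each term
measures one member's distance from the 0.5 midline in the direction the
rule expects, and the normalizer 1.5 is the maximum attainable sum, so
qualifying scores live in $[0.6, 1]$: 0.6 exactly at the band boundaries
$(0.8, 0.8, 0.2)$, 1 at complete separation $(1, 1, 0)$. The score is
symmetric under reflection $\beta \mapsto 1-\beta$ with the direction
flipped, which the test suite checks property-style.

## Gene lists

Each qualifying CpG is mapped to its annotated gene(s); a multi-gene probe
supports every gene it is annotated to (the 450K manifest convention). A
gene's score is the **maximum** TbSSch over its supporting CpGs — the list
ranks genes by their single best CpG rather than an average, keeping a
strong single-locus signal visible. Lists are built genome-wide and, in a
second pass, restricted to promoter links (TSS200/TSS1500 region groups).
A gene may enter a list through CpGs of opposite directions; both
directions are retained and reported. The **family pool** contains genes
appearing in more than one trio's list (multiplicity $\ge 2$, strictly),
again at their maximum score. Sorting is by descending score with
lexicographic gene-symbol tie-break, so output files are reproducible
byte-for-byte.

Downstream enrichment consumes per-gene p-values. TbSSch is a separation
score, not a test statistic, and no calibrated conversion exists; the
package uses the documented convention $p = \max(1-\mathrm{score},
10^{-6})$, strictly decreasing in the score. These values rank genes; they
are not significance claims, and `scores_to_pvalues()` says so in its
documentation.

## Active-subnetwork pathway enrichment

Gene p-values become z-scores $z = \Phi^{-1}(1-p)$, and a gene set's
aggregate is $z_A = \sum z_i / \sqrt{k}$, which keeps sets of different
sizes comparable. The classical active-modules formulation searches by
simulated annealing; methtrio instead uses a **deterministic greedy
seed-and-extend**: from each of the top 20 genes by z, repeatedly add the
neighboring node that maximizes $z_A$, stopping when the best addition
would decrease it or the subnetwork reaches 50 members. Candidates are
accepted in descending $z_A$ order subject to pairwise overlap at most
50%, up to 5 subnetworks. Determinism (ties broken lexicographically)
makes runs reproducible and testable; the trade-off is that greedy search
carries no optimality guarantee, and a test logs the greedy-to-exhaustive
$z_A$ ratio on small graphs rather than asserting optimality. Overlap
between subnetworks is measured relative to the smaller set,
$|a \cap b| / \min(|a|,|b|)$. Network genes without a score receive
$p = 1$ (clamped just below 1), so they join only when topology demands.
Monte-Carlo calibration of $z_A$ against random gene sets is omitted; raw
$z_A$ ranks candidates.

Each subnetwork is tested against every pathway with a **two-sided
hypergeometric test** (enrichment or depletion) using the
minimum-likelihood method: the p-value sums all point probabilities in the
support not exceeding that of the observed overlap (a doubled-tail variant
is available behind a flag). The direction is enriched when the overlap is
at or above its expectation $n K / N$. Bonferroni correction uses $m =$
the number of pathways tested **per subnetwork**, matching the
per-pathway-list reading of the procedure; a pathway significant in
several subnetworks is reported once at its most significant occurrence.
The background universe defaults to the union of all pathway genes and can
be supplied explicitly.

## The pooled arm

The rescaling map used for dual-color annotation applies
$y = C + (x-A)(D-C)/(B-A)$ piecewise — $[0, 0.5] \to [-1, 0]$ and
$[0.5, 1] \to [0, 1]$. Both pieces reduce to $y = 2x - 1$; the tests
verify the identity on a $10^{-3}$ grid and the agreement of both pieces
at $x = 0.5$. Gene-level group means are computed over CpG-island probes
only, per group, and a gene is flagged **dual** when its two rescaled
means differ by more than 0.05 on the scaled axis (configurable; the
original criterion is rendering-based, so any operationalization is a
choice). Sitewise testing uses the Welch unequal-variance t-test — the
sources say only "t-test", and Welch is the safer default — with
Benjamini–Hochberg adjustment across probes. The heatmap stage selects the
1000 highest-variance probes by default and clusters probes and samples
with average-linkage hierarchical clustering on Euclidean distances;
distance and linkage are unstated in the sources and documented here as
package defaults.

## What the simulator emulates — and what it does not

`simulate_trio_betas()` emulates the *structure* of a 15-trio, 45-sample
450K cohort at reduced scale: a bimodal marginal beta distribution,
probes annotated to genes, promoter blocks and islands, a few `rs` and
X/Y probes for the filters, and planted trio-differential events. The
background model draws a mixture component — Beta(0.5, 10) (low) or
Beta(10, 0.5) (high), weight 0.5 — **once per probe**, and all samples at
that probe i.i.d. from that component. This matches how arrays behave: a
CpG has a characteristic methylation state, and bimodality is a
cross-probe phenomenon. The alternative (redrawing the component per
sample) would make family members independent at every probe and the trio
rule would fire on roughly 22% of background probes — a regime no real
array exhibits and in which no planted signal could be ranked. Under the
probe-level model the analytic chance-qualifier rate,
$\sum_c w_c \left[ p_{\mathrm{hyper}|c}^2\, p_{\mathrm{hypo}|c} +
p_{\mathrm{hypo}|c}^2\, p_{\mathrm{hyper}|c} \right]$, is about
$2 \times 10^{-8}$ with the default mixture; the calibration test
therefore also runs a permissive flat Beta(2, 2) mixture where the rate
($\approx 2.2 \times 10^{-3}$) is large enough for a meaningful binomial
comparison.

Planted events overwrite the affected pair with draws from $[0.85, 1]$
and the unaffected parent from $[0, 0.15]$ (or mirrored; directions
alternate), guaranteeing qualification with TbSSch $\ge 0.7$. The same
probes are planted in every trio — one probe per planted gene, preferring
promoter links so the promoter-scope pipeline is exercised — which makes
the family pool recover the planted gene set. The companion network
simulator wires the planted genes into a clique on top of an Erdős–Rényi
background (default edge probability 0.003, mean degree ≈ 6 at 2,000
genes) and emits one planted pathway plus 20 random decoys.

The simulator does **not** model: intensity-level artifacts, probe-type
chemistry, batch effects, age or cell-composition covariates, within-family
genetic correlation of methylation, or linkage disequilibrium between
probes. Passing recovery tests therefore demonstrates that the pipeline's
logic is correct and sensitive under its stated model — not that the
biological findings of any particular cohort would be reproduced.

## Reference problem sizes and study conditions

The recovery study runs 13 trios × 20,000 probes × 2,000 genes with 0.2%
planted probes (40 events per trio), over 20 independent seeds; the suite
asserts ≥ 95% planted-event recovery per seed and planted-pathway rank 1
in at least 18 of 20 seeds. The trio-rule equivalence check runs 13 trios
on 10,000-probe matrices for 20 seeds against an independent state-scan
oracle. The null pooled-arm simulation uses 1,000 probes at 6 vs 6
samples. These sizes are the package's reference conditions; all are
arguments.

One numerical caveat measured during development: with the extreme bimodal
background mixture at 6 samples per group, the Welch test is
*conservative* (empirical type-I rate near 0.02–0.03 at nominal 0.05) —
a known small-sample property under strong skew. The null-calibration
check therefore draws from the smooth symmetric Beta(2, 2), where nominal
calibration is the property actually under test; the conservatism under
bimodal nulls is a limitation users should expect on real beta values at
these sample sizes.

## Numerical and degenerate-input choices

* Hypergeometric ties: point probabilities equal to the observed one are
  included using a relative tolerance of $10^{-7}$, guarding against
  floating-point noise in `dhyper`.
* `greedycut_like` (the simplified reliability filter; the original
  procedure is delegated to an external package in the sources, without
  parameters): detection-p threshold 0.05, stop fraction 0.05, ties broken
  probe-before-sample then lexicographically; removing everything warns
  rather than errors; the filter is idempotent on its own output.
* Missing betas: a trio triple with any missing member is skipped for that
  probe and trio; sitewise tests require two non-missing values per group
  and skip zero-variance probes with a recorded reason.
* Probes without annotation are retained by default (they cannot reach a
  gene list) and can be dropped; `chrX`-style labels are normalized.
* All output writers fix column order, number formatting, and line
  endings, so identical inputs give byte-identical files.
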