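---
title: "Methods: weighted TF regulatory networks from differential co-expression"
author: "dcTFnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted TF regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcTFnet)
```

# The problem

In two-condition expression studies (tumour versus non-tumour tissue being the
motivating case) a transcription factor (TF) can matter in two distinguishable
ways: its own transcript can change, and — more subtly — its *coupling* to its
target genes can change, even when mean levels barely move. `dcTFnet`
implements a pipeline that ranks candidate TFs by combining both signals: it
weights every TF→target edge of a user-supplied regulatory network by how much
its within-group rank correlation differs between the two groups, keeps edges
whose differential coupling beats a permutation null, scores each hub TF's
subnetwork with a GSEA-style running-sum enrichment statistic, trims it to the
leading edge, scores the trimmed gene set against the genome-wide differential
expression profile, and ranks TFs by the sum of the two standardized scores.

The edge list is deliberately generic (two-column TSV): any curated TF→target
resource can be supplied. Probe-level preprocessing (e.g. RMA) is upstream and
out of scope; the pipeline consumes an already-normalized log2 matrix.

# The model, stage by stage

## Differential expression

For gene $i$ with group sample sizes $n_1, n_2$, the log2 fold change is the
difference of group means (group 2 minus group 1, groups ordered by sorted
label). The pooled residual variance $s_i^2$ on $d = n_1 + n_2 - 2$ df is
moderated toward the prior $s_0^2 = \operatorname{mean}_i(s_i^2)$:

$$\tilde{s}_i^2 = \frac{d_0 s_0^2 + d\, s_i^2}{d_0 + d}, \qquad
t_i = \frac{\Delta_i}{\sqrt{\tilde{s}_i^2 (1/n_1 + 1/n_2)}},$$

with $t_i$ referred to a $t$ distribution on $d + d_0$ df. The prior df
$d_0$ (`priorDf`, default 4) sets the moderation strength; $d_0 = 0$ recovers
the classical pooled t-test exactly (the identity our test suite exploits as an
oracle), and $d_0 = \infty$ pins every variance at $s_0^2$. A gene is flagged
a DEG when $p < 0.05$ **and** $|\log_2 FC| > 1.5$, both strict; the p here is
the raw p, with the Benjamini–Hochberg adjusted value reported alongside. This
raw-p reading is a deliberate choice (the cut-off pair is conventional in the
microarray literature this pipeline serves); both thresholds are arguments.

## Edge weighting

For edge $E_{ij}$ (TF $V_i$, target $V_j$) the Spearman coefficient
$r_{E_{ij}g}$ is computed within each group $g$ as the Pearson correlation of
average ranks (ties share the mean rank). Two derived quantities follow:

$$\text{weight} = \tfrac12\,|r_{E_{ij}1} + r_{E_{ij}2}|, \qquad
\delta = \tfrac12\,|r_{E_{ij}1} - r_{E_{ij}2}|.$$

The weight captures coupling that is consistent across conditions; $\delta$
(the *differential coefficient*) captures coupling that changes. They satisfy
$\text{weight} + \delta \le 1$. A constant within-group expression vector has
undefined ranks; its coefficient is defined as 0 with a warning, which is
conservative for both quantities.

## Permutation filter

The null for $\delta$ is built by reshuffling the sample→group assignment
(group sizes preserved) `nPermutations` times (default 1000, minimum 100) and
recomputing every edge's $\delta$; all null deltas are pooled and the threshold
is their 0.90 quantile (configurable). Pooling across edges rather than
per-edge nulls was chosen for stability at practical permutation counts: with
$P$ permutations a per-edge null has only $P$ values, while the pool has
$P \times |E|$. Under the default `keep_above` mode an edge passes iff
$\delta$ exceeds the threshold — retaining differentially co-regulated edges,
which is the biologically coherent direction for a pipeline whose later stages
rank edges *by* $\delta$. The inverted `drop_above` mode is provided for the
literal "high deltas are excluded" reading. On pure-null data `keep_above` at
quantile $q$ passes $\approx 1-q$ of edges by construction; the acceptance
suite verifies 0.10 ± 0.03 at $q = 0.90$.

## Subnet enrichment score

TFs with out-degree $> 15$ (strict) are hubs. For hub $T$, the background $E$
is *all* passing edges ranked by $\delta$ descending (ties broken by
`tf->target` id for determinism), the objective set $S$ is $T$'s passing
edges, and with $r_j$ the $\delta$ of the $j$-th ranked edge and $P = 1$:

$$P_{hit}(S, i) = \sum_{E_j \in S,\, j \le i} \frac{|r_j|^P}{N_R},\quad
N_R = \sum_{E_j \in S} |r_j|^P; \qquad
P_{miss}(S, i) = \sum_{E_j \notin S,\, j \le i} \frac{1}{N - N_H}.$$

The enrichment score is the maximum deviation $\max_i\,(P_{hit} - P_{miss})$.
Because both curves end at 1, the positive-deviation maximum is always
$\ge 0$ and $ES \in [-1, 1]$; an absolute-deviation convention is available
(`convention = "absolute"`) for users who want the two-sided statistic. The
$P_{miss}$ membership condition is the standard GSEA complement
($E_j \notin S$), the only reading under which the $N - N_H$ denominator makes
the curve end at 1. Members at ranks up to the ES position form the leading
edge; members beyond it do not contribute and are trimmed.

The null is `nNull` (default 1000) uniform size-matched subsets of $E$ drawn
without replacement, giving $Z_s = (ES - \overline{ES})/S'$. A null with zero
spread is flagged degenerate ($Z_s =$ NA) rather than divided through.

## Gene-level score and combined ranking

The trimmed subnet's distinct target genes (plus the TF itself when expressed;
`includeTf = TRUE` by default, on the view that a regulator belongs to its own
module — configurable) are scored against the whole expression universe ranked
by $-\log_{10} p$ descending, with $r_j = -\log_{10} p_j$ and the same
running-sum engine. $-\log_{10} p$ is used because the ranking is by p-value
while $r_j$ must measure the magnitude of differential expression; the
negative log satisfies both monotonically (p is floored at the smallest
positive double first). A $|\log_2 FC|$ weighting is a documented alternative.
$Z_{trimmed}$ standardizes against size-matched random gene sets, and the
final ranking key is

$$Z_{combined} = Z_s + Z_{trimmed},$$

the raw sum of the two standardized scores; an optional mode re-standardizes
each component across the scored TFs before summing (useful when the two
scales differ wildly across a large hub set). Ties are broken
lexicographically by TF id, degenerate scores sort last, and the top
`topK` (default 5) TFs are reported with their regulated DEGs.

# The synthetic-data generator

The generator exists so that every stage can be tested against *known* truth
at desk scale. It emulates:

* two unequal groups (defaults 23 vs 77, the unbalanced design typical of
  tumour/non-tumour GEO series) of log2-scale Gaussian expression,
  $N(8, \sigma^2)$ with $\sigma = 0.5$ by default — the magnitude and spread
  of RMA-normalized microarray intensities;
* planted DEGs: a mean shift of `degLog2fc` (default 2.0) in group 2;
* a TF→target network with configurable hub sizes;
* planted differential co-regulation: for each target of a planted TF,
  $z_{target} = \rho_g z_{tf} + \sqrt{1 - \rho_g^2}\,\epsilon$ within group
  $g$ (defaults $\rho_1 = 0.8$, $\rho_2 = -0.2$) — a Gaussian copula
  construction whose *population* within-group correlation is exactly
  $\rho_g$, which makes Monte-Carlo recovery tests sharp;
* null genes and edges carrying no systematic signal.

By default planted DEGs avoid planted-TF targets so the two signals can be
studied separately; `overlapDegsWithPlantedTargets = TRUE` draws the DEGs from
the planted hub's targets instead, producing the fully-coupled scenario the
end-to-end recovery test uses (a hub that is both differentially co-regulated
and regulates DEGs must rank first).

What it does **not** emulate: probe-level artifacts, batch effects,
heavy-tailed or count-distributed expression, correlated null genes
(co-expression modules), and overlapping TF modules. Passing tests therefore
demonstrate correctness of the machinery and calibration under a clean
Gaussian world, not performance on real arrays — on real data the permutation
null absorbs some but not all of these violations.

# Numerical and design choices

* **Group order.** Group levels are the two labels sorted; log2FC is level 2
  minus level 1. Swapping labels negates every fold change and leaves p,
  weight and $\delta$ unchanged (tested).
* **Determinism.** Every stochastic step takes an explicit seed; the pipeline
  derives per-stage seeds from one master seed, and reruns are byte-identical
  on the result tables. Numeric TSV output uses 15 significant digits.
* **Tie-breaks.** Edge ranking ties break by edge id, gene ranking ties by
  gene id, ranking ties by TF id — all lexicographic, all deterministic.
* **Degenerate inputs.** Zero-variance genes get an infinitesimal-variance
  guard ($p = 1$ when the fold change is 0); constant vectors get $\rho = 0$;
  zero-spread nulls flag the score degenerate instead of producing $\pm\infty$.
* **Degrees.** Hub degree is counted on the filtered network by default;
  `degreeSource = "all"` counts the unfiltered degree, which is the right
  choice when the filter is aggressive and one wants all nominal hubs to
  compete in the ranking (the end-to-end recovery analysis uses it for exactly
  that reason).
* **Problem sizes in the test suite.** The suite calibrates the permutation
  filter on 1,000-edge networks at 30+30 samples with 500 permutations across
  10 seeds, checks DEG recovery on 1,000-gene matrices across 10 seeds, and
  runs the full pipeline 100 times at 300 genes / 10 hubs / 25 targets each —
  sizes chosen so each property is measured with useful precision while the
  whole suite stays comfortably interactive.

# A worked run

```{r example, eval = FALSE}
cfg <- simulationConfig(nGroup1 = 15, nGroup2 = 15, nGenes = 300, nTfs = 10,
                        targetsPerTf = c(25, 25), nPlantedDegs = 25,
                        degLog2fc = 2, nPlantedDiffcoregTfs = 1,
                        plantedRhoGroup1 = 0.8, plantedRhoGroup2 = -0.2,
                        seed = 7, overlapDegsWithPlantedTargets = TRUE)
res <- runAll(pipelineConfig(outDir = "run1", seed = 7, simulate = cfg,
                             nPermutations = 200, nNull = 300,
                             degreeSource = "all"))
res$ranking[1:3, c("tf_id", "z_s", "z_trimmed", "z_combined", "rank")]
res$truth$true_diffcoreg_tf_ids
```

The planted TF tops the table with a combined Z several units above the null
hubs; the README shows the exact numbers this produces.

# Known limitations

* Only the two-group design is supported; no covariates or contrasts.
* Over-representation analysis is the plain one-sided hypergeometric test;
  no ontology graph propagation or EASE-style score variants.
* Hub subnets are scored independently; overlapping regulons are not merged
  and shared targets count for every TF that reaches them.
* The permutation null reshuffles whole samples, so it preserves gene–gene
  correlation under the null but assumes exchangeability of samples across
  groups (no batch structure).
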